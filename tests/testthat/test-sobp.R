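test_that("beam spectrum constructor enforces invariants", {
  expect_error(beam_spectrum("C12", c(200, 150), c(1, 1)), "increasing")
  expect_error(beam_spectrum("C12", c(150, 200), c(1, -1)), ">= 0")
  expect_error(beam_spectrum("C12", c(150, 200), c(0, 0)), "positive")
  expect_error(sobp_plan(138, 78), "proximal")
})

test_that("profile interpolation: endpoint identity, linear midpoint, count", {
  set <- fix_profile_set("C12", "water")
  anchor_e <- 230
  q <- profile_at(set, anchor_e)
  j <- which(abs(set$energies - anchor_e) < 1e-9)
  expect_identical(q$physical, set$physical[, j])
  # midpoint between adjacent dense energies is the arithmetic mean
  mid <- profile_at(set, set$energies[10] + 0.5)
  expect_equal(mid$physical,
               (set$physical[, 10] + set$physical[, 11]) / 2,
               tolerance = 1e-12)
  expect_error(profile_at(set, max(set$energies) + 5), "extrapolation")
  expect_error(interpolate_profiles(list(list(energy = 1)), 1), "2 simulated")
})

test_that("the oxygen anchor set {177,237,297,345,418} with 1 MeV/u steps
           yields 242 dense profiles", {
  ph <- water_phantom(250)
  anchors <- lapply(c(177, 237, 297, 345, 418), function(E)
    list(energy = E,
         dose = suppressWarnings(depth_dose_profile(E, "O16", ph, grid_step = 2))))
  set <- interpolate_profiles(anchors, step = 1)
  expect_equal(length(set$energies), (418 - 177) + 1)
  expect_equal(length(set$energies), 242)
  # anchors reproduced exactly within the dense set
  j <- which(set$energies == 297)
  expect_equal(set$physical[, j], anchors[[3]]$dose$dose, tolerance = 1e-12)
})

test_that("a single flat profile gets weight target/value", {
  depth <- seq(0, 200, by = 1)
  v <- 4
  col <- rep(v, length(depth))
  col[length(col)] <- v * (1 + 1e-9)   # place the formal peak distally
  set <- structure(list(depth = depth, energies = 250,
                        physical = matrix(col, ncol = 1),
                        biological = matrix(col, ncol = 1),
                        species = get_species("C12")),
                   class = "sobp_profile_set")
  w <- optimize_sobp_weights(set, sobp_plan(78, 138), target_value = 3)
  expect_equal(w$components$weight, 3 / v, tolerance = 1e-9)
})

test_that("NNLS matches a brute-force grid search on a 2-energy toy", {
  A <- matrix(c(1.0, 0.6, 0.1,
                0.2, 0.7, 1.1), ncol = 2)
  b <- c(1, 1, 1)
  fit <- nnls_fit(A, b)
  grid <- seq(0, 2, by = 0.002)
  sse <- outer(grid, grid, function(w1, w2)
    colSums((matrix(b, 3, length(w1)) -
             A %*% rbind(w1, w2))^2))
  best <- which(sse == min(sse), arr.ind = TRUE)[1, ]
  expect_lte(fit$deviance, min(sse) + 1e-9)
  expect_equal(fit$x, c(grid[best[1]], grid[best[2]]), tolerance = 0.005)
})

test_that("NNLS matches an independent quadratic-programming oracle", {
  set.seed(31)
  for (rep in 1:5) {
    A <- matrix(runif(20 * 5), 20, 5)
    b <- runif(20, 0, 2)
    fit <- nnls_fit(A, b)
    qp <- quadprog::solve.QP(Dmat = crossprod(A), dvec = crossprod(A, b),
                             Amat = diag(5), bvec = rep(0, 5))
    expect_equal(fit$x, qp$solution, tolerance = 1e-6)
  }
})

test_that("NNLS solution beats 1000 random non-negative weight vectors", {
  set <- fix_profile_set("C12", "water")
  rows <- which(set$depth >= 78 & set$depth <= 138)
  A <- set$biological[rows, ]
  b <- rep(1, length(rows))
  fit <- nnls_fit(A, b)
  set.seed(99)
  scale <- mean(fit$x[fit$x > 0])
  for (i in 1:1000) {
    w <- runif(ncol(A), 0, 2 * scale)
    expect_lte(fit$deviance, sum((b - A %*% w)^2))
  }
})

test_that("optimized SOBP is flat and its biological dose is flatter than
           the physical dose", {
  set <- fix_profile_set("C12", "water")
  plan <- fix_plan()
  beam <- fix_sobp_beam("C12", "water")
  expect_lte(attr(beam, "flatness"), plan$flatness_tolerance)
  prof <- biological_dose_profile(beam, set, plan = plan)
  rows <- set$depth >= plan$proximal & set$depth <= plan$distal
  flat_phys <- max(abs(prof$physical[rows] / mean(prof$physical[rows]) - 1))
  expect_lte(prof$flatness, flat_phys)
  # entrance dose below the SOBP level, as for measured SOBPs
  expect_lt(prof$entrance_to_sobp, 1)
})

test_that("optimizer reports infeasibility instead of returning a bad fit", {
  set <- fix_profile_set("C12", "water")
  plan <- sobp_plan(78, 138, flatness_tolerance = 1e-9)
  # a 2-anchor interpolated set cannot reach 1e-9 flatness
  sub <- set
  keep <- c(1, length(set$energies))
  sub$energies <- set$energies[keep]
  sub$physical <- set$physical[, keep]
  sub$biological <- set$biological[, keep]
  expect_error(optimize_sobp_weights(sub, plan), "flatness|cover")
})

test_that("stable-to-radioactive mapping preserves peak depths and weights", {
  bs <- fix_sobp_beam("C12", "water")
  b11 <- map_weights_to_radioactive(bs, "C11")
  expect_identical(b11$components$weight, bs$components$weight)
  # identity species: energies unchanged (idempotent)
  b12 <- map_weights_to_radioactive(bs, "C12")
  expect_equal(b12$components$energy, bs$components$energy, tolerance = 1e-12)
  # endpoints map exactly to the energies whose ranges match the stable ones
  e <- bs$components$energy
  expect_equal(range_from_energy(min(b11$components$energy), "C11"),
               range_from_energy(min(e), "C12"), tolerance = 1e-9)
  expect_equal(range_from_energy(max(b11$components$energy), "C11"),
               range_from_energy(max(e), "C12"), tolerance = 1e-9)
  # verified through the depth-dose peak finder, within one grid step
  ph <- water_phantom(250)
  for (pick in c(which.min(e), which.max(e))) {
    p_stable <- peak_depth(depth_dose_profile(e[pick], "C12", ph, grid_step = 0.5))
    p_rad <- peak_depth(depth_dose_profile(b11$components$energy[pick], "C11",
                                           ph, grid_step = 0.5))
    expect_lte(abs(p_stable - p_rad), 0.5)
  }
})

test_that("biological dose reduces to physical dose when RBE is one", {
  set <- fix_profile_set("C12", "water")
  beam <- fix_sobp_beam("C12", "water")
  unit_rbe <- structure(data.frame(depth = set$depth, rbe_mean = 1, rbe_sd = 0),
                        class = c("rbe_profile", "data.frame"))
  prof <- biological_dose_profile(beam, set, rbe = unit_rbe)
  expect_equal(prof$biological, prof$physical, tolerance = 1e-12)
  bad <- beam_spectrum("C12", min(set$energies) + 0.123, 1)
  expect_error(biological_dose_profile(bad, set), "grid mismatch")
})

test_that("beam spectrum TSV round trip", {
  bs <- fix_sobp_beam("C12", "water")
  path <- tempfile(fileext = ".tsv")
  write_beam_spectrum(bs, path)
  back <- read_beam_spectrum(path)
  expect_equal(back$components$energy, bs$components$energy, tolerance = 1e-8)
  expect_equal(back$components$weight, bs$components$weight, tolerance = 1e-8)
  expect_equal(back$species$name, "C12")
})
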