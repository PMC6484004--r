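test_that("spill schedule invariants and window arithmetic", {
  expect_error(spill_schedule(beam_off = -1), "beam_off")
  expect_error(spill_schedule(n_spills = 0), "n_spills")
  s <- spill_schedule()
  # inter-spill window k = [k*3.3 - 1.4, k*3.3)
  expect_equal(interspill_window(s, 1), c(1.9, 3.3))
  expect_equal(interspill_window(s, 5), c(5 * 3.3 - 1.4, 16.5))
  expect_equal(irradiation_end(s), 19 * 3.3 + 1.9)
})

test_that("stable beam with fragmentation off produces no events", {
  beam <- beam_spectrum("C12", 250, 1)
  ev <- simulate_treatment(beam, water_phantom(250), spill_schedule(),
                           n_primaries = 5000, fragment_prob = 0, seed = 1)
  expect_equal(nrow(ev), 0)
})

test_that("event simulation is bit-identical for a fixed seed", {
  beam <- beam_spectrum("C10", c(230, 260), c(1, 2))
  ev1 <- simulate_treatment(beam, water_phantom(250), spill_schedule(),
                            n_primaries = 2e4, seed = 77)
  ev2 <- simulate_treatment(beam, water_phantom(250), spill_schedule(),
                            n_primaries = 2e4, seed = 77)
  expect_identical(ev1, ev2)
  expect_true(all(ev1$t_s >= 0))
  expect_true(all(ev1$z_mm >= 0 & ev1$z_mm <= 250))
})

test_that("fragment fractions must sum to one", {
  beam <- beam_spectrum("C12", 250, 1)
  expect_error(simulate_treatment(beam, water_phantom(250),
                                  fragment_fractions = c(C11 = 0.5, C10 = 0.2,
                                                         O15 = 0.2), seed = 1),
               "sum to 1")
})

test_that("decays follow the exponential law: half in the first half-life,
           window counts match N(exp(-l t1) - exp(-l t2))", {
  # one near-instantaneous spill: all stopping times ~ 0
  sched <- spill_schedule(n_spills = 1, beam_on = 1e-6, beam_off = 1.4)
  beam <- beam_spectrum("C10", 250, 1)
  n <- 2e4
  ev <- simulate_treatment(beam, water_phantom(250), sched, n_primaries = n,
                           fragment_prob = 0, seed = 13)
  expect_equal(nrow(ev), n)   # every radioactive primary decays
  T_half <- 19.29
  lambda <- log(2) / T_half
  expect_lt(abs(sum(ev$t_s < T_half) - n / 2), 4 * sqrt(n / 2))
  for (w in list(c(0, 10), c(10, 40), c(40, 120))) {
    expe <- n * (exp(-lambda * w[1]) - exp(-lambda * w[2]))
    expect_lt(abs(sum(ev$t_s >= w[1] & ev$t_s < w[2]) - expe),
              4 * sqrt(expe))
  }
  # recovered half-life (exponential MLE) within 3 SE of 19.29 s
  T_hat <- log(2) * mean(ev$t_s)
  expect_lt(abs(T_hat - T_half), 3 * T_hat / sqrt(n))
})

test_that("first-interspill event count orders by half-life: 10C > 11C", {
  sched <- spill_schedule()
  w1 <- interspill_window(sched, 1)
  counts <- sapply(c("C10", "C11"), function(sn) {
    beam <- beam_spectrum(sn, 250, 1)
    ev <- simulate_treatment(beam, water_phantom(250), sched,
                             n_primaries = 1e5, seed = 4)
    sum(ev$t_s >= w1[1] & ev$t_s < w1[2])
  })
  expect_gt(counts["C10"], counts["C11"])
})

test_that("binning: empty sets, single events, additivity, bad windows", {
  beam <- beam_spectrum("C10", 250, 1)
  ev <- simulate_treatment(beam, water_phantom(250), spill_schedule(),
                           n_primaries = 5000, seed = 2)
  expect_error(bin_events(ev, c(5, 1)), "inverted")
  m0 <- bin_events(ev[0, ], c(0, 10),
                   bounds = list(x = c(-45, 45), y = c(-45, 45), z = c(0, 250)))
  expect_equal(sum(m0$counts), 0)
  # one event at a voxel centre -> one count in that voxel
  one <- data.frame(x_mm = 0.75, y_mm = 0.75, z_mm = 0.75, t_s = 1,
                    species = "C10", origin = "primary")
  m1 <- bin_events(one, c(0, 10), voxel = 1.5,
                   bounds = list(x = c(0, 15), y = c(0, 15), z = c(0, 15)))
  expect_equal(sum(m1$counts), 1)
  expect_equal(m1$counts[1, 1, 1], 1)
  # disjoint windows add up to the union
  ma <- bin_events(ev, c(0, 30)); mb <- bin_events(ev, c(30, 70))
  mu <- bin_events(ev, c(0, 70))
  expect_equal(ma$counts + mb$counts, mu$counts)
  # dropped events are counted
  mnar <- bin_events(ev, c(0, 1e5),
                     bounds = list(x = c(-2, 2), y = c(-2, 2), z = c(0, 250)))
  expect_gt(attr(mnar, "n_dropped"), 0)
  expect_equal(sum(mnar$counts) + attr(mnar, "n_dropped"), nrow(ev))
})

test_that("Gaussian blur conserves intensity and has the right width", {
  counts <- array(0, dim = c(21, 21, 21))
  counts[11, 11, 11] <- 100
  map <- structure(list(counts = counts, voxel = 1.5, window = c(0, 1),
                        origin = c(0, 0, 0)), class = "annihilation_map")
  expect_identical(blur_map(map, 0), map)
  bl <- blur_map(map, 3.5)
  expect_equal(sum(bl$counts), 100, tolerance = 1e-6)
  # impulse-response second moment = sigma^2 per axis within 1%
  sigma <- 3.5 / (2 * sqrt(2 * log(2)))
  x <- (seq_len(21) - 11) * 1.5
  for (axis in 1:3) {
    prof <- apply(bl$counts, axis, sum)
    v <- sum(prof * x^2) / sum(prof)
    expect_equal(v, sigma^2, tolerance = 0.01)
  }
  expect_error(blur_map(map, -1), "fwhm")
})

test_that("annihilation depth structure: radioactive beams concentrate at
           stopping depths, stable beams light the whole path", {
  sched <- spill_schedule()
  ph <- water_phantom(250)
  irr <- irradiation_end(sched)
  post <- c(irr, irr + 300)
  # monoenergetic radioactive beam: post-window profile peaks within one
  # straggling width (+ a voxel) of the range
  b10 <- beam_spectrum("C10", 250, 1)
  R <- range_from_energy(250, "C10")
  ev <- simulate_treatment(b10, ph, sched, n_primaries = 5e4, seed = 21)
  m <- bin_events(ev, post)
  zprof <- apply(m$counts, 3, sum)
  zc <- m$origin[3] + (seq_along(zprof) - 0.5) * m$voxel
  expect_lt(abs(zc[which.max(zprof)] - R), 0.01 * R + m$voxel)
  # stable beam: fragment signal spans the entrance path
  b12 <- beam_spectrum("C12", 250, 1)
  ev12 <- simulate_treatment(b12, ph, sched, n_primaries = 2e5, seed = 22)
  m12 <- bin_events(ev12, post)
  z12 <- apply(m12$counts, 3, sum)
  support <- sum(z12 > 0.1 * max(z12)) * m12$voxel
  expect_gt(support, 0.6 * R)
})

test_that("map export writes MetaImage plus a dense TSV dump", {
  counts <- array(0, dim = c(4, 4, 4)); counts[2, 3, 1] <- 7
  map <- structure(list(counts = counts, voxel = 1.5, window = c(0, 2),
                        origin = c(-3, -3, 0)), class = "annihilation_map")
  base <- tempfile()
  write_map(map, base)
  expect_true(file.exists(paste0(base, ".mhd")))
  hdr <- readLines(paste0(base, ".mhd"))
  expect_true(any(grepl("DimSize = 4 4 4", hdr)))
  raw <- readBin(paste0(base, ".raw"), "double", n = 64, endian = "little")
  expect_equal(array(raw, dim = c(4, 4, 4)), counts)
  dump <- read.table(paste0(base, ".tsv"), header = TRUE, comment.char = "#")
  expect_equal(nrow(dump), 1)
  expect_equal(dump$value, 7)
})
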