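test_that("y* closed forms: delta spectrum, saturation, low-y limit", {
  # point mass at y_d = y0 = 150: y* = y0 (1 - e^-1)
  sp <- lineal_spectrum(150, 1)
  expect_equal(saturation_corrected_ystar(sp, 150), 150 * (1 - exp(-1)),
               tolerance = 1e-12)
  # far below saturation y* -> y_d (first order in (y_d/y0)^2)
  sp_low <- lineal_spectrum(1, 1)
  expect_equal(saturation_corrected_ystar(sp_low, 150), 1, tolerance = 1e-4)
  # rescaling f leaves y* unchanged
  y <- exp(seq(log(2), log(400), length.out = 300))
  f <- dlnorm(y, log(30), 0.6)
  s1 <- saturation_corrected_ystar(lineal_spectrum(y, f), 150)
  s7 <- saturation_corrected_ystar(lineal_spectrum(y, 7 * f), 150)
  expect_equal(s1, s7, tolerance = 1e-12)
  expect_error(saturation_corrected_ystar(lineal_spectrum(c(1, 2), c(0, 0))),
               "empty")
})

test_that("y* tends to the dose-mean lineal energy as y0 grows", {
  y <- exp(seq(log(1), log(500), length.out = 2001))
  f <- dlnorm(y, log(40), 0.7)
  sp <- lineal_spectrum(y, f)
  expect_equal(saturation_corrected_ystar(sp, 1e6),
               dose_mean_lineal_energy(sp), tolerance = 1e-6)
})

test_that("MKM alpha is affine in y* with the documented unit constant", {
  expect_equal(alpha_mkm(0), 0.13, tolerance = 1e-12)
  # hand unit-conversion oracle at y* = 46 keV/um
  expect_equal(alpha_mkm(46), 0.13 + 0.05 * 0.1602 * 46 / (pi * 0.42^2),
               tolerance = 1e-12)
  expect_equal(alpha_mkm(46), 0.79488, tolerance = 1e-4)
  # linearity: doubling y* doubles alpha - alpha0
  expect_equal(alpha_mkm(92) - 0.13, 2 * (alpha_mkm(46) - 0.13),
               tolerance = 1e-12)
})

test_that("RBE10 uses the natural-log convention and the quadratic root", {
  # alpha such that the ion D10 is exactly the 5 Gy X-ray reference
  alpha_ref <- (log(10) - 0.05 * 25) / 5
  expect_equal(rbe10_from_alpha(alpha_ref, 0.05, 5), 1, tolerance = 1e-12)
  # independent quadratic-formula oracle at alpha = 0.7949
  a <- 0.79488
  d10 <- max(Re(polyroot(c(-log(10), a, 0.05))))
  expect_equal(rbe10_from_alpha(a, 0.05, 5), 5 / d10, tolerance = 1e-9)
  expect_equal(rbe10_from_alpha(a, 0.05, 5), 1.9978, tolerance = 1e-4)
  # strictly increasing in alpha
  rbe <- rbe10_from_alpha(seq(0.2, 2, by = 0.05))
  expect_true(all(diff(rbe) > 0))
  expect_error(rbe10_from_alpha(-1), "alpha")
  expect_error(rbe10_from_alpha(0.5, beta = 0), "beta")
})

test_that("full MKM pipeline is invariant to spectrum normalization", {
  y <- exp(seq(log(1), log(800), length.out = 500))
  f <- dlnorm(y, log(60), 0.8)
  r1 <- rbe10_from_spectrum(lineal_spectrum(y, f))
  r2 <- rbe10_from_spectrum(lineal_spectrum(y, f * 1234.5))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("spectrum generator is seeded, rises toward the peak, and matches
           its documented mixture moments", {
  beam <- beam_spectrum("C12", 290, 1)
  s1 <- synthetic_lineal_spectrum(100, beam, seed = 42)
  s2 <- synthetic_lineal_spectrum(100, beam, seed = 42)
  expect_identical(s1, s2)
  # dose-mean 1 mm before the monoenergetic peak exceeds the entrance value
  R <- range_from_energy(290, "C12")
  y_near <- dose_mean_lineal_energy(
    synthetic_lineal_spectrum(R - 1, beam, n_events = 5000, seed = 1))
  y_ent <- dose_mean_lineal_energy(
    synthetic_lineal_spectrum(1, beam, n_events = 5000, seed = 2))
  expect_gt(y_near, y_ent)
  # sample mean converges to the analytic mixture mean within 3 SE at n=1e5
  p <- lineal_mixture_params(100, beam)
  m_true <- sum(p$weight * exp(p$meanlog + p$sdlog^2 / 2))
  draws <- sample_lineal_energies(1e5, 100, beam, seed = 7)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - m_true), 3 * se)
})

test_that("expected (deterministic) y* agrees with a large-sample estimate", {
  beam <- beam_spectrum("C12", c(230, 290), c(1, 2))
  ys_det <- expected_ystar(120, beam)
  sp <- synthetic_lineal_spectrum(120, beam, n_events = 2e5, seed = 3,
                                  n_bins = 400)
  ys_mc <- saturation_corrected_ystar(sp, 150)
  expect_equal(ys_mc, ys_det, tolerance = 0.03)
})

test_that("RBE depth profile: 11-volume statistics, bounds, material gate", {
  beam <- fix_sobp_beam("C12", "water")
  wp <- water_phantom(250)
  # fewer than 11 volumes available near the entry face
  expect_error(rbe_depth_profile(beam, wp, depths = 0.2, seed = 1),
               "11 sensitive volumes")
  # all-water phantom: the brain-tissue correction factor is never applied
  r_corr <- rbe_depth_profile(beam, wp, depths = c(50, 111), seed = 5,
                              tissue_correction = 1.05)
  r_none <- rbe_depth_profile(beam, wp, depths = c(50, 111), seed = 5,
                              tissue_correction = 1.0)
  expect_identical(r_corr$rbe_mean, r_none$rbe_mean)
  expect_true(all(r_corr$rbe_sd >= 0))
  expect_equal(attr(r_corr, "n_volumes_per_stat"), 11L)
  # in the skull phantom the correction changes the result
  sk <- skull_phantom()
  beam_sk <- fix_sobp_beam("C12", "skull")
  s_corr <- rbe_depth_profile(beam_sk, sk, depths = 111, seed = 5,
                              tissue_correction = 1.05)
  s_none <- rbe_depth_profile(beam_sk, sk, depths = 111, seed = 5,
                              tissue_correction = 1.0)
  expect_false(identical(s_corr$rbe_mean, s_none$rbe_mean))
})

test_that("RBE10 rises from entrance into the SOBP and drops in the tail", {
  beam <- fix_sobp_beam("C12", "water")
  prof <- rbe_profile_expected(beam, water_phantom(250),
                               depths = c(50, 81, 111, 131, 171),
                               depths_are_wed = TRUE)
  expect_gt(prof$rbe_mean[2], prof$rbe_mean[1])   # SOBP start > entrance
  expect_gt(prof$rbe_mean[4], prof$rbe_mean[3])   # distal end highest in SOBP
  expect_lt(prof$rbe_mean[5], prof$rbe_mean[1])   # low-LET fragment tail
})

test_that("lineal spectrum TSV round trip", {
  beam <- beam_spectrum("O16", 300, 1)
  sp <- synthetic_lineal_spectrum(60, beam, n_events = 1000, seed = 9)
  path <- tempfile(fileext = ".tsv")
  write_lineal_spectrum(sp, path)
  back <- read_lineal_spectrum(path)
  expect_equal(back$y, sp$y, tolerance = 1e-9)
  expect_equal(back$f, sp$f, tolerance = 1e-8)
  expect_equal(back$depth, 60, tolerance = 1e-9)
  expect_equal(back$n_events, 1000L)
})
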