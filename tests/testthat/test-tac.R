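test_that("total activity: sum at origin, half-life definition, mixture", {
  hl <- c(C11 = 1220.04, C10 = 19.29, O15 = 122.24)
  A0 <- c(C11 = 100, C10 = 50, O15 = 200)
  expect_equal(total_activity(0, A0, hl), 350)
  expect_equal(total_activity(19.29, c(C10 = 80), c(C10 = 19.29)), 40,
               tolerance = 1e-12)
  # direct evaluation oracle at t = one 15O half-life
  t <- 122.24
  expect_equal(total_activity(t, A0, hl),
               100 * 2^(-t / 1220.04) + 50 * 2^(-t / 19.29) + 100,
               tolerance = 1e-12)
  expect_error(total_activity(1, c(A = 1), c(A = -5)), "half-lives")
})

test_that("noiseless Eq-style curves are recovered exactly", {
  hl <- fix_half_lives()
  tt <- seq(0, 3600, length.out = 31)
  frames <- data.frame(t_start = tt[-31], t_end = tt[-1])
  A0 <- c(C11 = 40, C10 = 700, O15 = 90)
  X <- ribeam:::.decay_basis(frames$t_start, frames$t_end, log(2) / hl)
  tac <- time_activity_curve(frames$t_start, frames$t_end, drop(X %*% A0))
  fit <- fit_initial_activities(tac, hl)
  expect_equal(unname(fit$A0), unname(A0), tolerance = 1e-6)
  expect_lt(fit$residual_ss, 1e-12)
  # relative yields sum to 100 and are scale invariant
  expect_equal(sum(fit$relative_yield), 100, tolerance = 1e-9)
  fit2 <- fit_initial_activities(
    time_activity_curve(frames$t_start, frames$t_end, 37 * tac$activity), hl)
  expect_equal(fit2$relative_yield, fit$relative_yield, tolerance = 1e-9)
})

test_that("single-species curves leave the other amplitudes at zero", {
  hl <- fix_half_lives()
  tt <- seq(0, 600, length.out = 21)
  act <- 500 * 2^(-tt / 122.24)
  tac <- time_activity_curve(tt[-21], tt[-1],
                             total_activity((tt[-21] + tt[-1]) / 2,
                                            c(O15 = 500), c(O15 = 122.24)))
  fit <- fit_initial_activities(tac, hl)
  expect_equal(unname(fit$A0[c("C11", "C10")]), c(0, 0), tolerance = 1e-6)
  expect_gt(fit$A0[["O15"]], 0)
})

test_that("Poisson-noise curves at 1e4 counts/frame recover yields within
           3 SE (fixed seed)", {
  hl <- fix_half_lives()
  # 25 frames spanning three 11C half-lives
  tt <- seq(0, 3 * hl[["C11"]], length.out = 26)
  frames <- data.frame(t_start = tt[-26], t_end = tt[-1])
  dt <- diff(tt)
  A0 <- c(C11 = 30, C10 = 500, O15 = 120)
  X <- ribeam:::.decay_basis(frames$t_start, frames$t_end, log(2) / hl)
  act <- drop(X %*% A0)
  scale <- 25 * 1e4 / sum(act * dt)   # expected 1e4 counts per frame
  set.seed(7)
  counts <- rpois(25, act * dt * scale)
  tac <- time_activity_curve(frames$t_start, frames$t_end, counts / dt / scale)
  fit <- fit_initial_activities(tac, hl)
  z <- abs(fit$relative_yield - 100 * A0 / sum(A0)) / fit$se_yield
  expect_true(all(z < 3))
})

test_that("degenerate designs are refused", {
  tac <- time_activity_curve(c(0, 10, 20), c(10, 20, 30), c(5, 4, 3))
  expect_error(fit_initial_activities(tac, c(A = 100, B = 100)),
               "duplicated|rank")
  expect_error(fit_initial_activities(tac[1:2, ], fix_half_lives()),
               "3 frames")
})

test_that("frame-averaged basis converges to the instantaneous basis", {
  lambda <- log(2) / c(20, 120)
  t0 <- c(5, 50, 200)
  inst <- ribeam:::.decay_basis(t0, t0, lambda)   # zero-length frames
  expect_equal(inst, ribeam:::.decay_basis(t0, t0 + 1e-7, lambda),
               tolerance = 1e-7)
  expect_equal(inst[, 1], exp(-lambda[1] * t0), tolerance = 1e-12)
})

test_that("5%-rule ROI bounds: degenerate, rectangular and Bragg inputs", {
  # flat profile: never rises 5% above its own plateau
  flat <- list(depth = 0:100, dose = rep(3, 101))
  expect_error(roi_bounds_from_dose(flat), "never rises")
  # rectangular pulse on a plateau that ends with the pulse
  z <- 0:100
  dose <- ifelse(z < 40, 10, ifelse(z < 60, 100, 0))
  b <- roi_bounds_from_dose(list(depth = z, dose = dose))
  expect_equal(b, c(40, 59))
  # synthetic Bragg curve: bounds match a brute-force threshold scan
  dd <- depth_dose_profile(250, "C12", water_phantom(250), grid_step = 0.5)
  got <- roi_bounds_from_dose(dd)
  plateau <- mean(dd$dose[seq_len(floor(length(dd$depth) * 0.1))])
  z_start <- dd$depth[min(which(dd$dose >= 1.05 * plateau))]
  z_end <- dd$depth[max(which(dd$dose >= 0.05 * max(dd$dose)))]
  expect_equal(got, c(z_start, z_end))
  expect_lt(got[1], peak_depth(dd))
  expect_gte(got[2], peak_depth(dd))
})

test_that("TACs built from simulated events feed the fit", {
  sched <- spill_schedule(n_spills = 1, beam_on = 1e-6, beam_off = 1)
  beam <- beam_spectrum("O15", 250, 1)
  ev <- simulate_treatment(beam, water_phantom(250), sched,
                           n_primaries = 3e4, fragment_prob = 0, seed = 6)
  tt <- seq(0, 800, length.out = 17)
  tac <- tac_from_events(ev, data.frame(t_start = tt[-17], t_end = tt[-1]),
                         roi_z = c(0, 250))
  fit <- fit_initial_activities(tac)
  expect_gt(fit$relative_yield[["O15"]], 95)
})
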