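# Time-activity curves and multi-exponential decomposition.
#
# Total activity in a region is a sum of exponentials with the known
# half-lives of the positron emitters present; the amplitudes (initial
# activities A0) are linear parameters, physically non-negative, so the fit
# is a non-negative least squares on an exponential design matrix. Dynamic
# frames report the frame-averaged activity, so the basis functions are the
# analytic frame averages of the exponentials.

#' Total activity of a multi-species mixture
#'
#' \deqn{A(t) = \sum_s A_{0,s}\, e^{-\ln 2\, t / T_s}}
#'
#' @param t times, s (vectorized).
#' @param A0 named vector of initial activities, Bq.
#' @param half_lives named vector of half-lives, s (> 0), aligned with `A0`
#'   by name (or by position if unnamed).
#' @return activity at `t`, Bq.
#' @export
total_activity <- function(t, A0, half_lives) {
  if (any(half_lives <= 0)) stopf("half-lives must be > 0")
  if (!is.null(names(A0)) && !is.null(names(half_lives)))
    half_lives <- half_lives[names(A0)]
  if (length(A0) != length(half_lives)) stopf("A0 and half_lives lengths differ")
  out <- numeric(length(t))
  for (s in seq_along(A0))
    out <- out + A0[[s]] * exp(-log(2) * t / half_lives[[s]])
  out
}

#' Time-activity curve container
#'
#' @param t_start,t_end frame boundaries, s (`t_start` increasing,
#'   `t_end > t_start`); `t_end = t_start` denotes instantaneous samples.
#' @param activity frame-averaged activity (Bq) or counts-per-second.
#' @return data.frame of class `time_activity_curve`.
#' @export
time_activity_curve <- function(t_start, t_end, activity) {
  if (any(diff(t_start) <= 0)) stopf("frame start times must be increasing")
  if (any(t_end < t_start)) stopf("frame end before start")
  if (any(activity < 0)) stopf("activity must be >= 0")
  structure(data.frame(t_start = t_start, t_end = t_end, activity = activity),
            class = c("time_activity_curve", "data.frame"))
}

#' Build a TAC from simulated annihilation events in a depth ROI
#'
#' Counts events with `z` inside `roi_z` per frame and divides by the frame
#' length, giving frame-averaged decays/s.
#'
#' @param events an `annihilation_events` data.frame.
#' @param frames data.frame with `t_start`, `t_end` columns (s).
#' @param roi_z length-2 physical depth bounds, mm.
#' @return a [time_activity_curve].
#' @export
tac_from_events <- function(events, frames, roi_z) {
  inroi <- events$z_mm >= roi_z[1] & events$z_mm < roi_z[2]
  t <- events$t_s[inroi]
  act <- vapply(seq_len(nrow(frames)), function(i) {
    sum(t >= frames$t_start[i] & t < frames$t_end[i]) /
      (frames$t_end[i] - frames$t_start[i])
  }, numeric(1))
  time_activity_curve(frames$t_start, frames$t_end,
                      act * (attr(events, "weight") %||% 1))
}

# Frame-averaged exponential basis: for frame [t1, t2],
# (exp(-l t1) - exp(-l t2)) / (l (t2 - t1)); the instantaneous exponential
# when t2 == t1.
.decay_basis <- function(t_start, t_end, lambda) {
  vapply(lambda, function(l) {
    inst <- t_end <= t_start
    out <- numeric(length(t_start))
    out[inst] <- exp(-l * t_start[inst])
    d <- !inst
    out[d] <- (exp(-l * t_start[d]) - exp(-l * t_end[d])) /
      (l * (t_end[d] - t_start[d]))
    out
  }, numeric(length(t_start)))
}

#' Fit initial activities to a TAC with fixed half-lives
#'
#' Non-negative least squares on the frame-averaged exponential design
#' matrix; half-lives are fixed to their known physical constants (default:
#' 11C, 10C, 15O). Returns the initial activities, relative yields
#' (A0_s / sum(A0) x 100), and a fit covariance with delta-method standard
#' errors for the yields.
#'
#' @param tac a [time_activity_curve] (>= 3 frames).
#' @param half_lives named half-lives, s; duplicated values make the design
#'   rank-deficient and are an error.
#' @return object of class `yield_estimate`: list with `A0`, `se_A0`,
#'   `relative_yield` (percent), `se_yield`, `covariance`, `fitted`.
#' @export
fit_initial_activities <- function(tac, half_lives = c(C11 = 20.334 * 60,
                                                       C10 = 19.29,
                                                       O15 = 122.24)) {
  if (nrow(tac) < 3) stopf("need at least 3 frames, got %d", nrow(tac))
  if (anyDuplicated(half_lives))
    stopf("duplicated half-lives make the design matrix rank-deficient")
  lambda <- log(2) / half_lives
  X <- .decay_basis(tac$t_start, tac$t_end, lambda)
  if (qr(X)$rank < ncol(X))
    stopf("exponential design matrix is rank-deficient on this frame grid")
  fit <- nnls_fit(X, tac$activity)
  A0 <- stats::setNames(fit$x, names(half_lives))
  dof <- max(nrow(tac) - ncol(X), 1)
  # Counting-statistics (sandwich) covariance: frame variance taken
  # proportional to fitted activity over frame length, with the dispersion
  # estimated from the residuals. Reduces to zero on noiseless curves.
  dt <- pmax(tac$t_end - tac$t_start, 1e-12)
  vhat <- pmax(fit$fitted, max(fit$fitted) * 1e-9 + 1e-300) / dt
  phi <- sum(fit$residual^2 / vhat) / dof
  xtxi <- solve(crossprod(X))
  covA <- xtxi %*% crossprod(X * (phi * vhat), X) %*% xtxi
  S <- sum(A0)
  if (S <= 0) stopf("fit returned all-zero activities; empty TAC?")
  # delta method for yields y_s = 100 * A0_s / S
  J <- 100 * (diag(length(A0)) * S - matrix(A0, length(A0), length(A0))) / S^2
  covY <- J %*% covA %*% t(J)
  structure(list(A0 = A0,
                 se_A0 = stats::setNames(sqrt(pmax(diag(covA), 0)), names(A0)),
                 relative_yield = 100 * A0 / S,
                 se_yield = stats::setNames(sqrt(pmax(diag(covY), 0)), names(A0)),
                 covariance = covA, fitted = fit$fitted,
                 residual_ss = fit$deviance),
            class = "yield_estimate")
}

#' @export
print.yield_estimate <- function(x, ...) {
  cat("<yield_estimate>\n")
  df <- data.frame(species = names(x$A0),
                   A0 = signif(x$A0, 5),
                   yield_pct = signif(x$relative_yield, 4),
                   se_pct = signif(x$se_yield, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Build-up/Bragg-peak ROI from a depth-dose profile (5% rule)
#'
#' The region runs from the first depth where the dose has risen 5% above
#' the entrance-plateau level to the last depth where it still exceeds 5%
#' of the peak value. The entrance plateau is estimated as the mean dose
#' over the first `plateau_frac` of the depth grid.
#'
#' @param profile a `depth_dose_profile`.
#' @param plateau_frac fraction of the grid treated as entrance plateau.
#' @return length-2 depth bounds `[z_start, z_end]`, mm.
#' @export
roi_bounds_from_dose <- function(profile, plateau_frac = 0.1) {
  z <- profile$depth; d <- profile$dose
  n_ent <- max(2L, floor(length(z) * plateau_frac))
  plateau <- mean(d[seq_len(n_ent)])
  i_start <- which(d >= 1.05 * plateau)
  if (!length(i_start))
    stopf("dose never rises 5%% above the entrance plateau; no ROI")
  i_end <- which(d >= 0.05 * max(d))
  z_start <- z[i_start[1]]
  z_end <- z[i_end[length(i_end)]]
  if (z_start >= z_end) stopf("degenerate ROI: z_start >= z_end")
  c(z_start, z_end)
}

#' Write a yield estimate as TSV (species, A0_Bq, yield_pct, se_pct)
#' @param est a `yield_estimate`.
#' @param path file path.
#' @export
write_yields <- function(est, path) {
  write_tsv(data.frame(species = names(est$A0), A0_Bq = est$A0,
                       yield_pct = est$relative_yield, se_pct = est$se_yield),
            path)
}
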