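# Shared fixtures. Dense profile sets take a few seconds to build, so they
# are cached per (stable species, phantom kind) for the whole test run.

.fix <- new.env(parent = emptyenv())

fix_plan <- function() sobp_plan(78, 138)

fix_phantom <- function(kind = c("water", "skull")) {
  kind <- match.arg(kind)
  if (kind == "water") water_phantom(250) else skull_phantom()
}

fix_target_wed <- function(kind = "water") {
  ph <- fix_phantom(kind)
  plan <- fix_plan()
  water_equivalent_depth(ph, c(plan$proximal, plan$distal))
}

fix_profile_set <- function(stable = "C12", kind = "water") {
  key <- paste0("set_", stable, "_", kind)
  if (is.null(.fix[[key]])) {
    ph <- fix_phantom(kind)
    rng <- fix_target_wed(kind)
    anchor_e <- seq(floor(energy_from_range(rng[1] - 8, stable)),
                    ceiling(energy_from_range(rng[2] + 4, stable)), by = 1)
    anchors <- lapply(anchor_e, function(E) {
      dd <- depth_dose_profile(E, stable, ph, grid_step = 1)
      rbe <- rbe_profile_expected(beam_spectrum(stable, E, 1), ph,
                                  depths = dd$depth[seq(1, length(dd$depth), 2)],
                                  depths_are_wed = TRUE)
      list(energy = E, dose = dd, rbe = rbe)
    })
    .fix[[key]] <- interpolate_profiles(anchors, step = 1)
  }
  .fix[[key]]
}

fix_sobp_beam <- function(stable = "C12", kind = "water") {
  key <- paste0("beam_", stable, "_", kind)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- optimize_sobp_weights(fix_profile_set(stable, kind),
                                         fix_plan(),
                                         target_range = fix_target_wed(kind))
  .fix[[key]]
}

# Independent Simpson quadrature in log space (substitution u = log y),
# used as the oracle against the package's trapezoid-on-grid integrals.
simpson_log <- function(g, la, lb, n = 20001) {
  u <- seq(la, lb, length.out = n)
  h <- (lb - la) / (n - 1)
  w <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1) * h / 3
  sum(w * g(exp(u)) * exp(u))
}

# Half-lives used throughout: 11C 20.334 min, 10C 19.29 s, 15O 122.24 s.
fix_half_lives <- function() c(C11 = 20.334 * 60, C10 = 19.29, O15 = 122.24)
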