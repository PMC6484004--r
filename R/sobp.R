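# Spread-out Bragg peak construction.
#
# A polyenergetic spectrum (energy, weight) is optimized so that the
# biological dose — per-energy physical dose times per-energy RBE10 — is
# flat across the planned depth range. Radioactive analogs inherit the
# stable spectrum's weights through an affine energy mapping that places
# their Bragg peaks at the same proximal/distal depths.

#' Polyenergetic beam spectrum
#'
#' @param species an [ion_species] or name.
#' @param energy strictly increasing energies, MeV/u.
#' @param weight non-negative weights (primaries per spill, or relative);
#'   at least one must be positive.
#' @return object of class `beam_spectrum` with a `components` data.frame.
#' @export
beam_spectrum <- function(species, energy, weight = rep(1, length(energy))) {
  species <- get_species(species)
  if (length(energy) != length(weight)) stopf("energy and weight lengths differ")
  if (length(energy) > 1 && any(diff(energy) <= 0))
    stopf("energies must be strictly increasing")
  if (any(weight < 0)) stopf("weights must be >= 0")
  if (!any(weight > 0)) stopf("at least one weight must be positive")
  structure(list(species = species,
                 components = data.frame(energy = as.double(energy),
                                         weight = as.double(weight))),
            class = "beam_spectrum")
}

#' @export
print.beam_spectrum <- function(x, ...) {
  cat(sprintf("<beam_spectrum> %s, %d components, E in [%.6g, %.6g] MeV/u\n",
              x$species$name, nrow(x$components),
              min(x$components$energy), max(x$components$energy)))
  invisible(x)
}

#' SOBP treatment plan
#'
#' Default values are the study plan: a flat biological dose rate of
#' 5 Gy(RBE)/min across a 60 mm SOBP spanning depths 78-138 mm.
#'
#' @param proximal,distal SOBP edges, mm depth (proximal < distal).
#' @param dose_rate target biological dose rate, Gy(RBE)/min (> 0).
#' @param flatness_tolerance maximum tolerated |relative deviation| of the
#'   biological dose from its mean inside the target range.
#' @return object of class `sobp_plan`.
#' @export
sobp_plan <- function(proximal = 78, distal = 138, dose_rate = 5,
                      flatness_tolerance = 0.02) {
  if (proximal >= distal) stopf("proximal (%s) must be < distal (%s)", proximal, distal)
  if (dose_rate <= 0) stopf("dose_rate must be > 0")
  structure(list(proximal = proximal, distal = distal, dose_rate = dose_rate,
                 flatness_tolerance = flatness_tolerance), class = "sobp_plan")
}

#' Dense energy-indexed profile set by linear interpolation
#'
#' From depth-dose (and optionally RBE10) profiles simulated at a sparse set
#' of anchor energies, builds physical- and biological-dose-per-primary
#' matrices on a dense energy grid (default 1 MeV/u increments) by linear
#' interpolation between adjacent anchors at every depth. Anchor energies
#' are reproduced exactly; queries outside the anchor hull are an error (no
#' extrapolation).
#'
#' @param anchors list of entries, each a list with elements `energy`,
#'   `dose` (a [depth_dose_profile]; all must share one depth grid) and
#'   optionally `rbe` (an `rbe_profile`, interpolated onto the depth grid;
#'   absent means RBE = 1).
#' @param step energy increment of the dense grid, MeV/u.
#' @return object of class `sobp_profile_set`: `depth`, `energies`,
#'   matrices `physical` and `biological` (depth x energy), `species`.
#' @export
interpolate_profiles <- function(anchors, step = 1) {
  if (length(anchors) < 2) stopf("need at least 2 simulated anchor energies")
  if (step <= 0) stopf("step must be > 0")
  e_anchor <- vapply(anchors, `[[`, numeric(1), "energy")
  ord <- order(e_anchor)
  anchors <- anchors[ord]; e_anchor <- e_anchor[ord]
  depth <- anchors[[1]]$dose$depth
  for (a in anchors)
    if (!isTRUE(all.equal(a$dose$depth, depth)))
      stopf("all anchor profiles must share a common depth grid")
  phys <- vapply(anchors, function(a) a$dose$dose, numeric(length(depth)))
  bio <- vapply(anchors, function(a) {
    r <- if (is.null(a$rbe)) rep(1, length(depth))
    else stats::approx(a$rbe$depth, a$rbe$rbe_mean, xout = depth, rule = 2)$y
    a$dose$dose * r
  }, numeric(length(depth)))
  energies <- seq(e_anchor[1], e_anchor[length(e_anchor)], by = step)
  if (energies[length(energies)] < e_anchor[length(e_anchor)] - 1e-9)
    energies <- c(energies, e_anchor[length(e_anchor)])
  # linear interpolation operator anchors -> dense grid
  iv <- pmin(pmax(findInterval(energies, e_anchor), 1L), length(e_anchor) - 1L)
  t_frac <- (energies - e_anchor[iv]) / (e_anchor[iv + 1] - e_anchor[iv])
  interp <- function(M) {
    M[, iv, drop = FALSE] * rep(1 - t_frac, each = nrow(M)) +
      M[, iv + 1, drop = FALSE] * rep(t_frac, each = nrow(M))
  }
  structure(list(depth = depth, energies = energies,
                 physical = interp(phys), biological = interp(bio),
                 species = anchors[[1]]$dose$species),
            class = "sobp_profile_set")
}

#' Query a dense profile set at one energy
#' @param set an `sobp_profile_set`.
#' @param energy MeV/u; must lie within the anchor hull.
#' @return list with `depth`, `physical`, `biological` vectors.
#' @export
profile_at <- function(set, energy) {
  e <- set$energies
  if (energy < e[1] - 1e-9 || energy > e[length(e)] + 1e-9)
    stopf("energy %.6g outside interpolated hull [%.6g, %.6g]; no extrapolation",
          energy, e[1], e[length(e)])
  j <- which.min(abs(e - energy))
  if (abs(e[j] - energy) < 1e-9)
    return(list(depth = set$depth, physical = set$physical[, j],
                biological = set$biological[, j]))
  i <- findInterval(energy, e)
  t_frac <- (energy - e[i]) / (e[i + 1] - e[i])
  list(depth = set$depth,
       physical = (1 - t_frac) * set$physical[, i] + t_frac * set$physical[, i + 1],
       biological = (1 - t_frac) * set$biological[, i] + t_frac * set$biological[, i + 1])
}

#' Optimize SOBP component weights by non-negative least squares
#'
#' Minimizes \eqn{\sum_{z \in \mathrm{target}} (\sum_e w_e b_e(z) - t)^2}
#' over non-negative weights, where `b_e` are the biological-dose-per-primary
#' columns of the profile set and `t` the target level. Errors if the
#' achieved flatness (max |relative deviation from the in-range mean|)
#' exceeds the plan's tolerance.
#'
#' @param set an `sobp_profile_set`.
#' @param plan an [sobp_plan]; its `[proximal, distal]` select the target
#'   depths unless `target_range` overrides (e.g. water-equivalent bounds).
#' @param target_range optional length-2 depth bounds, same units as
#'   `set$depth`.
#' @param target_value target biological dose level per primary-weight unit.
#' @return a [beam_spectrum] of the nonzero-weight components, with
#'   attributes `flatness` (achieved), `fitted` (biological dose on the full
#'   grid) and `target_rows`.
#' @export
optimize_sobp_weights <- function(set, plan, target_range = NULL,
                                  target_value = 1) {
  rng <- target_range %||% c(plan$proximal, plan$distal)
  rows <- which(set$depth >= rng[1] & set$depth <= rng[2])
  if (length(rows) < 2) stopf("target range [%.1f, %.1f] covers <2 depth rows",
                              rng[1], rng[2])
  fit <- nnls_fit(set$biological[rows, , drop = FALSE],
                  rep(target_value, length(rows)))
  achieved <- drop(set$biological %*% fit$x)
  flat <- max(abs(achieved[rows] / mean(achieved[rows]) - 1))
  if (flat > plan$flatness_tolerance)
    stopf("flatness %.4f exceeds tolerance %.4f: target unreachable with this profile set",
          flat, plan$flatness_tolerance)
  keep <- fit$x > 0
  out <- beam_spectrum(set$species, set$energies[keep], fit$x[keep])
  attr(out, "flatness") <- flat
  attr(out, "fitted") <- achieved
  attr(out, "target_rows") <- rows
  out
}

#' Map a stable SOBP spectrum to a radioactive analog
#'
#' Finds the radioactive-species energies whose Bragg peaks sit at the
#' stable spectrum's proximal and distal peak depths (closed-form inversion
#' of the range-energy law), then affinely maps every stable component
#' energy into that interval, preserving the weights. The mapped spectrum
#' spans the same SOBP. Identity when the species is unchanged.
#'
#' @param stable a [beam_spectrum] of a stable species.
#' @param radioactive target [ion_species] or name.
#' @return a [beam_spectrum] for the radioactive species.
#' @export
map_weights_to_radioactive <- function(stable, radioactive) {
  radioactive <- get_species(radioactive)
  comp <- stable$components
  if (radioactive$Z == stable$species$Z && radioactive$A == stable$species$A)
    return(beam_spectrum(radioactive, comp$energy, comp$weight))
  e_min <- min(comp$energy); e_max <- max(comp$energy)
  r_min <- range_from_energy(e_min, stable$species, "water")
  r_max <- range_from_energy(e_max, stable$species, "water")
  e_prox <- energy_from_range(r_min, radioactive, "water")
  e_dist <- energy_from_range(r_max, radioactive, "water")
  frac <- if (e_max > e_min) (comp$energy - e_min) / (e_max - e_min) else 0
  beam_spectrum(radioactive, e_prox + frac * (e_dist - e_prox), comp$weight)
}

#' Biological and physical dose profiles of a weighted beam
#'
#' Sums the profile set's per-energy doses with the spectrum weights.
#' `biological = RBE10(z) * physical(z)` when a mixed-field `rbe` profile is
#' supplied; otherwise the per-energy biological columns (each already
#' RBE-converted) are summed. Reports flatness inside the target range and
#' the entrance-to-SOBP dose ratio (entrance = mean over the first 10% of
#' the depth grid).
#'
#' @param beam a [beam_spectrum] whose energies lie on `set$energies`.
#' @param set an `sobp_profile_set` (grid mismatch is an error).
#' @param rbe optional mixed-field `rbe_profile`.
#' @param plan optional [sobp_plan] for the flatness report.
#' @param target_range optional override of the plan range, grid units.
#' @return list with `depth`, `physical`, `biological`, `flatness`,
#'   `entrance_to_sobp`.
#' @export
biological_dose_profile <- function(beam, set, rbe = NULL, plan = NULL,
                                    target_range = NULL) {
  idx <- match(round(beam$components$energy, 9), round(set$energies, 9))
  if (anyNA(idx))
    stopf("beam energies not on the profile set's energy grid (grid mismatch)")
  w <- beam$components$weight
  phys <- drop(set$physical[, idx, drop = FALSE] %*% w)
  bio <- if (!is.null(rbe)) {
    r <- stats::approx(rbe$depth, rbe$rbe_mean, xout = set$depth, rule = 2)$y
    r * phys
  } else drop(set$biological[, idx, drop = FALSE] %*% w)
  flat <- entrance_ratio <- NA_real_
  if (!is.null(plan) || !is.null(target_range)) {
    rng <- target_range %||% c(plan$proximal, plan$distal)
    rows <- set$depth >= rng[1] & set$depth <= rng[2]
    flat <- max(abs(bio[rows] / mean(bio[rows]) - 1))
    ent <- set$depth <= stats::quantile(set$depth, 0.1)
    entrance_ratio <- mean(bio[ent]) / mean(bio[rows])
  }
  list(depth = set$depth, physical = phys, biological = bio,
       flatness = flat, entrance_to_sobp = entrance_ratio)
}

#' Read/write beam spectra as TSV (energy_MeV_u, weight)
#' @param beam a [beam_spectrum].
#' @param path file path.
#' @export
write_beam_spectrum <- function(beam, path) {
  write_tsv(data.frame(energy_MeV_u = beam$components$energy,
                       weight = beam$components$weight), path,
            comments = sprintf("species: %s", beam$species$name))
}

#' @rdname write_beam_spectrum
#' @export
read_beam_spectrum <- function(path) {
  df <- read_tsv(path)
  cm <- read_tsv_comments(path)
  sp <- sub("^species:\\s*", "", grep("^species:", cm, value = TRUE))
  beam_spectrum(sp, df$energy_MeV_u, df$weight)
}
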