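# Bulk incidental activity/dose from radioactive-beam decays, and the
# variance-based convergence procedure for choosing simulation size.

#' Initial activity concentration of stopped radioactive ions
#'
#' \deqn{A_0 / V = N \ln 2 / T_{1/2} / V}
#'
#' @param n_atoms number of stopped radioactive nuclei.
#' @param species a radioactive [ion_species] or name.
#' @param volume volume, cc (> 0).
#' @return activity concentration in MBq/cc.
#' @export
activity_concentration <- function(n_atoms, species, volume) {
  species <- get_species(species)
  if (species$stable) stopf("species '%s' is stable: no activity", species$name)
  if (volume <= 0) stopf("volume must be > 0")
  n_atoms * log(2) / species$half_life / volume / 1e6
}

#' Bulk incidental dose from positron-emitter decays
#'
#' Deposits per decay the mean positron kinetic energy plus a configurable
#' absorbed fraction of the two 511 keV annihilation photons (1.022 MeV),
#' spread uniformly over the volume:
#' \deqn{D = N (\bar{E}_\beta + f_\gamma \cdot 1.022\,\mathrm{MeV})
#'       \cdot 1.602\times10^{-13} / (V \rho)}
#' reported in mSv with radiation weighting factor 1. The mean 11C positron
#' energy (0.386 MeV) and the gamma absorbed fraction (0.3 for a head-sized
#' volume) are assumptions, not values from the source study.
#'
#' @param n_atoms number of decaying nuclei.
#' @param volume volume, cc.
#' @param mean_positron_energy MeV per decay.
#' @param gamma_absorbed_fraction fraction of annihilation photon energy
#'   absorbed locally, in `[0, 1]`.
#' @param tissue_density g/cc.
#' @return dose in mSv.
#' @export
incidental_dose <- function(n_atoms, volume, mean_positron_energy = 0.386,
                            gamma_absorbed_fraction = 0.3,
                            tissue_density = 1) {
  if (gamma_absorbed_fraction < 0 || gamma_absorbed_fraction > 1)
    stopf("gamma_absorbed_fraction must be in [0, 1]")
  e_mev <- mean_positron_energy + gamma_absorbed_fraction * 1.022
  joules <- n_atoms * e_mev * 1.602e-13
  mass_kg <- volume * tissue_density / 1000
  joules / mass_kg * 1000   # Gy -> mSv at w_R = 1
}

#' Incidental-dose report for a treatment
#'
#' @param n_primaries planned primaries delivered (all assumed stopped in
#'   the treatment volume).
#' @param species radioactive beam species.
#' @param volume treatment volume, cc.
#' @param ... passed to [incidental_dose()].
#' @return list of class `incidental_report`, serializable with
#'   [write_incidental_report()].
#' @export
incidental_report <- function(n_primaries, species, volume = 1000, ...) {
  species <- get_species(species)
  dots <- list(...)
  structure(list(
    species = species$name,
    n_primaries = n_primaries,
    volume_cc = volume,
    activity_concentration_MBq_cc =
      activity_concentration(n_primaries, species, volume),
    decay_dose_mSv = incidental_dose(n_primaries, volume, ...),
    assumptions = utils::modifyList(list(
      mean_positron_energy_MeV = 0.386,
      gamma_absorbed_fraction = 0.3,
      tissue_density_g_cc = 1,
      note = paste("bulk estimate: all primaries stop and decay inside the",
                   "volume; positron energy and gamma absorbed fraction are",
                   "package assumptions")), dots)),
    class = "incidental_report")
}

#' @rdname incidental_report
#' @param report an `incidental_report`.
#' @param path output path (YAML).
#' @export
write_incidental_report <- function(report, path) {
  yaml::write_yaml(unclass(report), path)
  invisible(path)
}

#' Variance-based selection of the number of primaries
#'
#' Runs `M` seeded replicates of `estimator(seed, N)` at each `N`, doubling
#' `N` from `n_start` until the ratio of the replicate standard deviation to
#' the replicate mean falls below `threshold` (the study used M = 50 and a
#' 1% threshold). Returns the first qualifying `N` and the full trace.
#'
#' @param estimator function of `(seed, N)` returning a finite scalar.
#' @param M replicates per `N` (>= 2).
#' @param threshold SD/mean stopping threshold (> 0).
#' @param n_start starting `N`.
#' @param seed base seed; replicate seeds are derived from it.
#' @param max_doublings safety cap on the number of doublings.
#' @return list with `N_required` and `trace` (data.frame `N`, `cv`).
#' @export
convergence_study <- function(estimator, M = 50, threshold = 0.01,
                              n_start = 100, seed = 1, max_doublings = 20) {
  if (M < 2) stopf("M must be >= 2 (SD undefined for M = 1)")
  if (threshold <= 0) stopf("threshold must be > 0")
  N <- n_start
  trace <- data.frame(N = numeric(0), cv = numeric(0))
  for (step in seq_len(max_doublings)) {
    vals <- vapply(seq_len(M), function(m)
      estimator(child_seed(seed, step * 1000 + m), N), numeric(1))
    if (any(!is.finite(vals))) stopf("estimator returned a non-finite value at N=%g", N)
    cv <- stats::sd(vals) / mean(vals)
    trace <- rbind(trace, data.frame(N = N, cv = cv))
    if (is.finite(cv) && cv < threshold)
      return(list(N_required = N, trace = trace))
    N <- N * 2
  }
  stopf("convergence_study did not reach SD/mean < %g within %d doublings",
        threshold, max_doublings)
}
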