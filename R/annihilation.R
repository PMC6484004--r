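# Positron-decay event simulation under a synchrotron spill schedule.
#
# Each primary is born uniformly within a beam-on interval. Radioactive
# primaries stop at their component's range (Gaussian range straggling) and
# decay after an exponential delay set by the species half-life; a
# configurable fraction of primaries instead produces a positron-emitting
# fragment (species mix per fragment_fractions) that stops upstream of the
# primary range with a linearly decreasing depth profile. Stable primaries
# produce events only through fragmentation. Annihilation positions are the
# stopping points blurred by an isotropic positron-range Gaussian.

#' Spill schedule
#'
#' Defaults are the study schedule: 20 spills, beam on 1.9 s / off 1.4 s,
#' 1e9 primaries per second.
#'
#' @param n_spills number of spills.
#' @param beam_on,beam_off seconds per spill (> 0).
#' @param intensity primaries per second during beam-on.
#' @return object of class `spill_schedule`.
#' @export
spill_schedule <- function(n_spills = 20, beam_on = 1.9, beam_off = 1.4,
                           intensity = 1e9) {
  if (n_spills < 1) stopf("n_spills must be >= 1")
  if (beam_on <= 0) stopf("beam_on must be > 0 (got %s)", beam_on)
  if (beam_off <= 0) stopf("beam_off must be > 0 (got %s)", beam_off)
  if (intensity <= 0) stopf("intensity must be > 0")
  structure(list(n_spills = as.integer(n_spills), beam_on = beam_on,
                 beam_off = beam_off, intensity = intensity,
                 period = beam_on + beam_off),
            class = "spill_schedule")
}

# k-th inter-spill window (k = 1..n_spills), t = 0 at start of spill 1:
# [k * period - beam_off, k * period).
interspill_window <- function(schedule, k) {
  c(k * schedule$period - schedule$beam_off, k * schedule$period)
}

# End of the final beam-on interval.
irradiation_end <- function(schedule) {
  (schedule$n_spills - 1) * schedule$period + schedule$beam_on
}

# Default fragment species mix by primary element: relative yields of the
# dominant positron emitters for carbon (80/5/15) and oxygen (44/7/49)
# primaries, as percentages of C11/C10/O15.
default_fragment_fractions <- function(species) {
  species <- get_species(species)
  if (species$Z == 6) c(C11 = 0.80, C10 = 0.05, O15 = 0.15)
  else if (species$Z == 8) c(C11 = 0.44, C10 = 0.07, O15 = 0.49)
  else stopf("no default fragment mix for Z=%d", species$Z)
}

#' Simulate annihilation events for a treatment delivery
#'
#' @param beam a [beam_spectrum].
#' @param phantom a [phantom]; stopping depths are converted from
#'   water-equivalent ranges to physical depths inside it.
#' @param schedule a [spill_schedule].
#' @param n_primaries number of primaries to simulate (desk-scale default
#'   1e6); the attribute `weight` records `plan_primaries / n_primaries` so
#'   maps can be rescaled to the planned delivery.
#' @param fragment_fractions named fractions (`C11`, `C10`, `O15`) summing
#'   to 1; defaults per primary element.
#' @param fragment_prob fraction of primaries that fragment before stopping
#'   (default 0.2; not printed in the source study, exposed as config).
#' @param positron_blur isotropic positron-range Gaussian sigma, mm.
#' @param field_mm transverse field width (square, centred on the axis), mm.
#' @param plan_primaries planned total primaries (default
#'   `intensity * beam_on * n_spills`).
#' @param energy_spread optional relative beam energy spread mapped to range
#'   straggling (sigma_R = 1.75 * spread * R); default: 1% of range.
#' @param seed RNG seed (determinism contract: fixed seed, identical events).
#' @return data.frame of class `annihilation_events` with columns `x_mm`,
#'   `y_mm`, `z_mm` (physical depth), `t_s`, `species`, `origin`
#'   (`"primary"`/`"fragment"`); attributes `phantom`, `field_mm`, `weight`.
#' @export
simulate_treatment <- function(beam, phantom, schedule = spill_schedule(),
                               n_primaries = 1e6,
                               fragment_fractions = NULL,
                               fragment_prob = 0.2, positron_blur = 1,
                               field_mm = 60, plan_primaries = NULL,
                               energy_spread = NULL, seed = 1) {
  if (n_primaries < 1) stopf("n_primaries must be >= 1")
  sp <- beam$species
  fragment_fractions <- fragment_fractions %||% default_fragment_fractions(sp)
  if (abs(sum(fragment_fractions) - 1) > 1e-9)
    stopf("fragment_fractions must sum to 1 (got %.12g)", sum(fragment_fractions))
  plan_primaries <- plan_primaries %||%
    (schedule$intensity * schedule$beam_on * schedule$n_spills)
  n <- as.integer(n_primaries)
  comp <- beam$components
  R <- range_from_energy(comp$energy, sp, "water")
  sigR <- range_sigma(R, sp, energy_spread)
  frag_tab <- .species_table()[names(fragment_fractions)]
  ev <- with_seed(seed, {
    spill <- sample.int(schedule$n_spills, n, replace = TRUE) - 1L
    t_birth <- spill * schedule$period + stats::runif(n) * schedule$beam_on
    ci <- if (nrow(comp) == 1L) rep(1L, n)
          else sample.int(nrow(comp), n, replace = TRUE, prob = comp$weight)
    is_frag <- stats::runif(n) < fragment_prob
    # stopping depth in water-equivalent mm
    z_wed <- R[ci] + stats::rnorm(n) * sigR[ci]
    if (any(is_frag)) {
      # fragments stop upstream with density f(u) = (1 - u/2)/0.75, u = z/R
      v <- stats::runif(sum(is_frag))
      z_wed[is_frag] <- R[ci][is_frag] * 2 * (1 - sqrt(1 - 0.75 * v))
      fi <- sample.int(length(frag_tab), sum(is_frag), replace = TRUE,
                       prob = fragment_fractions)
    }
    species_name <- rep(sp$name, n)
    half <- rep(if (sp$stable) NA_real_ else sp$half_life, n)
    if (any(is_frag)) {
      species_name[is_frag] <- names(frag_tab)[fi]
      half[is_frag] <- vapply(frag_tab, `[[`, numeric(1), "half_life")[fi]
    }
    emitter <- !is.na(half)
    if (!any(emitter)) {
      data.frame(x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                 t_s = numeric(0), species = character(0), origin = character(0))
    } else {
      idx <- which(emitter)
      t_decay <- t_birth[idx] + stats::rexp(length(idx), log(2) / half[idx])
      z_phys <- physical_from_wed(phantom, pmax(z_wed[idx], 0)) +
        stats::rnorm(length(idx)) * positron_blur
      data.frame(
        x_mm = stats::runif(length(idx), -field_mm / 2, field_mm / 2) +
          stats::rnorm(length(idx)) * positron_blur,
        y_mm = stats::runif(length(idx), -field_mm / 2, field_mm / 2) +
          stats::rnorm(length(idx)) * positron_blur,
        z_mm = pmin(pmax(z_phys, 0), phantom$thickness),
        t_s = t_decay,
        species = species_name[idx],
        origin = ifelse(is_frag[idx], "fragment", "primary"),
        stringsAsFactors = FALSE
      )
    }
  })
  structure(ev, phantom = phantom, field_mm = field_mm,
            weight = plan_primaries / n_primaries, schedule = schedule,
            class = c("annihilation_events", "data.frame"))
}

#' Bin annihilation events into a voxel map
#'
#' Counts events with `t` in the half-open time window into half-open
#' isotropic voxel bins. Events outside the spatial bounds are dropped and
#' the count recorded in attribute `n_dropped`.
#'
#' @param events an `annihilation_events` data.frame.
#' @param window length-2 `[t_start, t_end)` in seconds.
#' @param voxel isotropic voxel size, mm (default 1.5).
#' @param bounds list with `x`, `y`, `z` length-2 ranges in mm; default: the
#'   transverse field +/- 15 mm and the phantom depth extent.
#' @return object of class `annihilation_map`: `counts` (3D array, x-y-z),
#'   `voxel`, `window`, `origin` (lower corner, mm).
#' @export
bin_events <- function(events, window, voxel = 1.5, bounds = NULL) {
  if (window[2] <= window[1]) stopf("inverted time window [%s, %s)", window[1], window[2])
  if (voxel <= 0) stopf("voxel must be > 0")
  if (is.null(bounds)) {
    fw <- attr(events, "field_mm") %||% 60
    ph <- attr(events, "phantom")
    zmax <- if (!is.null(ph)) ph$thickness else 250
    bounds <- list(x = c(-fw / 2 - 15, fw / 2 + 15),
                   y = c(-fw / 2 - 15, fw / 2 + 15), z = c(0, zmax))
  }
  dims <- vapply(bounds, function(b) as.integer(ceiling((b[2] - b[1]) / voxel - 1e-9)),
                 integer(1))
  sel <- events$t_s >= window[1] & events$t_s < window[2]
  ix <- floor((events$x_mm[sel] - bounds$x[1]) / voxel)
  iy <- floor((events$y_mm[sel] - bounds$y[1]) / voxel)
  iz <- floor((events$z_mm[sel] - bounds$z[1]) / voxel)
  ok <- ix >= 0 & ix < dims[1] & iy >= 0 & iy < dims[2] & iz >= 0 & iz < dims[3]
  lin <- 1 + ix[ok] + dims[1] * (iy[ok] + dims[2] * iz[ok])
  counts <- array(tabulate(lin, nbins = prod(dims)), dim = dims)
  structure(list(counts = counts, voxel = voxel, window = window,
                 origin = vapply(bounds, `[`, numeric(1), 1),
                 weight = attr(events, "weight") %||% 1),
            n_dropped = sum(sel) - sum(ok),
            class = "annihilation_map")
}

#' @export
print.annihilation_map <- function(x, ...) {
  cat(sprintf("<annihilation_map> %s voxels @ %.2g mm, window [%.4g, %.4g) s, %d counts\n",
              paste(dim(x$counts), collapse = "x"), x$voxel,
              x$window[1], x$window[2], round(sum(x$counts))))
  invisible(x)
}

# Sum compatible maps (same geometry); window becomes the union hull.
sum_maps <- function(maps) {
  out <- maps[[1]]
  for (m in maps[-1]) {
    stopifnot(all(dim(m$counts) == dim(out$counts)))
    out$counts <- out$counts + m$counts
    out$window <- range(c(out$window, m$window))
  }
  out
}

#' Gaussian system-resolution blur of a map
#'
#' Separable Gaussian convolution with per-axis sigma = fwhm/2.3548,
#' reflective boundary, kernel normalized so total intensity is conserved.
#' `fwhm = 0` is the identity. The default 3.5 mm is the estimated spatial
#' resolution of the PET scanner modelled by the study.
#'
#' @param map an `annihilation_map`.
#' @param fwhm full width at half maximum of the point-spread function, mm.
#' @return an `annihilation_map` with real-valued `counts`.
#' @export
blur_map <- function(map, fwhm = 3.5) {
  if (fwhm < 0) stopf("fwhm must be >= 0")
  if (fwhm == 0) return(map)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))   # 2.3548...
  sig_vox <- sigma / map$voxel
  r <- max(1L, as.integer(ceiling(4 * sig_vox)))
  k <- stats::dnorm(-r:r, sd = sig_vox)
  k <- k / sum(k)
  a <- map$counts
  for (axis in 1:3) a <- .conv_axis(a, k, axis)
  map$counts <- a
  map$psf_fwhm <- fwhm
  map
}

# 1D convolution along one axis of a 3D array with reflective boundary.
.conv_axis <- function(a, k, axis) {
  n <- dim(a)[axis]
  r <- (length(k) - 1L) / 2L
  out <- array(0, dim = dim(a))
  idx <- seq_len(n)
  for (j in -r:r) {
    src <- idx + j
    src <- ifelse(src < 1L, 2L - src, src)
    src <- ifelse(src > n, 2L * n - src, src)
    piece <- switch(axis,
                    a[src, , , drop = FALSE],
                    a[, src, , drop = FALSE],
                    a[, , src, drop = FALSE])
    out <- out + k[j + r + 1L] * piece
  }
  out
}

#' Export a map as MetaImage (.mhd/.raw) plus a dense TSV dump
#'
#' The MetaImage header is a short plain-text key-value file; the paired
#' `.raw` holds the voxel values as little-endian float64 in x-fastest
#' order. The TSV dump lists nonzero voxels as `ix iy iz value` (0-based).
#'
#' @param map an `annihilation_map`.
#' @param path output path without extension; writes `path.mhd`, `path.raw`
#'   and `path.tsv`.
#' @return invisibly, the `.mhd` path.
#' @export
write_map <- function(map, path) {
  d <- dim(map$counts)
  mhd <- paste0(path, ".mhd"); raw <- paste0(path, ".raw")
  writeLines(c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %g %g %g", map$voxel, map$voxel, map$voxel),
    sprintf("Offset = %g %g %g", map$origin[1], map$origin[2], map$origin[3]),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", basename(raw))
  ), mhd)
  con <- file(raw, open = "wb")
  writeBin(as.double(map$counts), con, size = 8, endian = "little")
  close(con)
  nz <- which(map$counts != 0, arr.ind = TRUE)
  write_tsv(data.frame(ix = nz[, 1] - 1L, iy = nz[, 2] - 1L, iz = nz[, 3] - 1L,
                       value = map$counts[nz]),
            paste0(path, ".tsv"),
            comments = sprintf("window_s: [%.6g, %.6g); voxel_mm: %g",
                               map$window[1], map$window[2], map$voxel))
  invisible(mhd)
}
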