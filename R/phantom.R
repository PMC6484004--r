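# Layered slab phantoms and water-equivalent depth.

# Default densities (g/cm^3) and water-equivalent ratios per material.
# The source study never prints WER values, so they are explicit, documented
# constants that every constructor accepts as overrides.
.material_defaults <- function() {
  data.frame(
    material = c("water", "PMMA", "bone", "brain"),
    density  = c(1.00, 1.19, 1.85, 1.05),
    wer      = c(1.00, 1.16, 1.60, 1.04),
    stringsAsFactors = FALSE
  )
}

#' Phantom slab
#'
#' One homogeneous layer of a slab phantom. `"brain"` denotes brain tissue
#' modelled as muscle. Density and water-equivalent ratio default to the
#' package's material table and can be overridden.
#'
#' @param material one of `"water"`, `"PMMA"`, `"bone"`, `"brain"`.
#' @param thickness slab thickness in mm (> 0).
#' @param density g/cm^3; default from the material table.
#' @param wer water-equivalent ratio (dimensionless, > 0).
#' @return an object of class `phantom_slab`.
#' @export
phantom_slab <- function(material, thickness, density = NULL, wer = NULL) {
  tab <- .material_defaults()
  if (!material %in% tab$material)
    stopf("unknown material '%s' (known: %s)", material,
          paste(tab$material, collapse = ", "))
  row <- tab[tab$material == material, ]
  density <- density %||% row$density
  wer <- wer %||% row$wer
  if (thickness <= 0) stopf("slab thickness must be > 0 (got %s)", thickness)
  if (density <= 0 || wer <= 0) stopf("density and wer must be > 0")
  structure(list(material = material, thickness = as.double(thickness),
                 density = as.double(density), wer = as.double(wer)),
            class = "phantom_slab")
}

#' Layered phantom
#'
#' An ordered, contiguous stack of slabs traversed by the beam along the
#' depth axis. Depth is measured in mm from the entry face (depth 0).
#'
#' @param slabs list of [phantom_slab] objects, in beam order.
#' @param entry_face_position position of the entry face in the lab frame, mm.
#' @return an object of class `phantom`.
#' @seealso [water_phantom()], [skull_phantom()]
#' @export
phantom <- function(slabs, entry_face_position = 0) {
  if (!length(slabs)) stopf("phantom needs at least one slab")
  if (inherits(slabs, "phantom_slab")) slabs <- list(slabs)
  stopifnot(all(vapply(slabs, inherits, logical(1), "phantom_slab")))
  thick <- vapply(slabs, `[[`, numeric(1), "thickness")
  structure(list(slabs = slabs,
                 entry_face_position = as.double(entry_face_position),
                 thickness = sum(thick),
                 boundaries = c(0, cumsum(thick))),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d slab(s), %.1f mm total\n", length(x$slabs), x$thickness))
  for (s in x$slabs)
    cat(sprintf("  %-6s %6.1f mm  (rho=%.2f, wer=%.2f)\n",
                s$material, s$thickness, s$density, s$wer))
  invisible(x)
}

#' @rdname phantom
#' @param thickness water thickness in mm.
#' @export
water_phantom <- function(thickness = 250) phantom(list(phantom_slab("water", thickness)))

#' Skull phantom: 10 mm bone followed by 240 mm brain tissue (as muscle)
#' @rdname phantom
#' @export
skull_phantom <- function() {
  phantom(list(phantom_slab("bone", 10), phantom_slab("brain", 240)))
}

#' Water-equivalent depth in a layered phantom
#'
#' Accumulates `thickness * wer` across the slabs traversed down to
#' `physical_depth`: piecewise linear, continuous across slab boundaries and
#' monotone increasing. `physical_from_wed()` is the exact inverse.
#'
#' @param phantom a [phantom].
#' @param physical_depth depth(s) from the entry face, mm; must lie in
#'   `[0, thickness]`.
#' @return water-equivalent depth(s) in mm.
#' @examples
#' water_equivalent_depth(skull_phantom(), 10)  # 10 mm bone * 1.6 = 16 mm
#' @export
water_equivalent_depth <- function(phantom, physical_depth) {
  if (any(physical_depth < 0)) stopf("physical_depth must be >= 0")
  if (any(physical_depth > phantom$thickness + 1e-9))
    stopf("physical_depth exceeds phantom thickness (%.1f mm)", phantom$thickness)
  wers <- vapply(phantom$slabs, `[[`, numeric(1), "wer")
  b <- phantom$boundaries
  wed_b <- c(0, cumsum(diff(b) * wers))
  i <- pmin(findInterval(physical_depth, b, rightmost.closed = TRUE,
                         left.open = FALSE), length(wers))
  i <- pmax(i, 1L)
  wed_b[i] + (physical_depth - b[i]) * wers[i]
}

#' @rdname water_equivalent_depth
#' @param wed water-equivalent depth(s), mm.
#' @export
physical_from_wed <- function(phantom, wed) {
  wers <- vapply(phantom$slabs, `[[`, numeric(1), "wer")
  b <- phantom$boundaries
  wed_b <- c(0, cumsum(diff(b) * wers))
  if (any(wed < 0)) stopf("wed must be >= 0")
  i <- pmin(findInterval(wed, wed_b, rightmost.closed = TRUE), length(wers))
  i <- pmax(i, 1L)
  out <- b[i] + (wed - wed_b[i]) / wers[i]
  pmin(out, phantom$thickness)
}

# Material of the slab containing a physical depth.
material_at_depth <- function(phantom, physical_depth) {
  b <- phantom$boundaries
  i <- pmin(pmax(findInterval(physical_depth, b, rightmost.closed = TRUE), 1L),
            length(phantom$slabs))
  vapply(phantom$slabs[i], `[[`, character(1), "material")
}

# Total water-equivalent extent of the phantom.
wed_extent <- function(phantom) water_equivalent_depth(phantom, phantom$thickness)
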