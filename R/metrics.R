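# Contrast-to-noise ratio between paired regions at the SOBP edges.

#' Region pair for CNR scoring
#'
#' @param inside,outside disjoint, non-empty vectors of linear voxel indices.
#' @param edge_label one of `"proximal"`, `"distal"`, `"lateral"`.
#' @return object of class `region_pair`.
#' @export
region_pair <- function(inside, outside, edge_label = "distal") {
  if (!length(inside) || !length(outside)) stopf("regions must be non-empty")
  if (length(intersect(inside, outside))) stopf("regions must be disjoint")
  structure(list(inside = as.integer(inside), outside = as.integer(outside),
                 edge_label = edge_label), class = "region_pair")
}

#' Contrast-to-noise ratio between two regions
#'
#' \deqn{CNR = |\mu_a - \mu_b| / \sqrt{\sigma_a^2 + \sigma_b^2}}
#' with population standard deviations (denominator = region size; the
#' defining expression carries no n-1 convention). Symmetric in the two
#' regions and invariant under affine intensity maps with positive scale.
#' If both SDs are zero: returns 0 when the means are equal, `Inf` with a
#' warning otherwise.
#'
#' @param map an `annihilation_map` (blurred or raw).
#' @param pair a [region_pair].
#' @return dimensionless CNR.
#' @export
cnr <- function(map, pair) {
  a <- map$counts[pair$inside]
  b <- map$counts[pair$outside]
  pop_var <- function(v) mean((v - mean(v))^2)
  va <- pop_var(a); vb <- pop_var(b)
  dmu <- abs(mean(a) - mean(b))
  if (va + vb == 0) {
    if (dmu == 0) return(0)
    warnf("zero variance in both regions with unequal means; CNR is infinite")
    return(Inf)
  }
  dmu / sqrt(va + vb)
}

#' SOBP edge region pairs on a map
#'
#' For each of the proximal, distal and upper-lateral SOBP boundaries,
#' builds an inside slab of thickness `slab` just inside the boundary and a
#' mirrored outside slab just beyond it, separated by `margin`. Proximal and
#' distal pairs are restricted to the central 50% of the transverse field;
#' the lateral pair to depths within the SOBP. The boundary geometry is not
#' specified by the source study; slab 10 mm, margin 0 are the package
#' defaults.
#'
#' @param map an `annihilation_map` (supplies geometry).
#' @param plan an [sobp_plan]; its `[proximal, distal]` are physical depths.
#' @param field_mm transverse field width, mm.
#' @param slab slab thickness, mm.
#' @param margin separation between inside and outside slabs, mm.
#' @return named list of three [region_pair]s (`proximal`, `distal`,
#'   `lateral`).
#' @export
sobp_edge_regions <- function(map, plan, field_mm = 60, slab = 10, margin = 0) {
  d <- dim(map$counts)
  cx <- map$origin[1] + (seq_len(d[1]) - 0.5) * map$voxel
  cy <- map$origin[2] + (seq_len(d[2]) - 0.5) * map$voxel
  cz <- map$origin[3] + (seq_len(d[3]) - 0.5) * map$voxel
  grid <- expand.grid(x = cx, y = cy, z = cz, KEEP.OUT.ATTRS = FALSE)
  central <- abs(grid$x) < field_mm / 4 & abs(grid$y) < field_mm / 4
  band <- function(v, lo, hi) v >= lo & v < hi
  check <- function(lo, hi, axis_range, what) {
    if (lo < axis_range[1] - 1e-9 || hi > axis_range[2] + 1e-9)
      stopf("%s region [%.1f, %.1f) exceeds map bounds [%.1f, %.1f)",
            what, lo, hi, axis_range[1], axis_range[2])
  }
  zr <- c(map$origin[3], map$origin[3] + d[3] * map$voxel)
  yr <- c(map$origin[2], map$origin[2] + d[2] * map$voxel)
  check(plan$proximal - margin - slab, plan$proximal, zr, "proximal-outside")
  check(plan$distal, plan$distal + margin + slab, zr, "distal-outside")
  check(field_mm / 2, field_mm / 2 + margin + slab, yr, "lateral-outside")
  proximal <- region_pair(
    which(central & band(grid$z, plan$proximal, plan$proximal + slab)),
    which(central & band(grid$z, plan$proximal - margin - slab, plan$proximal - margin)),
    "proximal")
  distal <- region_pair(
    which(central & band(grid$z, plan$distal - slab, plan$distal)),
    which(central & band(grid$z, plan$distal + margin, plan$distal + margin + slab)),
    "distal")
  in_sobp <- band(grid$z, plan$proximal, plan$distal) & abs(grid$x) < field_mm / 4
  lateral <- region_pair(
    which(in_sobp & band(grid$y, field_mm / 2 - slab, field_mm / 2)),
    which(in_sobp & band(grid$y, field_mm / 2 + margin, field_mm / 2 + margin + slab)),
    "lateral")
  list(proximal = proximal, distal = distal, lateral = lateral)
}

#' CNR table over maps and edges
#'
#' @param maps named list of `annihilation_map`s (names = acquisition
#'   windows).
#' @param pairs named list of [region_pair]s, as from [sobp_edge_regions()].
#' @return data.frame `window` x `edge` with CNR values.
#' @export
cnr_table <- function(maps, pairs) {
  out <- expand.grid(window = names(maps), edge = names(pairs),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$cnr <- mapply(function(w, e) cnr(maps[[w]], pairs[[e]]),
                    out$window, out$edge)
  out
}
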