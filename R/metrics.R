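#' Volume-weighted region statistics
#'
#' Mean and population-style standard deviation of a field over a masked
#' region, weighted by element (or voxel) volumes. Both outputs are invariant
#' to rescaling all weights.
#'
#' @param field numeric vector of values.
#' @param mask logical vector selecting the region (non-empty).
#' @param weights positive volumes, same length as `field`.
#' @return named vector `c(mean =, sd =)`.
#' @export
region_stats <- function(field, mask, weights) {
  stopifnot(length(field) == length(mask), length(field) == length(weights))
  if (!any(mask)) stop("empty mask")
  w <- weights[mask] / sum(weights[mask])
  x <- field[mask]
  mu <- sum(w * x)
  c(mean = mu, sd = sqrt(max(0, sum(w * (x - mu)^2))))
}

#' Volume-weighted Sorensen-Dice overlap of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)` with set sizes measured by the supplied
#' volumes; masks must live on the same discretization.
#'
#' @param mask_a,mask_b logical vectors of equal length.
#' @param weights positive volumes.
#' @return dimensionless overlap in `[0, 1]`.
#' @export
dice_coefficient <- function(mask_a, mask_b, weights) {
  stopifnot(length(mask_a) == length(mask_b), length(mask_a) == length(weights))
  va <- sum(weights[mask_a]); vb <- sum(weights[mask_b])
  if (va + vb == 0) stop("both masks empty")
  2 * sum(weights[mask_a & mask_b]) / (va + vb)
}

#' Volume fraction of a masked region above a threshold
#'
#' @param field numeric vector.
#' @param mask logical vector (non-empty).
#' @param threshold strict lower bound.
#' @param weights positive volumes.
#' @return fraction in `[0, 1]`.
#' @export
fraction_above <- function(field, mask, threshold, weights) {
  stopifnot(length(field) == length(mask), length(field) == length(weights))
  if (!any(mask)) stop("empty mask")
  sum(weights[mask & field > threshold]) / sum(weights[mask])
}

#' Geometry of the deformed tumor seed surface
#'
#' The material surface of the initial seed sphere, advected by the
#' displacement field, described both exactly (closed triangulated surface:
#' volume, area, sphericity) and as a star-shaped radius function over the
#' shared mesh directions (for overlap comparisons between runs).
#'
#' @param mesh a `gm_mesh`.
#' @param u n x 3 displacement field (mm), or `NULL` for the reference shape.
#' @return list of class `gm_tumor_shape`: `radius` (per seed direction, mm),
#'   `solid_angle`, `volume` (mm^3), `area` (mm^2), `sphericity` (1 for a
#'   perfect sphere).
#' @export
tumor_shape <- function(mesh, u = NULL) {
  x <- mesh$nodes[mesh$seed_nodes, , drop = FALSE]
  if (!is.null(u)) x <- x + u[mesh$seed_nodes, , drop = FALSE]
  lookup <- integer(nrow(mesh$nodes))
  lookup[mesh$seed_nodes] <- seq_along(mesh$seed_nodes)
  f <- matrix(lookup[mesh$seed_faces], ncol = 3)
  v1 <- x[f[, 1], , drop = FALSE]
  v2 <- x[f[, 2], , drop = FALSE]
  v3 <- x[f[, 3], , drop = FALSE]
  cr <- cbind(
    (v2[, 2] - v1[, 2]) * (v3[, 3] - v1[, 3]) - (v2[, 3] - v1[, 3]) * (v3[, 2] - v1[, 2]),
    (v2[, 3] - v1[, 3]) * (v3[, 1] - v1[, 1]) - (v2[, 1] - v1[, 1]) * (v3[, 3] - v1[, 3]),
    (v2[, 1] - v1[, 1]) * (v3[, 2] - v1[, 2]) - (v2[, 2] - v1[, 2]) * (v3[, 1] - v1[, 1]))
  area <- sum(sqrt(rowSums(cr^2))) / 2
  vol <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) +
             v1[, 2] * (v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]) +
             v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
  structure(list(radius = sqrt(rowSums(x^2)),
                 solid_angle = mesh$solid_angle,
                 volume = vol, area = area,
                 sphericity = pi^(1 / 3) * (6 * vol)^(2 / 3) / area),
            class = "gm_tumor_shape")
}

#' Dice overlap of two star-shaped tumor shapes
#'
#' Both shapes are represented by their radius functions over the same
#' direction set; the overlap volume integrates `min(R_a, R_b)^3 / 3` over
#' solid angle, matching the volume formula used for each shape alone.
#'
#' @param shape_a,shape_b `gm_tumor_shape` objects from the same mesh family.
#' @return Sorensen-Dice coefficient in `[0, 1]`.
#' @export
shape_dice <- function(shape_a, shape_b) {
  stopifnot(length(shape_a$radius) == length(shape_b$radius))
  w <- shape_a$solid_angle
  vab <- sum(w * pmin(shape_a$radius, shape_b$radius)^3) / 3
  va <- sum(w * shape_a$radius^3) / 3
  vb <- sum(w * shape_b$radius^3) / 3
  2 * vab / (va + vb)
}

#' Angular asymmetry of an intratumoral field
#'
#' Volume-weighted means of the field over the eight coordinate octants of
#' the tumor region; the asymmetry is the SD of the octant means divided by
#' the absolute overall mean. The octahedral mesh is symmetric under octant
#' reflections, so a radially symmetric simulation yields asymmetry at the
#' level of solver noise only.
#'
#' @param field per-element values.
#' @param mesh a `gm_mesh`.
#' @param weights per-element volumes (deformed volumes recommended).
#' @param mask logical per-element region mask (default: tumor region).
#' @return dimensionless asymmetry >= 0.
#' @export
angular_asymmetry <- function(field, mesh, weights, mask = NULL) {
  if (is.null(mask)) mask <- mesh$region == "tumor"
  cent <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
           mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  oct <- 1 + (cent[, 1] > 0) + 2 * (cent[, 2] > 0) + 4 * (cent[, 3] > 0)
  means <- vapply(1:8, function(o) {
    sel <- mask & oct == o
    if (!any(sel)) return(NA_real_)
    sum(field[sel] * weights[sel]) / sum(weights[sel])
  }, numeric(1))
  overall <- sum(field[mask] * weights[mask]) / sum(weights[mask])
  stats::sd(means, na.rm = TRUE) / abs(overall)
}
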