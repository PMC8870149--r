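#' Specification of a correlated random modulus field
#'
#' The generator emulates the spatial heterogeneity seen in elastography maps
#' of brain tissue: white noise smoothed with a Gaussian kernel of standard
#' deviation `correlation_length`, affinely rescaled to the requested mean and
#' standard deviation and clipped from below to keep moduli physical. The
#' defaults are literature-plausible magnitudes for brain tissue at 50 Hz,
#' not values taken from any specific acquisition.
#'
#' @param target_mean Pa, mean of the storage modulus before clipping.
#' @param target_sd Pa, standard deviation before clipping.
#' @param correlation_length mm, Gaussian smoothing kernel sigma.
#' @param loss_to_storage_ratio loss modulus as fraction of storage, in (0,1).
#' @param seed integer RNG seed.
#' @param clip_floor Pa, lower clip for the storage modulus.
#' @return object of class `gm_field_spec`.
#' @export
field_generator_spec <- function(target_mean = 1500, target_sd = 300,
                                 correlation_length = 8,
                                 loss_to_storage_ratio = 0.4,
                                 seed = 1L, clip_floor = 100) {
  if (target_mean <= 0) stop("target_mean must be positive")
  if (target_sd < 0) stop("target_sd must be non-negative")
  if (correlation_length <= 0) stop("correlation_length must be positive")
  if (clip_floor <= 0) stop("clip_floor must be positive")
  if (loss_to_storage_ratio <= 0 || loss_to_storage_ratio >= 1)
    stop("loss_to_storage_ratio must lie in (0,1)")
  structure(list(target_mean = target_mean, target_sd = target_sd,
                 correlation_length = correlation_length,
                 loss_to_storage_ratio = loss_to_storage_ratio,
                 seed = as.integer(seed), clip_floor = clip_floor),
            class = "gm_field_spec")
}

#' Tumor seed geometry
#' @param center mm 3-vector.
#' @param radius mm, positive; 5 mm default.
#' @return object of class `gm_seed_spec`.
#' @export
tumor_seed_spec <- function(center = c(0, 0, 0), radius = 5) {
  if (radius <= 0) stop("seed radius must be positive")
  structure(list(center = as.numeric(center), radius = radius),
            class = "gm_seed_spec")
}

# Gaussian smoothing along each axis with edge-renormalized truncated kernel
gauss_smooth3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    off <- (-half):half
    ker <- exp(-off^2 / (2 * s^2))
    n <- d[a]
    K <- matrix(0, n, n)
    for (j in seq_along(off)) {
      i <- seq_len(n)
      tgt <- i + off[j]
      ok <- tgt >= 1 & tgt <= n
      K[cbind(i[ok], tgt[ok])] <- K[cbind(i[ok], tgt[ok])] + ker[j]
    }
    K <- K / rowSums(K)
    perm <- c(a, setdiff(1:3, a))
    ap <- aperm(arr, perm)
    dp <- dim(ap)
    ap <- K %*% matrix(ap, nrow = dp[1])
    dim(ap) <- dp
    arr <- aperm(ap, order(perm))
  }
  arr
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a correlated storage/loss modulus voxel field
#'
#' Produces paired `storage_modulus_Pa` and `loss_modulus_Pa` channels on the
#' given grid geometry. Before clipping, the empirical mean and SD of the
#' storage modulus equal the targets exactly (affine rescaling); clipping at
#' `clip_floor` perturbs them slightly when the floor is active. The loss
#' modulus is a fixed fraction of the storage modulus: downstream mechanics
#' only uses the reconstructed elastic shear modulus, so the viscous channel
#' needs no independent spatial structure.
#'
#' @param spec a [field_generator_spec()].
#' @param grid a `gm_voxel_field` (channels ignored) or list with `origin`,
#'   `spacing`, `dims` defining the lattice; at least 4 voxels per axis.
#' @return `gm_voxel_field` with both modulus channels.
#' @export
generate_modulus_field <- function(spec, grid) {
  stopifnot(inherits(spec, "gm_field_spec"))
  dims <- as.integer(grid$dims)
  if (any(dims < 4)) stop("grid must have at least 4 voxels per axis")
  g <- with_seed(spec$seed, {
    z <- array(rnorm(prod(dims)), dims)
    z <- gauss_smooth3d(z, spec$correlation_length / grid$spacing)
    z <- (z - mean(z)) / max(sd(z), .Machine$double.eps)
    spec$target_mean + spec$target_sd * z
  })
  if (spec$target_sd == 0) g <- array(spec$target_mean, dims)
  g <- pmax(g, spec$clip_floor)
  voxel_field(grid$origin, grid$spacing, dims,
              list(storage_modulus_Pa = g,
                   loss_modulus_Pa = spec$loss_to_storage_ratio * g))
}

#' Generate a synthetic DTI-like tensor voxel field
#'
#' Voxelwise symmetric positive-definite tensors with exact trace
#' `3 * base_diffusivity`: `D = base * ((1-f) I + 3 f n n^T)` with a smoothed
#' random unit direction field `n` and anisotropy fraction `f`. Eigenvalues
#' are `base (1-f)` (twice) and `base (1+2f)`, so SPD holds for `f < 1` and
#' `f = 0` gives exactly `base * I`.
#'
#' @param base_diffusivity mm^2/day, positive.
#' @param anisotropy_fraction in `[0, 1)`.
#' @param seed integer RNG seed.
#' @param grid lattice geometry as in [generate_modulus_field()].
#' @param correlation_length mm smoothing of the direction field.
#' @return `gm_voxel_field` with tensor channel `dti_mm2_per_day`
#'   (lower-triangular order xx, yx, yy, zx, zy, zz).
#' @export
generate_dti_field <- function(base_diffusivity, anisotropy_fraction, seed,
                               grid, correlation_length = 6) {
  if (base_diffusivity <= 0) stop("base_diffusivity must be positive")
  if (anisotropy_fraction < 0 || anisotropy_fraction >= 1)
    stop("anisotropy_fraction must lie in [0, 1)")
  dims <- as.integer(grid$dims)
  f <- anisotropy_fraction
  nfield <- with_seed(seed, {
    v <- lapply(1:3, function(i)
      gauss_smooth3d(array(rnorm(prod(dims)), dims),
                     correlation_length / grid$spacing))
    nrm <- sqrt(v[[1]]^2 + v[[2]]^2 + v[[3]]^2)
    nrm[nrm < 1e-12] <- 1
    lapply(v, function(a) a / nrm)
  })
  b <- base_diffusivity
  ten <- array(0, c(dims, 6))
  ten[, , , 1] <- b * ((1 - f) + 3 * f * nfield[[1]]^2)            # xx
  ten[, , , 2] <- b * 3 * f * nfield[[2]] * nfield[[1]]            # yx
  ten[, , , 3] <- b * ((1 - f) + 3 * f * nfield[[2]]^2)            # yy
  ten[, , , 4] <- b * 3 * f * nfield[[3]] * nfield[[1]]            # zx
  ten[, , , 5] <- b * 3 * f * nfield[[3]] * nfield[[2]]            # zy
  ten[, , , 6] <- b * ((1 - f) + 3 * f * nfield[[3]]^2)            # zz
  voxel_field(grid$origin, grid$spacing, dims, list(dti_mm2_per_day = ten))
}

#' Embed patient tumor data into the spherical seed
#'
#' Affinely maps the rectangular parallelepiped `bbox` (the smallest box
#' containing the patient's tumor data) onto the axis-aligned cube
#' circumscribing the seed sphere, then samples the patient field at the
#' requested seed-interior points by trilinear interpolation of the mapped
#' coordinates.
#'
#' @param patient_field a `gm_voxel_field` holding the patient data.
#' @param bbox list with mm 3-vectors `lo` and `hi`; positive extent on all
#'   axes.
#' @param seed a [tumor_seed_spec()].
#' @param points k x 3 matrix of world points (seed frame, mm).
#' @param channel channel of `patient_field` to sample.
#' @return k-vector (or k x 6 matrix for tensor channels) of sampled values.
#' @export
embed_tumor_data <- function(patient_field, bbox, seed, points,
                             channel = "storage_modulus_Pa") {
  ext <- bbox$hi - bbox$lo
  if (any(ext <= 0)) stop("bbox must have positive extent on all axes")
  stopifnot(inherits(seed, "gm_seed_spec"))
  points <- rbind(points)
  cube_lo <- seed$center - seed$radius
  # map seed cube -> patient bbox
  tloc <- sweep(sweep(points, 2, cube_lo, "-"), 2, rep(2 * seed$radius, 3), "/")
  mapped <- sweep(sweep(tloc, 2, ext, "*"), 2, bbox$lo, "+")
  interpolate_voxels(patient_field, mapped, channel)
}

#' Interpolate a voxel channel onto mesh nodes
#'
#' Trilinear interpolation inside the lattice of voxel centers with
#' nearest-voxel (clamped) extrapolation outside; exact for fields that are
#' globally linear in the coordinates.
#'
#' @param field a `gm_voxel_field`.
#' @param mesh a `gm_mesh`.
#' @param channel channel name.
#' @return per-node vector or k x 6 matrix.
#' @export
interpolate_to_mesh <- function(field, mesh, channel) {
  if (is.null(mesh$nodes) || nrow(mesh$nodes) == 0) stop("empty mesh")
  interpolate_voxels(field, mesh$nodes, channel)
}

#' Generate a complete synthetic virtual patient
#'
#' Bundles the host elastography field, the patient tumor elastography field
#' on its own parallelepiped, and the DTI tensor field. Distinct seeds derived
#' from `seed` keep the three fields independent; the whole bundle is
#' deterministic in `seed`.
#'
#' @param config a [simulation_config()]; uses its `patient` block.
#' @param seed integer master seed overriding the config seed, or `NULL`.
#' @return list with `host` (modulus field), `tumor` (modulus field),
#'   `tumor_bbox`, `dti` (tensor field), `seed_spec`.
#' @export
virtual_patient <- function(config = simulation_config(), seed = NULL) {
  p <- config$patient
  if (!is.null(seed)) p$seed <- as.integer(seed)
  host_grid <- list(origin = rep(-p$host_extent_mm, 3),
                    spacing = rep(p$host_spacing_mm, 3),
                    dims = rep(2L * as.integer(p$host_extent_mm / p$host_spacing_mm) + 1L, 3))
  host_spec <- field_generator_spec(
    target_mean = p$host_mean_Pa, target_sd = p$host_sd_Pa,
    correlation_length = p$host_corr_mm,
    loss_to_storage_ratio = p$loss_to_storage_ratio,
    seed = p$seed, clip_floor = p$clip_floor_Pa)
  host <- generate_modulus_field(host_spec, host_grid)

  bbox <- list(lo = c(0, 0, 0), hi = p$tumor_bbox_mm)
  tumor_grid <- list(origin = c(0, 0, 0),
                     spacing = p$tumor_bbox_mm / (p$tumor_grid_n - 1),
                     dims = rep(as.integer(p$tumor_grid_n), 3))
  tumor_spec <- field_generator_spec(
    target_mean = p$tumor_mean_Pa, target_sd = p$tumor_sd_Pa,
    correlation_length = p$tumor_corr_mm,
    loss_to_storage_ratio = p$loss_to_storage_ratio,
    seed = p$seed + 1000L, clip_floor = p$clip_floor_Pa)
  tumor <- generate_modulus_field(tumor_spec, tumor_grid)

  dti <- generate_dti_field(p$dti_base_mm2_day, p$dti_anisotropy,
                            p$seed + 2000L, host_grid,
                            correlation_length = p$dti_corr_mm)
  list(host = host, tumor = tumor, tumor_bbox = bbox, dti = dti,
       seed_spec = tumor_seed_spec(radius = config$geometry$tumor_radius))
}

#' Nodal material fields for a virtual patient on a mesh
#'
#' Host moduli are interpolated everywhere; nodes inside the tumor seed are
#' overwritten with the embedded patient tumor data. Storage/loss pairs are
#' then inverted to the elastic shear modulus.
#'
#' @param patient output of [virtual_patient()].
#' @param mesh a `gm_mesh`.
#' @param omega rad/s MRE driving frequency.
#' @return list with per-node `G_storage`, `G_loss`, `G`, `tau_m` and
#'   per-node tensor matrix `dti` (n x 6, mm^2/day).
#' @export
patient_on_mesh <- function(patient, mesh, omega = 2 * pi * 50) {
  Gs <- interpolate_to_mesh(patient$host, mesh, "storage_modulus_Pa")
  Gl <- interpolate_to_mesh(patient$host, mesh, "loss_modulus_Pa")
  tn <- tumor_nodes(mesh)
  Gs[tn] <- embed_tumor_data(patient$tumor, patient$tumor_bbox,
                             patient$seed_spec, mesh$nodes[tn, , drop = FALSE],
                             "storage_modulus_Pa")
  Gl[tn] <- embed_tumor_data(patient$tumor, patient$tumor_bbox,
                             patient$seed_spec, mesh$nodes[tn, , drop = FALSE],
                             "loss_modulus_Pa")
  rec <- reconstruct_shear_modulus(Gs, Gl, omega)
  dti <- interpolate_to_mesh(patient$dti, mesh, "dti_mm2_per_day")
  list(G_storage = Gs, G_loss = Gl, G = rec$G, tau_m = rec$tau_m, dti = dti)
}
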