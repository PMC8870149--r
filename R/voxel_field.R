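#' Voxel field container
#'
#' Scalar or symmetric-tensor values on a regular axis-aligned 3D lattice.
#' World coordinates follow `x = origin + (index - 1) * spacing` with 1-based
#' voxel indices (the first voxel center sits at `origin`).
#'
#' @param origin mm 3-vector of the first voxel center.
#' @param spacing positive mm 3-vector.
#' @param dims 3 positive integers.
#' @param channels named list of arrays; scalar channels have dimension
#'   `dims`, tensor channels `c(dims, 6)` in lower-triangular order
#'   (xx, yx, yy, zx, zy, zz).
#' @return object of class `gm_voxel_field`.
#' @export
voxel_field <- function(origin, spacing, dims, channels = list()) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3, length(spacing) == 3, length(dims) == 3)
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  if (any(dims < 1)) stop("dims must be positive")
  for (nm in names(channels)) {
    d <- dim(channels[[nm]])
    if (!(identical(d[1:3], dims) && (length(d) == 3 || (length(d) == 4 && d[4] == 6L))))
      stop("channel '", nm, "' shape does not match dims")
  }
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 channels = channels),
            class = "gm_voxel_field")
}

#' @export
print.gm_voxel_field <- function(x, ...) {
  cat(sprintf("<gm_voxel_field> %dx%dx%d, spacing %s mm, channels: %s\n",
              x$dims[1], x$dims[2], x$dims[3],
              paste(signif(x$spacing, 3), collapse = "x"),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Voxel-center world coordinates along each axis
#' @param field a `gm_voxel_field`.
#' @return list of 3 numeric vectors.
#' @export
voxel_axes <- function(field) {
  lapply(1:3, function(a) field$origin[a] + (seq_len(field$dims[a]) - 1) * field$spacing[a])
}

#' Trilinear interpolation of a voxel channel at world points
#'
#' Points outside the lattice of voxel centers are clamped to it, which
#' realizes nearest-voxel extrapolation: a point straight outside a face
#' takes values from that face.
#'
#' @param field a `gm_voxel_field`.
#' @param points k x 3 matrix of world coordinates (mm).
#' @param channel channel name.
#' @return k-vector (scalar channel) or k x 6 matrix (tensor channel).
#' @export
interpolate_voxels <- function(field, points, channel) {
  arr <- field$channels[[channel]]
  if (is.null(arr)) stop("no channel '", channel, "'")
  points <- rbind(points)
  if (nrow(points) == 0) stop("no points to interpolate")
  idx <- sweep(sweep(points, 2, field$origin, "-"), 2, field$spacing, "/") + 1
  ncomp <- if (length(dim(arr)) == 4) 6L else 1L
  out <- matrix(NA_real_, nrow(points), ncomp)
  i0 <- w <- matrix(0, nrow(points), 3)
  for (a in 1:3) {
    xi <- pmin(pmax(idx[, a], 1), field$dims[a])
    i0[, a] <- pmin(floor(xi), field$dims[a] - 1L)
    if (field$dims[a] == 1L) i0[, a] <- 1
    w[, a] <- xi - i0[, a]
  }
  d <- field$dims
  for (cc in seq_len(ncomp)) {
    a3 <- if (ncomp == 1) arr else arr[, , , cc]
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ww <- (if (dx == 1) w[, 1] else 1 - w[, 1]) *
            (if (dy == 1) w[, 2] else 1 - w[, 2]) *
            (if (dz == 1) w[, 3] else 1 - w[, 3])
      ii <- cbind(pmin(i0[, 1] + dx, d[1]), pmin(i0[, 2] + dy, d[2]),
                  pmin(i0[, 3] + dz, d[3]))
      acc <- acc + ww * a3[ii]
    }
    out[, cc] <- acc
  }
  if (ncomp == 1) out[, 1] else out
}

#' Write a voxel field to NIfTI
#'
#' Scalar channels are written as 3D volumes, tensor channels as 4D volumes
#' with 6 components (lower-triangular order). Geometry goes in the qform
#' (axis-aligned scaling plus translation; no oblique affines).
#'
#' @param field a `gm_voxel_field`.
#' @param path file path without channel suffix; each channel `ch` is written
#'   to `<path>_<ch>.nii.gz`.
#' @return invisibly, the named vector of files written.
#' @export
write_voxel_field <- function(field, path) {
  files <- c()
  for (nm in names(field$channels)) {
    img <- RNifti::asNifti(field$channels[[nm]])
    nd <- length(dim(field$channels[[nm]]))
    img <- RNifti::`pixdim<-`(img, c(field$spacing, rep(1, nd - 3)))
    sf <- diag(c(field$spacing, 1))
    sf[1:3, 4] <- field$origin
    img <- RNifti::`qform<-`(img, structure(sf, code = 2L))
    f <- paste0(path, "_", nm, ".nii.gz")
    RNifti::writeNifti(img, f)
    files[nm] <- f
  }
  invisible(files)
}

#' Read a voxel field from NIfTI files written by [write_voxel_field()]
#'
#' @param path base path used at write time.
#' @param channels channel names to read.
#' @return a `gm_voxel_field`.
#' @export
read_voxel_field <- function(path, channels) {
  chan <- list()
  origin <- spacing <- dims <- NULL
  for (nm in channels) {
    img <- RNifti::readNifti(paste0(path, "_", nm, ".nii.gz"))
    xf <- RNifti::xform(img)
    a <- as.array(img)
    chan[[nm]] <- a
    origin <- xf[1:3, 4]
    spacing <- diag(xf)[1:3]
    dims <- dim(a)[1:3]
  }
  voxel_field(origin, spacing, dims, chan)
}
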