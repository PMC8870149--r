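#' Stress-induced vessel compression
#'
#' Maps the bulk solid stress (trace of the Cauchy stress; negative =
#' compression) to the degree of vessel compression `d/d0`. An exponential
#' half-compression law is used: the diameter ratio is 1 at zero or tensile
#' bulk stress, halves at a compressive magnitude of `sigma_half`, and decays
#' exponentially beyond: `d/d0 = exp(-ln 2 * max(0, -sigma_bulk)/sigma_half)`.
#' The law is monotone, bounded in (0, 1] and controlled by a single
#' interpretable parameter.
#'
#' @param sigma_bulk Pa, bulk solid stress (vectorized).
#' @param sigma_half Pa > 0, compressive bulk stress at which the vessel
#'   diameter halves.
#' @return dimensionless diameter ratio in (0, 1].
#' @export
vessel_compression <- function(sigma_bulk, sigma_half = 1000) {
  if (sigma_half <= 0) stop("sigma_half must be positive")
  exp(-log(2) * pmax(0, -sigma_bulk) / sigma_half)
}

#' Functional vascular density from vessel compression
#'
#' Stress affects vessel diameter but not vessel length or number, so the
#' functional vascular surface density scales linearly with the diameter
#' ratio: `S_v = (d/d0) S_v0`.
#'
#' @param d_ratio diameter ratio in `[0, 1]`.
#' @param S_v0 reference (host) vascular density, 1/mm, >= 0.
#' @return functional vascular density, 1/mm.
#' @export
functional_density <- function(d_ratio, S_v0) {
  if (any(d_ratio < 0 | d_ratio > 1)) stop("d_ratio must lie in [0, 1]")
  if (any(S_v0 < 0)) stop("S_v0 must be non-negative")
  d_ratio * S_v0
}
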