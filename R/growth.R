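#' Oxygen-limited mass growth rate
#'
#' Michaelis-Menten dependence on the local oxygen concentration scaled by the
#' normalized cancer-cell density: `r_g = k1 * c_ox / (k2 + c_ox) * T_cel`,
#' bounded above by `k1 * T_cel`.
#'
#' @param c_ox oxygen concentration (model units), non-negative (vectorized).
#' @param T_cel normalized cell density, non-negative.
#' @param k1 1/day maximal specific growth rate.
#' @param k2 oxygen half-saturation (same units as `c_ox`).
#' @return 1/day growth rate.
#' @export
growth_rate <- function(c_ox, T_cel, k1, k2) {
  if (any(c_ox < 0)) stop("c_ox must be non-negative")
  if (any(T_cel < 0)) stop("T_cel must be non-negative")
  k1 * c_ox / (k2 + c_ox) * T_cel
}

#' Stress-biased growth anisotropy multipliers
#'
#' Distributes the mass growth among the laboratory axes with a normalized
#' exponential weighting of the normal Cauchy stresses:
#' `Gamma_a = exp(A sigma_aa / k) / sum_b exp(A sigma_bb / k)`.
#' Growth is biased toward directions of less compressive (more tensile)
#' normal stress; `A = 0` gives the isotropic split (1/3, 1/3, 1/3).
#' Computed with max-subtraction so arbitrarily large `|A sigma / k|` cannot
#' overflow.
#'
#' @param sigma_diag length-3 vector (or n x 3 matrix) of normal Cauchy
#'   stresses (Pa) in the laboratory frame.
#' @param A dimensionless anisotropy degree, >= 0.
#' @param k Pa bulk modulus used as the stress normalization.
#' @return length-3 vector (or n x 3 matrix) of multipliers summing to 1.
#' @export
anisotropy_multipliers <- function(sigma_diag, A, k) {
  if (k <= 0) stop("bulk modulus k must be positive")
  if (A < 0) stop("anisotropy degree A must be non-negative")
  s <- rbind(sigma_diag)
  z <- A * s / k
  z <- z - apply(z, 1, max)
  e <- exp(z)
  out <- e / rowSums(e)
  if (is.matrix(sigma_diag)) out else drop(out)
}

#' Advance the growth stretch ratios by one time step
#'
#' The stretch-rate law `dlambda_a/dt = Gamma_a r_g lambda_a` is linear in
#' each stretch at frozen coefficients, so the step uses the exact
#' exponential map `lambda_a <- lambda_a * exp(Gamma_a r_g dt)`. Since the
#' multipliers sum to one, `det Fg` grows exactly by `exp(r_g dt)` per step
#' regardless of how growth is distributed. Stretches are floored at 1
#' (growth only, no resorption).
#'
#' @param lambda_g length-3 vector (or n x 3 matrix) of growth stretches.
#' @param r_g 1/day growth rate (scalar or length-n).
#' @param Gamma multipliers from [anisotropy_multipliers()].
#' @param dt day, positive.
#' @return updated stretches, same shape as `lambda_g`.
#' @export
step_growth_stretches <- function(lambda_g, r_g, Gamma, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (any(r_g < 0)) stop("r_g must be non-negative")
  lam <- rbind(lambda_g) * exp(rbind(Gamma) * r_g * dt)
  lam <- pmax(lam, 1)
  if (is.matrix(lambda_g)) lam else drop(lam)
}
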