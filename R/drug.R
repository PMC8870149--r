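# Centerline hydrodynamic resistance coefficients for a sphere in a
# cylindrical pore, Bungay & Brenner (1973); also tabulated by Deen (1987).
.bb_a <- c(-73 / 60, 77293 / 50400, -22.5083, -5.6117, -0.3363, -1.216, 1.647)
.bb_b <- c(7 / 60, -2227 / 50400, 4.0180, -3.9788, -1.9215, 4.392, 5.006)

.bb_K <- function(lam, coef) {
  t1 <- 9 / 4 * pi^2 * sqrt(2) * (1 - lam)^(-5 / 2) *
    (1 + coef[1] * (1 - lam) + coef[2] * (1 - lam)^2)
  t2 <- coef[3] + coef[4] * lam + coef[5] * lam^2 + coef[6] * lam^3 +
    coef[7] * lam^4
  t1 + t2
}

#' Hindrance factors for a spherical solute in a cylindrical pore
#'
#' Hard-sphere hindered transport through the vessel-wall pores: the steric
#' partition coefficient `F = (1-lambda)^2`, the Bungay-Brenner hydrodynamic
#' resistances `K_t`, `K_s`, the diffusive hindrance `H = 6 pi F / K_t`, the
#' convective hindrance `w = F (2-F) K_s / (2 K_t)` and the reflection
#' coefficient `sigma_f = 1 - w`. A point particle (`lambda = 0`) passes
#' unhindered (`H = w = 1`, `sigma_f = 0`); at `lambda = 1` the pore excludes
#' the solute completely.
#'
#' @param lambda_ratio solute radius / pore radius, in `[0, 1]` (vectorized).
#' @return list with `F_part`, `K_t`, `K_s`, `H`, `w`, `sigma_f`.
#' @export
hindrance_factors <- function(lambda_ratio) {
  lam <- as.numeric(lambda_ratio)
  if (any(lam < 0 | lam > 1)) stop("lambda_ratio must lie in [0, 1]")
  F_part <- (1 - lam)^2
  Kt <- .bb_K(lam, .bb_a)
  Ks <- .bb_K(lam, .bb_b)
  H <- 6 * pi * F_part / Kt
  w <- F_part * (2 - F_part) * Ks / (2 * Kt)
  # lambda = 1: complete exclusion; the resistances diverge and the factors
  # vanish with F
  H[lam == 1] <- 0
  w[lam == 1] <- 0
  list(F_part = F_part, K_t = Kt, K_s = Ks, H = H, w = w, sigma_f = 1 - w)
}

#' Vessel-wall transport coefficients from pore geometry and drug size
#'
#' Pore-level expressions for the wall hydraulic conductivity
#' `L_p = gamma r0^2 / (8 eta L_vw)`, the drug permeability
#' `Per = gamma H D0 / L_vw` and the reflection coefficient
#' `sigma_f = 1 - w`.
#'
#' @param gamma pore area fraction of the wall (dimensionless).
#' @param r0 pore radius, mm.
#' @param eta plasma viscosity, Pa s.
#' @param L_vw vessel wall thickness, mm.
#' @param D0 free-solution diffusivity of the drug, mm^2/s.
#' @param lambda_ratio drug radius / pore radius.
#' @return list with `L_p` (mm/(Pa s)), `Per` (mm/s), `sigma_f`, plus the
#'   underlying hindrance factors.
#' @export
wall_transport <- function(gamma, r0, eta, L_vw, D0, lambda_ratio) {
  stopifnot(gamma > 0, r0 > 0, eta > 0, L_vw > 0, D0 > 0)
  hf <- hindrance_factors(lambda_ratio)
  list(L_p = gamma * r0^2 / (8 * eta * L_vw),
       Per = gamma * hf$H * D0 / L_vw,
       sigma_f = hf$sigma_f,
       hindrance = hf)
}

#' Stokes-Einstein free-solution diffusivity
#' @param radius_mm particle radius, mm.
#' @param temperature_K absolute temperature (310 K default).
#' @param eta Pa s solvent viscosity.
#' @return mm^2/s.
#' @export
stokes_einstein_D0 <- function(radius_mm, temperature_K = 310,
                               eta = 3e-3) {
  kB <- 1.380649e-23                      # J/K
  r_m <- radius_mm * 1e-3
  D_m2s <- kB * temperature_K / (6 * pi * eta * r_m)
  D_m2s * 1e6                             # m^2/s -> mm^2/s
}

#' Vascular drug concentration after a bolus injection
#'
#' Single exponential plasma decay, normalized to 1 at the injection time;
#' zero before the injection.
#'
#' @param t day (vectorized).
#' @param t0 day, injection time.
#' @param k_d day, circulation decay constant, > 0.
#' @return dimensionless concentration.
#' @export
vascular_concentration <- function(t, t0, k_d) {
  if (k_d <= 0) stop("k_d must be positive")
  ifelse(t >= t0, exp(-(t - t0) / k_d), 0)
}

#' Starling transvascular drug flux
#'
#' Diffusive plus convective (reflection-weighted filtration) exchange across
#' the vessel wall:
#' `Q = Per S_v (C_iv - c_f) + L_p S_v (p_v - p_i) (1 - sigma_f) C_iv`.
#'
#' @param Per mm/s vascular permeability of the drug.
#' @param S_v 1/mm functional vascular density (vectorized).
#' @param C_iv vascular (plasma) concentration.
#' @param c_f free interstitial concentration.
#' @param L_p mm/(Pa s) wall hydraulic conductivity.
#' @param p_v,p_i Pa vascular and interstitial pressures.
#' @param sigma_f reflection coefficient.
#' @return volumetric source, 1/s (concentration per second).
#' @export
starling_flux <- function(Per, S_v, C_iv, c_f, L_p, p_v, p_i, sigma_f) {
  if (any(S_v < 0)) stop("S_v must be non-negative")
  Per * S_v * (C_iv - c_f) + L_p * S_v * (p_v - p_i) * (1 - sigma_f) * C_iv
}

#' Advance the free/bound/internalized drug fields by one sub-step
#'
#' Free drug: backward-Euler diffusion with explicit conservative convection,
#' transvascular source and binding exchange; bound and internalized pools:
#' explicit local kinetics. Binding, unbinding and internalization transfers
#' are evaluated once from the previous state and applied with equal and
#' opposite signs, so with vessels and flow off the (mass-lumped) spatial
#' total of `c_f + c_b + c_int` is conserved to solver accuracy.
#'
#' @param state list with per-node `c_f`, `c_b`, `c_int`.
#' @param v_f m x 3 mm/s fluid velocity.
#' @param Q_sta per-node transvascular source, 1/s (e.g. from
#'   [starling_flux()]).
#' @param mesh a `gm_mesh`.
#' @param params list with `D_f` (mm^2/s), `k_on`, `k_off`, `k_int` (1/s),
#'   `c_e` (receptor concentration), `Phi` (accessible volume fraction).
#' @param dt seconds.
#' @param ops cached [fem_operators()] (optional).
#' @param chol_A cached Cholesky factor of the diffusion system (optional;
#'   built when `NULL`).
#' @param conv cached convection matrix for the current velocity field
#'   (optional; rebuilt when `NULL` and the velocity is non-zero).
#' @return updated state list (with the factor attached as attribute
#'   `chol_A` for reuse).
#' @export
step_drug <- function(state, v_f, Q_sta, mesh, params, dt, ops = NULL,
                      chol_A = NULL, conv = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (is.null(ops)) ops <- fem_operators(mesh)
  n <- ops$n
  cf <- state$c_f; cb <- state$c_b; ci <- state$c_int
  bind <- params$k_on * params$c_e * params$Phi * cf
  unbind <- params$k_off * cb
  internal <- params$k_int * cb
  rhs <- ops$M * cf + dt * ops$M * (Q_sta - bind + unbind)
  if (is.null(conv) && any(v_f != 0)) conv <- ops$convection(v_f)
  if (!is.null(conv)) rhs <- rhs + dt * as.numeric(conv %*% cf)
  if (params$D_f > 0) {
    if (is.null(chol_A)) {
      A <- Matrix::Diagonal(n, ops$M) + dt * ops$stiffness(params$D_f)
      chol_A <- Matrix::Cholesky(Matrix::forceSymmetric(A))
    }
    cf1 <- as.numeric(Matrix::solve(chol_A, rhs))
  } else {
    cf1 <- rhs / ops$M
  }
  out <- list(c_f = pmax(cf1, 0),
              c_b = pmax(cb + dt * (bind - unbind - internal), 0),
              c_int = ci + dt * internal)
  attr(out, "chol_A") <- chol_A
  out
}
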