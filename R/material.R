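#' Invert storage/loss moduli to the elastic shear modulus
#'
#' The complex shear modulus of a single-relaxation-time solid at driving
#' frequency `omega` has storage part `G (w tau)^2 / (1 + (w tau)^2)` and loss
#' part `G w tau / (1 + (w tau)^2)`. Given measured storage and loss moduli
#' this inverts uniquely to the elastic shear modulus
#' `G = G' + G''^2 / G'` and decay time `tau_m = G' / (G'' omega)`.
#' The viscous branch is reported but unused by the quasi-static mechanics:
#' growth-scale deformation rates are far below the relaxation rate.
#'
#' @param G_storage Pa, positive (vectorized).
#' @param G_loss Pa, non-negative.
#' @param omega rad/s, positive.
#' @return list with `G` (Pa) and `tau_m` (s; `Inf` in the purely elastic
#'   limit `G_loss = 0`).
#' @export
reconstruct_shear_modulus <- function(G_storage, G_loss, omega) {
  if (any(G_storage <= 0)) stop("G_storage must be positive")
  if (any(G_loss < 0)) stop("G_loss must be non-negative")
  if (any(omega <= 0)) stop("omega must be positive")
  G <- G_storage + G_loss^2 / G_storage
  tau_m <- ifelse(G_loss == 0, Inf, G_storage / (G_loss * omega))
  list(G = G, tau_m = tau_m)
}

#' Storage and loss moduli of the single-relaxation-time solid
#'
#' Forward counterpart of [reconstruct_shear_modulus()].
#'
#' @param G Pa shear modulus.
#' @param tau_m s decay time (may be `Inf`).
#' @param omega rad/s.
#' @return list with `G_storage`, `G_loss` (Pa).
#' @export
viscoelastic_moduli <- function(G, tau_m, omega) {
  wt <- omega * tau_m
  Gs <- ifelse(is.infinite(wt), G, G * wt^2 / (1 + wt^2))
  Gl <- ifelse(is.infinite(wt), 0, G * wt / (1 + wt^2))
  list(G_storage = Gs, G_loss = Gl)
}

#' Neo-Hookean strain energy and Cauchy stress
#'
#' Compressible neo-Hookean response of the solid phase evaluated at an
#' elastic deformation gradient `Fe`. By default the shear term uses the
#' isochoric first invariant `Ibar1 = Je^(-2/3) I1`, which makes the
#' reference state exactly stress-free; `isochoric = FALSE` selects the
#' uncorrected invariant `I1` (which carries a spurious reference stress and
#' is kept only for comparison).
#'
#' @param Fe 3x3 elastic deformation gradient with positive determinant.
#' @param G Pa shear modulus.
#' @param k Pa bulk modulus.
#' @param isochoric logical, see above.
#' @return list of class `gm_elastic_state`: `Fe`, `Je`, `I1`, `W` (Pa),
#'   `sigma` (3x3 Cauchy stress, Pa).
#' @export
cauchy_stress <- function(Fe, G, k, isochoric = TRUE) {
  Fe <- as.matrix(Fe)
  stopifnot(all(dim(Fe) == c(3, 3)))
  Je <- det(Fe)
  if (Je <= 0) stop("inverted element: det(Fe) <= 0")
  I1 <- sum(Fe^2)
  FeinvT <- t(solve(Fe))
  if (isochoric) {
    W <- G / 2 * (Je^(-2 / 3) * I1 - 3) + k / 2 * (Je - 1)^2
    dWdFe <- G * Je^(-2 / 3) * (Fe - I1 / 3 * FeinvT) + k * (Je - 1) * Je * FeinvT
  } else {
    W <- G / 2 * (I1 - 3) + k / 2 * (Je - 1)^2
    dWdFe <- G * Fe + k * (Je - 1) * Je * FeinvT
  }
  sigma <- dWdFe %*% t(Fe) / Je
  sigma <- (sigma + t(sigma)) / 2
  structure(list(Fe = Fe, Je = Je, I1 = I1, W = W, sigma = sigma),
            class = "gm_elastic_state")
}
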