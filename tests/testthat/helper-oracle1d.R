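# Independent 1D spherically symmetric reference solvers used as oracles for
# the 3D finite-element code. They share no code with the package: finite
# differences on a radial grid, with the constitutive response written out
# in closed form for diagonal stretches.

# Cauchy stress components for a radially symmetric deformation with
# principal stretches (lr, lt, lt), isotropic growth stretch lg:
# neo-Hookean with isochoric shear invariant.
.oracle_sigma_radial <- function(lr, lt, lg, G, k) {
  er <- lr / lg
  et <- lt / lg
  Je <- er * et^2
  I1 <- er^2 + 2 * et^2
  c1 <- G * Je^(-2 / 3)
  srr <- (c1 * (er^2 - I1 / 3) + k * (Je - 1) * Je) / Je
  stt <- (c1 * (et^2 - I1 / 3) + k * (Je - 1) * Je) / Je
  list(srr = srr, stt = stt)
}

# Equilibrium d(sigma_rr)/dr + 2 (sigma_rr - sigma_tt)/r = 0 in the deformed
# radial coordinate r = R + u, with u(0) = 0 and u(R_out) = 0 (confined) and
# isotropic growth lg inside the tumor radius. Newton on the nodal
# displacements with a finite-difference banded Jacobian.
oracle_confined_growth_1d <- function(R_tumor = 5, R_out = 50, lam_g = 1.1,
                                      G = 1000, k = 15000, n = 500,
                                      grade = 2.5) {
  # graded grid: fine near the tumor interface
  s <- seq(0, 1, length.out = n)
  R <- R_out * (exp(grade * s) - 1) / (exp(grade) - 1)
  R <- R[abs(R - R_tumor) > R_out / (4 * n)]  # avoid near-duplicate at interface
  R <- sort(unique(c(R, R_tumor)))
  n <- length(R)
  mid <- (R[-1] + R[-n]) / 2
  lg_mid <- ifelse(mid < R_tumor, lam_g, 1)

  # finite-volume residual of d(r^2 sigma_rr)/dr = 2 r sigma_tt on the
  # deformed grid; exact for homogeneous states (sigma_rr = sigma_tt const)
  # on arbitrary grids
  resid <- function(u) {
    r <- R + u
    lr <- diff(u) / diff(R) + 1
    lt <- (r[-1] + r[-n]) / (R[-1] + R[-n])
    sg <- .oracle_sigma_radial(lr, lt, lg_mid, G, k)
    rm <- (r[-1] + r[-n]) / 2          # deformed midpoints (cell faces)
    flux <- rm^2 * sg$srr
    ri <- r[2:(n - 1)]
    wp <- rm[-1]^2 - ri^2              # integral weights of 2 r dr
    wm <- ri^2 - rm[-(n - 1)]^2
    src <- sg$stt[-1] * wp + sg$stt[-(n - 1)] * wm
    (diff(flux) - src) / (ri^2 * (mid[-1] - mid[-(n - 1)]))
  }

  u <- numeric(n)
  # load stepping on lam_g
  for (theta in seq(0.2, 1, by = 0.2)) {
    lg_mid <- ifelse(mid < R_tumor, lam_g^theta, 1)
    for (it in 1:60) {
      r0 <- resid(u)
      if (max(abs(r0)) < 1e-11 * G) break
      # banded FD Jacobian on interior unknowns (tridiagonal coupling)
      J <- matrix(0, n - 2, n - 2)
      h <- 1e-7 * R_out
      for (shift in 0:2) {
        cols <- seq(2 + shift, n - 1, by = 3)
        up <- u
        up[cols] <- up[cols] + h
        rp <- resid(up)
        for (cidx in cols) {
          rows <- intersect((cidx - 1):(cidx + 1), 2:(n - 1))
          J[rows - 1, cidx - 1] <- (rp[rows - 1] - r0[rows - 1]) / h
        }
      }
      du <- solve(J, -r0)
      alpha <- 1
      repeat {
        ut <- u
        ut[2:(n - 1)] <- ut[2:(n - 1)] + alpha * du
        if (max(abs(resid(ut))) < max(abs(r0)) || alpha < 1e-4) break
        alpha <- alpha / 2
      }
      u[2:(n - 1)] <- u[2:(n - 1)] + alpha * du
    }
  }
  r <- R + u
  lr <- diff(u) / diff(R) + 1
  lt <- (r[-1] + r[-n]) / (R[-1] + R[-n])
  sg <- .oracle_sigma_radial(lr, lt, lg_mid, G, k)
  list(R = R, u = u, r_mid = mid, r_mid_def = (r[-1] + r[-n]) / 2,
       sigma_rr = sg$srr, sigma_tt = sg$stt,
       sigma_bulk = sg$srr + 2 * sg$stt)
}

# Steady interstitial fluid pressure for a uniform vascularized sphere:
# -(k_th / r^2) d/dr(r^2 dp/dr) = a(r) (p_v - p) - b(r) (p - p_vl)
# with a = L_p S_v (everywhere), b = lymphatic drainage in the host only;
# p'(0) = 0, p(R_out) = 0. Second-order finite differences, direct solve.
oracle_ifp_1d <- function(R_tumor = 5, R_out = 50, k_th = 4e-7,
                          Lp_tumor = 1e-8, Lp_host = 1e-9, Sv = 7,
                          p_v = 2000, Lpl_Svl = 1.6e-8, p_vl = 0, n = 4000) {
  r <- seq(0, R_out, length.out = n)
  h <- r[2] - r[1]
  a <- ifelse(r < R_tumor, Lp_tumor, Lp_host) * Sv
  b <- ifelse(r < R_tumor, 0, Lpl_Svl)
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  for (i in 2:(n - 1)) {
    rp <- r[i] + h / 2
    rm <- r[i] - h / 2
    A[i, i - 1] <- -k_th * rm^2 / (h^2 * r[i]^2)
    A[i, i + 1] <- -k_th * rp^2 / (h^2 * r[i]^2)
    A[i, i] <- k_th * (rp^2 + rm^2) / (h^2 * r[i]^2) + a[i] + b[i]
    rhs[i] <- a[i] * p_v + b[i] * p_vl
  }
  # r = 0: symmetry; laplacian -> 6 (p1 - p0) / h^2
  A[1, 1] <- 6 * k_th / h^2 + a[1] + b[1]
  A[1, 2] <- -6 * k_th / h^2
  rhs[1] <- a[1] * p_v + b[1] * p_vl
  A[n, n] <- 1
  rhs[n] <- 0
  p <- solve(A, rhs)
  list(r = r, p = p)
}
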