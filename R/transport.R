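#' Assemble and cache scalar FEM operators for a mesh
#'
#' @param mesh a `gm_mesh`.
#' @return list with `M` (lumped mass vector, mm^3) and closures building
#'   stiffness/convection sparse matrices.
#' @keywords internal
fem_operators <- function(mesh) {
  n <- nrow(mesh$nodes)
  list(
    n = n,
    M = as.numeric(.lumped_mass(n, mesh$tets, mesh$vol)),
    stiffness = function(D_elem) {
      D <- if (is.matrix(D_elem)) D_elem else matrix(rep_len(D_elem, nrow(mesh$tets)), ncol = 1)
      tr <- .scalar_stiffness(mesh$tets, mesh$grads, mesh$vol, D)
      Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(n, n))
    },
    convection = function(v_elem) {
      tr <- .convection_matrix(mesh$tets, mesh$grads, mesh$vol, v_elem)
      Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(n, n))
    }
  )
}

#' Solve the interstitial fluid pressure and Darcy velocity
#'
#' Steady Darcy flow with Starling filtration from the functional vasculature
#' and lymphatic drainage (host tissue only; tumors lack functional
#' lymphatics): `-div(k_th grad p_i) = L_P S_v (p_v - p_i) -
#' L_Pl S_vl (p_i - p_vl)`. The outer boundary is pinned to the far-field
#' reference (0 Pa gauge) when `pin_boundary` is `TRUE`; otherwise a no-flux
#' (natural) condition applies and the source terms must render the system
#' non-singular.
#'
#' @param mesh a `gm_mesh`.
#' @param Sv_node per-node functional vascular density, 1/mm.
#' @param wall list with `L_p` (mm/(Pa s)) per node or scalar, `p_v` (Pa).
#' @param lymph list with `L_pl` (mm/(Pa s)), `S_vl` (1/mm), `p_vl` (Pa);
#'   applied on host nodes only.
#' @param k_th mm^2/(Pa s) hydraulic conductivity (scalar or per element).
#' @param pin_boundary pin outer boundary nodes to 0 Pa.
#' @param ops cached [fem_operators()] (optional).
#' @return list of class `gm_fluid_state`: `p_i` (Pa per node), `v_f`
#'   (m x 3 mm/s per element), `grad_p` (m x 3).
#' @export
solve_ifp <- function(mesh, Sv_node, wall, lymph, k_th, pin_boundary = TRUE,
                      ops = NULL) {
  if (any(k_th <= 0)) stop("k_th must be positive")
  if (any(Sv_node < 0)) stop("Sv must be non-negative")
  if (is.null(ops)) ops <- fem_operators(mesh)
  n <- ops$n
  m_el <- nrow(mesh$tets)
  # wall conductivity given per element (region-wise) is accumulated to nodes
  # through the element integrals, so interface nodes see the correct mixture
  # of tumor and host wall properties
  Lp_node <- if (length(wall$L_p) == m_el && m_el != n) {
    acc <- numeric(n)
    w <- mesh$vol / 4
    for (a4 in 1:4) acc <- acc + tapply_add(mesh$tets[, a4], wall$L_p * w, n)
    acc / ops$M
  } else rep_len(wall$L_p, n)
  a <- Lp_node * Sv_node
  b_elem <- ifelse(mesh$region == "host",
                   rep_len(lymph$L_pl, m_el) * rep_len(lymph$S_vl, m_el), 0)
  b <- {
    acc <- numeric(n)
    w <- mesh$vol / 4
    for (a4 in 1:4) acc <- acc + tapply_add(mesh$tets[, a4], b_elem * w, n)
    acc / ops$M
  }
  if (!pin_boundary && all(a + b == 0))
    stop("singular system: no sources and no boundary pinning")
  K <- ops$stiffness(k_th)
  A <- K + Matrix::Diagonal(n, ops$M * (a + b))
  rhs <- ops$M * (a * wall$p_v + b * lymph$p_vl)
  chol_solve <- function(M, b) {
    tryCatch(as.numeric(Matrix::solve(
      Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE, super = TRUE),
      b)), error = function(e) as.numeric(Matrix::solve(M, b)))
  }
  if (pin_boundary) {
    fix <- mesh$outer_nodes
    free <- setdiff(seq_len(n), fix)
    p <- numeric(n)
    p[free] <- chol_solve(A[free, free], rhs[free])
  } else {
    p <- chol_solve(A, rhs)
  }
  gp <- .elem_gradient(mesh$tets, mesh$grads, p)
  kt <- rep_len(k_th, nrow(mesh$tets))
  structure(list(p_i = p, v_f = -kt * gp, grad_p = gp),
            class = "gm_fluid_state")
}

#' Advance the cancer-cell density by one growth step
#'
#' Operator splitting: reaction first, integrated exactly per node (both the
#' tumor oxygen-limited term and the host constant proliferation are linear
#' in the density at frozen oxygen), then one backward-Euler step of the
#' DTI-anisotropic diffusion. Non-negativity is preserved by construction.
#'
#' @param T_cel per-node normalized cell density.
#' @param D_T per-element tensor matrix (m x 6, mm^2/day) or scalar/vector
#'   isotropic diffusivity.
#' @param c_ox per-node oxygen concentration.
#' @param mesh a `gm_mesh`.
#' @param params list with `k1`, `k2` (tumor growth) and `rho_cell` (1/day,
#'   host proliferation).
#' @param dt day.
#' @param ops cached [fem_operators()] (optional).
#' @param tumor_node logical per node, tumor region membership.
#' @return updated per-node density.
#' @export
step_cells <- function(T_cel, D_T, c_ox, mesh, params, dt, ops = NULL,
                       tumor_node = NULL) {
  if (dt <= 0) stop("dt must be positive")
  # P1 diffusion on a general tet mesh has no discrete maximum principle;
  # tolerate front undershoots at the discretization-noise level but reject
  # genuinely negative densities
  if (any(T_cel < -1e-3 * max(abs(T_cel), 1)))
    stop("T_cel must be non-negative")
  if (is.matrix(D_T)) {
    # SPD via Sylvester's criterion (vectorized leading principal minors)
    d11 <- D_T[, 1]; d21 <- D_T[, 2]; d22 <- D_T[, 3]
    d31 <- D_T[, 4]; d32 <- D_T[, 5]; d33 <- D_T[, 6]
    m2 <- d11 * d22 - d21^2
    m3 <- d11 * (d22 * d33 - d32^2) - d21 * (d21 * d33 - d32 * d31) +
      d31 * (d21 * d32 - d22 * d31)
    scl <- pmax(d11, d22, d33, 1e-300)
    if (any(d11 < -1e-12 * scl) || any(m2 < -1e-12 * scl^2) ||
        any(m3 < -1e-12 * scl^3))
      stop("D_T must be symmetric positive definite")
  }
  if (is.null(ops)) ops <- fem_operators(mesh)
  if (is.null(tumor_node)) tumor_node <- seq_len(ops$n) %in% tumor_nodes(mesh)
  rate <- ifelse(tumor_node,
                 params$k1 * c_ox / (params$k2 + c_ox),
                 params$rho_cell)
  T1 <- T_cel * exp(rate * dt)
  if (all(D_T == 0)) return(T1)
  K <- ops$stiffness(D_T)
  A <- Matrix::Diagonal(ops$n, ops$M) + dt * K
  as.numeric(Matrix::solve(A, ops$M * T1))
}

#' Advance the oxygen concentration by one time step
#'
#' Splitting scheme for the convection-diffusion-reaction balance: one
#' backward-Euler diffusion/convection step followed by exact-tolerance
#' integration of the local vascular supply and Michaelis-Menten uptake
#' (classical RK4 sub-stepping). With transport off this reduces to the
#' well-mixed ODE; with reactions off the spatial integral is conserved
#' exactly (lumped mass, integrated-by-parts convection).
#'
#' @param c_ox per-node concentration.
#' @param v_f m x 3 interstitial fluid velocity, mm/s.
#' @param S_v per-node functional vascular density, 1/mm.
#' @param T_cel per-node cell density.
#' @param mesh a `gm_mesh`.
#' @param params list with `D_ox` (mm^2/s), `A_ox` (1/s), `k_ox`, `c_iox`,
#'   `Per_ox` (mm/s).
#' @param dt seconds.
#' @param ops cached [fem_operators()] (optional).
#' @return updated per-node concentration.
#' @export
step_oxygen <- function(c_ox, v_f, S_v, T_cel, mesh, params, dt, ops = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (is.null(ops)) ops <- fem_operators(mesh)
  n <- ops$n
  c1 <- c_ox
  if (params$D_ox > 0 || any(v_f != 0)) {
    A <- Matrix::Diagonal(n, ops$M)
    if (params$D_ox > 0) A <- A + dt * ops$stiffness(params$D_ox)
    rhs <- ops$M * c_ox
    if (any(v_f != 0)) rhs <- rhs + dt * as.numeric(ops$convection(v_f) %*% c_ox)
    c1 <- as.numeric(Matrix::solve(A, rhs))
  }
  # local source/sink: dc/dt = Per_ox S_v (c_iox - c) - A_ox c/(c+k_ox) T
  sup <- params$Per_ox * S_v
  f <- function(cc) sup * (params$c_iox - cc) - params$A_ox * cc / (cc + params$k_ox) * T_cel
  nsub <- max(1L, ceiling(dt * max(sup, params$A_ox * max(T_cel, 1)) / 0.1))
  h <- dt / nsub
  for (s in seq_len(nsub)) {
    k1v <- f(c1)
    k2v <- f(pmax(c1 + h / 2 * k1v, 0))
    k3v <- f(pmax(c1 + h / 2 * k2v, 0))
    k4v <- f(pmax(c1 + h * k3v, 0))
    c1 <- c1 + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
  }
  c1
}

#' Quasi-steady oxygen field
#'
#' Picard iteration on the steady convection-diffusion-reaction balance with
#' the Michaelis-Menten uptake linearized about the previous iterate. Used by
#' the growth loop: oxygen equilibrates in minutes, far below the 0.5-day
#' growth step.
#'
#' @inheritParams step_oxygen
#' @param c_init starting guess.
#' @param tol relative update tolerance.
#' @param maxit maximum Picard iterations.
#' @return per-node steady concentration.
#' @export
solve_oxygen_steady <- function(v_f, S_v, T_cel, mesh, params,
                                c_init = NULL, tol = 1e-10, maxit = 60,
                                ops = NULL) {
  if (is.null(ops)) ops <- fem_operators(mesh)
  n <- ops$n
  cc <- if (is.null(c_init)) rep(params$c_iox, n) else c_init
  K <- ops$stiffness(params$D_ox)
  Cm <- if (any(v_f != 0)) ops$convection(v_f) else NULL
  sup <- params$Per_ox * S_v
  for (it in seq_len(maxit)) {
    upt <- params$A_ox * T_cel / (cc + params$k_ox)
    A <- K + Matrix::Diagonal(n, ops$M * (sup + upt))
    if (!is.null(Cm)) A <- A - Cm
    rhs <- ops$M * (sup * params$c_iox)
    cnew <- pmin(pmax(as.numeric(Matrix::solve(A, rhs)), 0), params$c_iox)
    if (max(abs(cnew - cc)) <= tol * params$c_iox) { cc <- cnew; break }
    cc <- cnew
  }
  cc
}
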