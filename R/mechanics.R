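#' Solve the quasi-static stress balance for the grown configuration
#'
#' Total-Lagrangian displacement formulation of
#' `div(sigma_s - p_i I) = 0` with the multiplicative split `F = Fe Fg`
#' and compressible neo-Hookean solid response, discretized with first-order
#' tetrahedra. Newton iterations use a consistent (element finite-difference)
#' tangent with backtracking line search; the growth tensor is ramped
#' automatically in sub-increments if a full step fails to converge.
#'
#' @param mesh a `gm_mesh`.
#' @param G_elem,k_elem Pa per-element shear and bulk moduli.
#' @param Fg_elem m x 3 matrix of diagonal growth stretches (or `NULL` for
#'   no growth).
#' @param p_node per-node interstitial pressure (Pa) entering the total
#'   stress, or `NULL`.
#' @param bc `"fixed_outer"` (outer boundary clamped, the default),
#'   `"free"` (test-only: rigid modes pinned at the center node and two
#'   axis nodes) or a list `list(nodes=, values=)` prescribing displacements
#'   of the outer-boundary nodes (patch tests).
#' @param u0 n x 3 initial guess (warm start), or `NULL`.
#' @param isochoric use the isochoric-invariant strain energy (default TRUE).
#' @param tol relative residual tolerance of the Newton loop.
#' @param maxit maximum Newton iterations per load increment.
#' @param verbose print per-iteration residuals.
#' @return list of class `gm_mech_solution`: `u` (n x 3 mm), `sigma`
#'   (m x 6 Cauchy solid stress, lower-tri order), `sigma_bulk` (m, trace),
#'   `J`, `Je` (m), `iterations`, `residual`.
#' @export
solve_displacement <- function(mesh, G_elem, k_elem, Fg_elem = NULL,
                               p_node = NULL, bc = "fixed_outer", u0 = NULL,
                               isochoric = TRUE, tol = 1e-8, maxit = 50,
                               verbose = FALSE) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tets)
  G_elem <- rep_len(G_elem, m)
  k_elem <- rep_len(k_elem, m)
  if (any(G_elem <= 0) || any(k_elem <= 0)) stop("material moduli must be positive")
  if (is.null(Fg_elem)) Fg_elem <- matrix(1, m, 3)
  Fg_elem <- rbind(Fg_elem)
  if (nrow(Fg_elem) == 1) Fg_elem <- matrix(Fg_elem, m, 3, byrow = TRUE)
  if (any(Fg_elem < 1 - 1e-12)) stop("growth stretches must be >= 1")
  pvec <- if (is.null(p_node)) numeric(0) else rep_len(p_node, n)

  u <- if (is.null(u0)) matrix(0, n, 3) else u0
  fixed <- matrix(FALSE, n, 3)
  if (is.character(bc) && bc == "fixed_outer") {
    fixed[mesh$outer_nodes, ] <- TRUE
    u[mesh$outer_nodes, ] <- 0
  } else if (is.character(bc) && bc == "free") {
    ctr <- which.min(rowSums(mesh$nodes^2))
    fixed[ctr, ] <- TRUE
    # kill rotations: node on +x axis may not move in y,z; node on +y axis not in z
    ax <- function(dir) {
      d <- mesh$nodes %*% dir
      r <- sqrt(rowSums(mesh$nodes^2))
      which.max(d - 0.999 * r)
    }
    nx <- ax(c(1, 0, 0)); ny <- ax(c(0, 1, 0))
    fixed[nx, c(2, 3)] <- TRUE
    fixed[ny, 3] <- TRUE
    u[fixed] <- 0
  } else if (is.list(bc)) {
    fixed[bc$nodes, ] <- TRUE
    u[bc$nodes, ] <- bc$values
  } else stop("unknown bc")
  free_dof <- which(!t(fixed))   # dof order (node-major, xyz fastest)

  # force scale for the absolute convergence floor
  fscale <- stats::median(G_elem) * mean(mesh$vol)^(2 / 3) * sqrt(n)

  chol_cache <- NULL   # symbolic Cholesky analysis reused across iterations

  resid_norm <- function(uu) {
    r <- .mech_residual(mesh$nodes, mesh$tets, mesh$grads, mesh$vol, uu,
                        G_elem, k_elem, Fg_cur, pvec, isochoric)
    if (!isTRUE(r$ok)) return(list(ok = FALSE))
    list(ok = TRUE, norm = sqrt(sum(r$resid[free_dof]^2)), resid = r$resid)
  }

  nsub <- 1
  repeat {
    ok_all <- TRUE
    u_try <- u
    for (s in seq_len(nsub)) {
      theta <- s / nsub
      Fg_cur <- exp(theta * log(Fg_elem))
      conv <- FALSE
      it <- 0
      r0 <- NA_real_
      while (it < maxit) {
        asm <- .mech_assemble(mesh$nodes, mesh$tets, mesh$grads, mesh$vol,
                              u_try, G_elem, k_elem, Fg_cur, pvec, isochoric,
                              TRUE)
        if (!isTRUE(asm$ok)) { ok_all <- FALSE; break }
        rn <- sqrt(sum(asm$resid[free_dof]^2))
        if (it == 0) r0 <- max(rn, tol * fscale)
        if (verbose) message(sprintf("  sub %d it %d resid %.3e", s, it, rn))
        if (rn <= tol * max(r0, fscale)) { conv <- TRUE; break }
        K <- Matrix::sparseMatrix(i = asm$Ti, j = asm$Tj, x = asm$Tx,
                                  dims = c(3 * n, 3 * n))
        # the hyperelastic tangent is symmetric up to finite-difference noise;
        # prefer (supernodal) Cholesky, fall back to LDL then LU when the
        # tangent is indefinite far from equilibrium
        Kf <- Matrix::forceSymmetric(K[free_dof, free_dof])
        rhs <- -asm$resid[free_dof]
        sol_lin <- suppressWarnings(tryCatch({
          ch <- if (is.null(chol_cache)) {
            Matrix::Cholesky(Kf, LDL = FALSE, super = TRUE)
          } else {
            Matrix::update(chol_cache, Kf)
          }
          chol_cache <- ch
          as.numeric(Matrix::solve(ch, rhs))
        }, error = function(e) tryCatch(
          as.numeric(Matrix::solve(Matrix::Cholesky(Kf), rhs)),
          error = function(e2)
            as.numeric(Matrix::solve(K[free_dof, free_dof], rhs)))))
        du <- numeric(3 * n)
        du[free_dof] <- sol_lin
        step <- matrix(du, n, 3, byrow = TRUE)
        alpha <- 1
        repeat {
          cand <- resid_norm(u_try + alpha * step)
          if (cand$ok && cand$norm < (1 - 1e-4 * alpha) * rn) break
          alpha <- alpha / 2
          if (alpha < 1e-6) break
        }
        u_try <- u_try + alpha * step
        it <- it + 1
      }
      if (!ok_all || !conv) { ok_all <- FALSE; break }
    }
    if (ok_all) { u <- u_try; break }
    nsub <- nsub * 2
    if (nsub > 16)
      stop(sprintf("mechanics solve did not converge (last residual %.3e)",
                   if (exists("rn")) rn else NA))
  }

  Fg_cur <- Fg_elem
  asm <- .mech_assemble(mesh$nodes, mesh$tets, mesh$grads, mesh$vol, u,
                        G_elem, k_elem, Fg_elem, pvec, isochoric, FALSE)
  rn <- sqrt(sum(asm$resid[free_dof]^2))
  structure(list(u = u, sigma = asm$sigma,
                 sigma_bulk = bulk_stress(asm$sigma),
                 J = asm$J, Je = asm$Je,
                 residual = rn), class = "gm_mech_solution")
}

#' Bulk solid stress (trace of the Cauchy stress)
#'
#' Negative values denote compression. Accepts a single 3x3 tensor or an
#' m x 6 matrix in lower-triangular order (xx, yx, yy, zx, zy, zz).
#'
#' @param sigma stress tensor(s), Pa.
#' @return scalar or m-vector, Pa.
#' @export
bulk_stress <- function(sigma) {
  if (is.matrix(sigma) && ncol(sigma) == 6)
    return(sigma[, 1] + sigma[, 3] + sigma[, 6])
  if (is.matrix(sigma) && all(dim(sigma) == c(3, 3)))
    return(sum(diag(sigma)))
  stop("sigma must be 3x3 or m x 6")
}

#' Diagonal (normal) components of element stresses in the laboratory frame
#' @param sigma m x 6 lower-triangular stress components.
#' @return m x 3 matrix (sigma_xx, sigma_yy, sigma_zz).
#' @export
normal_stresses <- function(sigma) {
  cbind(sigma[, 1], sigma[, 3], sigma[, 6])
}
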