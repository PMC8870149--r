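test_that("IFP with no sources relaxes to the far-field reference", {
  m <- small_mesh()
  n <- nrow(m$nodes)
  f <- solve_ifp(m, rep(7, n), list(L_p = 0, p_v = 2000),
                 list(L_pl = 0, S_vl = 7, p_vl = 0), 4e-7)
  expect_lt(max(abs(f$p_i)), 1e-9)
  expect_lt(max(abs(f$v_f)), 1e-12)
  expect_error(solve_ifp(m, rep(7, n), list(L_p = 0, p_v = 2000),
                         list(L_pl = 0, S_vl = 7, p_vl = 0), 4e-7,
                         pin_boundary = FALSE), "singular")
})

test_that("IFP matches the 1D finite-difference oracle", {
  m <- ball_mesh(ball_shells(n_tumor = 3, n_rim = 4, n_far = 7), subdiv = 3)
  n <- nrow(m$nodes)
  Lp_t <- wall_transport(1e-3, 1e-4, 3e-3, 5e-3, 1e-4, 0.01)$L_p
  Lp_h <- wall_transport(1e-3, 1e-5, 3e-3, 5e-3, 1e-4, 0.1)$L_p
  Lp <- ifelse(m$region == "tumor", Lp_t, Lp_h)
  f <- solve_ifp(m, rep(7, n), list(L_p = Lp, p_v = 2000),
                 list(L_pl = 2.3e-9, S_vl = 7, p_vl = 0), 4e-7)
  o <- oracle_ifp_1d(Lp_tumor = Lp_t, Lp_host = Lp_h, Lpl_Svl = 2.3e-9 * 7)
  # compare the radial pressure profile (per-shell means); nodewise values
  # carry angular faceting scatter at the interface boundary layer
  shl <- round(sqrt(rowSums(m$nodes^2)), 6)
  prof <- tapply(f$p_i, shl, mean)
  p1 <- approx(o$r, o$p, as.numeric(names(prof)), rule = 2)$y
  expect_lt(max(abs(prof - p1)) / 2000, 0.01)
})

test_that("cell density: pure reaction follows the closed-form exponential", {
  m <- small_mesh()
  n <- nrow(m$nodes)
  # host-only field, no diffusion: T(t) = T(0) exp(rho t)
  T0 <- rep(0.3, n)
  prm <- list(k1 = 0, k2 = 0.25, rho_cell = 0.04)
  T1 <- step_cells(T0, 0, rep(1, n), m, prm, dt = 2,
                   tumor_node = rep(FALSE, n))
  expect_equal(T1, T0 * exp(0.08), tolerance = 1e-12)
  # zero diffusion and zero reaction: unchanged
  prm0 <- list(k1 = 0, k2 = 0.25, rho_cell = 0)
  expect_equal(step_cells(T0, 0, rep(1, n), m, prm0, dt = 1), T0)
  expect_error(step_cells(T0 - 10, 0, rep(1, n), m, prm0, dt = 1),
               "non-negative")
})

test_that("cell diffusion spreads a point release at the right rate", {
  # isotropic D on a fine ball mesh: second moment of a compact release grows
  # as 2 D t per axis
  m <- ball_mesh(c(1.5, 3, 5, 7, 9, 12, 16, 21, 27, 34, 42, 50), subdiv = 3,
                 tumor_radius = 5)
  n <- nrow(m$nodes)
  ops <- gliomech:::fem_operators(m)
  nr <- sqrt(rowSums(m$nodes^2))
  T0 <- exp(-nr^2 / (2 * 2^2))   # gaussian, var 4 per axis
  D <- 0.5
  prm <- list(k1 = 0, k2 = 1, rho_cell = 0)
  Tt <- T0
  dt <- 0.5
  for (s in 1:8) Tt <- step_cells(Tt, D, rep(1, n), m, prm, dt, ops = ops)
  t_tot <- 8 * dt
  m2 <- function(f) sum(ops$M * f * nr^2) / sum(ops$M * f) / 3  # per-axis var
  expect_equal(m2(Tt) - m2(T0), 2 * D * t_tot, tolerance = 0.05)
})

test_that("cell step rejects indefinite diffusion tensors", {
  m <- small_mesh()
  Dbad <- matrix(rep(c(1, 0, 1, 0, 0, -2), each = nrow(m$tets)), nrow(m$tets))
  expect_error(step_cells(rep(1, nrow(m$nodes)), Dbad, rep(1, nrow(m$nodes)),
                          m, list(k1 = 0, k2 = 1, rho_cell = 0), 1),
               "positive definite")
})

test_that("oxygen step conserves mass without sources and holds its bounds", {
  m <- small_mesh()
  n <- nrow(m$nodes)
  ops <- gliomech:::fem_operators(m)
  set.seed(2)
  c0 <- runif(n, 0.2, 0.9)
  prm <- list(D_ox = 0.5, A_ox = 0, k_ox = 0.1, c_iox = 1, Per_ox = 0)
  cc <- c0
  for (s in 1:20) cc <- step_oxygen(cc, matrix(0, nrow(m$tets), 3), rep(0, n),
                                    rep(0, n), m, prm, dt = 0.5, ops = ops)
  expect_equal(sum(ops$M * cc), sum(ops$M * c0), tolerance = 1e-8)
  # maximum principle: bounded sources keep the band [0, c_iox]
  prm2 <- list(D_ox = 0.5, A_ox = 2e-2, k_ox = 0.1, c_iox = 1, Per_ox = 1e-2)
  cc <- c0
  for (s in 1:20) cc <- step_oxygen(cc, matrix(0, nrow(m$tets), 3), rep(5, n),
                                    runif(n), m, prm2, dt = 1, ops = ops)
  expect_gt(min(cc), -1e-8)
  expect_lt(max(cc), 1 + 1e-8)
})

test_that("well-mixed oxygen trajectory matches an independent ODE solution", {
  m <- small_mesh()
  n <- nrow(m$nodes)
  prm <- list(D_ox = 0, A_ox = 3e-3, k_ox = 0.15, c_iox = 1, Per_ox = 2e-3)
  Sv <- 5; Tc <- 2
  cc <- rep(0.9, n)
  nst <- 40; dt <- 5
  for (s in seq_len(nst))
    cc <- step_oxygen(cc, matrix(0, nrow(m$tets), 3), rep(Sv, n), rep(Tc, n),
                      m, prm, dt = dt)
  ref <- deSolve::ode(c(c = 0.9), seq(0, nst * dt, length.out = 5),
                      function(t, y, p)
                        list(prm$Per_ox * Sv * (prm$c_iox - y) -
                             prm$A_ox * y / (y + prm$k_ox) * Tc),
                      NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(cc[1]), unname(ref[5, "c"]), tolerance = 1e-6)
  expect_lt(diff(range(cc)), 1e-12)
})

test_that("steady oxygen balances supply and uptake pointwise without transport", {
  m <- small_mesh()
  n <- nrow(m$nodes)
  prm <- list(D_ox = 0, A_ox = 3e-3, k_ox = 0.15, c_iox = 1, Per_ox = 2e-3)
  cc <- solve_oxygen_steady(matrix(0, nrow(m$tets), 3), rep(5, n), rep(2, n),
                            m, prm)
  res <- prm$Per_ox * 5 * (1 - cc) - prm$A_ox * cc / (cc + prm$k_ox) * 2
  expect_lt(max(abs(res)), 1e-8)
})

test_that("IFP two-regime behavior: plateau rises and rim sharpens with pore size", {
  m <- medium_mesh()
  n <- nrow(m$nodes)
  tum_el <- m$region == "tumor"
  nr <- sqrt(rowSums(m$nodes^2))
  Lp_h <- wall_transport(1e-3, 1e-5, 3e-3, 5e-3, 1e-4, 0.1)$L_p
  core <- sapply(c(100, 200, 300), function(pore) {
    Lp_t <- wall_transport(1e-3, pore / 2 * 1e-6, 3e-3, 5e-3, 1e-4, 0.01)$L_p
    f <- solve_ifp(m, rep(7, n), list(L_p = ifelse(tum_el, Lp_t, Lp_h), p_v = 2000),
                   list(L_pl = 2.3e-9, S_vl = 7, p_vl = 0), 4e-7)
    mean(f$p_i[nr < 2.5])
  })
  expect_true(all(diff(core) > 0))
  expect_gt(core[3] / 2000, 0.99)
})
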