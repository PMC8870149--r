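test_that("hindrance factors have exact exclusion limits and near-unit passage", {
  h1 <- hindrance_factors(1)
  expect_equal(h1$F_part, 0)
  expect_equal(h1$H, 0)
  expect_equal(h1$w, 0)
  expect_equal(h1$sigma_f, 1)
  # the published resistance coefficients are rounded to ~5 digits, so the
  # point-particle limit holds to that precision
  h0 <- hindrance_factors(0)
  expect_equal(h0$F_part, 1)
  expect_equal(h0$H, 1, tolerance = 1e-5)
  expect_equal(h0$w, 1, tolerance = 1e-5)
  expect_equal(h0$sigma_f, 0, tolerance = 1e-5)
  expect_error(hindrance_factors(1.5), "0, 1")
})

test_that("hindrance factors match the extended-precision series oracle", {
  got <- hindrance_factors(hindrance_reference$lambda)
  expect_equal(got$H, hindrance_reference$H, tolerance = 1e-10)
  expect_equal(got$w, hindrance_reference$w, tolerance = 1e-10)
  expect_equal(got$sigma_f, 1 - hindrance_reference$w, tolerance = 1e-10)
})

test_that("hindrance factors are monotone in the size ratio", {
  lam <- seq(0.005, 0.95, by = 0.005)
  h <- hindrance_factors(lam)
  expect_true(all(diff(h$F_part) < 0))
  expect_true(all(diff(h$H) < 0))
  expect_true(all(diff(h$w) < 0))
  expect_true(all(diff(h$sigma_f) > 0))
})

test_that("wall transport coefficients follow the pore-geometry formulas", {
  # gamma 0.05, pore radius 100 nm, eta 3e-3 Pa s, wall 5 um:
  # L_p = 0.05 * (1e-7 m)^2 / (8 * 3e-3 * 5e-6) ~ 4.1667e-9 m/(Pa s)
  wt <- wall_transport(0.05, 1e-4, 3e-3, 5e-3, 1e-4, 0.01)
  expect_equal(wt$L_p * 1e-3, 4.1667e-9, tolerance = 1e-4)  # mm -> m
  # doubling the pore radius quadruples L_p
  wt2 <- wall_transport(0.05, 2e-4, 3e-3, 5e-3, 1e-4, 0.01)
  expect_equal(wt2$L_p / wt$L_p, 4, tolerance = 1e-12)
  # exclusion limit kills the permeability
  expect_equal(wall_transport(0.05, 1e-4, 3e-3, 5e-3, 1e-4, 1)$Per, 0)
})

test_that("bolus concentration decays from unity after injection", {
  expect_equal(vascular_concentration(41, 41, 0.5), 1)
  expect_equal(vascular_concentration(41.5, 41, 0.5), exp(-1))
  expect_equal(vascular_concentration(40.9, 41, 0.5), 0)
  expect_error(vascular_concentration(1, 0, -1), "positive")
})

test_that("Starling flux vanishes at equilibrium and is linear in Sv", {
  expect_equal(starling_flux(1e-5, 7, 0.5, 0.5, 1e-8, 2000, 2000, 0.3), 0)
  q1 <- starling_flux(1e-5, 7, 1, 0.2, 1e-8, 2000, 500, 0.3)
  q2 <- starling_flux(1e-5, 14, 1, 0.2, 1e-8, 2000, 500, 0.3)
  expect_equal(q2, 2 * q1, tolerance = 1e-12)
})

test_that("binding-internalization kinetics follow the closed-form solution", {
  m <- small_mesh()
  n <- nrow(m$nodes)
  ops <- gliomech:::fem_operators(m)
  # binding off, start fully bound: c_b = e^(-k_int t), c_int = 1 - e^(-k_int t)
  prm <- list(D_f = 0, k_on = 0, k_off = 0, k_int = 1e-3, c_e = 1, Phi = 1)
  st <- list(c_f = rep(0, n), c_b = rep(1, n), c_int = rep(0, n))
  dt <- 1; nst <- 200
  for (s in 1:nst) st <- step_drug(st, matrix(0, nrow(m$tets), 3), rep(0, n),
                                   m, prm, dt, ops = ops)
  t_tot <- nst * dt
  # explicit kinetics: first-order accurate, k dt = 1e-3 per step
  expect_equal(st$c_b[1], exp(-1e-3 * t_tot), tolerance = 1e-3)
  expect_equal(st$c_int[1], 1 - exp(-1e-3 * t_tot), tolerance = 1e-3)
  expect_equal(st$c_b + st$c_int, rep(1, n), tolerance = 1e-12)
})

test_that("all pools freeze when every rate is off", {
  m <- small_mesh()
  n <- nrow(m$nodes)
  prm <- list(D_f = 0, k_on = 0, k_off = 0, k_int = 0, c_e = 1, Phi = 1)
  set.seed(4)
  st0 <- list(c_f = runif(n), c_b = runif(n), c_int = runif(n))
  st <- step_drug(st0, matrix(0, nrow(m$tets), 3), rep(0, n), m, prm, 60)
  expect_equal(st$c_f, st0$c_f)
  expect_equal(st$c_b, st0$c_b)
  expect_equal(st$c_int, st0$c_int)
})

test_that("closed tissue conserves total drug over a thousand steps", {
  m <- small_mesh()
  n <- nrow(m$nodes)
  ops <- gliomech:::fem_operators(m)
  prm <- list(D_f = 2e-5, k_on = 1e-3, k_off = 1e-4, k_int = 1e-5,
              c_e = 1, Phi = 0.3)
  set.seed(6)
  nr <- sqrt(rowSums(m$nodes^2))
  st <- list(c_f = exp(-nr / 10), c_b = rep(0, n), c_int = rep(0, n))
  tot0 <- sum(ops$M * (st$c_f + st$c_b + st$c_int))
  ch <- NULL
  for (s in 1:1000) {
    st <- step_drug(st, matrix(0, nrow(m$tets), 3), rep(0, n), m, prm, 60,
                    ops = ops, chol_A = ch)
    ch <- attr(st, "chol_A")
  }
  tot1 <- sum(ops$M * (st$c_f + st$c_b + st$c_int))
  expect_equal(tot1 / tot0, 1, tolerance = 1e-6)
  expect_true(all(st$c_f >= 0) && all(st$c_b >= 0) && all(st$c_int >= 0))
})
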