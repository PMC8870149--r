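test_that("growth rate has Michaelis-Menten limits", {
  expect_equal(growth_rate(0, 1, 0.3, 0.25), 0)
  expect_equal(growth_rate(0.25, 1, 0.3, 0.25), 0.15)          # half saturation
  expect_equal(growth_rate(0.25, 0.5, 0.3, 0.25), 0.075)       # linear in T
  expect_equal(growth_rate(1e6 * 0.25, 2, 0.3, 0.25), 0.6, tolerance = 1e-5)
  expect_error(growth_rate(-1, 1, 0.3, 0.25), "non-negative")
})

test_that("anisotropy multipliers reduce to isotropy and follow stress", {
  expect_equal(anisotropy_multipliers(c(-500, 200, 900), 0, 1e4), rep(1 / 3, 3))
  expect_equal(anisotropy_multipliers(c(700, 700, 700), 37, 1e4), rep(1 / 3, 3))
  # closed-form check: A = 25, sigma = (-0.1 k, 0, 0)
  k <- 4e4
  g <- anisotropy_multipliers(c(-0.1 * k, 0, 0), 25, k)
  expect_equal(g[1], exp(-2.5) / (exp(-2.5) + 2), tolerance = 1e-12)
  expect_equal(g[2], 1 / (exp(-2.5) + 2), tolerance = 1e-12)
  expect_equal(g[2], g[3])
  # the compressed direction grows least
  expect_lt(g[1], g[2])
  expect_error(anisotropy_multipliers(c(0, 0, 0), 25, -1), "positive")
})

test_that("multiplier normalization survives extreme arguments", {
  set.seed(3)
  n <- 1e4
  sig <- matrix(rnorm(3 * n, 0, 2e4), n, 3)
  A <- runif(n, 0, 100)
  k <- runif(n, 500, 5e4)
  # include magnitudes up to |A sigma / k| ~ 500
  sig[1:100, 1] <- 5e5
  g <- anisotropy_multipliers(sig, A[1], k[1])
  expect_lt(max(abs(rowSums(g) - 1)), 1e-12)
  for (i in seq_len(200)) {
    gi <- anisotropy_multipliers(sig[i, ], A[i], k[i])
    expect_lt(abs(sum(gi) - 1), 1e-12)
    expect_true(all(gi >= 0))
  }
})

test_that("raising one normal stress raises its multiplier and lowers the rest", {
  base <- c(-1000, 200, 500)
  g0 <- anisotropy_multipliers(base, 25, 1e4)
  g1 <- anisotropy_multipliers(base + c(500, 0, 0), 25, 1e4)
  expect_gt(g1[1], g0[1])
  expect_lt(g1[2], g0[2])
  expect_lt(g1[3], g0[3])
})

test_that("growth stretch step uses the exact exponential map", {
  # no growth
  expect_equal(step_growth_stretches(c(1, 1, 1), 0, rep(1 / 3, 3), 1), c(1, 1, 1))
  # isotropic growth: each stretch e^(r dt / 3), volume e^(r dt)
  lam <- step_growth_stretches(c(1, 1, 1), 0.3, rep(1 / 3, 3), 1)
  expect_equal(lam, rep(exp(0.1), 3), tolerance = 1e-14)
  expect_equal(prod(lam), exp(0.3), tolerance = 1e-14)
  # fully one-sided growth
  lam <- step_growth_stretches(c(1, 1, 1), 0.2, c(1, 0, 0), 0.5)
  expect_equal(lam, c(exp(0.1), 1, 1))
  expect_error(step_growth_stretches(c(1, 1, 1), 0.1, rep(1 / 3, 3), 0), "positive")
})

test_that("volume growth is independent of the anisotropy split", {
  set.seed(5)
  lamA <- lamB <- c(1, 1, 1)
  total <- 0
  for (s in 1:50) {
    rg <- runif(1, 0, 0.4)
    sig <- rnorm(3, -500, 400)
    g <- anisotropy_multipliers(sig, 25, 1e4)
    lamA <- step_growth_stretches(lamA, rg, g, 0.5)
    lamB <- step_growth_stretches(lamB, rg, rep(1 / 3, 3), 0.5)
    total <- total + rg * 0.5
  }
  expect_equal(prod(lamA), exp(total), tolerance = 1e-12)
  expect_equal(prod(lamB), exp(total), tolerance = 1e-12)
  # isotropic case keeps the three stretches identical (closed form of the
  # isotropic rate law)
  expect_equal(lamB[1], lamB[2])
  expect_equal(lamB[2], lamB[3])
})
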