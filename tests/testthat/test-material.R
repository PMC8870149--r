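test_that("shear modulus reconstruction inverts the viscoelastic moduli", {
  omega <- 2 * pi * 50
  r <- reconstruct_shear_modulus(900, 300, omega)
  expect_equal(r$G, 1000)
  expect_equal(r$tau_m, 3 / omega)
  back <- viscoelastic_moduli(r$G, r$tau_m, omega)
  expect_equal(back$G_storage, 900, tolerance = 1e-12)
  expect_equal(back$G_loss, 300, tolerance = 1e-12)

  # equal storage and loss: omega tau = 1, G = 2 G'
  r2 <- reconstruct_shear_modulus(500, 500, omega)
  expect_equal(r2$G, 1000)
  expect_equal(r2$tau_m * omega, 1)

  # purely elastic limit
  r3 <- reconstruct_shear_modulus(1000, 0, omega)
  expect_equal(r3$G, 1000)
  expect_identical(r3$tau_m, Inf)

  expect_error(reconstruct_shear_modulus(-1, 10, omega), "positive")
})

test_that("reconstruction round-trips random draws at 1e-10", {
  set.seed(42)
  n <- 1e4
  G <- runif(n, 100, 1e4)
  tau <- runif(n, 1e-4, 1)
  omega <- runif(n, 2 * pi * 10, 2 * pi * 100)
  fw <- viscoelastic_moduli(G, tau, omega)
  bk <- reconstruct_shear_modulus(fw$G_storage, fw$G_loss, omega)
  expect_lt(max(abs(bk$G - G) / G), 1e-10)
  expect_lt(max(abs(bk$tau_m - tau) / tau), 1e-10)
})

test_that("reference state is stress-free and small strains are linear elastic", {
  st <- cauchy_stress(diag(3), 1000, 15000)
  expect_equal(max(abs(st$sigma)), 0)
  expect_equal(st$W, 0)

  # simple shear: sigma_12 ~ G gamma
  g <- 1e-4
  Fe <- diag(3); Fe[1, 2] <- g
  st <- cauchy_stress(Fe, 1000, 15000)
  expect_equal(st$sigma[1, 2] / (1000 * g), 1, tolerance = 1e-3)

  # pure dilatation: isotropic diagonal stress
  st <- cauchy_stress(1.1 * diag(3), 1000, 20000)
  expect_lt(max(abs(st$sigma - st$sigma[1, 1] * diag(3))), 1e-9 * abs(st$sigma[1, 1]))

  expect_error(cauchy_stress(-diag(3), 1000, 15000), "[Ii]nverted")
})

test_that("stress agrees with finite differences of the energy density", {
  set.seed(7)
  for (iso in c(TRUE, FALSE)) {
    for (rep in 1:25) {
      repeat {
        Fe <- diag(3) + matrix(rnorm(9, 0, 0.12), 3)
        if (det(Fe) > 0.7 && det(Fe) < 1.4) break
      }
      G <- runif(1, 200, 3000); k <- runif(1, 1000, 3e4)
      st <- cauchy_stress(Fe, G, k, isochoric = iso)
      h <- 1e-6
      P <- matrix(0, 3, 3)
      for (i in 1:3) for (j in 1:3) {
        Fp <- Fe; Fp[i, j] <- Fp[i, j] + h
        Fm <- Fe; Fm[i, j] <- Fm[i, j] - h
        P[i, j] <- (cauchy_stress(Fp, G, k, iso)$W -
                    cauchy_stress(Fm, G, k, iso)$W) / (2 * h)
      }
      sig_fd <- P %*% t(Fe) / det(Fe)
      sig_fd <- (sig_fd + t(sig_fd)) / 2
      expect_lt(max(abs(sig_fd - st$sigma)) / max(abs(st$sigma), 1), 1e-5)
    }
  }
})

test_that("stress response is objective under rotations", {
  set.seed(11)
  for (rep in 1:20) {
    Fe <- diag(3) + matrix(rnorm(9, 0, 0.1), 3)
    if (det(Fe) <= 0.2) next
    qr_d <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_d)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    s1 <- cauchy_stress(R %*% Fe, 900, 12000)$sigma
    s2 <- R %*% cauchy_stress(Fe, 900, 12000)$sigma %*% t(R)
    expect_lt(max(abs(s1 - s2)), 1e-9 * max(abs(s2), 1))
  }
})

test_that("small-strain moduli recovered from numerical linearization", {
  G <- 1234; k <- 8765
  h <- 1e-6
  # shear modulus from sigma_12 under simple shear
  Fs <- diag(3); Fs[1, 2] <- h
  G_num <- cauchy_stress(Fs, G, k)$sigma[1, 2] / h
  expect_equal(G_num, G, tolerance = 0.01)
  # bulk modulus from pressure under dilatation: tr sigma / 3 = k * dV/V
  Fd <- (1 + h) * diag(3)
  k_num <- sum(diag(cauchy_stress(Fd, G, k)$sigma)) / (3 * 3 * h)
  expect_equal(k_num, k, tolerance = 0.01)
})

test_that("as-printed energy variant carries a non-zero reference stress", {
  st <- cauchy_stress(1.2 * diag(3), 1000, 10000, isochoric = FALSE)
  # the uncorrected shear term contributes G/J (b - I) type terms; at a pure
  # dilatation the two variants differ
  st_iso <- cauchy_stress(1.2 * diag(3), 1000, 10000, isochoric = TRUE)
  expect_gt(max(abs(st$sigma - st_iso$sigma)), 1)
})
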