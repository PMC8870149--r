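test_that("field generator spec validates its inputs", {
  expect_error(field_generator_spec(target_mean = -1), "positive")
  expect_error(field_generator_spec(correlation_length = 0), "positive")
  expect_error(field_generator_spec(clip_floor = 0), "positive")
  expect_error(field_generator_spec(loss_to_storage_ratio = 1.2), "0,1")
})

test_that("degenerate variance gives a constant field at the target mean", {
  spec <- field_generator_spec(target_mean = 1500, target_sd = 0, seed = 9)
  f <- generate_modulus_field(spec, small_grid())
  expect_true(all(f$channels$storage_modulus_Pa == 1500))
  expect_true(all(f$channels$loss_modulus_Pa == 0.4 * 1500))
})

test_that("same spec and seed reproduce bit-identical fields", {
  spec <- field_generator_spec(seed = 123)
  f1 <- generate_modulus_field(spec, small_grid())
  f2 <- generate_modulus_field(spec, small_grid())
  expect_identical(f1$channels$storage_modulus_Pa, f2$channels$storage_modulus_Pa)
  d1 <- generate_dti_field(0.02, 0.4, 77, small_grid())
  d2 <- generate_dti_field(0.02, 0.4, 77, small_grid())
  expect_identical(d1$channels$dti_mm2_per_day, d2$channels$dti_mm2_per_day)
})

test_that("modulus fields hit the requested moments across seeds", {
  grid <- small_grid(n = 32, spacing = 1)
  means <- sds <- numeric(10)
  for (s in 1:10) {
    spec <- field_generator_spec(target_mean = 1500, target_sd = 400,
                                 correlation_length = 8, seed = s)
    g <- generate_modulus_field(spec, grid)$channels$storage_modulus_Pa
    means[s] <- mean(g); sds[s] <- sd(g)
    expect_true(all(g >= spec$clip_floor))
    # paired loss channel
  }
  # affine rescaling enforces the moments exactly unless the clip floor bites
  expect_lt(abs(mean(means) - 1500), 3 * 400 / sqrt(10))
  expect_lt(abs(mean(sds) - 400) / 400, 0.15)
})

test_that("loss channel is the configured fraction of storage", {
  spec <- field_generator_spec(seed = 5, loss_to_storage_ratio = 0.25)
  f <- generate_modulus_field(spec, small_grid())
  expect_equal(f$channels$loss_modulus_Pa,
               0.25 * f$channels$storage_modulus_Pa)
})

test_that("DTI field is SPD with exact trace and isotropic limit", {
  g <- small_grid(n = 10)
  iso <- generate_dti_field(0.05, 0, 3, g)$channels$dti_mm2_per_day
  expect_equal(max(abs(iso[, , , 1] - 0.05)), 0)
  expect_equal(max(abs(iso[, , , 2])), 0)

  traces <- numeric(10)
  for (s in 1:10) {
    ten <- generate_dti_field(0.05, 0.5, s, g)$channels$dti_mm2_per_day
    traces[s] <- mean(ten[, , , 1] + ten[, , , 3] + ten[, , , 6]) / 3
    # minimum eigenvalue = base (1 - f) > 0 by construction; verify on a sample
    idx <- cbind(sample(10, 20, TRUE), sample(10, 20, TRUE), sample(10, 20, TRUE))
    for (r in seq_len(nrow(idx))) {
      d <- ten[idx[r, 1], idx[r, 2], idx[r, 3], ]
      Dm <- matrix(d[c(1, 2, 4, 2, 3, 5, 4, 5, 6)], 3, 3)
      expect_gt(min(eigen(Dm, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
  expect_lt(abs(mean(traces) - 0.05) / 0.05, 0.05)
  expect_error(generate_dti_field(0.05, 1, 1, g), "anisotropy_fraction")
})

test_that("tumor embedding maps the parallelepiped affinely onto the seed cube", {
  # constant field passes through unchanged
  g <- list(origin = c(0, 0, 0), spacing = c(2, 3, 1), dims = c(6L, 5L, 9L))
  const <- voxel_field(g$origin, g$spacing, g$dims,
                       list(storage_modulus_Pa = array(1200, g$dims)))
  seed <- tumor_seed_spec(radius = 5)
  pts <- matrix(runif(60, -4, 4), ncol = 3)
  expect_equal(embed_tumor_data(const, list(lo = c(0, 0, 0), hi = c(10, 12, 8)),
                                seed, pts), rep(1200, 20))

  # linear-in-x field: sampled values linear along x, extremes at cube faces
  ax <- voxel_axes(const)
  lin <- voxel_field(g$origin, g$spacing, g$dims,
                     list(storage_modulus_Pa =
                            array(rep(ax[[1]], prod(g$dims[2:3])), g$dims)))
  bbox <- list(lo = c(0, 0, 0), hi = c(10, 12, 8))
  xs <- seq(-5, 5, length.out = 11)
  pts <- cbind(xs, 0, 0)
  v <- embed_tumor_data(lin, bbox, seed, pts)
  # affine map: x in [-5,5] -> [0,10]
  expect_equal(v, (xs + 5), tolerance = 1e-12)
  expect_equal(v[1], 0)      # min at cube face
  expect_equal(v[11], 10)    # max at cube face

  expect_error(embed_tumor_data(const, list(lo = c(0, 0, 0), hi = c(10, 12, 0)),
                                seed, pts), "positive extent")
})

test_that("mesh interpolation is exact for constant and linear fields", {
  mesh <- small_mesh()
  g <- small_grid(n = 24, spacing = 5)
  arr_const <- array(321, g$dims)
  fc <- voxel_field(g$origin, g$spacing, g$dims, list(v = arr_const))
  expect_equal(interpolate_to_mesh(fc, mesh, "v"), rep(321, nrow(mesh$nodes)))

  ax <- voxel_axes(fc)
  lin <- outer(outer(2 * ax[[1]], 3 * ax[[2]], "+"), -ax[[3]], "+")
  fl <- voxel_field(g$origin, g$spacing, g$dims, list(v = lin))
  got <- interpolate_to_mesh(fl, mesh, "v")
  want <- 2 * mesh$nodes[, 1] + 3 * mesh$nodes[, 2] - mesh$nodes[, 3]
  # all nodes are interior to this grid
  expect_lt(max(abs(got - want)), 1e-10)
  expect_error(interpolate_to_mesh(fl, list(nodes = matrix(0, 0, 3)), "v"),
               "empty mesh")
})

test_that("points outside the grid take the nearest in-bounds voxel value", {
  g <- small_grid(n = 6, spacing = 1, origin = 0)
  arr <- array(rnorm(216), g$dims)
  f <- voxel_field(g$origin, g$spacing, g$dims, list(v = arr))
  # straight outside the -x face at a voxel-center row: nearest voxel is (1,3,4)
  got <- interpolate_voxels(f, cbind(-1.7, 2, 3), "v")
  expect_equal(got, arr[1, 3, 4])
  # outside a corner
  got <- interpolate_voxels(f, cbind(9, 9, 9), "v")
  expect_equal(got, arr[6, 6, 6])
})

test_that("NIfTI round trip preserves arrays and geometry", {
  spec <- field_generator_spec(seed = 31)
  f <- generate_modulus_field(spec, small_grid())
  base <- file.path(withr::local_tempdir(), "vp")
  write_voxel_field(f, base)
  g <- read_voxel_field(base, c("storage_modulus_Pa", "loss_modulus_Pa"))
  expect_equal(g$channels$storage_modulus_Pa, f$channels$storage_modulus_Pa,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(g$origin, f$origin)
  expect_equal(g$spacing, f$spacing)

  d <- generate_dti_field(0.03, 0.3, 4, small_grid())
  write_voxel_field(d, base)
  d2 <- read_voxel_field(base, "dti_mm2_per_day")
  expect_equal(d2$channels$dti_mm2_per_day, d$channels$dti_mm2_per_day,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("virtual patient bundle is deterministic and writable", {
  cfg <- simulation_config()
  p1 <- virtual_patient(cfg, seed = 11)
  p2 <- virtual_patient(cfg, seed = 11)
  expect_identical(p1$host$channels$storage_modulus_Pa,
                   p2$host$channels$storage_modulus_Pa)
  base <- file.path(withr::local_tempdir(), "pat")
  files <- write_virtual_patient(p1, base)
  expect_true(all(file.exists(files)))
  prov <- jsonlite::read_json(files[["provenance"]])
  expect_match(prov$generator, "synthetic")
})
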