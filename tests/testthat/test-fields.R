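test_that("random isotropic field: determinants follow the uniform draw", {
  g <- build_grid(c(10, 10), c(50, 50))
  f0 <- random_isotropic_field(g, beta = 0, seed = 7)
  expect_equal(f0$tensors[, 1, 1], rep(1, g$n_cells))
  expect_equal(f0$tensors[, 1, 2], rep(0, g$n_cells))

  f <- random_isotropic_field(g, beta = 0.8, seed = 7)
  det_ <- tensor_determinants(f)
  expect_true(all(det_ >= 0.2 - 1e-12 & det_ <= 1.8 + 1e-12))
  # each cell tensor is a scalar multiple of the identity with det = delta
  expect_equal(f$tensors[, 1, 1], f$tensors[, 2, 2])
  expect_equal(det_, f$delta)
  # reproducible for a fixed seed
  f2 <- random_isotropic_field(g, beta = 0.8, seed = 7)
  expect_identical(f$tensors, f2$tensors)
  f3 <- random_isotropic_field(g, beta = 0.8, seed = 8)
  expect_false(identical(f$tensors, f3$tensors))
  expect_error(random_isotropic_field(g, beta = 1, seed = 1), "positive definiteness")
})

test_that("random isotropic field determinant mean approaches 1 with cell count", {
  g_small <- build_grid(c(10, 10), c(20, 20))       # 400 cells
  g_big <- build_grid(c(10, 10), c(200, 200))       # 40000 cells
  dev_small <- abs(mean(tensor_determinants(
    random_isotropic_field(g_small, 0.8, seed = 11))) - 1)
  dev_big <- abs(mean(tensor_determinants(
    random_isotropic_field(g_big, 0.8, seed = 11))) - 1)
  expect_lt(dev_big, dev_small)
  expect_lt(dev_big, 3 * 0.8 / sqrt(3 * g_big$n_cells))
})

test_that("butterfly field produces the three-band modulation", {
  g <- build_grid(c(200, 200), c(60, 60))
  f <- butterfly_field(g)
  cc <- cell_centers(g)
  expect_equal(f$tensors[, 1, 1], 1 + 0.9 * sin(3 * pi * cc[, 1] / 200))
  # band extremes reach ~1.9 (outer thirds) and ~0.1 (middle strip)
  expect_equal(max(f$tensors[, 1, 1]), 1.9, tolerance = 0.01)
  expect_equal(min(f$tensors[, 1, 1]), 0.1, tolerance = 0.05)
  expect_equal(f$tensors[, 2, 2], f$tensors[, 1, 1])
  expect_equal(f$tensors[, 1, 2], rep(0, g$n_cells))
  expect_error(butterfly_field(g, amplitude = 1), "non-positive")
  expect_error(butterfly_field(build_grid(10, 10), 0.9), "2D")
})

test_that("DTI scaling preserves eigenvectors and fractional anisotropy", {
  g <- build_grid(c(4, 4, 4), c(3, 3, 3))
  f <- synthetic_anisotropic_field(g, contrast = 1.5, bands = 2)
  fa_before <- fractional_anisotropy(f)
  sc <- scale_dti(f, 5e-12)
  expect_equal(fractional_anisotropy(sc), fa_before)
  expect_equal(tensor_determinants(sc), tensor_determinants(f) * (5e-12)^3)
  same <- scale_dti(f, 1)
  expect_equal(same$tensors, f$tensors)
})

test_that("scale_dti rejects or repairs non-SPD cells", {
  g <- build_grid(c(2, 2), c(2, 2))
  tens <- array(0, dim = c(4, 2, 2))
  for (i in 1:4) tens[i, , ] <- diag(2)
  tens[3, , ] <- matrix(c(1, 0, 0, -0.5), 2)   # indefinite cell
  f <- structure(list(grid = g, tensors = tens), class = "tensor_field")
  expect_error(scale_dti(f, 1), "cells: 3")
  rep_ <- scale_dti(f, 1, repair = TRUE)
  expect_length(gliostat:::check_spd(rep_$tensors), 0)
})

test_that("tensor divergence: constant, linear and sinusoidal oracles", {
  g <- build_grid(c(10, 10), c(40, 40))
  expect_equal(tensor_divergence(homogeneous_field(g, 2))$b,
               matrix(0, g$n_cells, 2))
  # D = diag(c x1, c x2) has divergence (c, c) exactly (linear in x)
  cc <- cell_centers(g)
  tens <- array(0, dim = c(g$n_cells, 2, 2))
  tens[, 1, 1] <- 0.3 * cc[, 1] + 1
  tens[, 2, 2] <- 0.3 * cc[, 2] + 1
  f <- tensor_field(g, tens, check = FALSE)
  b <- tensor_divergence(f)$b
  expect_equal(b[, 1], rep(0.3, g$n_cells), tolerance = 1e-12)
  expect_equal(b[, 2], rep(0.3, g$n_cells), tolerance = 1e-12)
  # butterfly field: symbolic derivative oracle, first-order FD error
  gb <- build_grid(c(200, 200), c(100, 100))
  fb <- butterfly_field(gb)
  bb <- tensor_divergence(fb)$b
  ccb <- cell_centers(gb)
  exact <- 0.9 * (3 * pi / 200) * cos(3 * pi * ccb[, 1] / 200)
  interior <- ccb[, 1] > gb$spacing[1] & ccb[, 1] < 200 - gb$spacing[1]
  expect_lt(max(abs(bb[interior, 1] - exact[interior])),
            0.01 * max(abs(exact)))
  expect_equal(bb[, 2], rep(0, gb$n_cells))
  expect_error(tensor_divergence(homogeneous_field(build_grid(1, 1), 1)),
               "single cell")
})

test_that("tensor divergence refines at first order against a smooth oracle", {
  err_at <- function(n) {
    g <- build_grid(c(2, 2), c(n, n))
    cc <- cell_centers(g)
    tens <- array(0, dim = c(g$n_cells, 2, 2))
    tens[, 1, 1] <- 2 + sin(cc[, 1]) * cos(cc[, 2])
    tens[, 2, 2] <- 2 + cos(cc[, 1]) * sin(cc[, 2])
    tens[, 1, 2] <- 0.2 * sin(cc[, 1] + cc[, 2])
    tens[, 2, 1] <- tens[, 1, 2]
    f <- tensor_field(g, tens, check = FALSE)
    b <- tensor_divergence(f)$b
    b1 <- cos(cc[, 1]) * cos(cc[, 2]) + 0.2 * cos(cc[, 1] + cc[, 2])
    b2 <- 0.2 * cos(cc[, 1] + cc[, 2]) + cos(cc[, 1]) * cos(cc[, 2])
    max(abs(b - cbind(b1, b2)))
  }
  e1 <- err_at(20)
  e2 <- err_at(40)
  expect_lt(e2, e1)   # converges under refinement
})

test_that("fractional anisotropy matches hand values and invariances", {
  g <- build_grid(c(2, 2, 2), c(2, 2, 2))
  expect_equal(fractional_anisotropy(homogeneous_field(g, 3)),
               rep(0, g$n_cells))
  tens <- array(0, dim = c(g$n_cells, 3, 3))
  for (i in 1:3) tens[, i, i] <- c(2, 1, 1)[i]
  f <- tensor_field(g, tens, check = FALSE)
  expect_equal(fractional_anisotropy(f), rep(sqrt(1.5) / 3, g$n_cells))
  # rank-deficient limit approaches 1
  tens2 <- tens
  tens2[, 2, 2] <- 1e-9
  tens2[, 3, 3] <- 1e-9
  f2 <- tensor_field(g, tens2, check = FALSE)
  expect_true(all(fractional_anisotropy(f2) > 0.999))
  # invariance under uniform scaling and orthogonal conjugation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tens3 <- tens
  for (c_idx in seq_len(g$n_cells)) {
    tens3[c_idx, , ] <- R %*% tens[c_idx, , ] %*% t(R)
  }
  f3 <- tensor_field(g, tens3, check = FALSE)
  expect_equal(fractional_anisotropy(f3), fractional_anisotropy(f),
               tolerance = 1e-10)
  expect_equal(fractional_anisotropy(scale_dti(f, 7)),
               fractional_anisotropy(f))
})

test_that("Peclet screen is zero for homogeneous media and linear in spacing", {
  g <- build_grid(c(10, 10), c(20, 20))
  f <- homogeneous_field(g, 1.5)
  expect_equal(peclet_field(f), rep(0, g$n_cells))
  # direct formula check: |b| = 0.3, L = 1, |D|_F = 1
  tens <- array(0, dim = c(g$n_cells, 2, 2))
  tens[, 1, 1] <- 1 / sqrt(2)
  tens[, 2, 2] <- 1 / sqrt(2)
  f2 <- tensor_field(g, tens, check = FALSE)
  drift <- structure(list(grid = g, b = cbind(rep(0.3, g$n_cells), 0)),
                     class = "drift_field")
  expect_equal(peclet_field(f2, drift, spacing = 1), rep(0.3, g$n_cells))
  expect_equal(peclet_field(f2, drift, spacing = 2),
               2 * peclet_field(f2, drift, spacing = 1))
})
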