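test_that("newton solver handles textbook cases", {
  # scalar quadratic from guess 3
  r <- function(x) x^2 - 4
  J <- function(x) Matrix::Matrix(2 * x, 1, 1, sparse = TRUE)
  out <- newton_solve(r, J, 3)
  expect_true(out$report$converged)
  expect_equal(out$solution, 2, tolerance = 1e-10)
  # a linear residual converges in one step
  A <- Matrix::Matrix(diag(c(2, 3)), sparse = TRUE)
  rl <- function(x) as.numeric(A %*% x) - c(2, 6)
  Jl <- function(x) A
  outl <- newton_solve(rl, Jl, c(10, -10))
  expect_true(outl$report$converged)
  expect_equal(outl$report$iterations, 1L)
  expect_equal(outl$solution, c(1, 2))
})

test_that("stationary residual Jacobian agrees with finite differences", {
  g <- build_grid(10, 20)
  f <- homogeneous_field(g, 1)
  sys <- assemble(g, f)
  params <- model_params()
  n <- g$n_nodes
  ML <- sys$ML
  A <- sys$K + sys$B
  res <- function(u) {
    fr <- gliostat:::reaction_term(u, params$rho, params$v_mag, TRUE)
    as.numeric(A %*% u) + ML * fr$value
  }
  jac <- function(u) {
    fr <- gliostat:::reaction_term(u, params$rho, params$v_mag, TRUE)
    A + Matrix::Diagonal(n, ML * fr$deriv)
  }
  set.seed(3)
  u <- runif(n, 0.05, 0.95)   # interior of [0,1]: smooth reaction branch
  v <- rnorm(n)
  eps <- 1e-7
  fd <- (res(u + eps * v) - res(u - eps * v)) / (2 * eps)
  an <- as.numeric(jac(u) %*% v)
  expect_lt(max(abs(fd - an)) / max(abs(an)), 1e-5)
})

test_that("bicgstab solves the implicit-Euler Jacobian to tight residual", {
  g <- build_grid(c(4, 4, 4), c(6, 6, 6))
  sys <- assemble(g, synthetic_anisotropic_field(g, 1.5, 2))
  J <- Matrix::Diagonal(g$n_nodes, sys$ML / 0.2) - sys$K - sys$B
  set.seed(5)
  b <- rnorm(g$n_nodes)
  x <- gliostat:::bicgstab(J, b, tol = 1e-12)
  expect_false(is.null(x))
  expect_lt(sqrt(sum((as.numeric(J %*% x) - b)^2)) / sqrt(sum(b^2)), 1e-10)
})

test_that("forward solver preserves the homogeneous fixed points", {
  g <- build_grid(10, 20)
  f <- homogeneous_field(g, 1)
  p <- model_params()
  tc <- time_controls(2, dt = 0.5)
  out0 <- solve_forward(g, f, p, rep(0, g$n_nodes), tc)
  expect_true(out0$report$converged)
  expect_equal(max(abs(out0$states)), 0)
  out1 <- solve_forward(g, f, p, rep(1, g$n_nodes), tc)
  expect_true(out1$report$converged)
  expect_equal(out1$states, matrix(1, g$n_nodes, length(out1$times)),
               tolerance = 1e-9)
})

test_that("near-zero diffusion reduces to the logistic growth law", {
  g <- build_grid(1, 4)
  f <- homogeneous_field(g, 1e-14)
  p <- model_params(rho = 1)
  u0 <- 0.1
  tc <- time_controls(5, dt = 0.01)
  out <- solve_forward(g, f, p, rep(u0, g$n_nodes), tc)
  expect_true(out$report$converged)
  t_end <- max(out$times)
  exact <- u0 * exp(t_end) / (1 - u0 + u0 * exp(t_end))
  # implicit Euler is first order: loose tolerance
  expect_equal(out$states[3, ncol(out$states)], exact, tolerance = 0.01)
})

test_that("forward solutions remain within [0,1] up to solver tolerance with the guard", {
  run <- run_1d_homogeneous()
  expect_true(all(run$fwd$states >= -1e-8))
  expect_true(all(run$fwd$states <= 1 + 1e-8))
})

test_that("forward solver rejects invalid input", {
  g <- build_grid(5, 5)
  f <- homogeneous_field(g, 1)
  p <- model_params()
  expect_error(time_controls(2, dt = -0.1), "dt")
  expect_error(solve_forward(g, f, p, rep(2, g$n_nodes), time_controls(1)),
               "\\[0, 1\\]")
})

test_that("stationary solution reproduces the translated closed-form front", {
  run <- run_1d_homogeneous()
  g <- run$grid
  u_ref <- run$fwd$states[, ncol(run$fwd$states)]
  cons <- extract_constraints(g, u_ref, 0.16, interior = TRUE)
  st <- solve_stationary(g, run$field, run$params, cons, system = run$sys)
  expect_true(st$report$converged)
  # pinned nodes exactly theta; residual small at free nodes (checked by
  # the converged report); compare against the analytically translated
  # closed-form profile on the right-moving front, anchored where the
  # constraint sits
  x <- node_coords(g)[, 1]
  right_shell <- max(cons$indices)
  x_anchor <- x[right_shell]
  offset <- x_anchor - limit_inverse(0.16)
  sel <- x > x_anchor & x < x_anchor + 25
  expect_lt(max(abs(st$u[sel] - limit_profile(x[sel] - offset))), 0.03)
  expect_identical(unique(st$u[cons$indices]), 0.16)
})

test_that("outwards branch decreases monotonically away from the constraint", {
  run <- run_1d_homogeneous()
  g <- run$grid
  u_ref <- run$fwd$states[, ncol(run$fwd$states)]
  cons <- extract_constraints(g, u_ref, 0.16, interior = TRUE)
  st <- solve_stationary(g, run$field, run$params, cons, system = run$sys)
  right <- max(cons$indices)
  expect_true(all(diff(st$u[right:g$n_nodes]) <= 1e-12))
  left <- min(cons$indices)
  expect_true(all(diff(st$u[1:left]) >= -1e-12))
})

test_that("an inward-style guess converges to a different solution branch", {
  run <- run_1d_homogeneous()
  g <- run$grid
  u_ref <- run$fwd$states[, ncol(run$fwd$states)]
  cons <- extract_constraints(g, u_ref, 0.16)   # shell only
  oms <- solve_stationary(g, run$field, run$params, cons, system = run$sys)
  ims_guess <- rep(1, g$n_nodes)
  ims <- solve_stationary(g, run$field, run$params, cons, guess = ims_guess,
                          system = run$sys)
  expect_true(oms$report$converged)
  expect_true(ims$report$converged)
  expect_gt(max(abs(ims$u - oms$u)), 0.1)   # two distinct branches exist
})

test_that("degenerate constraint sets behave as documented", {
  g <- build_grid(10, 30)
  f <- homogeneous_field(g, 1)
  p <- model_params()
  sys <- assemble(g, f)
  # empty constraints: converges to the trivial zero state and flags it
  cs0 <- constraint_set(g, integer(0))
  st0 <- solve_stationary(g, f, p, cs0, system = sys)
  expect_true(st0$report$converged)
  expect_lt(max(abs(st0$u)), 1e-8)
  expect_match(st0$report$failure, "trivial")
  # all nodes pinned: solution is identically theta
  csall <- constraint_set(g, seq_len(g$n_nodes), value = 0.16)
  stall <- solve_stationary(g, f, p, csall, system = sys)
  expect_equal(stall$u, rep(0.16, g$n_nodes))
})
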