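#' Model and time-stepping parameter containers
#'
#' `model_params` collects the growth-model parameters: logistic growth rate
#' `rho` (1/time), wave-pinning penalty magnitude `v_mag` (the limit front
#' speed; 0 disables the penalty), imaging-visibility threshold `theta`, and
#' the DTI scaling factor `alpha` applied when a water-diffusion field is
#' supplied.  `time_controls` fixes the implicit-Euler stepping and the
#' checkpoint times returned by the forward solver.
#'
#' @param rho Growth rate, > 0.
#' @param v_mag Penalty magnitude, >= 0 (default: the special wave speed
#'   \eqn{5/\sqrt 6}).
#' @param theta Visibility threshold in (0, 1), default 0.16.
#' @param alpha DTI scaling factor, > 0, default 1.
#' @return An object of class `model_params`.
#' @export
model_params <- function(rho = 1, v_mag = fisher_wave_speed(),
                         theta = 0.16, alpha = 1) {
  stopifnot(rho > 0, v_mag >= 0, theta > 0, theta < 1, alpha > 0)
  structure(list(rho = rho, v_mag = v_mag, theta = theta, alpha = alpha),
            class = "model_params")
}

#' @rdname model_params
#' @param t_end End time, > `t_start`.
#' @param dt Implicit-Euler step, > 0 (default 0.1 in nondimensional time).
#' @param t_start Start time (default 0).
#' @param checkpoints Times at which the trajectory is stored (default:
#'   every unit of time plus `t_end`); each is snapped to the nearest step.
#' @return An object of class `time_controls`.
#' @export
time_controls <- function(t_end, dt = 0.1, t_start = 0, checkpoints = NULL) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (t_end <= t_start) stop("t_end must exceed t_start", call. = FALSE)
  if (is.null(checkpoints)) {
    checkpoints <- unique(c(seq(t_start, t_end, by = max(1, dt)), t_end))
  }
  checkpoints <- sort(unique(pmin(pmax(checkpoints, t_start), t_end)))
  structure(list(t_start = t_start, t_end = t_end, dt = dt,
                 checkpoints = checkpoints), class = "time_controls")
}

#' Damped Newton solver with backtracking line search
#'
#' Classical Newton iteration on a nonlinear residual with halving line
#' search on the residual norm.  Linear updates are computed by a sparse
#' direct solve.  Convergence requires the residual norm to fall below
#' `abs_tol` or by a factor `rel_tol` relative to the initial residual.
#'
#' Linear updates are computed either by a sparse direct LU
#' (`linear_solver = "direct"`, deterministic, the default for small
#' systems) or by Jacobi-preconditioned BiCGSTAB
#' (`linear_solver = "bicgstab"`, the Newton-Krylov configuration, which
#' avoids the fill-in cost of 3D factorizations); `"auto"` (the solver
#' entry points resolve it from the grid) uses the Krylov solver for large
#' 3D systems, where LU fill-in dominates, and the direct solve otherwise.
#' A Krylov breakdown falls back to the direct solve.
#'
#' @param residual Function `u -> numeric` residual vector.
#' @param jacobian Function `u -> sparse Matrix` Jacobian.
#' @param guess Initial iterate.
#' @param abs_tol Absolute residual tolerance (default 1e-10).
#' @param rel_tol Relative residual reduction (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 50).
#' @param max_halvings Maximum step halvings per iteration (default 20).
#' @param linear_solver `"direct"`, `"bicgstab"` or `"auto"`.
#' @return List with `solution` and a `solve_report` (fields `converged`,
#'   `iterations`, `residual_norm`, `line_search_halvings`, `failure`).
#' @export
#' @examples
#' r <- function(x) x^2 - 4
#' J <- function(x) Matrix::Matrix(2 * x, 1, 1)
#' newton_solve(r, J, 3)$solution  # 2
newton_solve <- function(residual, jacobian, guess,
                         abs_tol = 1e-10, rel_tol = 1e-8,
                         max_iter = 50L, max_halvings = 20L,
                         linear_solver = c("direct", "bicgstab", "auto")) {
  linear_solver <- match.arg(linear_solver)
  u <- as.numeric(guess)
  r <- residual(u)
  rn0 <- sqrt(sum(r^2))
  rn <- rn0
  halvings <- 0L
  for (it in seq_len(max_iter)) {
    if (rn <= abs_tol || rn <= rel_tol * rn0) {
      return(list(solution = u,
                  report = solve_report(TRUE, it - 1L, rn, halvings)))
    }
    J <- jacobian(u)
    du <- linear_solve(J, -r, linear_solver)
    if (is.null(du) || any(!is.finite(du))) {
      return(list(solution = u,
                  report = solve_report(FALSE, it - 1L, rn, halvings,
                                        "singular-jacobian")))
    }
    step <- 1
    accepted <- FALSE
    for (k in 0:max_halvings) {
      u_try <- u + step * du
      r_try <- residual(u_try)
      rn_try <- sqrt(sum(r_try^2))
      if (is.finite(rn_try) && rn_try < rn) {
        u <- u_try; r <- r_try; rn <- rn_try
        halvings <- halvings + k
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      return(list(solution = u,
                  report = solve_report(FALSE, it, rn, halvings,
                                        "line-search-stall")))
    }
  }
  converged <- rn <= abs_tol || rn <= rel_tol * rn0
  list(solution = u,
       report = solve_report(converged, max_iter, rn, halvings,
                             if (!converged) "max-iterations" else NULL))
}

# "auto": Krylov for large 3D grids (LU fill-in dominates there), direct LU
# otherwise
resolve_linear_solver <- function(method, grid) {
  if (!identical(method, "auto")) return(method)
  if (grid$dim == 3 && grid$n_nodes > 3000) "bicgstab" else "direct"
}

# dispatch a sparse linear solve; Krylov failures fall back to direct LU
linear_solve <- function(J, b, method) {
  if (method == "auto") method <- "direct"
  if (method == "bicgstab") {
    x <- bicgstab(J, b, tol = 1e-10)
    if (!is.null(x)) return(x)
  }
  tryCatch(as.numeric(Matrix::solve(J, b)), error = function(e) NULL)
}

# Jacobi-preconditioned BiCGSTAB; returns NULL on breakdown/stagnation
bicgstab <- function(A, b, tol = 1e-10, maxit = 400L) {
  n <- length(b)
  dinv <- 1 / Matrix::diag(A)
  if (any(!is.finite(dinv))) return(NULL)
  x <- numeric(n)
  r <- b
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(x)
  rhat <- r
  rho <- 1; alpha <- 1; omega <- 1
  v <- numeric(n); p <- numeric(n)
  for (it in seq_len(maxit)) {
    rho1 <- sum(rhat * r)
    if (abs(rho1) < 1e-300) return(NULL)
    beta <- (rho1 / rho) * (alpha / omega)
    p <- r + beta * (p - omega * v)
    phat <- dinv * p
    v <- as.numeric(A %*% phat)
    denom <- sum(rhat * v)
    if (abs(denom) < 1e-300) return(NULL)
    alpha <- rho1 / denom
    s <- r - alpha * v
    if (sqrt(sum(s^2)) <= tol * bnorm) {
      return(x + alpha * phat)
    }
    shat <- dinv * s
    t_ <- as.numeric(A %*% shat)
    tt <- sum(t_ * t_)
    if (tt < 1e-300) return(NULL)
    omega <- sum(t_ * s) / tt
    x <- x + alpha * phat + omega * shat
    r <- s - omega * t_
    if (sqrt(sum(r^2)) <= tol * bnorm) return(x)
    rho <- rho1
  }
  NULL
}

solve_report <- function(converged, iterations, residual_norm,
                         line_search_halvings = 0L, failure = NULL) {
  structure(list(converged = converged, iterations = iterations,
                 residual_norm = residual_norm,
                 line_search_halvings = line_search_halvings,
                 failure = failure), class = "solve_report")
}

#' @export
print.solve_report <- function(x, ...) {
  cat(sprintf("solve_report: %s after %d iteration(s), |r| = %.3g%s\n",
              if (x$converged) "converged" else "FAILED",
              x$iterations, x$residual_norm,
              if (!is.null(x$failure)) paste0(" (", x$failure, ")") else ""))
  invisible(x)
}

#' Forward time integration of the growth model
#'
#' Integrates the anisotropic advection-diffusion-reaction model
#' \deqn{\partial_t u = \nabla\cdot(D\nabla u) + \nabla\cdot((\nabla\cdot D)u)
#'       + \rho u(1-u)}
#' by fully implicit (backward) Euler with a Newton solve per step; the
#' reaction term is treated implicitly, not operator-split.  The time
#' derivative and the nodal reaction use the lumped mass, which keeps the
#' step Jacobian diagonally dominant (Krylov-friendly and free of the
#' consistent-mass overshoot at sharp initial data); the spatial operators
#' are the consistent finite-element matrices.  Wherever an
#' iterate leaves \eqn{[0,1]} the logistic term is replaced by the
#' positivity guard \eqn{n(\omega)}, which pushes the amplitude back without
#' amplifying overshoot.  Zero-flux outer boundaries are natural to the weak
#' form.
#'
#' @param grid A `structured_grid`.
#' @param field A `tensor_field` (SPD).
#' @param params A `model_params` (the penalty is not active in the forward
#'   model; only `rho` is used).
#' @param init Nodal initial density in `[0, 1]`.
#' @param controls A `time_controls`.
#' @param guard Apply the positivity guard (default TRUE).
#' @param system Optional pre-assembled `assembled_system` to reuse.
#' @param linear_solver Passed to [newton_solve()] (default `"auto"`).
#' @return An object of class `forward_solution`: `times`, `states`
#'   (`n_nodes` x `length(times)` matrix), `grid`, `report`.
#' @export
solve_forward <- function(grid, field, params, init, controls,
                          guard = TRUE, system = NULL,
                          linear_solver = "auto") {
  stopifnot(inherits(params, "model_params"), inherits(controls, "time_controls"))
  if (length(init) != grid$n_nodes) stop("init has wrong length", call. = FALSE)
  if (any(init < 0) || any(init > 1)) {
    stop("initial density must lie in [0, 1]", call. = FALSE)
  }
  sys <- if (is.null(system)) assemble(grid, field) else system
  linear_solver <- resolve_linear_solver(linear_solver, grid)
  dt <- controls$dt
  nsteps <- ceiling((controls$t_end - controls$t_start) / dt - 1e-9)
  check_steps <- unique(pmin(pmax(round(
    (controls$checkpoints - controls$t_start) / dt), 0), nsteps))

  n <- grid$n_nodes
  ML <- sys$ML
  A0 <- Matrix::Diagonal(n, ML / dt) - sys$K - sys$B
  rho <- params$rho

  states <- matrix(NA_real_, n, length(check_steps))
  times <- controls$t_start + check_steps * dt
  u <- as.numeric(init)
  col <- 1L
  if (check_steps[1] == 0L) {
    states[, 1] <- u
    col <- 2L
  }
  total_iter <- 0L
  for (step in seq_len(nsteps)) {
    u_prev <- u
    Mup <- ML * u_prev / dt
    res <- function(w) {
      f <- reaction_term(w, rho, 0, guard)
      as.numeric(A0 %*% w) - Mup - ML * f$value
    }
    jac <- function(w) {
      f <- reaction_term(w, rho, 0, guard)
      A0 - Matrix::Diagonal(n, ML * f$deriv)
    }
    out <- newton_solve(res, jac, u, linear_solver = linear_solver)
    total_iter <- total_iter + out$report$iterations
    if (!out$report$converged) {
      out$report$failure <- sprintf("step %d (t = %g): %s", step, step * dt,
                                    out$report$failure %||% "no-convergence")
      return(structure(list(times = times[seq_len(col - 1L)],
                            states = states[, seq_len(col - 1L), drop = FALSE],
                            grid = grid, report = out$report),
                       class = "forward_solution"))
    }
    u <- out$solution
    if (col <= length(check_steps) && step == check_steps[col]) {
      states[, col] <- u
      col <- col + 1L
    }
  }
  structure(list(times = times, states = states, grid = grid,
                 report = solve_report(TRUE, total_iter,
                                       out$report$residual_norm)),
            class = "forward_solution")
}

# guarded reaction with or without the penalty; v_mag = 0 disables penalty
reaction_term <- function(u, rho, v_mag, guard) {
  if (guard) {
    guarded_reaction(u, rho, v_mag, pen = v_mag > 0)
  } else {
    val <- rho * u * (1 - u)
    der <- rho * (1 - 2 * u)
    if (v_mag > 0) {
      uc <- pmin(pmax(u, 0), 1)
      val <- val - penalty(uc, v_mag)
      der <- der - penalty_deriv(uc, v_mag)
    }
    list(value = val, deriv = der)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.forward_solution <- function(x, ...) {
  cat(sprintf("forward_solution: %d checkpoints on [%g, %g], %d nodes\n",
              length(x$times), min(x$times), max(x$times), nrow(x$states)))
  print(x$report)
  invisible(x)
}

#' Stationary solve of the wave-pinned model
#'
#' Solves the stationalized boundary-value problem
#' \deqn{0 = \nabla\cdot(D\nabla u_s) + \nabla\cdot((\nabla\cdot D)u_s)
#'       + \rho u_s(1-u_s) - |v|\sqrt{2/3}(1-\sqrt{u_s})u_s}
#' with zero-flux outer boundaries and the internal Dirichlet constraint
#' \eqn{u_s = \theta} on the pinned shell, by damped Newton.  The default
#' initial guess (`"oms-default"`) puts a small constant (1e-3) on free
#' nodes — well inside the penalizing regime — which reliably selects the
#' clinically relevant outwards-moving solution branch (OMS).  A guess near
#' 1 outside the constraint converges to the inward branch (IMS) instead.
#'
#' With an empty constraint set the solve converges to the trivial zero
#' state and flags it in the report.
#'
#' @param grid A `structured_grid`.
#' @param field A `tensor_field`.
#' @param params A `model_params` (`rho`, `v_mag` used; `theta` must match
#'   the constraint value).
#' @param constraints A `constraint_set` from [extract_constraints()].
#' @param guess `"oms-default"` or a numeric nodal vector.
#' @param system Optional pre-assembled `assembled_system`.
#' @param abs_tol,rel_tol,max_iter Newton controls.
#' @param linear_solver Passed to [newton_solve()] (default `"auto"`).
#' @return An object of class `stationary_solution`: `u`, `grid`,
#'   `constraints`, `report`.
#' @export
solve_stationary <- function(grid, field, params, constraints,
                             guess = "oms-default", system = NULL,
                             abs_tol = 1e-10, rel_tol = 1e-8, max_iter = 50L,
                             linear_solver = "auto") {
  stopifnot(inherits(params, "model_params"),
            inherits(constraints, "constraint_set"))
  sys <- if (is.null(system)) assemble(grid, field) else system
  linear_solver <- resolve_linear_solver(linear_solver, grid)
  n <- grid$n_nodes
  idx <- constraints$indices
  empty <- length(idx) == 0
  theta <- constraints$value
  pinned <- logical(n)
  pinned[idx] <- TRUE
  free_mask <- as.numeric(!pinned)

  if (identical(guess, "oms-default")) {
    u0 <- rep(1e-3, n)
    u0[idx] <- theta
  } else {
    u0 <- as.numeric(guess)
    stopifnot(length(u0) == n)
    u0[idx] <- theta
  }

  A <- sys$K + sys$B
  ML <- sys$ML
  rho <- params$rho
  v <- params$v_mag

  res <- function(u) {
    f <- reaction_term(u, rho, v, guard = TRUE)
    r <- as.numeric(A %*% u) + ML * f$value
    r[pinned] <- u[pinned] - theta
    r
  }
  jac <- function(u) {
    f <- reaction_term(u, rho, v, guard = TRUE)
    J <- A + Matrix::Diagonal(n, ML * f$deriv)
    if (any(pinned)) {
      J <- Matrix::Diagonal(n, free_mask) %*% J +
        Matrix::sparseMatrix(i = idx, j = idx, x = 1, dims = c(n, n))
    }
    J
  }
  out <- newton_solve(res, jac, u0, abs_tol = abs_tol, rel_tol = rel_tol,
                      max_iter = max_iter, linear_solver = linear_solver)
  rep_ <- out$report
  if (empty && rep_$converged && max(abs(out$solution)) < 1e-6) {
    rep_$failure <- "trivial-zero-state (empty constraint set)"
  }
  structure(list(u = out$solution, grid = grid, constraints = constraints,
                 report = rep_),
            class = "stationary_solution")
}

#' @export
print.stationary_solution <- function(x, ...) {
  cat(sprintf("stationary_solution: %d nodes, %d pinned at %g\n",
              length(x$u), length(x$constraints$indices), x$constraints$value))
  print(x$report)
  invisible(x)
}
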