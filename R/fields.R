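#' Diffusion tensor fields
#'
#' Per-cell symmetric positive definite diffusion tensors on the dual (cell)
#' grid, piecewise constant within each cell.  The drift field
#' \eqn{b = \nabla\cdot D} that the anisotropic model's advection term needs
#' is pre-computed from the tensors by first-order finite differences.
#'
#' @name tensor-fields
NULL

#' Construct a tensor field
#'
#' @param grid A `structured_grid`.
#' @param tensors Numeric array of shape `(n_cells, d, d)`; every slice must
#'   be symmetric positive definite.
#' @param check Validate symmetry/SPD (default TRUE; generators that build
#'   SPD tensors by construction skip it).
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(grid, tensors, check = TRUE) {
  stopifnot(inherits(grid, "structured_grid"))
  d <- grid$dim
  if (!is.array(tensors) || !all(dim(tensors) == c(grid$n_cells, d, d))) {
    stop("tensors must be an array of shape (n_cells, d, d)", call. = FALSE)
  }
  if (check) {
    bad <- check_spd(tensors)
    if (length(bad)) {
      stop(sprintf("non-SPD tensor in %d cell(s); first offenders: %s",
                   length(bad), paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(list(grid = grid, tensors = tensors), class = "tensor_field")
}

# indices of cells whose tensor is not symmetric positive definite
check_spd <- function(tensors) {
  d <- dim(tensors)[2]
  n <- dim(tensors)[1]
  bad <- logical(n)
  for (i in seq_len(d)) for (j in seq_len(i - 1)) {
    bad <- bad | abs(tensors[, i, j] - tensors[, j, i]) >
      1e-8 * (abs(tensors[, i, j]) + 1)
  }
  if (d == 1) {
    bad <- bad | tensors[, 1, 1] <= 0
  } else {
    # leading principal minors > 0 (Sylvester); cheap and vectorized
    bad <- bad | tensors[, 1, 1] <= 0
    m2 <- tensors[, 1, 1] * tensors[, 2, 2] - tensors[, 1, 2] * tensors[, 2, 1]
    bad <- bad | m2 <= 0
    if (d == 3) {
      det3 <- tensors[, 1, 1] * (tensors[, 2, 2] * tensors[, 3, 3] - tensors[, 2, 3] * tensors[, 3, 2]) -
        tensors[, 1, 2] * (tensors[, 2, 1] * tensors[, 3, 3] - tensors[, 2, 3] * tensors[, 3, 1]) +
        tensors[, 1, 3] * (tensors[, 2, 1] * tensors[, 3, 2] - tensors[, 2, 2] * tensors[, 3, 1])
      bad <- bad | det3 <= 0
    }
  }
  which(bad)
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("tensor_field: %d cells, %dx%d tensors\n",
              x$grid$n_cells, x$grid$dim, x$grid$dim))
  invisible(x)
}

#' Homogeneous (constant) tensor field
#'
#' @param grid A `structured_grid`.
#' @param D Scalar diffusivity or a single d x d SPD matrix.
#' @return A `tensor_field` with the same tensor in every cell.
#' @export
homogeneous_field <- function(grid, D = 1) {
  stopifnot(inherits(grid, "structured_grid"))
  d <- grid$dim
  Dm <- if (length(D) == 1) diag(as.numeric(D), d) else as.matrix(D)
  stopifnot(all(dim(Dm) == d))
  tens <- array(rep(Dm, each = grid$n_cells), dim = c(grid$n_cells, d, d))
  tensor_field(grid, tens)
}

#' Randomly perturbed isotropic diffusion field
#'
#' Cell-wise isotropic tensors \eqn{D_\beta = I_d\,\delta^{1/d}} with one
#' independent draw \eqn{\delta \sim \mathrm{unif}(1-\beta, 1+\beta)} per
#' cell.  The \eqn{1/d} exponent makes each cell's determinant equal its
#' \eqn{\delta} draw, so the field-average determinant is close to 1 for
#' every realization and perturbed media stay comparable to the homogeneous
#' baseline.
#'
#' @param grid A `structured_grid`.
#' @param beta Perturbation amplitude in `[0, 1)`.
#' @param seed Integer seed; draws are reproducible for a fixed seed and
#'   grid (one draw per cell, in cell-index order).
#' @return A `tensor_field`.
#' @export
#' @examples
#' f <- random_isotropic_field(build_grid(c(10, 10), c(20, 20)), beta = 0.8, seed = 1)
random_isotropic_field <- function(grid, beta, seed) {
  stopifnot(inherits(grid, "structured_grid"))
  if (!is.numeric(beta) || beta < 0 || beta >= 1) {
    stop("beta must lie in [0, 1): beta >= 1 loses positive definiteness",
         call. = FALSE)
  }
  d <- grid$dim
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  delta <- stats::runif(grid$n_cells, 1 - beta, 1 + beta)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  scale <- delta^(1 / d)
  tens <- array(0, dim = c(grid$n_cells, d, d))
  for (i in seq_len(d)) tens[, i, i] <- scale
  structure(list(grid = grid, tensors = tens, delta = delta),
            class = "tensor_field")
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
}

#' Banded sinusoidal ("butterfly") diffusion field
#'
#' Isotropic but inhomogeneous 2D field
#' \deqn{D(x) = I_2\,(1 + \sin(3\pi x_1/L_x)\,a),}
#' which splits the domain into three vertical bands: high diffusivity in
#' the outer thirds, low in the middle strip — a primitive gray/white-matter
#' contrast.  A front released in an outer band spreads into a butterfly
#' shape.
#'
#' @param grid A 2D `structured_grid`.
#' @param amplitude Modulation amplitude, `< 1` (default 0.9).
#' @param modes Number of half-bands (default 3).
#' @return A `tensor_field`.
#' @export
butterfly_field <- function(grid, amplitude = 0.9, modes = 3) {
  stopifnot(inherits(grid, "structured_grid"))
  if (grid$dim != 2) stop("butterfly_field requires a 2D grid", call. = FALSE)
  if (amplitude >= 1) {
    stop("amplitude >= 1 makes the tensor non-positive", call. = FALSE)
  }
  x1 <- cell_centers(grid)[, 1]
  s <- 1 + sin(modes * pi * x1 / grid$extents[1]) * amplitude
  tens <- array(0, dim = c(grid$n_cells, 2, 2))
  tens[, 1, 1] <- s
  tens[, 2, 2] <- s
  tensor_field(grid, tens, check = FALSE)
}

#' Synthetic banded anisotropic 3D field
#'
#' Procedurally generated SPD tensor volume with band-structured fractional
#' anisotropy: diagonal tensors whose first eigenvalue is modulated
#' sinusoidally along axis 1 while the others stay at 1.  Stands in for a
#' DTI-derived tumor diffusivity in the 3D validation scenario; it is
#' synthetic and does not reproduce real white-matter tract geometry.
#'
#' @param grid A 3D `structured_grid`.
#' @param contrast Peak relative elevation of the first eigenvalue
#'   (default 1.5, giving FA up to about 0.45).
#' @param bands Number of half-bands along axis 1 (default 2).
#' @return A `tensor_field`.
#' @export
synthetic_anisotropic_field <- function(grid, contrast = 1.5, bands = 2) {
  stopifnot(inherits(grid, "structured_grid"))
  if (grid$dim != 3) stop("requires a 3D grid", call. = FALSE)
  stopifnot(contrast >= 0)
  x1 <- cell_centers(grid)[, 1]
  lam1 <- 1 + contrast * (0.5 + 0.5 * sin(bands * pi * x1 / grid$extents[1]))
  tens <- array(0, dim = c(grid$n_cells, 3, 3))
  tens[, 1, 1] <- lam1
  tens[, 2, 2] <- 1
  tens[, 3, 3] <- 1
  tensor_field(grid, tens, check = FALSE)
}

#' Scale a water-diffusion tensor field to tumor diffusivity
#'
#' Applies the simple scalar DTI reconstruction \eqn{D = \alpha D_w}:
#' eigenvectors are unchanged, eigenvalues scale by `alpha`, and fractional
#' anisotropy is invariant.
#'
#' @param water_tensors A `tensor_field` of water-diffusion tensors.
#' @param alpha Positive dimensionless scaling factor.
#' @param repair If `TRUE`, repair non-SPD input cells by clamping
#'   eigenvalues to a floor of `1e-6` times the largest eigenvalue (common
#'   DTI hygiene); default is to reject with the offending cell indices.
#' @return A `tensor_field`.
#' @export
scale_dti <- function(water_tensors, alpha, repair = FALSE) {
  stopifnot(inherits(water_tensors, "tensor_field"))
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  tens <- water_tensors$tensors
  bad <- check_spd(tens)
  if (length(bad)) {
    if (!repair) {
      stop(sprintf("non-SPD input tensors in cells: %s%s",
                   paste(utils::head(bad, 10), collapse = ", "),
                   if (length(bad) > 10) ", ..." else ""), call. = FALSE)
    }
    d <- dim(tens)[2]
    for (c_idx in bad) {
      M <- (tens[c_idx, , ] + t(tens[c_idx, , ])) / 2
      eg <- eigen(M, symmetric = TRUE)
      floor_ev <- 1e-6 * max(abs(eg$values))
      vals <- pmax(eg$values, floor_ev)
      tens[c_idx, , ] <- eg$vectors %*% diag(vals, d) %*% t(eg$vectors)
    }
  }
  tensor_field(water_tensors$grid, tens * alpha, check = FALSE)
}

#' Drift field: matrix divergence of a tensor field
#'
#' Pre-computes \eqn{b_j = \sum_i \partial D_{ij}/\partial x_i} per cell by
#' first-order finite differences of neighboring cell tensors: central
#' differences in the interior, one-sided stencils at the field boundary.
#' For symmetric tensors the row-wise and column-wise divergence coincide.
#' Constant fields give an exactly zero drift.
#'
#' @param field A `tensor_field` on a grid with at least 2 cells per axis.
#' @return An object of class `drift_field` holding a `n_cells` x `d` matrix
#'   `b` (units length/time).
#' @export
tensor_divergence <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  grid <- field$grid
  d <- grid$dim
  if (any(grid$cells < 2)) {
    stop("divergence undefined along an axis with a single cell", call. = FALSE)
  }
  dims <- grid$cells
  b <- matrix(0, grid$n_cells, d)
  for (j in seq_len(d)) {
    acc <- array(0, dim = dims)
    for (i in seq_len(d)) {
      Dij <- array(field$tensors[, i, j], dim = dims)
      acc <- acc + fd_axis(Dij, axis = i, h = grid$spacing[i])
    }
    b[, j] <- as.vector(acc)
  }
  structure(list(grid = grid, b = b), class = "drift_field")
}

# first derivative of a cell array along one axis: central interior,
# one-sided at the ends
fd_axis <- function(A, axis, h) {
  dims <- dim(A)
  if (is.null(dims)) dims <- length(A)
  n <- dims[axis]
  shift <- function(off) {
    idx <- rep(list(quote(expr = )), length(dims))
    src <- pmin(pmax(seq_len(n) + off, 1L), n)
    idx[[axis]] <- src
    do.call(`[`, c(list(A), idx, list(drop = FALSE)))
  }
  up <- shift(1L)
  dn <- shift(-1L)
  # spacing between the sampled neighbors: 2h interior, h at the two ends
  den <- rep(2 * h, n)
  den[1] <- h
  den[n] <- h
  dshape <- rep(1L, length(dims))
  dshape[axis] <- n
  (up - dn) / array(rep(den, each = prod(dims[seq_len(axis - 1)])), dim = dims)
}

#' @export
print.drift_field <- function(x, ...) {
  cat(sprintf("drift_field: %d cells, max |b| = %.3g\n",
              x$grid$n_cells, max(sqrt(rowSums(x$b^2)))))
  invisible(x)
}

#' Fractional anisotropy of a tensor field
#'
#' The standard scale-invariant eigenvalue-dispersion measure
#' \deqn{FA = \sqrt{\frac{d}{d-1}} \;
#'   \frac{\|\lambda - \bar\lambda\|}{\|\lambda\|},}
#' 0 for isotropic tensors, approaching 1 in the rank-deficient limit.  The
#' same formula is applied to the eigenvalue pair in 2D.
#'
#' @param field A `tensor_field` with SPD tensors.
#' @return Numeric vector of per-cell FA values in `[0, 1]`.
#' @export
fractional_anisotropy <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  d <- field$grid$dim
  if (d == 1) return(rep(0, field$grid$n_cells))
  n <- field$grid$n_cells
  fa <- numeric(n)
  # diagonal fields avoid the eigen() loop entirely
  offdiag <- FALSE
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (i != j && any(field$tensors[, i, j] != 0)) offdiag <- TRUE
  }
  if (!offdiag) {
    lam <- sapply(seq_len(d), function(i) field$tensors[, i, i])
    lam <- matrix(lam, n, d)
    fa <- fa_from_eigenvalues(lam)
  } else {
    for (c_idx in seq_len(n)) {
      lam <- eigen(field$tensors[c_idx, , ], symmetric = TRUE,
                   only.values = TRUE)$values
      if (any(!is.finite(lam))) {
        stop(sprintf("non-finite eigenvalues in cell %d", c_idx), call. = FALSE)
      }
      fa[c_idx] <- fa_from_eigenvalues(matrix(lam, 1))
    }
  }
  fa
}

fa_from_eigenvalues <- function(lam) {
  d <- ncol(lam)
  mu <- rowMeans(lam)
  num <- rowSums((lam - mu)^2)
  den <- rowSums(lam^2)
  sqrt(d / (d - 1)) * sqrt(num / den)
}

#' Grid-scale Péclet number field
#'
#' The drift-to-diffusion strength ratio \eqn{\tau = |b L| / |D|} per cell,
#' with \eqn{b} the local drift vector, \eqn{L} the cell spacing and
#' \eqn{|D|} the Frobenius norm of the local tensor.  Used to screen whether
#' the diffusion-dominated assumption behind the stationalization holds:
#' values well below about 0.3 indicate drift is a small correction.
#'
#' @param field A `tensor_field`.
#' @param drift Matching `drift_field`; computed via [tensor_divergence()]
#'   when omitted.
#' @param spacing Cell edge length `L` (default: the grid's first-axis
#'   spacing).
#' @return Numeric vector of per-cell Péclet numbers.
#' @export
peclet_field <- function(field, drift = NULL, spacing = field$grid$spacing[1]) {
  stopifnot(inherits(field, "tensor_field"))
  if (is.null(drift)) drift <- tensor_divergence(field)
  stopifnot(inherits(drift, "drift_field"))
  if (!identical(drift$grid$cells, field$grid$cells)) {
    stop("drift must be derived from the same grid", call. = FALSE)
  }
  d <- field$grid$dim
  fro2 <- 0
  for (i in seq_len(d)) for (j in seq_len(d)) {
    fro2 <- fro2 + field$tensors[, i, j]^2
  }
  fro <- sqrt(fro2)
  if (any(fro == 0)) {
    stop(sprintf("zero tensor norm in cell(s) %s: Peclet undefined",
                 paste(utils::head(which(fro == 0), 5), collapse = ", ")),
         call. = FALSE)
  }
  sqrt(rowSums(drift$b^2)) * spacing / fro
}

#' Determinants of the per-cell tensors
#'
#' @param field A `tensor_field`.
#' @return Numeric vector of cell-tensor determinants.
#' @export
tensor_determinants <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  t_ <- field$tensors
  d <- field$grid$dim
  if (d == 1) {
    t_[, 1, 1]
  } else if (d == 2) {
    t_[, 1, 1] * t_[, 2, 2] - t_[, 1, 2] * t_[, 2, 1]
  } else {
    t_[, 1, 1] * (t_[, 2, 2] * t_[, 3, 3] - t_[, 2, 3] * t_[, 3, 2]) -
      t_[, 1, 2] * (t_[, 2, 1] * t_[, 3, 3] - t_[, 2, 3] * t_[, 3, 1]) +
      t_[, 1, 3] * (t_[, 2, 1] * t_[, 3, 2] - t_[, 2, 2] * t_[, 3, 1])
  }
}
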