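#' First-order finite-element assembly on structured grids
#'
#' Multilinear (Q1) trial and test functions on cubic cells, 2-point Gauss
#' quadrature per axis (exact for the multilinear integrands with
#' cell-constant tensors).  The assembled operators discretize the spatial
#' part of the growth model
#' \deqn{\partial_t u = \nabla\cdot(D\nabla u) + \nabla\cdot((\nabla\cdot D)\,u)
#'       + \rho u(1-u)}
#' in weak form with natural zero-flux (Neumann) outer boundaries:
#' * `M`  — consistent mass matrix,
#' * `K`  — diffusion operator, \eqn{K_{ij} = -\int \nabla\varphi_i \cdot D \nabla\varphi_j},
#' * `B`  — drift operator in once-integrated-by-parts form,
#'   \eqn{B_{ij} = -\int (\nabla\varphi_i \cdot b)\,\varphi_j} with
#'   \eqn{b = \nabla\cdot D},
#' * `ML` — lumped mass (row sums of `M`), used for the nodal reaction terms.
#'
#' Tensors and drift vectors are piecewise constant per cell (dual grid);
#' homogeneous fields yield an exactly zero drift operator.
#'
#' @param grid A `structured_grid`.
#' @param field A `tensor_field` on the same grid.
#' @param drift A `drift_field`; computed by [tensor_divergence()] when
#'   omitted (and skipped entirely for constant fields).
#' @return An object of class `assembled_system` with sparse matrices `M`,
#'   `K`, `B` and numeric vector `ML`.
#' @export
#' @examples
#' g <- build_grid(1, 4)
#' sys <- assemble(g, homogeneous_field(g, 1))
#' round(as.matrix(sys$K) * g$spacing, 10)  # [1, -2, 1] rows
assemble <- function(grid, field, drift = NULL) {
  stopifnot(inherits(grid, "structured_grid"), inherits(field, "tensor_field"))
  if (!identical(field$grid$cells, grid$cells)) {
    stop("field does not live on this grid", call. = FALSE)
  }
  d <- grid$dim
  h <- grid$spacing
  nloc <- 2^d

  if (is.null(drift)) {
    const_field <- all(apply(field$tensors, c(2, 3),
                             function(v) max(v) - min(v) == 0))
    drift <- if (const_field) {
      structure(list(grid = grid, b = matrix(0, grid$n_cells, d)),
                class = "drift_field")
    } else {
      tensor_divergence(field)
    }
  }
  if (!identical(drift$grid$cells, grid$cells)) {
    stop("drift does not live on this grid", call. = FALSE)
  }

  # 1D factor matrices per axis: mass m, stiffness s, convection g
  #   m[i,j] = int f_i f_j = h/6 [[2,1],[1,2]]
  #   s[i,j] = int f_i' f_j' = 1/h [[1,-1],[-1,1]]
  #   g[i,j] = int f_i' f_j = [[-1/2,-1/2],[1/2,1/2]]   (h-independent)
  m1 <- lapply(h, function(hh) hh / 6 * matrix(c(2, 1, 1, 2), 2))
  s1 <- lapply(h, function(hh) 1 / hh * matrix(c(1, -1, -1, 1), 2))
  g1 <- matrix(c(-0.5, 0.5, -0.5, 0.5), 2)  # rows: derivative index i

  # local basis multi-indices (0/1 per axis), axis 1 fastest
  loc <- as.matrix(expand.grid(rep(list(0:1), d))) # nloc x d

  # weight for local pair (i,j) and derivative axes (a on i, b on j);
  # a or b = 0 means no derivative on that side
  pair_weight <- function(i, j, a, b) {
    w <- 1
    for (k in seq_len(d)) {
      ik <- loc[i, k] + 1L
      jk <- loc[j, k] + 1L
      w <- w * if (k == a && k == b) {
        s1[[k]][ik, jk]
      } else if (k == a) {
        g1[ik, jk]
      } else if (k == b) {
        g1[jk, ik]
      } else {
        m1[[k]][ik, jk]
      }
    }
    w
  }

  # global node index (1-based) of local corner l for every cell
  cidx <- arrayInd(seq_len(grid$n_cells), .dim = grid$cells) - 1L # lower corner
  npa <- grid$nodes_per_axis
  mult <- cumprod(c(1, npa[-d]))
  corner_index <- function(l) {
    as.integer((cidx + matrix(loc[l, ], grid$n_cells, d, byrow = TRUE)) %*% mult) + 1L
  }
  gidx <- vapply(seq_len(nloc), corner_index, integer(grid$n_cells))

  ncells <- grid$n_cells
  nent <- nloc * nloc * ncells
  rows <- integer(nent); cols <- integer(nent)
  mval <- numeric(nent); kval <- numeric(nent); bval <- numeric(nent)

  Dab <- lapply(seq_len(d), function(a)
    lapply(seq_len(d), function(b) field$tensors[, a, b]))
  bvec <- lapply(seq_len(d), function(a) drift$b[, a])
  any_drift <- any(drift$b != 0)

  pos <- 1L
  for (i in seq_len(nloc)) {
    for (j in seq_len(nloc)) {
      mw <- pair_weight(i, j, 0L, 0L)
      kv <- numeric(ncells)
      for (a in seq_len(d)) for (b in seq_len(d)) {
        kv <- kv - Dab[[a]][[b]] * pair_weight(i, j, a, b)
      }
      bv <- numeric(ncells)
      if (any_drift) {
        for (a in seq_len(d)) {
          bv <- bv - bvec[[a]] * pair_weight(i, j, a, 0L)
        }
      }
      sl <- pos:(pos + ncells - 1L)
      rows[sl] <- gidx[, i]
      cols[sl] <- gidx[, j]
      mval[sl] <- mw
      kval[sl] <- kv
      bval[sl] <- bv
      pos <- pos + ncells
    }
  }

  n <- grid$n_nodes
  M <- Matrix::sparseMatrix(i = rows, j = cols, x = mval, dims = c(n, n))
  K <- Matrix::sparseMatrix(i = rows, j = cols, x = kval, dims = c(n, n))
  B <- Matrix::sparseMatrix(i = rows, j = cols, x = bval, dims = c(n, n))
  structure(list(grid = grid, M = M, K = K, B = B,
                 ML = as.numeric(Matrix::rowSums(M))),
            class = "assembled_system")
}

#' @export
print.assembled_system <- function(x, ...) {
  cat(sprintf("assembled_system: %d nodes, %d stored stiffness entries\n",
              x$grid$n_nodes, length(x$K@x)))
  invisible(x)
}

#' Apply the assembled spatial operator
#'
#' Computes `K u + B u`, the discrete
#' \eqn{\nabla\cdot(D\nabla u) + \nabla\cdot(b u)} in weak form (so the
#' result carries the test-function mass; divide by `ML` for a pointwise
#' rate).
#'
#' @param system An `assembled_system`.
#' @param u Numeric nodal vector.
#' @return Numeric vector of length `n_nodes`.
#' @export
apply_operator <- function(system, u) {
  stopifnot(inherits(system, "assembled_system"))
  as.numeric(system$K %*% u + system$B %*% u)
}
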