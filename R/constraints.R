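#' Internal Dirichlet constraints at the imaging-visibility threshold
#'
#' The stationary estimator is localized by pinning the density to the
#' visibility threshold \eqn{\theta} (default 0.16, the volume fraction
#' above which tumor is visible on imaging) on the discrete boundary shell
#' of the visible region: every node with \eqn{u \ge \theta} that has at
#' least one face-neighbor node with \eqn{u < \theta}.
#'
#' @name internal-dirichlet
NULL

#' Construct a constraint set
#'
#' @param grid A `structured_grid`.
#' @param indices Integer vector of pinned (1-based) node indices, unique
#'   and within the grid.
#' @param value Pinned density \eqn{\theta \in (0,1)} (default 0.16).
#' @return An object of class `constraint_set`.
#' @export
constraint_set <- function(grid, indices, value = 0.16) {
  stopifnot(inherits(grid, "structured_grid"))
  indices <- as.integer(indices)
  if (anyDuplicated(indices) || any(indices < 1) || any(indices > grid$n_nodes)) {
    stop("constraint indices must be unique and inside the grid", call. = FALSE)
  }
  if (!is.numeric(value) || value <= 0 || value >= 1) {
    stop("pinned value must lie strictly inside (0, 1)", call. = FALSE)
  }
  structure(list(grid = grid, indices = indices, value = value),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("constraint_set: %d pinned nodes at theta = %g\n",
              length(x$indices), x$value))
  invisible(x)
}

#' Extract the visible-region boundary shell as Dirichlet constraints
#'
#' Thresholds a nodal density field at `theta` and returns the one-node
#' boundary shell of the super-threshold region: nodes at or above the
#' threshold with at least one face neighbor below it.  In a forward-run
#' validation this plays the role of the segmented tumor border on the scan.
#' A field entirely above or below the threshold yields an empty set with a
#' warning.
#'
#' With `interior = TRUE` every super-threshold node is pinned, not just the
#' shell.  Outside the visible region both choices solve identically (the
#' one-node shell screens the interior from the free equations); interior
#' pinning fixes the inside to \eqn{\theta}, which keeps the estimate's
#' super-threshold region aligned with the segmentation when level-set
#' metrics are evaluated at thresholds below \eqn{\theta}.
#'
#' @param grid A `structured_grid`.
#' @param u Numeric nodal density field.
#' @param theta Visibility threshold in (0, 1), default 0.16.
#' @param interior Pin the full interior of the visible region as well
#'   (default `FALSE`: shell only).
#' @return A `constraint_set` (possibly empty).
#' @export
#' @examples
#' g <- build_grid(4, 4)
#' extract_constraints(g, c(1, 1, 1, 0, 0), theta = 0.16)  # node 3 pinned
extract_constraints <- function(grid, u, theta = 0.16, interior = FALSE) {
  stopifnot(inherits(grid, "structured_grid"), length(u) == grid$n_nodes)
  if (!is.numeric(theta) || theta <= 0 || theta >= 1) {
    stop("theta must lie strictly inside (0, 1)", call. = FALSE)
  }
  above <- array(u >= theta, dim = grid$nodes_per_axis)
  if (all(above) || !any(above)) {
    warning("field entirely on one side of theta: empty constraint shell")
    return(structure(list(grid = grid, indices = integer(0), value = theta),
                     class = "constraint_set"))
  }
  if (interior) {
    return(constraint_set(grid, which(as.vector(above)), theta))
  }
  has_low_neighbor <- array(FALSE, dim = grid$nodes_per_axis)
  d <- grid$dim
  dims <- grid$nodes_per_axis
  for (axis in seq_len(d)) {
    for (off in c(-1L, 1L)) {
      idx <- rep(list(quote(expr = )), d)
      n <- dims[axis]
      src <- seq_len(n) + off
      valid <- src >= 1L & src <= n
      idx_dst <- idx; idx_dst[[axis]] <- which(valid)
      idx_src <- idx; idx_src[[axis]] <- src[valid]
      neigh_below <- !do.call(`[`, c(list(above), idx_src, list(drop = FALSE)))
      cur <- do.call(`[`, c(list(has_low_neighbor), idx_dst, list(drop = FALSE)))
      has_low_neighbor <- do.call(`[<-`, c(list(has_low_neighbor), idx_dst,
                                           list(cur | neigh_below)))
    }
  }
  shell <- which(as.vector(above & has_low_neighbor))
  constraint_set(grid, shell, theta)
}

#' Impose constraints on a linear(ized) system
#'
#' Replaces the constrained rows of a system matrix by identity rows and the
#' corresponding right-hand-side entries by the pinned value, so the
#' solution equals \eqn{\theta} exactly at pinned nodes while unconstrained
#' equations see the pinned values as data.  An empty set leaves the system
#' unchanged.
#'
#' @param A Sparse system matrix (n x n).
#' @param rhs Right-hand-side vector.
#' @param constraints A `constraint_set`.
#' @return List with constrained `A` and `rhs`.
#' @export
apply_constraints <- function(A, rhs, constraints) {
  stopifnot(inherits(constraints, "constraint_set"))
  idx <- constraints$indices
  if (length(idx) == 0) return(list(A = A, rhs = rhs))
  n <- nrow(A)
  mask <- rep(1, n)
  mask[idx] <- 0
  A <- Matrix::Diagonal(n, mask) %*% A +
    Matrix::sparseMatrix(i = idx, j = idx, x = 1, dims = c(n, n))
  rhs[idx] <- constraints$value
  list(A = A, rhs = rhs)
}
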