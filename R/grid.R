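#' Axis-aligned structured grid
#'
#' Builds the cubic-cell grid all fields and operators live on.  Nodes sit at
#' cell corners; node indexing is lexicographic with axis 1 fastest, so node
#' `i` along axis 1 is at position `i * h1` (0-based).  Cells are indexed by
#' their lower corner and own their half-open box
#' \eqn{[x_c, x_c + h)} for point queries, so a point on a shared face
#' belongs to the lower-index cell.
#'
#' @param extents Numeric vector of physical lengths per axis (1, 2 or 3
#'   entries), all > 0.
#' @param cells Integer vector of cell counts per axis, same length, all
#'   >= 1.
#' @return An object of class `structured_grid` with elements `dim`,
#'   `extents`, `cells`, `spacing`, `nodes_per_axis`, `n_nodes`, `n_cells`.
#' @export
#' @examples
#' g <- build_grid(200, 1000)   # 1001 nodes, spacing 0.2
#' g$spacing
build_grid <- function(extents, cells) {
  extents <- as.numeric(extents)
  cells <- as.integer(cells)
  if (length(extents) < 1 || length(extents) > 3 ||
      length(cells) != length(extents)) {
    stop("extents and cells must have matching length 1, 2 or 3", call. = FALSE)
  }
  if (any(extents <= 0) || any(cells < 1)) {
    stop("extents must be positive and cells >= 1", call. = FALSE)
  }
  d <- length(extents)
  npa <- cells + 1L
  structure(list(
    dim = d,
    extents = extents,
    cells = cells,
    spacing = extents / cells,
    nodes_per_axis = npa,
    n_nodes = prod(npa),
    n_cells = prod(cells)
  ), class = "structured_grid")
}

#' @export
print.structured_grid <- function(x, ...) {
  cat(sprintf("structured_grid: %dD, extents [%s], cells [%s], %d nodes\n",
              x$dim, paste(signif(x$extents, 6), collapse = " x "),
              paste(x$cells, collapse = " x "), x$n_nodes))
  invisible(x)
}

# per-axis 0-based integer coordinates of every node, as a n_nodes x d matrix
node_multi_index <- function(grid) {
  idx <- arrayInd(seq_len(grid$n_nodes), .dim = grid$nodes_per_axis)
  idx - 1L
}

#' Node and cell-center coordinates
#'
#' @param grid A `structured_grid`.
#' @return A numeric matrix (`n_nodes` x `dim` or `n_cells` x `dim`) of
#'   physical coordinates in lexicographic index order (axis 1 fastest).
#' @export
node_coords <- function(grid) {
  stopifnot(inherits(grid, "structured_grid"))
  sweep(node_multi_index(grid), 2, grid$spacing, `*`)
}

#' @rdname node_coords
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "structured_grid"))
  idx <- arrayInd(seq_len(grid$n_cells), .dim = grid$cells) - 1L
  sweep(sweep(idx, 2, grid$spacing, `*`), 2, grid$spacing / 2, `+`)
}

#' Cell owning a physical point
#'
#' Half-open ownership: a point on a shared cell face belongs to the
#' lower-index cell; the upper domain boundary belongs to the last cell.
#'
#' @param grid A `structured_grid`.
#' @param x Numeric matrix of points (rows) or a single point vector.
#' @return Integer vector of 1-based cell indices.
#' @export
cell_of_point <- function(grid, x) {
  stopifnot(inherits(grid, "structured_grid"))
  x <- matrix(x, ncol = grid$dim)
  t_ <- sweep(x, 2, grid$spacing, `/`)
  ix <- floor(t_)
  # tie-break: points on a shared cell face belong to the lower-index cell
  on_face <- abs(t_ - round(t_)) < 1e-9 * pmax(1, abs(t_))
  ix[on_face] <- round(t_[on_face]) - 1
  ix <- pmin(pmax(ix, 0), matrix(grid$cells - 1L, nrow(x), grid$dim, byrow = TRUE))
  mult <- cumprod(c(1, grid$cells[-grid$dim]))
  as.integer(ix %*% mult) + 1L
}

# cell volume (all cells equal)
cell_volume <- function(grid) prod(grid$spacing)

#' Gaussian initial density bump
#'
#' A centered Gaussian of configurable amplitude and width, the standard
#' stand-in for the (unknown) carciogenesis seed in the synthetic scenarios.
#'
#' @param grid A `structured_grid`.
#' @param center Numeric vector, physical center (default: domain center).
#' @param sd Standard deviation in length units (default: 5 cells).
#' @param amplitude Peak density (default 1).
#' @return Numeric vector of nodal densities.
#' @export
gaussian_ic <- function(grid, center = grid$extents / 2,
                        sd = 5 * grid$spacing[1], amplitude = 1) {
  stopifnot(inherits(grid, "structured_grid"), sd > 0, amplitude > 0)
  xy <- node_coords(grid)
  r2 <- rowSums(sweep(xy, 2, center)^2)
  amplitude * exp(-r2 / (2 * sd^2))
}
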