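#' Field input/output
#'
#' Nodal scalar fields are written as legacy-ASCII VTK structured points
#' (readable by ParaView and VisIt); 3D scalar and tensor volumes round-trip
#' through NIfTI via the RNifti package (a Suggests dependency, loaded on
#' use).  Tensor volumes use the 6-component upper-triangle voxel layout
#' common to DTI exports; the lower-triangle dialect is accepted via
#' `layout = "lower"`.
#'
#' @name field-io
NULL

#' Write nodal fields to a legacy VTK structured-points file
#'
#' @param grid A `structured_grid`.
#' @param fields Named list of numeric nodal vectors.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_vtk <- function(grid, fields, path) {
  stopifnot(inherits(grid, "structured_grid"), is.list(fields),
            length(names(fields)) == length(fields))
  np <- c(grid$nodes_per_axis, rep(1L, 3 - grid$dim))
  h <- c(grid$spacing, rep(1, 3 - grid$dim))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "gliostat field export",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", np[1], np[2], np[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.17g %.17g %.17g", h[1], h[2], h[3]),
               sprintf("POINT_DATA %d", grid$n_nodes)), con)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    stopifnot(length(v) == grid$n_nodes)
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(format(v, digits = 17, scientific = TRUE, trim = TRUE), con)
  }
  invisible(path)
}

#' Write and read 3D nodal scalar fields as NIfTI
#'
#' @param grid A 3D `structured_grid`.
#' @param u Numeric nodal field.
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_scalar_nifti`: the path invisibly; `read_scalar_nifti`:
#'   a numeric nodal vector.
#' @export
write_scalar_nifti <- function(grid, u, path) {
  require_rnifti()
  stopifnot(grid$dim == 3, length(u) == grid$n_nodes)
  img <- array(u, dim = grid$nodes_per_axis)
  RNifti::writeNifti(RNifti::asNifti(img, pixdim = grid$spacing), path)
  invisible(path)
}

#' @rdname write_scalar_nifti
#' @export
read_scalar_nifti <- function(path, grid) {
  require_rnifti()
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (!all(dim(arr)[1:3] == grid$nodes_per_axis)) {
    stop("NIfTI volume dimensions do not match the grid", call. = FALSE)
  }
  as.vector(arr)
}

#' Read a per-voxel symmetric tensor volume from NIfTI
#'
#' Expects a 4D volume whose fourth dimension holds the 6 unique components
#' of the symmetric tensor per voxel, in upper-triangle row order
#' (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz) or lower-triangle order
#' (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz).  Voxels map to grid cells.
#'
#' @param path NIfTI file path.
#' @param grid A 3D `structured_grid` whose cell counts match the voxel
#'   grid.
#' @param layout `"upper"` (default) or `"lower"`.
#' @return A `tensor_field`.
#' @export
read_tensor_nifti <- function(path, grid, layout = c("upper", "lower")) {
  require_rnifti()
  layout <- match.arg(layout)
  stopifnot(grid$dim == 3)
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 4 || dim(arr)[4] != 6) {
    stop("expected a 4D volume with 6 tensor components per voxel",
         call. = FALSE)
  }
  if (!all(dim(arr)[1:3] == grid$cells)) {
    stop("voxel grid does not match the cell grid", call. = FALSE)
  }
  comp <- matrix(arr, ncol = 6)
  # map the component columns to (i, j) entries
  ord <- if (layout == "upper") {
    list(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3))
  } else {
    list(c(1, 1), c(1, 2), c(2, 2), c(1, 3), c(2, 3), c(3, 3))
  }
  tens <- array(0, dim = c(grid$n_cells, 3, 3))
  for (k in seq_along(ord)) {
    i <- ord[[k]][1]; j <- ord[[k]][2]
    tens[, i, j] <- comp[, k]
    tens[, j, i] <- comp[, k]
  }
  tensor_field(grid, tens, check = FALSE)
}

#' @rdname read_tensor_nifti
#' @param field A `tensor_field` on a 3D grid.
#' @export
write_tensor_nifti <- function(field, path, layout = c("upper", "lower")) {
  require_rnifti()
  layout <- match.arg(layout)
  grid <- field$grid
  stopifnot(grid$dim == 3)
  ord <- if (layout == "upper") {
    list(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3))
  } else {
    list(c(1, 1), c(1, 2), c(2, 2), c(1, 3), c(2, 3), c(3, 3))
  }
  comp <- sapply(ord, function(ij) field$tensors[, ij[1], ij[2]])
  arr <- array(comp, dim = c(grid$cells, 6))
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = grid$spacing), path)
  invisible(path)
}

require_rnifti <- function() {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI I/O requires the RNifti package", call. = FALSE)
  }
}
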