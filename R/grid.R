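#' Snap coordinates to the lattice
#'
#' Each coordinate component is replaced by `round(c / spacing) * spacing`,
#' with ties at half-grid rounded away from zero (so 0.25 at spacing 0.5
#' snaps to 0.5, and -0.25 to -0.5). Idempotent.
#'
#' @param coords numeric vector, 3-vector, or n x 3 matrix of Angstrom
#'   coordinates.
#' @param spacing lattice spacing in Angstrom (> 0).
#' @return object of the same shape with snapped coordinates.
#' @export
snap_coordinates <- function(coords, spacing) {
  stopifnot_scalar(spacing, "spacing", positive = TRUE)
  ## round half away from zero (base round() is banker's rounding)
  k <- sign(coords) * floor(abs(coords) / spacing + 0.5)
  k * spacing
}

#' Build the Cartesian lattice shared by all molecules
#'
#' Atom coordinates of every molecule in every supplied set are snapped to
#' the lattice; per axis the padded range is
#' `[min(snapped) - padding, max(snapped) + padding]` and the point count is
#' `ceiling(range / spacing) + 1` (both padded extremes are lattice points).
#' The origin is the minimum corner after padding. Train and test/predict
#' molecules must be passed together so all rows share one grid.
#'
#' @param sets a `comsia_molset` or list of them.
#' @param spacing lattice spacing, Angstrom (default 1).
#' @param padding buffer added beyond the extreme snapped coordinates,
#'   Angstrom (default 4).
#' @return an object of class `comsia_grid` with `origin`, `spacing`,
#'   `dims`, `padding`.
#' @export
build_grid <- function(sets, spacing = 1, padding = 4) {
  stopifnot_scalar(spacing, "spacing", positive = TRUE)
  stopifnot_scalar(padding, "padding")
  if (padding < 0) abort("`padding` must be >= 0")
  if (inherits(sets, "comsia_molset")) sets <- list(sets)
  mols <- unlist(lapply(sets, function(s) s$molecules), recursive = FALSE)
  if (!length(mols)) abort("cannot build a grid from an empty molecule set")
  xyz <- do.call(rbind, lapply(mols, coords_matrix))
  snapped <- snap_coordinates(xyz, spacing)
  lo <- apply(snapped, 2, min) - padding
  hi <- apply(snapped, 2, max) + padding
  dims <- as.integer(ceiling(round((hi - lo) / spacing, 9)) + 1L)
  structure(
    list(origin = unname(lo), spacing = spacing, dims = dims, padding = padding),
    class = "comsia_grid"
  )
}

#' @export
print.comsia_grid <- function(x, ...) {
  cat(sprintf(
    "<comsia_grid> %d x %d x %d points (spacing %g A, padding %g A), origin (%g, %g, %g)\n",
    x$dims[1], x$dims[2], x$dims[3], x$spacing, x$padding,
    x$origin[1], x$origin[2], x$origin[3]
  ))
  invisible(x)
}

#' Enumerate the lattice points
#'
#' Points are enumerated x-fastest (x varies first, then y, then z); the
#' first point is the origin and the last is
#' `origin + (dims - 1) * spacing`. This ordering is the `grid_index`
#' convention used by the column metadata and coefficient maps.
#'
#' @param grid a `comsia_grid`.
#' @return `prod(dims)` x 3 numeric matrix of Angstrom coordinates.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "comsia_grid"))
  ax <- lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$dims[a]) - 1) * grid$spacing)
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]], KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  pts
}

#' Number of lattice points
#' @param grid a `comsia_grid`.
#' @return integer, `prod(dims)`.
#' @export
n_grid_points <- function(grid) prod(grid$dims)

## TRUE if every snapped atom of every molecule lies >= margin inside the box
grid_covers <- function(grid, sets, margin = grid$padding) {
  if (inherits(sets, "comsia_molset")) sets <- list(sets)
  mols <- unlist(lapply(sets, function(s) s$molecules), recursive = FALSE)
  xyz <- do.call(rbind, lapply(mols, coords_matrix))
  snapped <- snap_coordinates(xyz, grid$spacing)
  lo <- grid$origin
  hi <- grid$origin + (grid$dims - 1) * grid$spacing
  eps <- 1e-9
  all(vapply(1:3, function(a) {
    all(snapped[, a] >= lo[a] + margin - eps) && all(snapped[, a] <= hi[a] - margin + eps)
  }, logical(1)))
}
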