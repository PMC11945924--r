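#' Scatter PLS coefficients back onto the lattice
#'
#' Each kept column's `coefficient * stored scaled-field standard deviation`
#' is placed at its grid point; filtered (dropped) columns hold 0. One map
#' per field; the plotted quantity is the conventional "coefficient x std"
#' product, so regions score by how much a field difference there moves the
#' predicted activity.
#'
#' @param model a `comsia_qsar`.
#' @param field one field code from the model's enabled fields.
#' @return object of class `comsia_coefmap`: `values` (3-d array in grid
#'   dims, x-fastest), `field`, `grid`.
#' @export
coefficient_map <- function(model, field) {
  if (!field %in% model$fields) abort(sprintf("field '%s' was not part of the model", field))
  cols <- model$columns
  kept <- cols[cols$kept, ]
  if (length(model$coefficients) != nrow(kept)) {
    abort("coefficient vector and kept-column metadata are out of step")
  }
  b <- model$coefficients * kept$sd_scaled
  flat <- numeric(n_grid_points(model$grid))
  sel <- kept$field == field
  flat[kept$grid_index[sel]] <- b[sel]
  structure(
    list(
      values = array(flat, dim = model$grid$dims),
      field = field,
      grid = model$grid
    ),
    class = "comsia_coefmap"
  )
}

#' @export
print.comsia_coefmap <- function(x, ...) {
  cat(sprintf("<comsia_coefmap> field %s, %d x %d x %d, range [%.4g, %.4g]\n",
              x$field, x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Percentile thresholds of a coefficient map
#'
#' The high threshold is the `(1 - top_fraction)` quantile and the low
#' threshold the `top_fraction` quantile of the NONZERO map values
#' (linear-interpolation quantiles). Quantiles are taken over nonzero values
#' only so that the empty-space zeros dominating the lattice cannot collapse
#' both thresholds to 0; `top_fraction` is per tail (default 0.05: the top
#' 5 percent most positive and most negative coefficient mass).
#'
#' @param map a `comsia_coefmap`.
#' @param top_fraction fraction per tail, in (0, 0.5).
#' @return named numeric `c(low, high)`.
#' @export
percentile_thresholds <- function(map, top_fraction = 0.05) {
  stopifnot_scalar(top_fraction, "top_fraction")
  if (top_fraction <= 0 || top_fraction >= 0.5) {
    abort("`top_fraction` must lie strictly between 0 and 0.5")
  }
  vals <- map$values[map$values != 0]
  if (!length(vals) || diff(range(map$values)) == 0) {
    abort(sprintf("no contourable signal: the %s coefficient map is constant", map$field))
  }
  qs <- quantile(vals, c(top_fraction, 1 - top_fraction), names = FALSE, type = 7)
  c(low = qs[1], high = qs[2])
}

#' Extract high/low isosurfaces from a coefficient map
#'
#' Marching-tetrahedra level-set extraction (each lattice cell split into
#' six tetrahedra, crossings linearly interpolated along edges): the
#' `high` mesh is the surface `values = thresholds["high"]` enclosing the
#' favorable region and `low` the surface at `thresholds["low"]`. Vertex
#' coordinates are in Angstrom (`origin + index * spacing`). A threshold
#' outside the value range yields an empty mesh with a warning, not an
#' error.
#'
#' @param map a `comsia_coefmap`.
#' @param thresholds numeric `c(low, high)` as from
#'   [percentile_thresholds()].
#' @return object of class `comsia_contour`: `field`, `low_threshold`,
#'   `high_threshold` and meshes `high`, `low` (each `vertices` n x 3,
#'   `faces` m x 3 of 1-based vertex indices).
#' @export
extract_isosurfaces <- function(map, thresholds) {
  lo <- unname(thresholds[["low"]])
  hi <- unname(thresholds[["high"]])
  rng <- range(map$values)
  mesh_at <- function(level, tag) {
    if (level <= rng[1] || level >= rng[2]) {
      if (diff(rng) > 0) {
        warn(sprintf("%s threshold %.4g of field %s lies outside the map range [%.4g, %.4g]; empty mesh",
                     tag, level, map$field, rng[1], rng[2]))
      }
      return(list(vertices = matrix(numeric(0), 0, 3), faces = matrix(integer(0), 0, 3)))
    }
    marching_tetrahedra(map$values, level, map$grid)
  }
  structure(
    list(
      field = map$field,
      low_threshold = lo,
      high_threshold = hi,
      high = mesh_at(hi, "high"),
      low = mesh_at(lo, "low")
    ),
    class = "comsia_contour"
  )
}

#' @export
print.comsia_contour <- function(x, ...) {
  cat(sprintf(
    "<comsia_contour> field %s: high %.4g (%d faces), low %.4g (%d faces)\n",
    x$field, x$high_threshold, nrow(x$high$faces), x$low_threshold, nrow(x$low$faces)
  ))
  invisible(x)
}

## ---------------------------------------------------------------------------
## marching tetrahedra: v is a nx x ny x nz array, level the iso value.
## Every cell is decomposed into 6 tetrahedra sharing the main diagonal
## (corners 0 and 6); within a tetrahedron the surface crossing is planar and
## linear interpolation along the crossing edges is exact for a trilinear
## patch restricted to the tet edges.

TET_DECOMP <- matrix(c(
  1, 6, 2, 7,
  1, 2, 3, 7,
  1, 3, 4, 7,
  1, 4, 8, 7,
  1, 8, 5, 7,
  1, 5, 6, 7
), ncol = 4, byrow = TRUE)

## cube corner offsets, 1-based rows matching TET_DECOMP indices
CUBE_OFFSETS <- matrix(c(
  0, 0, 0,
  1, 0, 0,
  1, 1, 0,
  0, 1, 0,
  0, 0, 1,
  1, 0, 1,
  1, 1, 1,
  0, 1, 1
), ncol = 3, byrow = TRUE)

marching_tetrahedra <- function(v, level, grid) {
  dims <- dim(v)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ## candidate cells: those whose 8 corners straddle the level
  verts <- list(); nv <- 0L
  tri <- list(); nt <- 0L
  interp <- function(pa, va, pb, vb) {
    t <- (level - va) / (vb - va)
    pa + t * (pb - pa)
  }
  ## precompute straddle mask over cells to skip empty space quickly
  below <- v < level
  cell_has <- function(i, j, k) {
    block <- below[i:(i + 1), j:(j + 1), k:(k + 1)]
    any(block) && !all(block)
  }
  for (k in seq_len(nz - 1L)) {
    for (j in seq_len(ny - 1L)) {
      for (i in seq_len(nx - 1L)) {
        if (!cell_has(i, j, k)) next
        corner_idx <- cbind(
          i + CUBE_OFFSETS[, 1], j + CUBE_OFFSETS[, 2], k + CUBE_OFFSETS[, 3]
        )
        cv <- v[corner_idx]
        cp <- sweep(corner_idx - 1, 2, grid$spacing, "*")
        cp <- sweep(cp, 2, grid$origin, "+")
        for (tt in seq_len(nrow(TET_DECOMP))) {
          ids <- TET_DECOMP[tt, ]
          tv <- cv[ids]
          inside <- tv > level
          nin <- sum(inside)
          if (nin == 0L || nin == 4L) next
          tp <- cp[ids, , drop = FALSE]
          if (nin == 1L || nin == 3L) {
            apex <- if (nin == 1L) which(inside) else which(!inside)
            others <- setdiff(1:4, apex)
            pts <- t(vapply(others, function(o) {
              interp(tp[apex, ], tv[apex], tp[o, ], tv[o])
            }, numeric(3)))
            verts[[nv + 1L]] <- pts
            tri[[nt + 1L]] <- matrix(nv + c(1L, 2L, 3L), 1, 3)
            nv <- nv + 3L; nt <- nt + 1L
          } else {
            ins <- which(inside); outs <- which(!inside)
            q <- rbind(
              interp(tp[ins[1], ], tv[ins[1]], tp[outs[1], ], tv[outs[1]]),
              interp(tp[ins[1], ], tv[ins[1]], tp[outs[2], ], tv[outs[2]]),
              interp(tp[ins[2], ], tv[ins[2]], tp[outs[2], ], tv[outs[2]]),
              interp(tp[ins[2], ], tv[ins[2]], tp[outs[1], ], tv[outs[1]])
            )
            verts[[nv + 1L]] <- q
            tri[[nt + 1L]] <- rbind(
              nv + c(1L, 2L, 3L),
              nv + c(1L, 3L, 4L)
            )
            nv <- nv + 4L; nt <- nt + 2L
          }
        }
      }
    }
  }
  if (!length(verts)) {
    return(list(vertices = matrix(numeric(0), 0, 3), faces = matrix(integer(0), 0, 3)))
  }
  list(vertices = do.call(rbind, verts), faces = do.call(rbind, tri))
}

## ---------------------------------------------------------------------------
## mesh and volume export

#' Export contour meshes
#'
#' Writes the high and low meshes of one or more contour sets as Wavefront
#' OBJ and/or legacy VTK polydata files under `dir`. Filenames encode field
#' and sign (`contour_<field>_<high|low>.<ext>`); metadata comments record
#' the threshold and the conventional favorable/unfavorable reading of each
#' sign.
#'
#' @param contours a `comsia_contour` or list of them.
#' @param dir output directory (created if needed).
#' @param format `"obj"`, `"vtk"` or both.
#' @return character vector of written paths, invisibly.
#' @export
export_contours <- function(contours, dir, format = c("obj", "vtk")) {
  format <- match.arg(format, several.ok = TRUE)
  if (inherits(contours, "comsia_contour")) contours <- list(contours)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (ct in contours) {
    for (side in c("high", "low")) {
      mesh <- ct[[side]]
      thr <- if (side == "high") ct$high_threshold else ct$low_threshold
      label <- if (side == "high") "favorable (positive coefficient x std)" else
        "unfavorable (negative coefficient x std)"
      stem <- file.path(dir, sprintf("contour_%s_%s", ct$field, side))
      if ("obj" %in% format) {
        p <- paste0(stem, ".obj")
        write_obj(mesh, p, comment = sprintf("field %s %s threshold %.6g: %s",
                                             ct$field, side, thr, label))
        written <- c(written, p)
      }
      if ("vtk" %in% format) {
        p <- paste0(stem, ".vtk")
        write_vtk_polydata(mesh, p, title = sprintf("field %s %s threshold %.6g",
                                                    ct$field, side, thr))
        written <- c(written, p)
      }
    }
  }
  invisible(written)
}

write_obj <- function(mesh, path, comment = NULL) {
  con <- file(path, "wt")
  on.exit(close(con), add = TRUE)
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  if (nrow(mesh$vertices)) {
    writeLines(sprintf("v %.6f %.6f %.6f",
                       mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("f %d %d %d",
                       mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  }
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  parse3 <- function(x, fun) {
    if (!length(x)) return(matrix(fun(numeric(0)), 0, 3))
    m <- do.call(rbind, strsplit(sub("^[vf] ", "", x), "\\s+"))
    matrix(fun(m), ncol = 3)
  }
  list(
    vertices = parse3(vl, as.numeric),
    faces = parse3(fl, as.integer)
  )
}

write_vtk_polydata <- function(mesh, path, title = "comsia contour") {
  con <- file(path, "wt")
  on.exit(close(con), add = TRUE)
  nvert <- nrow(mesh$vertices)
  nface <- nrow(mesh$faces)
  writeLines(c(
    "# vtk DataFile Version 3.0",
    title,
    "ASCII",
    "DATASET POLYDATA",
    sprintf("POINTS %d float", nvert)
  ), con)
  if (nvert) {
    writeLines(sprintf("%.6f %.6f %.6f",
                       mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  }
  writeLines(sprintf("POLYGONS %d %d", nface, nface * 4L), con)
  if (nface) {
    writeLines(sprintf("3 %d %d %d",
                       mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  }
  invisible(path)
}

## Gaussian cube volume (values in grid order, z-fastest per cube convention)
write_cube_volume <- function(values, grid, path, title = "comsia volume") {
  bohr <- 1 / 0.52917721092  # cube files are in atomic units
  arr <- array(values, dim = grid$dims)
  con <- file(path, "wt")
  on.exit(close(con), add = TRUE)
  writeLines(c(title, "generated by comsia"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", 1L,
                     grid$origin[1] * bohr, grid$origin[2] * bohr, grid$origin[3] * bohr), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[1], grid$spacing * bohr, 0, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[2], 0, grid$spacing * bohr, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[3], 0, 0, grid$spacing * bohr), con)
  ## one dummy atom (cube requires >= 1 atom record)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", 1L, 0, 0, 0, 0), con)
  for (i in seq_len(grid$dims[1])) {
    for (j in seq_len(grid$dims[2])) {
      row <- arr[i, j, ]
      chunks <- split(row, ceiling(seq_along(row) / 6))
      writeLines(vapply(chunks, function(ch) paste(sprintf("%13.5e", ch), collapse = ""),
                        character(1)), con)
    }
  }
  invisible(path)
}
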