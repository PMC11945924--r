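#' Field-calculation configuration
#'
#' @param alpha Gaussian attenuation factor in 1/Angstrom^2, applied to the
#'   squared distance: each source contributes `w * exp(-alpha * r^2)`.
#'   Default 0.3, the standard CoMSIA choice for 1-Angstrom grids.
#' @param fields character vector, a subset of `c("S","E","H","A","D")`
#'   (steric, electrostatic, hydrophobic, h-bond acceptor, h-bond donor), or
#'   a compact string like `"SEH"` / `"SEHAD"`.
#' @param pseudo_distance distance in Angstrom from a donor/acceptor heavy
#'   atom to its hydrogen-bond pseudoatoms (default 1.9).
#' @param clash_factor a pseudoatom closer than
#'   `clash_factor * vdw_radius` to any atom other than its parent (and the
#'   parent's hydrogens) is rejected as sterically implausible (default 0.7).
#' @param snap logical; compute field distances from lattice-snapped atom
#'   coordinates (default `TRUE`) or from the raw coordinates.
#' @param donor_placement `"heavy"` places donor pseudoatoms
#'   `pseudo_distance` from the donor heavy atom along each X-H bond
#'   direction (default); `"beyond_h"` places them `pseudo_distance` beyond
#'   the hydrogen along the same ray.
#' @param include_nonpolar_h logical; include hydrogens bonded to carbon as
#'   steric/electrostatic/hydrophobic sources (default `TRUE`).
#' @return a list of class `comsia_field_config`.
#' @export
field_config <- function(alpha = 0.3, fields = c("S", "E", "H", "A", "D"),
                         pseudo_distance = 1.9, clash_factor = 0.7,
                         snap = TRUE,
                         donor_placement = c("heavy", "beyond_h"),
                         include_nonpolar_h = TRUE) {
  stopifnot_scalar(alpha, "alpha", positive = TRUE)
  stopifnot_scalar(pseudo_distance, "pseudo_distance", positive = TRUE)
  stopifnot_scalar(clash_factor, "clash_factor")
  fields <- parse_fields(fields)
  donor_placement <- match.arg(donor_placement)
  structure(
    list(
      alpha = alpha, fields = fields, pseudo_distance = pseudo_distance,
      clash_factor = clash_factor, snap = snap,
      donor_placement = donor_placement,
      include_nonpolar_h = isTRUE(include_nonpolar_h)
    ),
    class = "comsia_field_config"
  )
}

parse_fields <- function(fields) {
  if (length(fields) == 1L && nchar(fields) > 1L) {
    fields <- strsplit(fields, "")[[1]]
  }
  fields <- toupper(fields)
  bad <- setdiff(fields, FIELD_ORDER)
  if (length(bad)) abort(sprintf("unknown field code(s): %s", paste(bad, collapse = ", ")))
  if (!length(fields)) abort("at least one field must be enabled")
  FIELD_ORDER[FIELD_ORDER %in% fields]
}

#' Accumulate Gaussian sources over the lattice
#'
#' The similarity-index kernel: the value at lattice point `q` is
#' `sum_i w_i * exp(-alpha * ||q - c_i||^2)`. Additive in sources; at a
#' source's own position the source contributes exactly its weight.
#'
#' @param centers m x 3 matrix of source positions (Angstrom), or NULL/0-row
#'   for an empty source list (all-zero field).
#' @param weights numeric vector of m source weights.
#' @param grid a `comsia_grid`.
#' @param alpha attenuation factor, 1/Angstrom^2.
#' @param points optional pre-computed [grid_points()] matrix.
#' @return numeric vector of length `n_grid_points(grid)` in grid order.
#' @export
gaussian_accumulate <- function(centers, weights, grid, alpha, points = NULL) {
  stopifnot_scalar(alpha, "alpha", positive = TRUE)
  if (is.null(points)) points <- grid_points(grid)
  n <- nrow(points)
  if (is.null(centers) || NROW(centers) == 0L) return(numeric(n))
  centers <- matrix(centers, ncol = 3)
  if (length(weights) != nrow(centers)) abort("one weight per source is required")
  ## squared distances via the expansion |p|^2 + |c|^2 - 2 p.c
  p2 <- rowSums(points^2)
  c2 <- rowSums(centers^2)
  cross <- points %*% t(centers)
  d2 <- outer(p2, c2, "+") - 2 * cross
  d2[d2 < 0] <- 0  # numerical guard
  as.numeric(exp(-alpha * d2) %*% weights)
}

## ---------------------------------------------------------------------------
## Source builders. Each returns list(centers = m x 3 matrix, weights = m).

## atoms contributing to the atom-centred fields (S, E, H)
included_atoms <- function(mol, cfg) {
  keep <- rep(TRUE, nrow(mol$atoms))
  if (!cfg$include_nonpolar_h) {
    el <- mol$atoms$element
    nb <- neighbor_list(mol)
    nonpolar_h <- vapply(seq_along(el), function(i) {
      el[i] == "H" && length(nb[[i]]) > 0 && el[nb[[i]][1]] == "C"
    }, logical(1))
    keep <- !nonpolar_h
  }
  which(keep)
}

#' Steric sources: one Gaussian per atom, weight = vdW radius cubed
#' @param mol an annotated `comsia_mol`.
#' @param cfg a [field_config()].
#' @param xyz optional coordinate matrix override (already snapped).
#' @return list with `centers` (m x 3) and `weights` (length m).
#' @export
steric_sources <- function(mol, cfg = field_config(), xyz = NULL) {
  if (!is_annotated(mol)) abort(sprintf("molecule '%s' is not annotated", mol$name))
  if (anyNA(mol$atoms$vdw_radius)) abort(sprintf("missing vdW radius in '%s'", mol$name))
  idx <- included_atoms(mol, cfg)
  if (is.null(xyz)) xyz <- coords_matrix(mol)
  list(centers = xyz[idx, , drop = FALSE], weights = mol$atoms$vdw_radius[idx]^3)
}

#' Electrostatic sources: one Gaussian per atom, weight = Gasteiger charge
#' @inheritParams steric_sources
#' @export
electrostatic_sources <- function(mol, cfg = field_config(), xyz = NULL) {
  if (!is_annotated(mol)) abort(sprintf("molecule '%s' is not annotated", mol$name))
  idx <- included_atoms(mol, cfg)
  if (is.null(xyz)) xyz <- coords_matrix(mol)
  list(centers = xyz[idx, , drop = FALSE], weights = mol$atoms$charge[idx])
}

#' Hydrophobic sources: one Gaussian per atom, weight = atomic logP
#'   contribution
#' @inheritParams steric_sources
#' @export
hydrophobic_sources <- function(mol, cfg = field_config(), xyz = NULL) {
  if (!is_annotated(mol)) abort(sprintf("molecule '%s' is not annotated", mol$name))
  idx <- included_atoms(mol, cfg)
  if (is.null(xyz)) xyz <- coords_matrix(mol)
  list(centers = xyz[idx, , drop = FALSE], weights = mol$atoms$hydrophobicity[idx])
}

## clash filter: drop pseudoatoms too close to any atom that is not the
## parent heavy atom or one of the parent's bonded hydrogens
clash_filter <- function(pseudo, parents, mol, xyz, cfg) {
  if (!nrow(pseudo)) return(logical(0))
  nb <- neighbor_list(mol)
  el <- mol$atoms$element
  radii <- mol$atoms$vdw_radius
  keep <- rep(TRUE, nrow(pseudo))
  for (k in seq_len(nrow(pseudo))) {
    parent <- parents[k]
    exempt <- c(parent, nb[[parent]][el[nb[[parent]]] == "H"])
    others <- setdiff(seq_len(nrow(xyz)), exempt)
    if (!length(others)) next
    d <- sqrt(rowSums((xyz[others, , drop = FALSE] -
                         matrix(pseudo[k, ], length(others), 3, byrow = TRUE))^2))
    if (any(d < cfg$clash_factor * radii[others])) keep[k] <- FALSE
  }
  keep
}

#' Hydrogen-bond donor pseudoatoms
#'
#' For every donor heavy atom and each of its bonded hydrogens, one
#' unit-weight pseudoatom is placed on the heavy-atom-to-hydrogen ray at
#' `pseudo_distance` from the heavy atom (or `pseudo_distance` beyond the
#' hydrogen with `donor_placement = "beyond_h"`), modelling the position of
#' the donated hydrogen in a hydrogen bond. Pseudoatoms failing the clash
#' filter are removed; donors with no locatable hydrogen are skipped with a
#' warning.
#'
#' @inheritParams steric_sources
#' @return list with `centers`, `weights` (all 1) and `parents` (atom index
#'   of each pseudoatom's donor atom).
#' @export
donor_pseudoatoms <- function(mol, cfg = field_config(), xyz = NULL) {
  if (!is_annotated(mol)) abort(sprintf("molecule '%s' is not annotated", mol$name))
  if (is.null(xyz)) xyz <- coords_matrix(mol)
  nb <- neighbor_list(mol)
  el <- mol$atoms$element
  centers <- matrix(numeric(0), 0, 3)
  parents <- integer(0)
  for (i in which(mol$atoms$is_donor)) {
    hs <- nb[[i]][el[nb[[i]]] == "H"]
    if (!length(hs)) {
      warn(sprintf("donor atom %d (%s) of '%s' has no locatable hydrogen; skipped",
                   i, el[i], mol$name))
      next
    }
    for (h in hs) {
      dir <- xyz[h, ] - xyz[i, ]
      if (vnorm(dir) < 1e-6) next
      dir <- unit(dir)
      p <- if (cfg$donor_placement == "heavy") {
        xyz[i, ] + cfg$pseudo_distance * dir
      } else {
        xyz[h, ] + cfg$pseudo_distance * dir
      }
      centers <- rbind(centers, p)
      parents <- c(parents, i)
    }
  }
  keep <- clash_filter(centers, parents, mol, xyz, cfg)
  list(
    centers = centers[keep, , drop = FALSE],
    weights = rep(1, sum(keep)),
    parents = parents[keep]
  )
}

#' Hydrogen-bond acceptor pseudoatoms
#'
#' Unit-weight pseudoatoms are placed `pseudo_distance` from each acceptor
#' atom along idealized lone-pair directions derived from its hybridization:
#' trigonal in-plane directions for sp2 acceptors, tetrahedral directions
#' for sp3, and the single anti-bond direction otherwise (also the fallback
#' for geometry-degenerate neighborhoods, with a warning). Clash-filtered
#' like the donor layer.
#'
#' @inheritParams steric_sources
#' @return list with `centers`, `weights` (all 1) and `parents`.
#' @export
acceptor_pseudoatoms <- function(mol, cfg = field_config(), xyz = NULL) {
  if (!is_annotated(mol)) abort(sprintf("molecule '%s' is not annotated", mol$name))
  if (is.null(xyz)) xyz <- coords_matrix(mol)
  nb <- neighbor_list(mol)
  centers <- matrix(numeric(0), 0, 3)
  parents <- integer(0)
  for (i in which(mol$atoms$is_acceptor)) {
    dirs <- lone_pair_directions(mol, i, xyz, nb)
    for (r in seq_len(NROW(dirs))) {
      centers <- rbind(centers, xyz[i, ] + cfg$pseudo_distance * dirs[r, ])
      parents <- c(parents, i)
    }
  }
  keep <- clash_filter(centers, parents, mol, xyz, cfg)
  list(
    centers = centers[keep, , drop = FALSE],
    weights = rep(1, sum(keep)),
    parents = parents[keep]
  )
}

## idealized VSEPR lone-pair unit vectors for acceptor atom i
lone_pair_directions <- function(mol, i, xyz, nb) {
  hyb <- mol$atoms$hybridization[i]
  neigh <- nb[[i]]
  if (!length(neigh)) {
    warn(sprintf("acceptor atom %d of '%s' has no neighbors; skipped", i, mol$name))
    return(matrix(numeric(0), 0, 3))
  }
  bond_dirs <- t(vapply(neigh, function(j) unit(xyz[j, ] - xyz[i, ]), numeric(3)))
  anti <- -colSums(bond_dirs)
  if (vnorm(anti) < 1e-6) {
    ## colinear / symmetric neighborhood: no usable anti-bond direction
    warn(sprintf("degenerate acceptor geometry at atom %d of '%s'; using single normal direction",
                 i, mol$name))
    return(matrix(perp_vector(bond_dirs[1, ]), 1, 3))
  }
  anti <- unit(anti)
  if (hyb == "sp2" && length(neigh) == 1L) {
    ## carbonyl-type: two in-plane lone pairs completing trigonal geometry.
    ## Plane defined by the neighbor's own substituents when available.
    u <- anti  # points away from the single neighbor
    j <- neigh[1]
    jn <- setdiff(nb[[j]], i)
    v <- if (length(jn)) {
      normal <- pracma_cross(unit(xyz[jn[1], ] - xyz[j, ]), -u)
      if (vnorm(normal) < 1e-6) perp_vector(u) else unit(pracma_cross(unit(normal), u))
    } else {
      perp_vector(u)
    }
    rbind(
      u * cos(pi / 3) + v * sin(pi / 3),
      u * cos(pi / 3) - v * sin(pi / 3)
    )
  } else if (hyb == "sp2" && length(neigh) == 2L) {
    ## pyridine-type: one in-plane lone pair along the anti-bisector
    matrix(anti, 1, 3)
  } else if (hyb == "sp3" && length(neigh) == 2L) {
    ## ether/hydroxyl-type: two lone pairs completing the tetrahedron
    w <- pracma_cross(bond_dirs[1, ], bond_dirs[2, ])
    if (vnorm(w) < 1e-6) {
      warn(sprintf("colinear bonds at acceptor atom %d of '%s'; falling back to anti-bond direction",
                   i, mol$name))
      return(matrix(anti, 1, 3))
    }
    w <- unit(w)
    half <- (109.471 / 2) * pi / 180
    rbind(
      unit(anti * cos(half) + w * sin(half)),
      unit(anti * cos(half) - w * sin(half))
    )
  } else if (hyb == "sp3" && length(neigh) == 3L) {
    matrix(anti, 1, 3)  # amine-type single lone pair
  } else if (hyb == "sp3" && length(neigh) == 1L) {
    ## terminal single-bonded acceptor (e.g. alkoxide): three tetrahedral
    ## lone pairs around the bond axis
    u <- anti
    v <- perp_vector(u)
    ang <- (180 - 109.471) * pi / 180
    t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
      unit(rotate_about(u * cos(ang) + v * sin(ang), u, phi))
    }, numeric(3)))
  } else {
    matrix(anti, 1, 3)  # sp / other: single anti-bond direction
  }
}

#' Compute all enabled similarity-index fields for a molecule set
#'
#' Evaluates each enabled field of every molecule at every lattice point.
#' With `cfg$snap` (the default) atom positions are first snapped to the
#' lattice, so all molecules are represented on the common frame; pseudoatom
#' positions are derived from the (snapped) parent geometry and are not
#' themselves snapped.
#'
#' @param set an annotated, aligned `comsia_molset`.
#' @param grid a `comsia_grid` built over all sets jointly.
#' @param cfg a [field_config()].
#' @return an object of class `comsia_fields`: a 3-d array `values`
#'   (molecules x fields x grid points) plus `fields`, `grid`,
#'   `molecule_names`, `activities`, `role`.
#' @export
compute_all_fields <- function(set, grid, cfg = field_config()) {
  stopifnot(inherits(set, "comsia_molset"), inherits(grid, "comsia_grid"))
  pts <- grid_points(grid)
  nm <- names(set)
  n_mol <- length(set)
  values <- array(
    0,
    dim = c(n_mol, length(cfg$fields), nrow(pts)),
    dimnames = list(nm, cfg$fields, NULL)
  )
  for (m in seq_len(n_mol)) {
    mol <- set[[m]]
    if (!is_annotated(mol)) abort(sprintf("molecule '%s' is not annotated", mol$name))
    xyz <- coords_matrix(mol)
    if (isTRUE(cfg$snap)) xyz <- snap_coordinates(xyz, grid$spacing)
    for (f in cfg$fields) {
      src <- switch(f,
        S = steric_sources(mol, cfg, xyz),
        E = electrostatic_sources(mol, cfg, xyz),
        H = hydrophobic_sources(mol, cfg, xyz),
        D = donor_pseudoatoms(mol, cfg, xyz),
        A = acceptor_pseudoatoms(mol, cfg, xyz)
      )
      values[m, f, ] <- gaussian_accumulate(src$centers, src$weights, grid, cfg$alpha, points = pts)
    }
  }
  if (!all(is.finite(values))) abort("field tensor contains non-finite values")
  structure(
    list(
      values = values, fields = cfg$fields, grid = grid,
      molecule_names = nm, activities = activities(set), role = set$role
    ),
    class = "comsia_fields"
  )
}

#' @export
print.comsia_fields <- function(x, ...) {
  cat(sprintf(
    "<comsia_fields> %d molecules x %d fields (%s) x %d grid points\n",
    dim(x$values)[1], dim(x$values)[2], paste(x$fields, collapse = ""), dim(x$values)[3]
  ))
  invisible(x)
}

#' Export one molecule/field layer as a Gaussian cube volume
#'
#' @param fields a `comsia_fields`.
#' @param molecule molecule name or index.
#' @param field field code.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field_cube <- function(fields, molecule, field, path) {
  m <- if (is.character(molecule)) match(molecule, fields$molecule_names) else molecule
  if (is.na(m)) abort(sprintf("unknown molecule '%s'", molecule))
  if (!field %in% fields$fields) abort(sprintf("field '%s' was not computed", field))
  v <- fields$values[m, field, ]
  write_cube_volume(v, fields$grid, path,
                    title = sprintf("%s field, molecule %s", FIELD_LABELS[[field]],
                                    fields$molecule_names[m]))
}
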