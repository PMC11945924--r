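#' Molecule and molecule-set containers
#'
#' A `comsia_mol` bundles an atom table, a bond table, a name, and an
#' optional activity (e.g. pKi). Atoms are stored as a tibble with one row
#' per atom: `element`, Cartesian `x`, `y`, `z` in Angstrom, and
#' `formal_charge`. [annotate_atoms()] adds the physicochemical columns the
#' field calculations need (`vdw_radius`, `charge`, `hydrophobicity`,
#' `is_donor`, `is_acceptor`, `hybridization`, `n_h`).
#'
#' @param name single string, unique within a set.
#' @param atoms tibble/data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `formal_charge` (default 0).
#' @param bonds tibble/data frame with columns `from`, `to` (1-based atom
#'   indices) and `order` (1, 2, 3; 4 denotes an aromatic bond as in MDL
#'   conventions). May have zero rows for a single atom.
#' @param activity numeric activity in log units (e.g. pKi) or `NA` when
#'   unknown (prediction molecules).
#' @param smiles optional SMILES string retained for molecules that still
#'   need 3D embedding.
#' @return an object of class `comsia_mol`.
#' @export
molecule <- function(name, atoms, bonds = NULL, activity = NA_real_, smiles = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string")
  }
  atoms <- tibble::as_tibble(atoms)
  required <- c("element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    abort(sprintf("atom table lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) < 1L) abort("a molecule needs at least one atom")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) abort(sprintf("molecule '%s' has non-finite coordinates", name))
  if (is.null(atoms[["formal_charge"]])) atoms$formal_charge <- 0L
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- tibble::tibble(from = integer(), to = integer(), order = integer())
  } else {
    bonds <- tibble::as_tibble(bonds)[, c("from", "to", "order")]
    if (any(bonds$from < 1 | bonds$to < 1 | bonds$from > nrow(atoms) | bonds$to > nrow(atoms))) {
      abort(sprintf("molecule '%s' has bond indices outside the atom table", name))
    }
  }
  if (!is.na(activity) && !is_scalar_number(activity)) {
    abort(sprintf("activity of molecule '%s' must be a single finite number", name))
  }
  structure(
    list(
      name = name, atoms = atoms, bonds = bonds,
      activity = as.numeric(activity), smiles = smiles
    ),
    class = "comsia_mol"
  )
}

#' @export
print.comsia_mol <- function(x, ...) {
  act <- if (is.na(x$activity)) "activity: <absent>" else sprintf("activity: %.4g", x$activity)
  annot <- if (is_annotated(x)) ", annotated" else ""
  cat(sprintf(
    "<comsia_mol> %s: %d atoms, %d bonds, %s%s\n",
    x$name, nrow(x$atoms), nrow(x$bonds), act, annot
  ))
  invisible(x)
}

is_annotated <- function(mol) all(c("vdw_radius", "charge", "hydrophobicity") %in% names(mol$atoms))

## coordinates as an n x 3 matrix
coords_matrix <- function(mol) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

set_coords <- function(mol, xyz) {
  mol$atoms$x <- xyz[, 1]
  mol$atoms$y <- xyz[, 2]
  mol$atoms$z <- xyz[, 3]
  mol
}

## 1-based neighbor list from the bond table
neighbor_list <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- vector("list", n)
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    nb[[b$from[i]]] <- c(nb[[b$from[i]]], b$to[i])
    nb[[b$to[i]]] <- c(nb[[b$to[i]]], b$from[i])
  }
  nb
}

#' Build an ordered set of molecules
#'
#' @param molecules list of [molecule()] objects.
#' @param role one of `"train"`, `"test"`, `"predict"`; training molecules
#'   must all carry activities.
#' @return an object of class `comsia_molset` (list-like; supports
#'   `length()`, `[`, `[[` and `names()`).
#' @export
molecule_set <- function(molecules, role = c("train", "test", "predict")) {
  role <- match.arg(role)
  if (!length(molecules)) abort("no records: a molecule set cannot be empty")
  ok <- vapply(molecules, inherits, logical(1), what = "comsia_mol")
  if (!all(ok)) abort("all elements must be comsia_mol objects")
  nm <- vapply(molecules, function(m) m$name, character(1))
  if (anyDuplicated(nm)) {
    abort(sprintf("molecule names must be unique within a set (duplicated: %s)",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  if (role == "train") {
    has_act <- !vapply(molecules, function(m) is.na(m$activity), logical(1))
    if (!all(has_act)) {
      abort(sprintf("training molecules lack activities: %s",
                    paste(nm[!has_act], collapse = ", ")))
    }
  }
  structure(
    list(molecules = setNames(molecules, nm), role = role),
    class = "comsia_molset"
  )
}

#' @export
length.comsia_molset <- function(x) length(x$molecules)

#' @export
names.comsia_molset <- function(x) names(x$molecules)

#' @export
`[.comsia_molset` <- function(x, i) molecule_set(unname(x$molecules[i]), role = x$role)

#' @export
`[[.comsia_molset` <- function(x, i) x$molecules[[i]]

#' @export
print.comsia_molset <- function(x, ...) {
  acts <- activities(x)
  cat(sprintf(
    "<comsia_molset> %d molecules (role: %s), %d with activity\n",
    length(x), x$role, sum(!is.na(acts))
  ))
  invisible(x)
}

#' Activities of a molecule set
#'
#' @param set a `comsia_molset`.
#' @return named numeric vector (NA where absent).
#' @export
activities <- function(set) {
  vapply(set$molecules, function(m) m$activity, numeric(1))
}

#' Mean and sample standard deviation of a set's activities
#'
#' The standard deviation uses the sample (n - 1) form, the convention of
#' published QSAR activity summaries.
#'
#' @param set a `comsia_molset`, or a bare numeric vector of activities.
#' @return a one-row tibble with `n`, `mean`, `sd` (`sd` is `NA` for n < 2).
#' @export
summarize_activities <- function(set) {
  y <- if (inherits(set, "comsia_molset")) activities(set) else as.numeric(set)
  y <- y[!is.na(y)]
  if (!length(y)) abort("no activities present")
  tibble::tibble(
    n = length(y),
    mean = mean(y),
    sd = if (length(y) >= 2) sd(y) else NA_real_
  )
}

#' Activities of the classic steroid CBG benchmark
#'
#' The corticosteroid-binding-globulin steroid benchmark (Coats' compilation)
#' is the canonical CoMSIA validation set: 21 training and 10 test steroids
#' with pKi activities. The package ships the activity table; the pre-aligned
#' 3D structures are distributed by the original benchmarking studies and are
#' not redistributed here (see the vignette on reproducing published
#' benchmarks).
#'
#' @return tibble with columns `name`, `pKi`, `set` ("train"/"test").
#' @export
steroid_activities <- function() {
  path <- system.file("extdata", "steroid_pki.csv", package = "comsia", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
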