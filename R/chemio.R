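#' Read molecules with activities from an MDL SDF (V2000) file
#'
#' One molecule per SDF record, in file order. When `activity_tag` names an
#' SDF data field its value is parsed as the molecule's activity; records
#' lacking the tag are flagged activity-absent (allowed for prediction sets,
#' an error for training sets at [molecule_set()] construction).
#'
#' @param path SDF file path.
#' @param activity_tag name of the SDF data field holding the activity
#'   (default `"activity"`).
#' @param role set role passed to [molecule_set()].
#' @return a `comsia_molset`.
#' @export
read_sdf <- function(path, activity_tag = "activity", role = c("predict", "train", "test")) {
  role <- match.arg(role)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (!length(grep("\\S", readLines(path, warn = FALSE)))) {
    abort(sprintf("no records in SDF file: %s", path))
  }
  sdfset <- tryCatch(
    ChemmineR::read.SDFset(path),
    error = function(e) abort(sprintf("failed to parse SDF '%s': %s", path, conditionMessage(e)))
  )
  n <- length(sdfset)
  if (n == 0) abort(sprintf("no records in SDF file: %s", path))
  mols <- vector("list", n)
  for (i in seq_len(n)) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    if (is.null(dim(ab)) || nrow(ab) < 1) {
      abort(sprintf("unparsable record %d in '%s': empty atom block", i, path))
    }
    element <- sub("_\\d+$", "", rownames(ab))
    ## old-style per-atom charge codes live in the 5th numeric column
    chg_code <- if (ncol(ab) >= 5) ab[, 5] else rep(0, nrow(ab))
    fc <- decode_charge_code(chg_code)
    atoms <- tibble::tibble(
      element = element,
      x = unname(ab[, 1]), y = unname(ab[, 2]), z = unname(ab[, 3]),
      formal_charge = fc
    )
    bb <- ChemmineR::bondblock(sdf)
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
      NULL
    } else {
      tibble::tibble(
        from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
        order = as.integer(bb[, 3])
      )
    }
    hdr <- ChemmineR::header(sdf)
    nm <- trimws(hdr[["Molecule_Name"]] %||% "")
    if (!nzchar(nm)) nm <- sprintf("mol_%03d", i)
    db <- ChemmineR::datablock(sdf)
    act <- NA_real_
    if (length(db) && activity_tag %in% names(db)) {
      act_raw <- db[[activity_tag]]
      act <- suppressWarnings(as.numeric(act_raw))
      if (is.na(act)) {
        abort(sprintf(
          "activity tag '%s' of molecule '%s' (record %d) is non-numeric: '%s'",
          activity_tag, nm, i, act_raw
        ))
      }
    }
    mols[[i]] <- molecule(nm, atoms, bonds, activity = act)
  }
  ## duplicate names in a file: disambiguate deterministically, keep order
  nms <- vapply(mols, function(m) m$name, character(1))
  if (anyDuplicated(nms)) {
    nms <- make.unique(nms, sep = "_")
    for (i in seq_along(mols)) mols[[i]]$name <- nms[i]
  }
  molecule_set(mols, role = role)
}

decode_charge_code <- function(code) {
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)
  out <- map[as.character(as.integer(code))]
  out[is.na(out)] <- 0L
  unname(out)
}

encode_charge_code <- function(fc) {
  map <- c(`3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L, `-1` = 5L, `-2` = 6L, `-3` = 7L)
  out <- map[as.character(as.integer(fc))]
  out[is.na(out)] <- 0L
  unname(out)
}

#' Write a molecule set as a strict MDL V2000 SDF file
#'
#' Coordinates are written as fixed-width 10.4f fields so that column-fixed
#' V2000 readers parse the file; activities are emitted under `activity_tag`
#' and omitted for activity-absent molecules. `read_sdf(write_sdf(x))`
#' reproduces names, coordinates (to 1e-4 Angstrom) and activities.
#'
#' @param set a `comsia_molset`.
#' @param path output file path.
#' @param activity_tag SDF data field name for activities.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(set, path, activity_tag = "activity") {
  stopifnot(inherits(set, "comsia_molset"))
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (mol in set$molecules) {
    a <- mol$atoms
    b <- mol$bonds
    lines <- c(
      mol$name,
      "  comsia",
      "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)),
      sprintf(
        "%10.4f%10.4f%10.4f %-3s%2d%3d%3d%3d%3d%3d%3d%3d%3d%3d%3d%3d",
        a$x, a$y, a$z, a$element, 0L, encode_charge_code(a$formal_charge),
        0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L
      )
    )
    if (nrow(b)) {
      lines <- c(lines, sprintf("%3d%3d%3d%3d%3d%3d%3d", b$from, b$to, b$order, 0L, 0L, 0L, 0L))
    }
    lines <- c(lines, "M  END")
    if (!is.na(mol$activity)) {
      lines <- c(lines, sprintf(">  <%s>", activity_tag), format(mol$activity, digits = 15), "")
    }
    lines <- c(lines, "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read molecules from a CSV table of SMILES strings
#'
#' Expects columns `name`, `smiles`, `activity` (header required; extra
#' columns ignored). The molecules carry topology only and must be embedded
#' and aligned (see [align_set()]) before field calculation.
#'
#' @param path CSV file path.
#' @param role set role.
#' @return a `comsia_molset` whose molecules are flagged as needing
#'   embedding.
#' @export
read_smiles_table <- function(path, role = c("train", "test", "predict")) {
  role <- match.arg(role)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "smiles")
  if (!all(need %in% names(tab))) {
    abort("SMILES table must have columns 'name', 'smiles' (and optionally 'activity')")
  }
  if (!nrow(tab)) abort(sprintf("no records in SMILES table: %s", path))
  if (is.null(tab$activity)) tab$activity <- NA_real_
  mols <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    mols[[i]] <- tryCatch(
      smiles_to_molecule(tab$smiles[i], tab$name[i], tab$activity[i]),
      error = function(e) {
        abort(sprintf("row %d ('%s'): %s", i, tab$name[i], conditionMessage(e)))
      }
    )
    mols[[i]]$needs_embedding <- TRUE
  }
  molecule_set(mols, role = role)
}

## TRUE if the molecule still lacks genuine 3D coordinates
needs_embedding <- function(mol) {
  isTRUE(mol$needs_embedding) || all(abs(coords_matrix(mol)) < 1e-9)
}

## ---------------------------------------------------------------------------

#' Annotate every atom with the properties the fields need
#'
#' Adds van der Waals radius (fixed Bondi-style table), Gasteiger partial
#' charge (OpenBabel), an atomic hydrophobicity contribution (fixed
#' Wildman-Crippen-type class table), hydrogen-bond donor/acceptor flags
#' (documented graph rules, overridable), hybridization, and the attached
#' hydrogen count. Molecules are expected to carry explicit hydrogens; with
#' `add_h = "auto"` hydrogens are added via OpenBabel when a molecule has
#' none at all.
#'
#' @param mol a `comsia_mol` with 3D coordinates.
#' @param donor_rule,acceptor_rule functions `(mol, ctx) -> logical` per
#'   atom, replacing the default classification. `ctx` carries
#'   `hybridization`, `degree`, `n_h`, `n_double`, `n_arom`, `amide_n`,
#'   `carbonyl_c`.
#' @param add_h one of `"auto"`, `"never"`, `"always"`.
#' @param charges optional pre-computed numeric charge vector (used
#'   internally to batch OpenBabel calls over a set).
#' @return the molecule with annotation columns filled in.
#' @export
annotate_atoms <- function(mol, donor_rule = default_donor_rule,
                           acceptor_rule = default_acceptor_rule,
                           add_h = c("auto", "never", "always"),
                           charges = NULL) {
  add_h <- match.arg(add_h)
  has_h <- any(mol$atoms$element == "H")
  if (add_h == "always" || (add_h == "auto" && !has_h && nrow(mol$atoms) > 1)) {
    mol <- obabel_add_hydrogens(mol)
  }
  ctx <- atom_context(mol)
  nb <- attr(ctx, "neighbors")
  if (is.null(charges)) {
    charges <- gasteiger_charges(molecule_set(list(mol), role = "predict"))[[1]]
  }
  cls <- hydrophobic_class(mol, ctx, nb)
  mol$atoms$vdw_radius <- vdw_radius(mol$atoms$element)
  mol$atoms$charge <- charges
  mol$atoms$hydrophobicity <- unname(HYDROPHOBIC_CONTRIB[cls])
  mol$atoms$hydrophobic_class <- cls
  mol$atoms$hybridization <- ctx$hybridization
  mol$atoms$n_h <- ctx$n_h
  mol$atoms$is_donor <- donor_rule(mol, ctx) & mol$atoms$element != "H"
  mol$atoms$is_acceptor <- acceptor_rule(mol, ctx) & mol$atoms$element != "H"
  mol
}

## bonded-environment context shared by the classifiers
atom_context <- function(mol) {
  ctx <- assign_hybridization(mol)
  nb <- neighbor_list(mol)
  el <- mol$atoms$element
  n <- nrow(mol$atoms)
  ctx$n_h <- vapply(seq_len(n), function(i) sum(el[nb[[i]]] == "H"), integer(1))
  carbonyl_c <- rep(FALSE, n)
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    if (b$order[i] == 2) {
      f <- b$from[i]; t <- b$to[i]
      if (el[f] == "C" && el[t] %in% c("O", "S")) carbonyl_c[f] <- TRUE
      if (el[t] == "C" && el[f] %in% c("O", "S")) carbonyl_c[t] <- TRUE
    }
  }
  ctx$carbonyl_c <- carbonyl_c
  ctx$amide_n <- vapply(seq_len(n), function(i) {
    el[i] == "N" && length(nb[[i]]) > 0 && any(carbonyl_c[nb[[i]]])
  }, logical(1))
  attr(ctx, "neighbors") <- nb
  ctx
}

#' Annotate all molecules of a set
#'
#' Batches the Gasteiger charge computation into a single OpenBabel call.
#'
#' @inheritParams annotate_atoms
#' @param set a `comsia_molset`.
#' @return the annotated set.
#' @export
annotate_molecules <- function(set, donor_rule = default_donor_rule,
                               acceptor_rule = default_acceptor_rule,
                               add_h = c("auto", "never", "always")) {
  add_h <- match.arg(add_h)
  for (i in seq_along(set$molecules)) {
    mol <- set$molecules[[i]]
    has_h <- any(mol$atoms$element == "H")
    if (add_h == "always" || (add_h == "auto" && !has_h && nrow(mol$atoms) > 1)) {
      set$molecules[[i]] <- obabel_add_hydrogens(mol)
    }
  }
  charges <- gasteiger_charges(set)
  for (i in seq_along(set$molecules)) {
    set$molecules[[i]] <- annotate_atoms(
      set$molecules[[i]],
      donor_rule = donor_rule, acceptor_rule = acceptor_rule,
      add_h = "never", charges = charges[[i]]
    )
  }
  set
}

## positions of hydrogens attached to atom i, as a matrix (possibly 0-row)
attached_h_positions <- function(mol, i, nb = NULL) {
  if (is.null(nb)) nb <- neighbor_list(mol)
  hs <- nb[[i]][mol$atoms$element[nb[[i]]] == "H"]
  xyz <- coords_matrix(mol)
  xyz[hs, , drop = FALSE]
}
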