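## Thin wrappers around the OpenBabel command-line tool. OpenBabel supplies
## the standard cheminformatics steps the package does not own: Gasteiger
## partial-charge assignment, SMILES parsing, hydrogen addition, and 3D
## structure generation. Everything passes through strict-V2000 SDF files so
## atom order is preserved across calls.

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    abort(paste(
      "the 'obabel' executable was not found on PATH;",
      "OpenBabel is required for charge assignment and SMILES/3D input"
    ))
  }
  p
}

run_obabel <- function(args) {
  out <- suppressWarnings(system2(obabel_path(), args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  list(output = out, status = status)
}

## SMILES string -> topology-only molecule (no coordinates yet)
smiles_to_molecule <- function(smiles, name, activity = NA_real_) {
  tmp <- comsia_tempfile(".sdf")
  on.exit(unlink(tmp), add = TRUE)
  res <- run_obabel(c(shQuote(paste0("-:", smiles)), "-osdf", "-O", shQuote(tmp), "-h"))
  ok <- file.exists(tmp) && length(readLines(tmp, warn = FALSE)) > 4
  if (res$status != 0 || !ok) {
    abort(sprintf("invalid SMILES for molecule '%s': %s", name, smiles))
  }
  set <- read_sdf(tmp)
  mol <- set[[1]]
  mol$name <- name
  mol$activity <- as.numeric(activity)
  mol$smiles <- smiles
  mol
}

## SMILES -> 3D coordinates via the OpenBabel structure builder. The "fast"
## level (rule-based placement + force-field minimization, no stochastic
## rotor search) is used because it is deterministic run-to-run, which the
## alignment determinism contract relies on; the slower levels randomize
## their rotor search.
embed_smiles <- function(smiles, name) {
  tmp <- comsia_tempfile(".sdf")
  on.exit(unlink(tmp), add = TRUE)
  res <- run_obabel(c(shQuote(paste0("-:", smiles)), "-osdf", "--gen3d", "fast", "-O", shQuote(tmp)))
  ok <- file.exists(tmp) && length(readLines(tmp, warn = FALSE)) > 4
  if (res$status != 0 || !ok) {
    abort(sprintf("3D embedding failed for molecule '%s'", name))
  }
  set <- read_sdf(tmp)
  mol <- set[[1]]
  mol$name <- name
  mol$smiles <- smiles
  mol
}

## add explicit hydrogens (with coordinates) to a 3D molecule
obabel_add_hydrogens <- function(mol) {
  fin <- comsia_tempfile(".sdf")
  fout <- comsia_tempfile(".sdf")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_sdf(molecule_set(list(mol), role = "predict"), fin)
  res <- run_obabel(c(shQuote(fin), "-osdf", "-h", "-O", shQuote(fout)))
  if (res$status != 0 || !file.exists(fout)) {
    abort(sprintf("hydrogen addition failed for molecule '%s'", mol$name))
  }
  out <- read_sdf(fout)[[1]]
  out$activity <- mol$activity
  out$smiles <- mol$smiles
  out
}

## Gasteiger-Marsili partial charges for every molecule of a set, computed
## in one obabel call (SDF -> MOL2 with --partialcharge gasteiger) and
## returned as a list of numeric vectors in atom order.
gasteiger_charges <- function(set) {
  fin <- comsia_tempfile(".sdf")
  fout <- comsia_tempfile(".mol2")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_sdf(set, fin)
  res <- run_obabel(c(
    shQuote(fin), "-omol2", "--partialcharge", "gasteiger", "-O", shQuote(fout)
  ))
  if (res$status != 0 || !file.exists(fout)) {
    abort("Gasteiger charge computation failed (obabel error)")
  }
  charges <- parse_mol2_charges(readLines(fout, warn = FALSE))
  if (length(charges) != length(set)) {
    abort(sprintf(
      "Gasteiger charge computation returned %d molecules for %d inputs",
      length(charges), length(set)
    ))
  }
  for (i in seq_along(charges)) {
    if (length(charges[[i]]) != nrow(set[[i]]$atoms)) {
      abort(sprintf("charge/atom count mismatch for molecule '%s'", set[[i]]$name))
    }
    if (!all(is.finite(charges[[i]]))) {
      abort(sprintf("non-finite Gasteiger charge for molecule '%s'", set[[i]]$name))
    }
  }
  charges
}

parse_mol2_charges <- function(lines) {
  mol_starts <- grep("^@<TRIPOS>MOLECULE", lines)
  lapply(seq_along(mol_starts), function(i) {
    lo <- mol_starts[i]
    hi <- if (i < length(mol_starts)) mol_starts[i + 1] - 1L else length(lines)
    block <- lines[lo:hi]
    astart <- grep("^@<TRIPOS>ATOM", block)[1]
    if (is.na(astart)) abort("malformed MOL2 output: no ATOM block")
    rest <- block[(astart + 1L):length(block)]
    next_sec <- grep("^@<TRIPOS>", rest)
    aend <- if (length(next_sec)) next_sec[1] - 1L else length(rest)
    atom_lines <- rest[seq_len(aend)]
    atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
    vapply(strsplit(trimws(atom_lines), "\\s+"), function(f) {
      as.numeric(f[[length(f)]])
    }, numeric(1))
  })
}
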