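coords_matrix_test <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

test_that("SDF round-trip preserves names, activities and coordinates", {
  set <- molecule_set(
    list(
      water_molecule("w1", activity = 5.0),
      methane_molecule("m1", activity = 6.25),
      formaldehyde_molecule("f1")  # activity-absent
    ),
    role = "predict"
  )
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(set, path, activity_tag = "pKi")
  back <- read_sdf(path, activity_tag = "pKi")
  expect_equal(names(back), c("w1", "m1", "f1"))
  expect_equal(activities(back), c(w1 = 5.0, m1 = 6.25, f1 = NA_real_))
  for (i in seq_along(set$molecules)) {
    expect_equal(coords_matrix_test(back[[i]]), coords_matrix_test(set[[i]]),
                 tolerance = 1e-4)
    expect_equal(back[[i]]$atoms$element, set[[i]]$atoms$element)
    expect_equal(nrow(back[[i]]$bonds), nrow(set[[i]]$bonds))
  }
  ## the activity-absent record carries no data tag
  txt <- paste(readLines(path), collapse = "\n")
  expect_equal(lengths(regmatches(txt, gregexpr("<pKi>", txt))), 2L)
})

test_that("read_sdf parses a single-record file and flags bad input", {
  one <- molecule_set(list(methane_molecule("methane", activity = 5.0)), role = "train")
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(one, path, activity_tag = "pKi")
  got <- read_sdf(path, activity_tag = "pKi", role = "train")
  expect_length(got, 1L)
  expect_equal(nrow(got[[1]]$atoms), 5L)  # explicit hydrogens kept
  expect_equal(got[[1]]$activity, 5.0)

  empty <- withr::local_tempfile(fileext = ".sdf")
  writeLines("", empty)
  expect_error(read_sdf(empty), "no records")

  ## non-numeric activity names the molecule
  bad <- withr::local_tempfile(fileext = ".sdf")
  lines <- readLines(path)
  lines[grep("^5", lines)[1]] <- "not-a-number"
  writeLines(lines, bad)
  expect_error(read_sdf(bad, activity_tag = "pKi"), "methane")
})

test_that("SMILES tables parse in row order and report bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "name,smiles,activity",
    "mol1,CCO,5.0",
    "mol2,c1ccccc1,6.1",
    "mol3,CC(=O)O,4.2"
  ), path)
  set <- read_smiles_table(path, role = "train")
  expect_equal(names(set), c("mol1", "mol2", "mol3"))
  expect_equal(sum(set[[1]]$atoms$element != "H"), 3L)  # C, C, O
  expect_equal(activities(set)[["mol1"]], 5.0)
  expect_true(all(vapply(set$molecules, comsia:::needs_embedding, logical(1))))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,smiles,activity", "mol1,XX$!,5.0"), bad)
  expect_error(read_smiles_table(bad), "row 1")
})

test_that("annotation assigns radii, charges, hydrophobicity and H-bond roles", {
  w <- annotated_water()
  expect_true(w$atoms$is_donor[1])
  expect_true(w$atoms$is_acceptor[1])
  expect_equal(w$atoms$vdw_radius[1], 1.52)

  m <- annotated_methane()
  expect_false(any(m$atoms$is_donor))
  expect_false(any(m$atoms$is_acceptor))
  expect_gt(m$atoms$hydrophobicity[1], 0)  # alkane carbon is hydrophobic

  f <- annotated_formaldehyde()
  expect_equal(f$atoms$hybridization[2], "sp2")
  expect_true(f$atoms$is_acceptor[2])
  expect_false(f$atoms$is_donor[2])
})

test_that("Gasteiger charges of neutral molecules sum to ~0 and are finite", {
  for (mol in list(annotated_water(), annotated_methane(),
                   annotated_formaldehyde(), annotated_dme())) {
    expect_true(all(is.finite(mol$atoms$charge)))
    expect_lt(abs(sum(mol$atoms$charge)), 1e-3)
  }
  ## carbonyl polarization: O negative, C positive
  f <- annotated_formaldehyde()
  expect_lt(f$atoms$charge[2], 0)
  expect_gt(f$atoms$charge[1], 0)
})

test_that("per-atom hydrophobicity sums to the scheme's molecular logP", {
  for (mol in list(annotated_methane(), annotated_butane(), annotated_dme())) {
    expect_equal(sum(mol$atoms$hydrophobicity), molecule_logp(mol), tolerance = 1e-6)
  }
  b <- annotated_butane()
  expect_true(all(b$atoms$hydrophobicity[b$atoms$element == "C"] > 0))
})

test_that("unknown elements are rejected", {
  expect_error(vdw_radius(c("C", "Xx")), "unknown element")
})
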