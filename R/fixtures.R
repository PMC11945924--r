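#' Specification for a synthetic aligned fixture set
#'
#' The generator enumerates substituted-scaffold molecules with exact,
#' code-built geometry on a shared frame (so the set is aligned by
#' construction), computes their fields, and assigns activities as a linear
#' function of a few columns of one chosen field plus Gaussian noise. It
#' emulates the structure of a congeneric QSAR series: one rigid core, a
#' small substituent alphabet, activities driven by a localized field
#' difference.
#'
#' @param n_train,n_test number of training / test molecules (train >= 5;
#'   `n_test = 0` for a training-only set).
#' @param substituents subset of `c("H","CH3","OH","NH2","F","Cl","OCH3")`
#'   decorating the variable scaffold positions.
#' @param variable_positions which of the six ring positions vary across the
#'   series (default positions 1 and 4, a para-disubstituted congeneric
#'   series); the remaining positions stay hydrogen. Keeping the variable
#'   sites few keeps the series' latent dimensionality well below the
#'   training size, as in a realistic congeneric QSAR set.
#' @param noise_sd standard deviation of the Gaussian activity noise, in
#'   activity (log) units.
#' @param true_field the field whose spatial values generate the activities.
#' @param n_true_columns how many high-variance columns of the true field
#'   carry signal.
#' @param seed integer seed; the same spec and seed reproduce the fixture
#'   bit for bit.
#' @param spacing,padding,alpha grid/field parameters used when generating
#'   the activity signal.
#' @param fields fields computed for the truth assignment.
#' @return a list of class `comsia_fixture_spec`.
#' @export
fixture_spec <- function(n_train = 21, n_test = 10,
                         substituents = c("H", "CH3", "OH", "NH2", "F", "Cl"),
                         variable_positions = c(1L, 4L),
                         noise_sd = 0.1, true_field = "E",
                         n_true_columns = 3, seed = 1L,
                         spacing = 1, padding = 4, alpha = 0.3,
                         fields = c("S", "E", "H", "A", "D")) {
  if (n_train < 5) abort("`n_train` must be >= 5")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  variable_positions <- as.integer(variable_positions)
  if (!length(variable_positions) || any(variable_positions < 1 | variable_positions > 6)) {
    abort("`variable_positions` must be ring positions in 1..6")
  }
  true_field <- parse_fields(true_field)
  fields <- parse_fields(fields)
  if (!true_field %in% fields) abort("`true_field` must be among the computed fields")
  bad <- setdiff(substituents, names(SUBSTITUENT_BUILDERS))
  if (length(bad)) abort(sprintf("unknown substituent(s): %s", paste(bad, collapse = ", ")))
  structure(
    list(
      n_train = n_train, n_test = n_test, substituents = substituents,
      variable_positions = variable_positions,
      noise_sd = noise_sd, true_field = true_field,
      n_true_columns = n_true_columns, seed = as.integer(seed),
      spacing = spacing, padding = padding, alpha = alpha, fields = fields
    ),
    class = "comsia_fixture_spec"
  )
}

## ---------------------------------------------------------------------------
## scaffold and substituent geometry. The scaffold is a benzene ring (Kekule
## bond orders) in the z = 0 plane; each ring position carries one
## substituent built in an exact local frame (u radial, w out-of-plane).

RING_CC <- 1.397
CC_SINGLE <- 1.50
CH_BOND <- 1.09
CO_BOND <- 1.36
CN_BOND <- 1.40
OH_BOND <- 0.96
NH_BOND <- 1.01
CF_BOND <- 1.35
CCL_BOND <- 1.77

## each builder returns list(atoms = tibble(element, x, y, z), bonds =
## tibble(from, to, order) internal to the group); atom 1 attaches to the ring
SUBSTITUENT_BUILDERS <- list(
  H = function(c_pos, u, w) {
    list(
      atoms = tibble::tibble(element = "H",
                             x = c_pos[1] + CH_BOND * u[1],
                             y = c_pos[2] + CH_BOND * u[2],
                             z = c_pos[3] + CH_BOND * u[3]),
      bonds = tibble::tibble(from = integer(), to = integer(), order = integer())
    )
  },
  F = function(c_pos, u, w) {
    p <- c_pos + CF_BOND * u
    list(atoms = tibble::tibble(element = "F", x = p[1], y = p[2], z = p[3]),
         bonds = tibble::tibble(from = integer(), to = integer(), order = integer()))
  },
  Cl = function(c_pos, u, w) {
    p <- c_pos + CCL_BOND * u
    list(atoms = tibble::tibble(element = "Cl", x = p[1], y = p[2], z = p[3]),
         bonds = tibble::tibble(from = integer(), to = integer(), order = integer()))
  },
  CH3 = function(c_pos, u, w) {
    cc <- c_pos + CC_SINGLE * u
    hs <- methyl_hydrogens(cc, u, w)
    list(
      atoms = tibble::tibble(
        element = c("C", "H", "H", "H"),
        x = c(cc[1], hs[, 1]), y = c(cc[2], hs[, 2]), z = c(cc[3], hs[, 3])
      ),
      bonds = tibble::tibble(from = c(1L, 1L, 1L), to = c(2L, 3L, 4L), order = 1L)
    )
  },
  OH = function(c_pos, u, w) {
    o <- c_pos + CO_BOND * u
    ## C-O-H angle ~109.5 deg, H tilted out of plane for 3D character
    hdir <- unit(rotate_about(u, unit(w + 0.3 * pracma_cross(u, w)), (180 - 109.5) * pi / 180))
    h <- o + OH_BOND * hdir
    list(
      atoms = tibble::tibble(element = c("O", "H"),
                             x = c(o[1], h[1]), y = c(o[2], h[2]), z = c(o[3], h[3])),
      bonds = tibble::tibble(from = 1L, to = 2L, order = 1L)
    )
  },
  NH2 = function(c_pos, u, w) {
    nn <- c_pos + CN_BOND * u
    ang <- (180 - 112) * pi / 180
    h1 <- nn + NH_BOND * unit(rotate_about(u, w, ang))
    h2 <- nn + NH_BOND * unit(rotate_about(u, -w, ang))
    list(
      atoms = tibble::tibble(element = c("N", "H", "H"),
                             x = c(nn[1], h1[1], h2[1]),
                             y = c(nn[2], h1[2], h2[2]),
                             z = c(nn[3], h1[3], h2[3])),
      bonds = tibble::tibble(from = c(1L, 1L), to = c(2L, 3L), order = 1L)
    )
  },
  OCH3 = function(c_pos, u, w) {
    o <- c_pos + CO_BOND * u
    cdir <- unit(rotate_about(u, w, (180 - 111) * pi / 180))
    cm <- o + 1.43 * cdir
    hs <- methyl_hydrogens(cm, cdir, w)
    list(
      atoms = tibble::tibble(
        element = c("O", "C", "H", "H", "H"),
        x = c(o[1], cm[1], hs[, 1]), y = c(o[2], cm[2], hs[, 2]),
        z = c(o[3], cm[3], hs[, 3])
      ),
      bonds = tibble::tibble(from = c(1L, 2L, 2L, 2L), to = c(2L, 3L, 4L, 5L), order = 1L)
    )
  }
)

## three tetrahedral hydrogens around axis `axis` at carbon `c_pos`
methyl_hydrogens <- function(c_pos, axis, ref) {
  ang <- (180 - 109.471) * pi / 180
  base <- unit(rotate_about(axis, ref, pi - ang))
  t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
    c_pos + CH_BOND * unit(rotate_about(base, axis, phi))
  }, numeric(3)))
}

## assemble one molecule from a 6-vector of substituent codes
build_fixture_molecule <- function(name, codes, activity = NA_real_) {
  theta <- (seq_len(6) - 1) * pi / 3
  ring <- cbind(RING_CC * cos(theta), RING_CC * sin(theta), 0)
  atoms <- tibble::tibble(
    element = rep("C", 6),
    x = ring[, 1], y = ring[, 2], z = ring[, 3]
  )
  ## Kekule ring bonds 1-2 2-3 ... 6-1, alternating orders
  bonds <- tibble::tibble(
    from = 1:6, to = c(2:6, 1L), order = rep(c(2L, 1L), 3)
  )
  w <- c(0, 0, 1)
  for (pos in seq_len(6)) {
    u <- unit(ring[pos, ] - c(0, 0, 0))
    grp <- SUBSTITUENT_BUILDERS[[codes[pos]]](ring[pos, ], u, w)
    offset <- nrow(atoms)
    atoms <- dplyr::bind_rows(atoms, grp$atoms)
    bonds <- dplyr::bind_rows(
      bonds,
      tibble::tibble(from = pos, to = offset + 1L, order = 1L),
      if (nrow(grp$bonds)) {
        tibble::tibble(from = grp$bonds$from + offset, to = grp$bonds$to + offset,
                       order = grp$bonds$order)
      }
    )
  }
  molecule(name, atoms, bonds, activity = activity)
}

#' Generate a synthetic aligned fixture set with known truth
#'
#' Enumerates substituted scaffolds (deterministic under `spec$seed`),
#' annotates them, computes the enabled fields on a grid covering train and
#' test jointly, selects the `n_true_columns` highest-variance columns of
#' the true field (variance over training molecules), and assigns
#' `activity = 6 + signal + N(0, noise_sd)` where the signal is a fixed
#' linear combination of those columns standardized to unit spread. Returns
#' the sets plus a truth record for recovery tests; optionally writes
#' train/test SDF files and a truth YAML.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory for `train.sdf`, `test.sdf`,
#'   `truth.yaml`.
#' @return list of class `comsia_fixture`: `train`, `test`
#'   (`comsia_molset`s with activities), `truth` (true field, column grid
#'   indices, coefficients, noise-free signal), `grid`, and the annotated
#'   sets' field tensors (`fields_train`, `fields_test`).
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "comsia_fixture_spec"))
  set.seed(spec$seed)
  n_total <- spec$n_train + spec$n_test
  ## substituent assignment: always include the bare scaffold, then sample
  ## the variable positions
  vp <- spec$variable_positions
  codes <- matrix("H", n_total, 6)
  for (i in 2:n_total) {
    codes[i, vp] <- sample(spec$substituents, length(vp), replace = TRUE)
  }
  ## de-duplicate deterministically by resampling clashing rows
  sig <- apply(codes, 1, paste, collapse = "|")
  tries <- 0L
  while (anyDuplicated(sig) && tries < 200L) {
    d <- which(duplicated(sig))
    for (i in d) codes[i, vp] <- sample(spec$substituents, length(vp), replace = TRUE)
    sig <- apply(codes, 1, paste, collapse = "|")
    tries <- tries + 1L
  }
  mols <- lapply(seq_len(n_total), function(i) {
    build_fixture_molecule(sprintf("fx_%03d", i), codes[i, ])
  })
  all_set <- molecule_set(mols, role = "predict")
  all_set <- annotate_molecules(all_set)
  cfg <- field_config(alpha = spec$alpha, fields = spec$fields)
  grid <- build_grid(all_set, spacing = spec$spacing, padding = spec$padding)
  tensor <- compute_all_fields(all_set, grid, cfg)
  ## truth: high-variance columns of the true field over the training rows
  f_idx <- match(spec$true_field, spec$fields)
  train_rows <- seq_len(spec$n_train)
  fvals <- tensor$values[, f_idx, , drop = TRUE]
  if (is.null(dim(fvals))) fvals <- matrix(fvals, nrow = n_total)
  col_var <- apply(fvals[train_rows, , drop = FALSE], 2, var)
  true_cols <- order(col_var, decreasing = TRUE)[seq_len(spec$n_true_columns)]
  ## one-signed coefficients: the signal is a localized bulk of the true
  ## field at the variable site (its dominant variance direction), which a
  ## PLS model can represent with few latent variables
  beta <- rep_len(c(1, 0.8, 0.6), spec$n_true_columns)
  raw_signal <- as.numeric(fvals[, true_cols, drop = FALSE] %*% beta)
  spread <- sd(raw_signal[train_rows])
  if (spread < 1e-9) abort("degenerate fixture: the true-field signal has no variance")
  signal <- (raw_signal - mean(raw_signal[train_rows])) / spread
  y <- 6 + signal + rnorm(n_total, 0, spec$noise_sd)
  for (i in seq_len(n_total)) all_set$molecules[[i]]$activity <- y[i]
  train <- molecule_set(unname(all_set$molecules[train_rows]), role = "train")
  test <- if (spec$n_test > 0) {
    molecule_set(unname(all_set$molecules[spec$n_train + seq_len(spec$n_test)]), role = "test")
  } else NULL
  truth <- list(
    true_field = spec$true_field,
    grid_index = true_cols,
    beta = beta,
    signal = signal,
    seed = spec$seed
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_sdf(train, file.path(dir, "train.sdf"), activity_tag = "activity")
    if (!is.null(test)) write_sdf(test, file.path(dir, "test.sdf"), activity_tag = "activity")
    yaml::write_yaml(
      truth[c("true_field", "grid_index", "beta", "seed")],
      file.path(dir, "truth.yaml")
    )
  }
  structure(
    list(train = train, test = test, truth = truth, grid = grid, spec = spec),
    class = "comsia_fixture"
  )
}

#' @export
print.comsia_fixture <- function(x, ...) {
  cat(sprintf(
    "<comsia_fixture> %d train + %d test molecules, signal in field %s (noise sd %g)\n",
    length(x$train), if (is.null(x$test)) 0L else length(x$test),
    x$truth$true_field, x$spec$noise_sd
  ))
  invisible(x)
}
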