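#' Stack training and prediction field tensors
#'
#' Rows are stacked train-first so that scaling and filtering statistics can
#' be computed once over the combined molecules and applied consistently to
#' every row, which is required for the prediction rows to live in the same
#' descriptor space as the training rows.
#'
#' @param train a `comsia_fields` for the training set.
#' @param ... further `comsia_fields` (test and/or prediction sets) sharing
#'   the same grid and enabled fields.
#' @return a `comsia_fields` whose first dimension concatenates all sets,
#'   with a `roles` element recording each row's origin.
#' @export
combine_sets <- function(train, ...) {
  others <- list(...)
  others <- others[!vapply(others, is.null, logical(1))]
  all_sets <- c(list(train), others)
  ok <- vapply(all_sets, inherits, logical(1), what = "comsia_fields")
  if (!all(ok)) abort("combine_sets() expects comsia_fields objects")
  g0 <- train$grid
  for (s in all_sets) {
    same <- identical(s$fields, train$fields) &&
      isTRUE(all.equal(s$grid$origin, g0$origin)) &&
      identical(s$grid$dims, g0$dims) &&
      isTRUE(all.equal(s$grid$spacing, g0$spacing))
    if (!same) abort("all sets must share one grid and one enabled-field list")
  }
  values <- do.call(abind_rows, lapply(all_sets, function(s) s$values))
  structure(
    list(
      values = values, fields = train$fields, grid = g0,
      molecule_names = unlist(lapply(all_sets, function(s) s$molecule_names)),
      activities = unlist(lapply(all_sets, function(s) s$activities)),
      roles = unlist(lapply(all_sets, function(s) rep(s$role, dim(s$values)[1]))),
      role = "combined"
    ),
    class = "comsia_fields"
  )
}

## rbind along the first dimension of mol x field x point arrays
abind_rows <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, dim = c(sum(vapply(parts, function(p) dim(p)[1], numeric(1))), d[2], d[3]))
  if (!is.null(dimnames(parts[[1]]))) {
    dimnames(out) <- list(NULL, dimnames(parts[[1]])[[2]], NULL)
  }
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

## flatten a mol x field x point tensor into a molecules x columns matrix;
## columns are field-major (all grid points of field 1, then field 2, ...),
## grid points in grid_points() order
flatten_tensor <- function(fields_obj) {
  v <- fields_obj$values
  n_mol <- dim(v)[1]; n_f <- dim(v)[2]; n_p <- dim(v)[3]
  m <- matrix(0, n_mol, n_f * n_p)
  for (fi in seq_len(n_f)) {
    m[, (fi - 1L) * n_p + seq_len(n_p)] <- v[, fi, ]
  }
  rownames(m) <- fields_obj$molecule_names
  m
}

column_meta_skeleton <- function(fields_obj) {
  n_p <- dim(fields_obj$values)[3]
  tibble::tibble(
    field = rep(fields_obj$fields, each = n_p),
    grid_index = rep(seq_len(n_p), times = length(fields_obj$fields)),
    kept = TRUE
  )
}

#' Low-variance column filter
#'
#' A column (one field at one grid point) is kept iff the range of its
#' values across all molecules is at least `threshold`. Filtering is off by
#' default in the pipeline (`threshold = NULL`); a threshold of 0 keeps
#' everything.
#'
#' @param fields_obj a (combined) `comsia_fields`.
#' @param threshold non-negative numeric.
#' @return logical keep mask over the flattened columns (field-major order).
#' @export
column_filter <- function(fields_obj, threshold) {
  stopifnot_scalar(threshold, "threshold")
  if (threshold < 0) abort("`threshold` must be >= 0")
  m <- flatten_tensor(fields_obj)
  rng <- apply(m, 2, function(col) max(col) - min(col))
  rng >= threshold
}

#' Block-scale the fields to zero mean and unit variance
#'
#' Standardization is per FIELD BLOCK: for each field, one mean and one
#' population variance are pooled over all kept columns of that field and
#' all molecules, and applied uniformly within the block. This equalizes the
#' overall magnitude of the five fields without flattening the spatial
#' contrast inside a field (per-column scaling would give every grid point
#' identical variance and destroy the map). The per-column standard
#' deviation of the scaled data is stored for contour generation and field
#' contributions.
#'
#' @param fields_obj a (combined) `comsia_fields`.
#' @param kept logical keep mask from [column_filter()], or NULL to keep all.
#' @param per_column logical; standardize each column individually instead
#'   of per field block (comparison mode, default `FALSE`).
#' @return list with `X` (molecules x kept columns, scaled) and `columns`
#'   (tibble of per-column metadata: field, grid_index, kept, scale_mean,
#'   scale_sd, sd_scaled).
#' @export
scale_fields <- function(fields_obj, kept = NULL, per_column = FALSE) {
  m <- flatten_tensor(fields_obj)
  if (nrow(m) < 2) abort("scaling requires at least two molecules")
  meta <- column_meta_skeleton(fields_obj)
  if (is.null(kept)) kept <- rep(TRUE, ncol(m))
  if (length(kept) != ncol(m)) abort("keep mask length does not match column count")
  meta$kept <- kept
  meta$scale_mean <- NA_real_
  meta$scale_sd <- NA_real_
  X <- m[, kept, drop = FALSE]
  kmeta <- meta[kept, ]
  for (f in fields_obj$fields) {
    block <- which(kmeta$field == f)
    if (!length(block)) next
    vals <- X[, block, drop = FALSE]
    mu <- mean(vals)
    if (per_column) {
      mus <- colMeans(vals)
      sds <- sqrt(colMeans(sweep(vals, 2, mus)^2))
      if (any(sds <= 0)) abort(sprintf("zero-variance column(s) in field %s", f))
      X[, block] <- sweep(sweep(vals, 2, mus), 2, sds, "/")
      kmeta$scale_mean[block] <- mus
      kmeta$scale_sd[block] <- sds
    } else {
      sigma <- sqrt(mean((vals - mu)^2))  # population variance over the block
      if (sigma <= 0) abort(sprintf("field %s has zero variance over the set", f))
      X[, block] <- (vals - mu) / sigma
      kmeta$scale_mean[block] <- mu
      kmeta$scale_sd[block] <- sigma
    }
  }
  ## per-column std of the *scaled* data (population form), kept for
  ## contouring: coefficient * column std is the plotted quantity
  kmeta$sd_scaled <- apply(X, 2, function(col) sqrt(mean((col - mean(col))^2)))
  meta$scale_mean[kept] <- kmeta$scale_mean
  meta$scale_sd[kept] <- kmeta$scale_sd
  meta$sd_scaled <- NA_real_
  meta$sd_scaled[kept] <- kmeta$sd_scaled
  list(X = X, columns = meta)
}

#' Assemble the centered feature matrix for PLS
#'
#' Column means are computed on the TRAINING rows only and subtracted from
#' every row; activities are centered by the training mean, which is
#' retained for back-transforming predictions. Prediction/test rows are
#' therefore expressed in the training frame with no leakage into the
#' centering.
#'
#' @param scaled output of [scale_fields()].
#' @param fields_obj the combined `comsia_fields` the scaling was computed
#'   from (provides roles and activities).
#' @return an object of class `comsia_features`: `X` (train rows), `y`
#'   (centered activities), `y_mean`, `X_new`/`y_new`/`new_roles` for
#'   non-training rows, `columns` metadata, `grid`, `fields`.
#' @export
assemble_features <- function(scaled, fields_obj) {
  roles <- fields_obj$roles %||% rep(fields_obj$role, nrow(scaled$X))
  is_train <- roles == "train"
  if (!any(is_train)) abort("no training rows present")
  y_all <- fields_obj$activities
  if (anyNA(y_all[is_train])) {
    abort(sprintf(
      "training molecules lack activities: %s",
      paste(fields_obj$molecule_names[is_train & is.na(y_all)], collapse = ", ")
    ))
  }
  X_all <- scaled$X
  col_means <- colMeans(X_all[is_train, , drop = FALSE])
  X_all <- sweep(X_all, 2, col_means)
  y_mean <- mean(y_all[is_train])
  structure(
    list(
      X = X_all[is_train, , drop = FALSE],
      y = y_all[is_train] - y_mean,
      y_mean = y_mean,
      row_names = fields_obj$molecule_names[is_train],
      X_new = if (any(!is_train)) X_all[!is_train, , drop = FALSE] else NULL,
      y_new = if (any(!is_train)) y_all[!is_train] else NULL,
      new_roles = if (any(!is_train)) roles[!is_train] else NULL,
      new_names = if (any(!is_train)) fields_obj$molecule_names[!is_train] else NULL,
      col_means = col_means,
      columns = scaled$columns,
      grid = fields_obj$grid,
      fields = fields_obj$fields
    ),
    class = "comsia_features"
  )
}

#' @export
print.comsia_features <- function(x, ...) {
  cat(sprintf(
    "<comsia_features> %d training rows%s x %d columns (fields %s), y_mean %.4g\n",
    nrow(x$X),
    if (!is.null(x$X_new)) sprintf(" + %d prediction rows", nrow(x$X_new)) else "",
    ncol(x$X), paste(x$fields, collapse = ""), x$y_mean
  ))
  invisible(x)
}

#' One-call preprocessing: tensors to centered feature matrix
#'
#' Combines the training tensor with optional test/prediction tensors,
#' optionally filters low-range columns, block-scales each field, and
#' assembles the centered matrix. Scaling statistics are pooled over the
#' combined rows when prediction rows are supplied (so all rows share one
#' descriptor space) and over the training rows alone otherwise.
#'
#' @param train a `comsia_fields` for the training molecules.
#' @param test,predict optional `comsia_fields` on the same grid.
#' @param filter_threshold numeric range threshold, or `NULL` (default) for
#'   no column filtering.
#' @param per_column see [scale_fields()].
#' @return a `comsia_features`.
#' @export
build_feature_matrix <- function(train, test = NULL, predict = NULL,
                                 filter_threshold = NULL, per_column = FALSE) {
  combined <- combine_sets(train, test, predict)
  kept <- if (is.null(filter_threshold)) NULL else column_filter(combined, filter_threshold)
  scaled <- scale_fields(combined, kept, per_column = per_column)
  assemble_features(scaled, combined)
}
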