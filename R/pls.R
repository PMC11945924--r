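## PLS1 (single-response partial least squares) via NIPALS, written for the
## fixed-preprocessing QSAR workflow: X and y arrive centered once (and the
## fields block-scaled) from the preprocessing stage, and LOOCV folds refit
## the latent structure but NOT the centering/scaling statistics.

## core NIPALS fit on (already centered) X, y; returns weights/loadings and
## the regression coefficient vector for each component count 1..k
pls1_nipals <- function(X, y, k) {
  n <- nrow(X); p <- ncol(X)
  k_max <- min(k, n - 1L, p)
  W <- matrix(0, p, k_max)
  P <- matrix(0, p, k_max)
  Tm <- matrix(0, n, k_max)
  qv <- numeric(k_max)
  Xd <- X; yd <- y
  a <- 0L
  for (comp in seq_len(k_max)) {
    w <- crossprod(Xd, yd)  # p x 1
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break  # residual X carries no covariance with y: rank exhausted
    w <- w / wn
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pv <- crossprod(Xd, t) / tt
    qq <- sum(yd * t) / tt
    W[, comp] <- w
    P[, comp] <- pv
    Tm[, comp] <- t
    qv[comp] <- qq
    Xd <- Xd - t %*% t(pv)
    yd <- yd - t * qq
    a <- comp
  }
  if (a == 0L) abort("PLS found no usable component (X has no covariance with y)")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]
  qv <- qv[seq_len(a)]
  ## coefficients B_a = W (P'W)^-1 q for the full component count a
  R <- W %*% solve(crossprod(P, W))
  list(
    coefficients = as.numeric(R %*% qv),
    weights = W, loadings = P, scores = Tm, y_loadings = qv,
    n_components = a
  )
}

## prediction of centered y from centered rows
pls1_predict <- function(fit, X) as.numeric(X %*% fit$coefficients)

#' Leave-one-out cross-validation curve
#'
#' For each candidate component count k, every training molecule is
#' predicted by a PLS model fitted to the remaining molecules, giving
#' `PRESS(k) = sum_i (y_i - yhat_(-i))^2`,
#' `q2(k) = 1 - PRESS(k) / sum_i (y_i - ybar)^2` and
#' `S_PRESS(k) = sqrt(PRESS(k) / (n - k - 1))`. The centering and scaling
#' statistics of the feature matrix are fixed from the preprocessing stage
#' and are not refit inside folds (set `refit_center = TRUE` for the strict
#' comparison mode).
#'
#' @param fm a `comsia_features`.
#' @param max_components largest component count to score; defaults to
#'   `min(10, n - 2)`. Counts beyond the effective rank are truncated with a
#'   warning.
#' @param refit_center logical; recenter X and y inside each fold.
#' @return a tibble of class `comsia_cv` with columns `ncomp`, `press`,
#'   `q2`, `s_press` and attributes `n`, `loo_pred` (matrix of per-fold
#'   predictions, centered scale).
#' @export
loocv <- function(fm, max_components = NULL, refit_center = FALSE) {
  stopifnot(inherits(fm, "comsia_features"))
  X <- fm$X; y <- fm$y
  n <- nrow(X)
  if (n < 3) abort("LOOCV needs at least 3 training molecules")
  max_components <- max_components %||% min(10L, n - 2L)
  max_components <- min(max_components, n - 2L)
  if (max_components < 1) abort("max_components must be >= 1")
  loo <- matrix(NA_real_, n, max_components)
  k_reached <- max_components
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    xnew <- X[i, , drop = FALSE]
    if (refit_center) {
      cm <- colMeans(Xi); ym <- mean(yi)
      Xi <- sweep(Xi, 2, cm); yi <- yi - ym
      xnew <- xnew - cm
    } else {
      ym <- 0
    }
    fit <- pls1_nipals(Xi, yi, max_components)
    k_reached <- min(k_reached, fit$n_components)
    for (k in seq_len(fit$n_components)) {
      Bk <- fit$weights[, 1:k, drop = FALSE] %*%
        solve(crossprod(fit$loadings[, 1:k, drop = FALSE], fit$weights[, 1:k, drop = FALSE])) %*%
        fit$y_loadings[1:k]
      loo[i, k] <- as.numeric(xnew %*% Bk) + ym
    }
  }
  if (k_reached < max_components) {
    warn(sprintf("component counts beyond %d exceed the effective rank; curve truncated", k_reached))
    loo <- loo[, seq_len(k_reached), drop = FALSE]
  }
  ssy <- sum((y - mean(y))^2)
  press <- colSums((loo - y)^2)
  ks <- seq_len(ncol(loo))
  out <- tibble::tibble(
    ncomp = ks,
    press = press,
    q2 = 1 - press / ssy,
    s_press = sqrt(press / (n - ks - 1))
  )
  class(out) <- c("comsia_cv", class(out))
  attr(out, "n") <- n
  attr(out, "loo_pred") <- loo
  out
}

#' Select the component count from a CV curve
#'
#' The component count maximizing q2; exact ties break toward the smaller
#' count (parsimony).
#'
#' @param curve a `comsia_cv` from [loocv()].
#' @return integer component count.
#' @export
select_components <- function(curve) {
  if (!nrow(curve)) abort("empty CV curve")
  curve$ncomp[which.max(curve$q2)]
}

#' Fit the final PLS model and compute the reported statistics
#'
#' Fits PLS with `k` components on the full training matrix and stores the
#' coefficient vector (in the centered/scaled column space), the training
#' statistics `r2_train = 1 - SSE/SSY` and `S = sqrt(SSE / (n - k - 1))`,
#' cross-validation statistics when a curve is supplied, and the per-field
#' contribution fractions `sum_j |b_j * s_j|` normalized over fields (s_j =
#' stored per-column standard deviation of the scaled data).
#'
#' @param fm a `comsia_features`.
#' @param k number of components.
#' @param curve optional `comsia_cv`, used to attach q2/S_PRESS at `k`.
#' @return an object of class `comsia_qsar`.
#' @export
fit_final <- function(fm, k, curve = NULL) {
  stopifnot(inherits(fm, "comsia_features"))
  if (!is_scalar_number(k) || k < 1) abort("`k` must be a positive integer")
  k <- as.integer(k)
  fit <- pls1_nipals(fm$X, fm$y, k)
  if (fit$n_components < k) {
    warn(sprintf("rank-deficient training matrix: fitted %d of %d requested components",
                 fit$n_components, k))
    k <- fit$n_components
  }
  n <- nrow(fm$X)
  fitted_centered <- pls1_predict(fit, fm$X)
  resid <- fm$y - fitted_centered
  sse <- sum(resid^2)
  ssy <- sum((fm$y - mean(fm$y))^2)
  metrics <- list(
    n_components = k,
    r2_train = 1 - sse / ssy,
    s_train = sqrt(sse / (n - k - 1)),
    q2 = if (!is.null(curve)) curve$q2[match(k, curve$ncomp)] else NA_real_,
    s_press = if (!is.null(curve)) curve$s_press[match(k, curve$ncomp)] else NA_real_,
    r2_pred = NA_real_,
    s_test = NA_real_
  )
  model <- structure(
    list(
      coefficients = fit$coefficients,
      n_components = k,
      y_mean = fm$y_mean,
      metrics = metrics,
      columns = fm$columns,
      col_means = fm$col_means,
      grid = fm$grid,
      fields = fm$fields,
      fitted = fitted_centered + fm$y_mean,
      residuals = setNames(resid, fm$row_names),
      observed = setNames(fm$y + fm$y_mean, fm$row_names),
      cv = curve,
      pls = fit
    ),
    class = "comsia_qsar"
  )
  model$field_contributions <- field_contributions(model)
  model
}

#' Per-field contribution fractions
#'
#' `contribution(f) = sum_{j in f} |b_j * s_j| / sum_all |b_j * s_j|`, where
#' `s_j` is the stored per-column standard deviation of the scaled field
#' data. The fractions sum to 1 and are invariant to rescaling a field block
#' with the compensating coefficient change.
#'
#' @param model a `comsia_qsar`.
#' @param columns optional column metadata override.
#' @return named numeric vector over the enabled fields.
#' @export
field_contributions <- function(model, columns = NULL) {
  columns <- columns %||% model$columns
  kept <- columns[columns$kept, ]
  mass <- abs(model$coefficients * kept$sd_scaled)
  total <- sum(mass)
  out <- vapply(model$fields, function(f) {
    if (total <= 0) 0 else sum(mass[kept$field == f]) / total
  }, numeric(1))
  if (total <= 0) out[] <- 1 / length(out)
  out
}

#' Predict activities for new rows
#'
#' Rows must already be transformed with the training statistics (they are,
#' when they come from the same [build_feature_matrix()] call). Returns
#' predictions in original activity units: `yhat = X b + y_mean`.
#'
#' @param object a `comsia_qsar`.
#' @param newdata matrix of transformed rows; defaults to the training rows
#'   (returning fitted values).
#' @param ... unused.
#' @return numeric vector of predicted activities.
#' @export
predict.comsia_qsar <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    abort(sprintf("newdata has %d columns; the model expects %d",
                  ncol(newdata), length(object$coefficients)))
  }
  as.numeric(newdata %*% object$coefficients) + object$y_mean
}

#' External-validation statistics on a test set
#'
#' `r2_pred = 1 - sum (y - yhat)^2 / sum (y - ybar_train)^2` (the
#' predictive-r2 convention: the denominator benchmarks against the
#' training-mean predictor), and
#' `s_test = sqrt(SSE / (n_test - k - 1))` when `n_test > k + 1`, otherwise
#' the test RMSE.
#'
#' @param model a `comsia_qsar`.
#' @param fm the `comsia_features` holding the transformed test rows, or a
#'   matrix of transformed rows.
#' @param y_test observed activities (taken from `fm` when omitted).
#' @return the model with `metrics$r2_pred`, `metrics$s_test` and a
#'   `test_predictions` tibble filled in.
#' @export
evaluate_test <- function(model, fm, y_test = NULL) {
  if (inherits(fm, "comsia_features")) {
    if (is.null(fm$X_new)) abort("no test rows present in the feature matrix")
    keep <- fm$new_roles == "test"
    X_test <- fm$X_new[keep, , drop = FALSE]
    y_test <- y_test %||% fm$y_new[keep]
    nms <- fm$new_names[keep]
  } else {
    X_test <- as.matrix(fm)
    nms <- rownames(X_test) %||% paste0("test_", seq_len(nrow(X_test)))
  }
  if (!NROW(X_test)) abort("empty test set: external metrics are absent, not zero")
  if (is.null(y_test) || anyNA(y_test)) abort("test activities are required for evaluation")
  yhat <- predict(model, X_test)
  sse <- sum((y_test - yhat)^2)
  ss0 <- sum((y_test - model$y_mean)^2)
  k <- model$n_components
  n_test <- length(y_test)
  model$metrics$r2_pred <- 1 - sse / ss0
  model$metrics$s_test <- if (n_test > k + 1) sqrt(sse / (n_test - k - 1)) else sqrt(sse / n_test)
  model$test_predictions <- tibble::tibble(
    molecule = nms, observed = y_test, predicted = yhat,
    residual = y_test - yhat
  )
  model
}

#' @export
print.comsia_qsar <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<comsia_qsar> PLS with %d components (fields %s)\n",
              x$n_components, paste(x$fields, collapse = "")))
  cat(sprintf("  q2 %.3f | S_PRESS %.3f | r2 %.3f | S %.3f",
              m$q2, m$s_press, m$r2_train, m$s_train))
  if (!is.na(m$r2_pred)) cat(sprintf(" | r2_pred %.3f | S_test %.3f", m$r2_pred, m$s_test))
  cat("\n  field contributions:",
      paste(sprintf("%s %.3f", names(x$field_contributions), x$field_contributions),
            collapse = ", "), "\n")
  invisible(x)
}
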