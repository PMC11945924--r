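## random centered regression problem
toy_problem <- function(n = 12, p = 30, seed = 4, noise = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X %*% c(rep(1.5, 3), rep(0, p - 3))) + rnorm(n, 0, noise)
  list(X = sweep(X, 2, colMeans(X)), y = y - mean(y))
}

## minimal comsia_features wrapper around a centered matrix
as_features <- function(X, y, y_mean = 0, fields = "S") {
  structure(
    list(
      X = X, y = y, y_mean = y_mean,
      row_names = sprintf("m%02d", seq_len(nrow(X))),
      X_new = NULL, y_new = NULL, new_roles = NULL, new_names = NULL,
      col_means = rep(0, ncol(X)),
      columns = tibble::tibble(
        field = rep(fields, each = ncol(X) / length(fields)),
        grid_index = rep(seq_len(ncol(X) / length(fields)), times = length(fields)),
        kept = TRUE, scale_mean = 0, scale_sd = 1,
        sd_scaled = apply(X, 2, function(c) sqrt(mean((c - mean(c))^2)))
      ),
      grid = NULL, fields = fields
    ),
    class = "comsia_features"
  )
}

test_that("NIPALS coefficients match the independent Krylov closed form", {
  tp <- toy_problem()
  for (k in 1:4) {
    fit <- comsia:::pls1_nipals(tp$X, tp$y, k)
    expect_equal(fit$coefficients, krylov_pls_coef(tp$X, tp$y, k), tolerance = 1e-9)
  }
})

test_that("the final fit agrees with an established PLS implementation", {
  tp <- toy_problem(seed = 8)
  colnames(tp$X) <- paste0("c", seq_len(ncol(tp$X)))
  k <- 3
  fit <- comsia:::pls1_nipals(tp$X, tp$y, k)
  mo <- mixOmics::pls(tp$X, tp$y, ncomp = k, mode = "regression", scale = FALSE)
  pr <- predict(mo, newdata = tp$X)$predict[, 1, k]
  expect_equal(as.numeric(tp$X %*% fit$coefficients), unname(pr), tolerance = 1e-8)
})

test_that("LOOCV predictions equal a brute-force per-fold refit oracle", {
  tp <- toy_problem(n = 8, p = 20, seed = 6)
  fm <- as_features(tp$X, tp$y)
  cv <- loocv(fm, max_components = 3)
  loo <- attr(cv, "loo_pred")
  for (i in seq_len(8)) {
    for (k in 1:3) {
      b <- krylov_pls_coef(tp$X[-i, ], tp$y[-i], k)
      expect_equal(loo[i, k], as.numeric(tp$X[i, , drop = FALSE] %*% b),
                   tolerance = 1e-10)
    }
  }
  ## and the summary statistics follow their definitions
  press <- colSums((loo - tp$y)^2)
  expect_equal(cv$press, press)
  expect_equal(cv$q2, 1 - press / sum((tp$y - mean(tp$y))^2))
  expect_equal(cv$s_press, sqrt(press / (8 - cv$ncomp - 1)))
})

test_that("a noiseless single-latent-variable response gives q2 of 1", {
  set.seed(10)
  t_scores <- rnorm(15)
  w <- rnorm(25)
  X <- t_scores %*% t(w)          # exact rank one
  y <- 2 * t_scores
  fm <- as_features(sweep(X, 2, colMeans(X)), y - mean(y))
  cv <- suppressWarnings(loocv(fm, max_components = 1))
  expect_equal(cv$q2[1], 1, tolerance = 1e-6)
})

test_that("component selection maximizes q2 with parsimony on ties", {
  curve <- tibble::tibble(ncomp = 1:3, press = 1, q2 = c(0.3, 0.6, 0.55),
                          s_press = 1)
  expect_equal(select_components(curve), 2L)
  tie <- tibble::tibble(ncomp = 1:2, press = 1, q2 = c(0.5, 0.5), s_press = 1)
  expect_equal(select_components(tie), 1L)
  single <- tibble::tibble(ncomp = 1L, press = 1, q2 = 0.1, s_press = 1)
  expect_equal(select_components(single), 1L)
})

test_that("the final model reproduces its analytic training diagnostics", {
  tp <- toy_problem(seed = 12)
  fm <- as_features(tp$X, tp$y, y_mean = 6)
  cv <- loocv(fm, max_components = 4)
  model <- fit_final(fm, select_components(cv), curve = cv)
  ## centered fit: residual mean is exactly zero
  expect_equal(mean(model$residuals), 0, tolerance = 1e-10)
  ## q2 never exceeds the training r2 at the same component count
  expect_lte(model$metrics$q2, model$metrics$r2_train)
  ## fitted values come back through predict() on the training rows
  expect_equal(predict(model, fm$X), model$fitted)
  ## an all-zero (mean) feature row predicts exactly y_mean
  expect_equal(predict(model, matrix(0, 1, ncol(fm$X))), 6)
  ## a duplicated training row predicts that row's fitted value
  expect_equal(predict(model, fm$X[3, , drop = FALSE]), model$fitted[3])
  ## column-count mismatch is an error
  expect_error(predict(model, fm$X[, -1]), "columns")
})

test_that("full-rank noiseless systems are fitted exactly", {
  set.seed(13)
  X <- matrix(rnorm(36), 6, 6)
  y <- as.numeric(X %*% rnorm(6))
  fm <- as_features(sweep(X, 2, colMeans(X)), y - mean(y))
  model <- suppressWarnings(fit_final(fm, 5))
  expect_equal(model$metrics$r2_train, 1, tolerance = 1e-8)
})

test_that("field contributions are normalized, symmetric and scale-consistent", {
  ## two fields, identical coefficient magnitudes and stds: 0.5 / 0.5
  model <- structure(
    list(
      coefficients = c(1, -1, 2, -2),
      columns = tibble::tibble(
        field = c("S", "S", "E", "E"), grid_index = c(1, 2, 1, 2),
        kept = TRUE, sd_scaled = c(2, 2, 1, 1)
      ),
      fields = c("S", "E")
    ),
    class = "comsia_qsar"
  )
  fc <- field_contributions(model)
  expect_equal(sum(fc), 1, tolerance = 1e-12)
  expect_equal(unname(fc), c(0.5, 0.5))

  ## zero-coefficient field contributes zero; single live field gets 1
  model$coefficients <- c(1, 2, 0, 0)
  fc2 <- field_contributions(model)
  expect_equal(unname(fc2["E"]), 0)
  expect_equal(unname(fc2["S"]), 1)

  ## multiplying a field block and dividing its coefficients leaves
  ## contributions unchanged
  model$coefficients <- c(1, -1, 2, -2)
  scaled <- model
  scaled$coefficients[1:2] <- scaled$coefficients[1:2] / 7
  scaled$columns$sd_scaled[1:2] <- scaled$columns$sd_scaled[1:2] * 7
  expect_equal(field_contributions(scaled), field_contributions(model))
})

test_that("external validation follows the predictive-r2 convention", {
  tp <- toy_problem(seed = 14)
  fm <- as_features(tp$X, tp$y, y_mean = 5)
  model <- fit_final(fm, 2)
  ## predictions that equal the training mean give r2_pred = 0
  X0 <- matrix(0, 4, ncol(fm$X))
  y0 <- c(4, 5, 6, 7)
  m0 <- evaluate_test(model, X0, y_test = y0)
  expect_equal(m0$metrics$r2_pred, 0)
  ## a perfect prediction vector gives r2_pred = 1 (prediction of the
  ## training rows against their own fitted values)
  m1 <- evaluate_test(model, fm$X[1:4, , drop = FALSE],
                      y_test = model$fitted[1:4])
  expect_equal(m1$metrics$r2_pred, 1, tolerance = 1e-12)
  ## s_test uses n - k - 1 when it can, RMSE otherwise
  expect_equal(m0$metrics$s_test, sqrt(sum((y0 - 5)^2) / (4 - 2 - 1)))
  m2 <- evaluate_test(model, X0[1:2, , drop = FALSE], y_test = c(4, 5))
  expect_equal(m2$metrics$s_test, sqrt(sum((c(4, 5) - 5)^2) / 2))
  ## an empty test set is an error, not a zero
  expect_error(evaluate_test(model, X0[0, , drop = FALSE], y_test = numeric(0)),
               "empty test set")
})

test_that("tidy/glance/augment expose the model in broom form", {
  fm <- small_feature_matrix()
  cv <- loocv(fm, max_components = 4)
  model <- evaluate_test(fit_final(fm, select_components(cv), cv), fm)
  td <- tidy(model)
  expect_equal(nrow(td), ncol(fm$X))
  expect_named(td, c("field", "grid_index", "estimate", "coef_x_std"))
  gl <- glance(model)
  expect_equal(gl$n_components, model$n_components)
  expect_equal(gl$q2, model$metrics$q2)
  expect_true(all(paste0("contribution_", model$fields) %in% names(gl)))
  au <- augment(model)
  expect_equal(au$observed - au$fitted, au$residual)
})
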