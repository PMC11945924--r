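## Shared synthetic fixtures, cached per test session (generation costs a
## couple of seconds each because of charge annotation and field evaluation).

`%||%` <- function(x, y) if (is.null(x)) y else x

fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

## default study-condition fixture: 21 train + 10 test
std_fixture <- function() {
  cached_fixture("std", suppressWarnings(generate_fixture(fixture_spec(seed = 11))))
}

## small, fast fixture for pipeline plumbing tests
small_fixture <- function() {
  cached_fixture("small", suppressWarnings(generate_fixture(
    fixture_spec(n_train = 8, n_test = 3, seed = 5, spacing = 1.5, padding = 3)
  )))
}

## feature matrix of the small fixture
small_feature_matrix <- function() {
  cached_fixture("small_fm", {
    fx <- small_fixture()
    cfg <- field_config(fields = fx$spec$fields, alpha = fx$spec$alpha)
    suppressWarnings(build_feature_matrix(
      compute_all_fields(fx$train, fx$grid, cfg),
      test = compute_all_fields(fx$test, fx$grid, cfg)
    ))
  })
}

## full pipeline run on the default fixture
std_run <- function() {
  cached_fixture("std_run", {
    fx <- std_fixture()
    suppressWarnings(run_comsia(run_config(train = fx$train, test = fx$test, seed = 11)))
  })
}

## independent PLS oracle: Krylov-subspace closed form. PLS1 with k
## components is regression on the Krylov basis {X'y, (X'X)X'y, ...}; this
## shares no code with the NIPALS implementation under test.
krylov_pls_coef <- function(X, y, k) {
  s <- crossprod(X, y)
  K <- matrix(0, ncol(X), k)
  v <- s
  for (j in seq_len(k)) {
    K[, j] <- v / sqrt(sum(v^2))
    v <- crossprod(X, X %*% K[, j])
  }
  XtX <- crossprod(X)
  as.numeric(K %*% solve(t(K) %*% XtX %*% K, t(K) %*% s))
}

## naive per-point/per-source Gaussian field evaluation (triple loop)
naive_gaussian_field <- function(centers, weights, grid, alpha) {
  pts <- grid_points(grid)
  out <- numeric(nrow(pts))
  for (q in seq_len(nrow(pts))) {
    acc <- 0
    for (s in seq_len(nrow(centers))) {
      d2 <- sum((pts[q, ] - centers[s, ])^2)
      acc <- acc + weights[s] * exp(-alpha * d2)
    }
    out[q] <- acc
  }
  out
}
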