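#' Tidy a fitted QSAR model
#'
#' One row per kept column with its field, grid index and coefficient
#' (`estimate`), plus the contour quantity `coef_x_std`.
#'
#' @param x a `comsia_qsar`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.comsia_qsar <- function(x, ...) {
  kept <- x$columns[x$columns$kept, ]
  tibble::tibble(
    field = kept$field,
    grid_index = kept$grid_index,
    estimate = x$coefficients,
    coef_x_std = x$coefficients * kept$sd_scaled
  )
}

#' One-row model summary
#'
#' @param x a `comsia_qsar`.
#' @param ... unused.
#' @return a one-row tibble with q2, S_PRESS, r2, S, component count,
#'   external-validation statistics (NA when no test set) and the field
#'   contributions.
#' @export
glance.comsia_qsar <- function(x, ...) {
  m <- x$metrics
  out <- tibble::tibble(
    q2 = m$q2, s_press = m$s_press, r2_train = m$r2_train, s_train = m$s_train,
    r2_pred = m$r2_pred, s_test = m$s_test, n_components = m$n_components
  )
  contrib <- tibble::as_tibble(as.list(setNames(
    unname(x$field_contributions),
    paste0("contribution_", names(x$field_contributions))
  )))
  dplyr::bind_cols(out, contrib)
}

#' Per-molecule observed/fitted values
#'
#' @param x a `comsia_qsar`.
#' @param ... unused.
#' @return tibble with `molecule`, `observed`, `fitted`, `residual`.
#' @export
augment.comsia_qsar <- function(x, ...) {
  tibble::tibble(
    molecule = names(x$observed),
    observed = unname(x$observed),
    fitted = unname(x$fitted),
    residual = unname(x$observed - x$fitted)
  )
}

#' Cross-validation curve plot
#'
#' q2 against the number of PLS components, with the selected maximum
#' highlighted.
#'
#' @param object a `comsia_cv` from [loocv()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.comsia_cv <- function(object, ...) {
  k_opt <- select_components(object)
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ncomp, y = .data$q2)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_point(
      data = df[df$ncomp == k_opt, ],
      color = "red", size = 3
    ) +
    ggplot2::scale_x_continuous(breaks = df$ncomp) +
    ggplot2::labs(
      x = "PLS components", y = expression(q^2),
      title = "Leave-one-out cross-validation",
      subtitle = sprintf("selected: %d components", k_opt)
    ) +
    ggplot2::theme_minimal()
}

#' Observed-versus-predicted plot
#'
#' Training fits and, when present, test-set predictions of a fitted model
#' or run.
#'
#' @param object a `comsia_qsar` or `comsia_run`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.comsia_qsar <- function(object, ...) {
  df <- augment(object)
  df$role <- "train"
  if (!is.null(object$test_predictions)) {
    tp <- object$test_predictions
    df <- dplyr::bind_rows(df, tibble::tibble(
      molecule = tp$molecule, observed = tp$observed,
      fitted = tp$predicted, residual = tp$residual, role = "test"
    ))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$fitted, color = .data$role)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_manual(values = c(train = "steelblue", test = "firebrick")) +
    ggplot2::labs(
      x = "observed activity", y = "predicted activity",
      title = "PLS model fit"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.comsia_run <- function(object, ...) autoplot(object$model, ...)

#' Tidy a CV curve
#' @param x a `comsia_cv`.
#' @param ... unused.
#' @return the curve as a plain tibble.
#' @export
tidy.comsia_cv <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "comsia_cv")
  out
}
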