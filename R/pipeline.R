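#' Pipeline configuration
#'
#' Assembles the full run configuration with the conventional defaults
#' (grid spacing 1 A, padding 4 A, attenuation 0.3 1/A^2, all five fields,
#' no column filtering, top 5 percent contours). Any value can be overridden
#' by a YAML config file ([read_run_config()]) or by arguments here; the CLI
#' maps flags onto the same keys.
#'
#' @param train,test,predict input paths (SDF, or CSV of SMILES for inputs
#'   needing alignment) or `comsia_molset` objects; only `train` is
#'   required.
#' @param activity_tag SDF data field holding activities.
#' @param fields field codes, e.g. `"SEH"` or `"SEHAD"`.
#' @param spacing,padding grid parameters, Angstrom.
#' @param alpha attenuation factor, 1/Angstrom^2.
#' @param pseudo_distance,clash_factor,snap,donor_placement,
#'   include_nonpolar_h see [field_config()].
#' @param max_components LOOCV search depth (default `min(10, n - 2)`).
#' @param filter_threshold column range filter; `NULL` (default) disables
#'   filtering.
#' @param top_fraction contour percentile per tail.
#' @param align force MCS alignment even for SDF input.
#' @param template optional alignment template name.
#' @param seed integer seed.
#' @param out_dir output directory for run artifacts, or `NULL`.
#' @return a named list of class `comsia_config`.
#' @export
run_config <- function(train = NULL, test = NULL, predict = NULL,
                       activity_tag = "activity", fields = "SEHAD",
                       spacing = 1, padding = 4, alpha = 0.3,
                       pseudo_distance = 1.9, clash_factor = 0.7,
                       snap = TRUE, donor_placement = "heavy",
                       include_nonpolar_h = TRUE,
                       max_components = NULL, filter_threshold = NULL,
                       top_fraction = 0.05, align = FALSE, template = NULL,
                       seed = 1L, out_dir = NULL) {
  cfg <- list(
    train = train, test = test, predict = predict,
    activity_tag = activity_tag, fields = parse_fields(fields),
    spacing = spacing, padding = padding, alpha = alpha,
    pseudo_distance = pseudo_distance, clash_factor = clash_factor,
    snap = snap, donor_placement = donor_placement,
    include_nonpolar_h = include_nonpolar_h,
    max_components = max_components, filter_threshold = filter_threshold,
    top_fraction = top_fraction, align = align, template = template,
    seed = as.integer(seed), out_dir = out_dir
  )
  class(cfg) <- "comsia_config"
  cfg
}

#' Read a YAML run configuration
#'
#' Keys mirror the arguments of [run_config()] (nested keys `grid.spacing`,
#' `grid.padding`, `fields.alpha`, `fields.enabled`, `fields.pseudo_distance`,
#' `fields.clash_factor`, `pls.max_components`, `filter.threshold`,
#' `contour.top_fraction` are also accepted).
#'
#' @param path YAML file.
#' @param ... overrides applied after the file.
#' @return a `comsia_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  flat <- list(
    train = y$train, test = y$test, predict = y$predict,
    activity_tag = y$activity_tag,
    fields = y$fields %||% y$fields.enabled %||% (y$fields_cfg %||% list())$enabled,
    spacing = y$spacing %||% (y$grid %||% list())$spacing,
    padding = y$padding %||% (y$grid %||% list())$padding,
    alpha = y$alpha %||% (y$fields_cfg %||% list())$alpha,
    pseudo_distance = y$pseudo_distance,
    clash_factor = y$clash_factor,
    snap = y$snap, donor_placement = y$donor_placement,
    include_nonpolar_h = y$include_nonpolar_h,
    max_components = y$max_components %||% (y$pls %||% list())$max_components,
    filter_threshold = y$filter_threshold %||% (y$filter %||% list())$threshold,
    top_fraction = y$top_fraction %||% (y$contour %||% list())$top_fraction,
    align = y$align, template = y$template, seed = y$seed, out_dir = y$out_dir
  )
  flat <- flat[!vapply(flat, is.null, logical(1))]
  overrides <- list(...)
  flat[names(overrides)] <- overrides
  do.call(run_config, flat)
}

resolve_input <- function(x, activity_tag, role) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "comsia_molset")) {
    x$role <- role
    return(x)
  }
  if (!is.character(x) || length(x) != 1L) abort("inputs must be paths or comsia_molset objects")
  if (grepl("\\.csv$", x, ignore.case = TRUE)) {
    read_smiles_table(x, role = role)
  } else {
    read_sdf(x, activity_tag = activity_tag, role = role)
  }
}

#' Run the full CoMSIA pipeline
#'
#' Reads the inputs, aligns them when they lack a shared 3D frame, annotates
#' atoms, builds the joint grid, computes the enabled fields, assembles the
#' feature matrix, selects the PLS component count by LOOCV, fits the final
#' model, evaluates the test set, predicts any prediction set, and extracts
#' the per-field coefficient contour meshes. With `out_dir` set, writes
#' `metrics.tsv`, `predictions.csv`, `cv_curve.csv`, the contour meshes, a
#' machine-readable `warnings.yaml` and a `run_log.yaml` capturing every
#' config key, the seed and package versions. All outputs are deterministic
#' for a given config and seed.
#'
#' @param config a `comsia_config` from [run_config()] /
#'   [read_run_config()], or the first argument of [run_config()] with
#'   further arguments in `...`.
#' @param ... overrides forwarded to [run_config()].
#' @return a list of class `comsia_run`: `model` (`comsia_qsar`), `cv`,
#'   `predictions` (tibble over all molecules), `contours`, `alignment`
#'   (when performed), `grid`, `config`, `warnings`.
#' @export
run_comsia <- function(config, ...) {
  if (!inherits(config, "comsia_config")) {
    config <- run_config(train = config, ...)
  }
  if (is.null(config$train)) abort("`train` input is required")
  collected_warnings <- character(0)
  run_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(sprintf("[%s] %s", stage, conditionMessage(e)))
      }),
      warning = function(w) {
        collected_warnings <<- c(collected_warnings, sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }
  set.seed(config$seed)

  train <- run_stage("chemio", resolve_input(config$train, config$activity_tag, "train"))
  test <- run_stage("chemio", resolve_input(config$test, config$activity_tag, "test"))
  pred <- run_stage("chemio", resolve_input(config$predict, config$activity_tag, "predict"))

  alignment <- NULL
  sets <- list(train = train, test = test, predict = pred)
  needs_align <- config$align ||
    any(vapply(sets, function(s) {
      !is.null(s) && any(vapply(s$molecules, needs_embedding, logical(1)))
    }, logical(1)))
  if (needs_align) {
    sizes <- vapply(sets, function(s) if (is.null(s)) 0L else length(s), integer(1))
    pooled <- molecule_set(
      unlist(lapply(sets[sizes > 0], function(s) unname(s$molecules)), recursive = FALSE),
      role = "predict"
    )
    alignment <- run_stage("alignment",
      align_set(pooled, seed = config$seed, template = config$template)
    )
    aligned <- alignment$aligned$molecules
    at <- 0L
    for (nm in names(sets)) {
      if (sizes[[nm]] > 0) {
        sets[[nm]]$molecules <- setNames(
          aligned[at + seq_len(sizes[[nm]])],
          names(sets[[nm]]$molecules)
        )
        at <- at + sizes[[nm]]
      }
    }
    train <- sets$train; test <- sets$test; pred <- sets$predict
  }

  fcfg <- field_config(
    alpha = config$alpha, fields = config$fields,
    pseudo_distance = config$pseudo_distance, clash_factor = config$clash_factor,
    snap = config$snap, donor_placement = config$donor_placement,
    include_nonpolar_h = config$include_nonpolar_h
  )
  train <- run_stage("annotate", annotate_molecules(train))
  if (!is.null(test)) test <- run_stage("annotate", annotate_molecules(test))
  if (!is.null(pred)) pred <- run_stage("annotate", annotate_molecules(pred))

  grid <- run_stage("grid", build_grid(
    Filter(Negate(is.null), list(train, test, pred)),
    spacing = config$spacing, padding = config$padding
  ))
  ft_train <- run_stage("fields", compute_all_fields(train, grid, fcfg))
  ft_test <- if (!is.null(test)) run_stage("fields", compute_all_fields(test, grid, fcfg)) else NULL
  ft_pred <- if (!is.null(pred)) run_stage("fields", compute_all_fields(pred, grid, fcfg)) else NULL

  fm <- run_stage("preprocess", build_feature_matrix(
    ft_train, test = ft_test, predict = ft_pred,
    filter_threshold = config$filter_threshold
  ))
  cv <- run_stage("pls", loocv(fm, max_components = config$max_components))
  k <- select_components(cv)
  model <- run_stage("pls", fit_final(fm, k, curve = cv))
  if (!is.null(test) && !anyNA(activities(test))) {
    model <- run_stage("pls", evaluate_test(model, fm))
  }

  predictions <- tibble::tibble(
    molecule = names(model$observed),
    role = "train",
    observed = unname(model$observed),
    predicted = unname(model$fitted),
    residual = unname(model$observed - model$fitted)
  )
  if (!is.null(fm$X_new)) {
    yhat_new <- predict(model, fm$X_new)
    predictions <- dplyr::bind_rows(predictions, tibble::tibble(
      molecule = fm$new_names,
      role = fm$new_roles,
      observed = fm$y_new,
      predicted = yhat_new,
      residual = fm$y_new - yhat_new
    ))
  }

  contours <- run_stage("contour", {
    out <- list()
    for (f in config$fields) {
      map <- coefficient_map(model, f)
      thr <- tryCatch(percentile_thresholds(map, config$top_fraction), error = function(e) NULL)
      if (!is.null(thr)) out[[f]] <- extract_isosurfaces(map, thr)
    }
    out
  })

  run <- structure(
    list(
      model = model, cv = cv, predictions = predictions, contours = contours,
      alignment = alignment, grid = grid, config = config,
      warnings = collected_warnings
    ),
    class = "comsia_run"
  )
  if (!is.null(config$out_dir)) write_run_artifacts(run, config$out_dir)
  run
}

#' @export
print.comsia_run <- function(x, ...) {
  cat("<comsia_run>\n")
  print(x$model)
  invisible(x)
}

#' Metrics table of a fitted run or model
#'
#' One row per reported statistic, mirroring the conventional CoMSIA report:
#' q2, S_PRESS, r2, S, component count and the per-field contribution
#' fractions.
#'
#' @param model a `comsia_qsar` or `comsia_run`.
#' @return tibble with `metric`, `value`.
#' @export
metrics_table <- function(model) {
  if (inherits(model, "comsia_run")) model <- model$model
  m <- model$metrics
  rows <- tibble::tibble(
    metric = c("q2", "S_PRESS", "r2", "S", "n_comp"),
    value = c(m$q2, m$s_press, m$r2_train, m$s_train, m$n_components)
  )
  if (!is.na(m$r2_pred)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      metric = c("r2_pred", "S_test"), value = c(m$r2_pred, m$s_test)
    ))
  }
  dplyr::bind_rows(rows, tibble::tibble(
    metric = paste0("contribution_", names(model$field_contributions)),
    value = unname(model$field_contributions)
  ))
}

write_run_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mt <- metrics_table(run$model)
  write.table(
    data.frame(metric = mt$metric, value = sprintf("%.10g", mt$value)),
    file.path(dir, "metrics.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write.csv(run$predictions, file.path(dir, "predictions.csv"), row.names = FALSE)
  write.csv(as.data.frame(run$cv), file.path(dir, "cv_curve.csv"), row.names = FALSE)
  if (length(run$contours)) {
    export_contours(run$contours, file.path(dir, "contours"), format = "obj")
  }
  yaml::write_yaml(run$warnings %||% character(0), file.path(dir, "warnings.yaml"))
  cfg <- run$config
  cfg_log <- lapply(cfg, function(v) {
    if (inherits(v, "comsia_molset")) sprintf("<molecule set: %d molecules>", length(v)) else v
  })
  log <- list(
    config = cfg_log,
    seed = cfg$seed,
    versions = list(
      comsia = as.character(packageVersion("comsia")),
      R = paste(R.version$major, R.version$minor, sep = ".")
    ),
    n_components = run$model$n_components,
    grid = list(
      origin = run$grid$origin, spacing = run$grid$spacing,
      dims = run$grid$dims, padding = run$grid$padding
    )
  )
  yaml::write_yaml(log, file.path(dir, "run_log.yaml"))
  invisible(dir)
}
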