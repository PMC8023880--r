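#' Pipeline run configuration
#'
#' Collects every tunable constant of the measurement-and-validation
#' pipeline in one place: the uncalibrated-radiograph level ratios (1.52
#' condyle widths for the femoral mid-shaft level, 1.42 plateau widths for
#' the tibial one), the meta-/epiphysis transition fraction (0.4 of the
#' main level), the number of cross-validation folds, the regression
#' variant, the FTA definitions to evaluate and the seed.
#'
#' @param schema [knee_schema()] for reading landmark files.
#' @param ratio_femur,ratio_tibia mid-shaft level ratios (> 0).
#' @param metaphysis_fraction meta-/epiphysis level as a fraction of the
#'   main mid-shaft level (0 < f < 1).
#' @param k_folds cross-validation folds (>= 2; additionally checked
#'   against n at run time).
#' @param seed integer seed for the fold assignment.
#' @param definitions subset of [FTA_COMBINATIONS] to evaluate.
#' @param model_variant regression variant passed to [fit_hkaa_model()].
#' @return an object of class `run_config`.
#' @export
run_config <- function(schema = default_knee_schema(),
                       ratio_femur = 1.52, ratio_tibia = 1.42,
                       metaphysis_fraction = 0.4,
                       k_folds = 5, seed = 1L,
                       definitions = FTA_COMBINATIONS,
                       model_variant = c("simple", "quadratic", "sex_adjusted")) {
  model_variant <- match.arg(model_variant)
  stopifnot(inherits(schema, "knee_schema"),
            ratio_femur > 0, ratio_tibia > 0,
            metaphysis_fraction > 0, metaphysis_fraction < 1,
            k_folds >= 2)
  if (!all(definitions %in% FTA_COMBINATIONS)) {
    stop("unknown FTA definitions: ",
         paste(setdiff(definitions, FTA_COMBINATIONS), collapse = ", "),
         call. = FALSE)
  }
  structure(list(schema = schema, ratio_femur = ratio_femur,
                 ratio_tibia = ratio_tibia,
                 metaphysis_fraction = metaphysis_fraction,
                 k_folds = as.integer(k_folds), seed = as.integer(seed),
                 definitions = definitions, model_variant = model_variant),
            class = "run_config")
}

# normalise run_experiment inputs to a list of list(knee, limb, meta)
as_case_list <- function(input, config) {
  if (inherits(input, "synthetic_cohort")) {
    return(list(cases = input$cases, skipped = data.frame(case_id = character(),
                                                          reason = character())))
  }
  if (inherits(input, "knee_cohort")) {
    return(list(cases = input$cases, skipped = input$skipped))
  }
  if (is.character(input) && length(input) == 1) {
    meta_path <- file.path(input, "meta.csv")
    if (!dir.exists(input) || !file.exists(meta_path)) {
      stop("input directory must exist and contain meta.csv: ", input, call. = FALSE)
    }
    cohort <- read_cohort(input, meta_path, schema = config$schema)
    if (length(cohort$cases) == 0) {
      stop("no paired cases found in ", input, call. = FALSE)
    }
    return(list(cases = cohort$cases, skipped = cohort$skipped))
  }
  stop("input must be a directory path, a knee_cohort or a synthetic_cohort",
       call. = FALSE)
}

#' Measure FTA (all definitions) and gold-standard HKAA for a cohort
#'
#' @param input a landmark-tree directory, [read_cohort()] result or
#'   [generate_cohort()] result.
#' @param config a [run_config()].
#' @return list with `fta` (long data frame: case_id, definition,
#'   value_deg, status), `hkaa` (case_id, hkaa_deg), `meta` and `skipped`.
#' @export
measure_cohort <- function(input, config = run_config()) {
  src <- as_case_list(input, config)
  fta <- do.call(rbind, lapply(src$cases, function(case) {
    fta_battery(case$knee, combinations = config$definitions,
                ratio_femur = config$ratio_femur,
                ratio_tibia = config$ratio_tibia,
                metaphysis_fraction = config$metaphysis_fraction)
  }))
  rownames(fta) <- NULL
  hk <- data.frame(
    case_id = vapply(src$cases, function(case) case$meta$case_id, character(1)),
    hkaa_deg = vapply(src$cases, function(case) hkaa(case$limb), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(hk) <- NULL
  meta <- do.call(rbind, lapply(src$cases, function(case) case$meta))
  rownames(meta) <- NULL
  list(fta = fta, hkaa = hk, meta = meta, skipped = src$skipped)
}

#' Run the full measurement-and-validation experiment
#'
#' End-to-end orchestration: measures the FTA under every requested
#' definition and the gold-standard HKAA, then, per definition, predicts
#' the HKAA from the FTA with k-fold cross-validation and summarises
#' agreement (Pearson, absolute-agreement ICC with CI, MAE, Bland-Altman).
#' Per-case or per-definition failures are collected into the `status`
#' column, never silently dropped, and the report always contains one row
#' per requested definition. Definitions are ranked by cross-validated
#' Pearson correlation, ties broken by ICC.
#'
#' @inheritParams measure_cohort
#' @return an object of class `validation_report`: `by_definition` (one
#'   row per definition), `predictions` (per-case out-of-fold predictions),
#'   `measurements`, `hkaa`, `skipped` and a reproducibility `manifest`.
#' @export
run_experiment <- function(input, config = run_config()) {
  meas <- measure_cohort(input, config)
  n_cases <- nrow(meas$hkaa)
  if (config$k_folds > n_cases / 2) {
    stop(sprintf("k_folds = %d requires at least %d cases, got %d",
                 config$k_folds, 2 * config$k_folds, n_cases), call. = FALSE)
  }

  rows <- list()
  predictions <- list()
  for (def in config$definitions) {
    m <- meas$fta[meas$fta$definition == def & meas$fta$status == "ok", ]
    d <- merge(m[, c("case_id", "value_deg")], meas$hkaa, by = "case_id")
    d <- merge(d, meas$meta[, c("case_id", "sex")], by = "case_id")
    d <- d[order(d$case_id), ]
    row <- data.frame(definition = def, n = nrow(d),
                      pearson_all = NA_real_, icc_all = NA_real_,
                      cv_pearson = NA_real_, cv_icc = NA_real_,
                      cv_icc_lower = NA_real_, cv_icc_upper = NA_real_,
                      cv_mae = NA_real_, cv_mae_sd = NA_real_,
                      cv_mae_min = NA_real_, cv_mae_max = NA_real_,
                      ba_bias = NA_real_, ba_loa_lower = NA_real_,
                      ba_loa_upper = NA_real_, status = "ok",
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      if (nrow(d) < 2 * config$k_folds) {
        stop(sprintf("only %d usable cases (need %d)", nrow(d), 2 * config$k_folds))
      }
      all_fit <- fit_hkaa_model(d$value_deg, d$hkaa_deg, sex = d$sex,
                                variant = config$model_variant)
      all_pred <- predict(all_fit, data.frame(fta = d$value_deg, sex = d$sex))
      cv <- kfold_predict(d$value_deg, d$hkaa_deg, sex = d$sex,
                          variant = config$model_variant,
                          k = config$k_folds, seed = config$seed,
                          case_ids = d$case_id)
      summ <- agreement_summary(cv$hkaa, cv$pred, sex = d$sex)
      row$pearson_all <- pearson_r(d$value_deg, d$hkaa_deg)
      row$icc_all <- icc_agreement(d$hkaa_deg, all_pred)$value
      row$cv_pearson <- summ$pearson
      row$cv_icc <- summ$icc$value
      row$cv_icc_lower <- summ$icc$lower
      row$cv_icc_upper <- summ$icc$upper
      row$cv_mae <- summ$mae
      row$cv_mae_sd <- summ$mae_sd
      row$cv_mae_min <- summ$mae_range[1]
      row$cv_mae_max <- summ$mae_range[2]
      row$ba_bias <- summ$bland_altman$bias
      row$ba_loa_lower <- summ$bland_altman$loa_lower
      row$ba_loa_upper <- summ$bland_altman$loa_upper
      cv$definition <- def
      cv$error <- cv$hkaa - cv$pred
      predictions[[def]] <- cv[, c("case_id", "definition", "fold",
                                   "fta", "hkaa", "pred", "error")]
      row
    }, error = function(e) {
      row$status <- paste0("failed: ", conditionMessage(e))
      row
    })
    rows[[def]] <- res
  }
  by_def <- do.call(rbind, rows)
  rownames(by_def) <- NULL
  ord <- order(-replace(by_def$cv_pearson, is.na(by_def$cv_pearson), -Inf),
               -replace(by_def$cv_icc, is.na(by_def$cv_icc), -Inf))
  by_def$rank <- NA_integer_
  by_def$rank[ord] <- seq_len(nrow(by_def))

  preds <- if (length(predictions)) do.call(rbind, predictions) else
    data.frame(case_id = character(), definition = character(), fold = integer(),
               fta = numeric(), hkaa = numeric(), pred = numeric(),
               error = numeric())
  rownames(preds) <- NULL

  manifest <- list(
    package = "kneealign",
    version = as.character(utils::packageVersion("kneealign")),
    seed = config$seed, k_folds = config$k_folds,
    model_variant = config$model_variant,
    ratio_femur = config$ratio_femur, ratio_tibia = config$ratio_tibia,
    metaphysis_fraction = config$metaphysis_fraction,
    schema = config$schema$name, definitions = config$definitions,
    n_cases = n_cases,
    input_hashes = input_hashes(input)
  )
  structure(list(by_definition = by_def, predictions = preds,
                 measurements = meas$fta, hkaa = meas$hkaa,
                 skipped = meas$skipped, manifest = manifest),
            class = "validation_report")
}

input_hashes <- function(input) {
  if (is.character(input) && length(input) == 1 && dir.exists(input)) {
    files <- sort(list.files(input, full.names = TRUE))
    h <- tools::md5sum(files)
    as.list(stats::setNames(unname(h), basename(files)))
  } else if (inherits(input, "synthetic_cohort")) {
    list(cohort_seed = input$seed, n = length(input$cases))
  } else {
    list()
  }
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d cases, %d definitions\n",
              x$manifest$n_cases, nrow(x$by_definition)))
  df <- x$by_definition[order(x$by_definition$rank),
                        c("rank", "definition", "pearson_all", "cv_pearson",
                          "cv_icc", "cv_mae", "status")]
  df[3:6] <- lapply(df[3:6], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a validation report as CSV files plus a JSON manifest
#'
#' Emits `agreement_by_definition.csv`, `predictions.csv`,
#' `measurements.csv`, `hkaa.csv`, `skipped.csv` and `manifest.json`.
#' Output is deterministic: identical inputs and seed give byte-identical
#' files.
#'
#' @param report a `validation_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$by_definition,
                   file.path(dir, "agreement_by_definition.csv"), row.names = FALSE)
  utils::write.csv(report$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(report$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(report$hkaa, file.path(dir, "hkaa.csv"), row.names = FALSE)
  utils::write.csv(report$skipped, file.path(dir, "skipped.csv"), row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Bland-Altman plot of cross-validated predictions
#'
#' Differences (observed - predicted) against the predicted HKAA by
#' default (see [bland_altman()] for why the classical pairwise-mean
#' abscissa is biased for regression predictions; it remains available via
#' `abscissa = "mean"`), with the bias and limits of agreement drawn as
#' horizontal lines. Requires ggplot2.
#'
#' @param report a `validation_report`.
#' @param definition which FTA definition's predictions to plot.
#' @param abscissa `"predicted"` or `"mean"`.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(report, definition = "Fem2+Tib1",
                              abscissa = c("predicted", "mean")) {
  abscissa <- match.arg(abscissa)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_bland_altman requires ggplot2", call. = FALSE)
  }
  d <- report$predictions[report$predictions$definition == definition, ]
  if (!nrow(d)) stop("no predictions for definition ", definition, call. = FALSE)
  ba <- bland_altman(d$hkaa, d$pred)
  df <- data.frame(x = if (abscissa == "predicted") d$pred else (d$hkaa + d$pred) / 2,
                   diff = d$hkaa - d$pred)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$bias) +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(
      x = if (abscissa == "predicted") "Predicted HKAA (deg)" else
        "Mean of observed and predicted HKAA (deg)",
      y = "Observed - predicted HKAA (deg)",
      title = paste("Bland-Altman:", definition)) +
    ggplot2::theme_minimal()
}
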