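# Orchestration: feature table -> filtered, cross-validated PLS models for
# the three outcomes, with table-shaped reports.

#' Fit one filtered, cross-validated PLS determinant model
#'
#' The statistical engine applied to one response: z-score standardization,
#' |r| > 0.95 correlation filter, VIF > 10 filter, 10-fold cross-validated
#' component selection by RMSECV, final NIPALS fit, VIP scores, max-|weight|
#' component assignment, and per-component F-test p-values.
#'
#' In `"paper_faithful"` mode the filters are applied once to the full data
#' before cross-validation; `"leak_free"` refits them inside every training
#' fold.
#'
#' @param features feature table (data.frame).
#' @param response one of `"ct"`, `"ht"`, `"rsi"` (or any column name).
#' @param config a [run_config()].
#' @return list of class `pls_report`: `model`, `assignment` (report
#'   table), `filter_cor`, `filter_vif`, `cv`, `p_values`, `metrics`.
#' @export
fit_determinant_model <- function(features, response, config = run_config()) {
  stopifnot(response %in% names(features))
  outcomes <- intersect(c("ct", "ht", "rsi"), names(features))
  y <- features[[response]]
  X <- as.matrix(features[, setdiff(names(features), outcomes), drop = FALSE])

  zs <- zscore_columns(X)
  cf <- correlation_filter(zs$scaled, config$cor_threshold)
  vf <- vif_filter(zs$scaled[, cf$retained, drop = FALSE], config$vif_threshold)
  keep <- vf$retained
  Xk <- X[, keep, drop = FALSE]

  maxc <- min(config$cv$max_components, qr(scale(Xk))$rank,
              nrow(Xk) - ceiling(nrow(Xk) / config$cv$folds) - 2)
  cv <- cross_validate_components(
    Xk, y, k = config$cv$folds, max_components = maxc,
    seed = config$cv$seed,
    refit_filters = identical(config$filter_mode, "leak_free"),
    cor_threshold = config$cor_threshold,
    vif_threshold = config$vif_threshold)

  model <- fit_pls(Xk, y, cv$selected)
  assignment <- assign_variables_to_components(model)
  pv <- model_p_value(model)
  metrics <- data.frame(
    n_components = seq_len(model$n_components),
    r2y_cum_pct = model$r2y_cum,
    q2 = cv$q2[seq_len(model$n_components)],
    rmsecv = cv$rmsecv[seq_len(model$n_components)],
    p_value = pv)
  structure(list(response = response, model = model,
                 assignment = assignment, filter_cor = cf, filter_vif = vf,
                 cv = cv, p_values = pv, metrics = metrics,
                 vip_threshold = config$vip_threshold),
            class = "pls_report")
}

#' @export
print.pls_report <- function(x, ...) {
  cat(sprintf("<pls_report [%s]: %d components, R2Y = %.1f%%, Q2 = %.2f, RMSECV = %.2f>\n",
              x$response, x$model$n_components,
              x$model$r2y_cum[x$model$n_components],
              x$cv$q2[x$model$n_components],
              x$cv$rmsecv[x$model$n_components]))
  nimp <- sum(x$assignment$important)
  cat(sprintf("  %d of %d retained predictors with VIP > %g\n",
              nimp, nrow(x$assignment), x$vip_threshold))
  invisible(x)
}

#' Descriptive summary of a feature table
#'
#' Mean, SD, minimum and maximum per variable, with units.
#'
#' @param features feature table.
#' @return data.frame `variable`, `unit`, `mean`, `sd`, `min`, `max`.
#' @export
describe_features <- function(features) {
  units <- attr(features, "units")
  data.frame(
    variable = names(features),
    unit = if (is.null(units)) "" else unname(units[names(features)]),
    mean = vapply(features, mean, numeric(1)),
    sd = vapply(features, stats::sd, numeric(1)),
    min = vapply(features, min, numeric(1)),
    max = vapply(features, max, numeric(1)),
    row.names = NULL)
}

#' Run the full statistical pipeline
#'
#' From a feature table (or a simulated cohort), produces the descriptive
#' summary and the three PLS determinant models (contact time, jump height,
#' RSI), writes the report CSVs and a JSON metrics file to
#' `config$out_dir`, and logs filter removals and selected component counts.
#'
#' @param features feature table data.frame, or path to a feature-table CSV.
#' @param config a [run_config()].
#' @param write write report files to `config$out_dir`.
#' @param quiet suppress log messages.
#' @return list `descriptive`, `models` (per response `pls_report`),
#'   `paths` (written files, if any).
#' @export
run_pipeline <- function(features, config = run_config(), write = FALSE,
                         quiet = TRUE) {
  if (is.character(features)) features <- read_feature_table(features)
  need <- c("ct", "ht", "rsi")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("feature table lacks outcome column(s): ", paste(miss, collapse = ", "))
  if (anyNA(features)) stop("feature table contains missing cells")
  say <- function(...) if (!quiet) message(...)

  desc <- describe_features(features)
  models <- lapply(stats::setNames(need, need), function(resp) {
    rep <- fit_determinant_model(features, resp, config)
    say(sprintf("[%s] correlation filter removed %d, VIF filter removed %d, ",
                resp, nrow(rep$filter_cor$removed), nrow(rep$filter_vif$removed)),
        sprintf("selected %d component(s)", rep$model$n_components))
    for (nm in rep$filter_cor$removed$name)
      say("  removed (|r| > ", config$cor_threshold, "): ", nm)
    for (nm in rep$filter_vif$removed$name)
      say("  removed (VIF > ", config$vif_threshold, "): ", nm)
    rep
  })

  paths <- character()
  if (write) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(config$out_dir, "descriptives.csv")
    utils::write.csv(desc, p, row.names = FALSE); paths <- c(paths, p)
    metrics <- list()
    for (resp in need) {
      rp <- models[[resp]]
      p <- file.path(config$out_dir, paste0("pls_", resp, ".csv"))
      tab <- rp$assignment
      tab$r2y_cum_pct <- rp$metrics$r2y_cum_pct[tab$component]
      tab$q2 <- rp$metrics$q2[tab$component]
      tab$rmsecv <- rp$metrics$rmsecv[tab$component]
      tab$p_value <- rp$metrics$p_value[tab$component]
      utils::write.csv(tab, p, row.names = FALSE); paths <- c(paths, p)
      metrics[[resp]] <- list(
        n_components = rp$model$n_components,
        r2y_cum_pct = rp$metrics$r2y_cum_pct,
        q2 = rp$metrics$q2, rmsecv = rp$metrics$rmsecv,
        p_value = unname(rp$metrics$p_value),
        removed_correlation = rp$filter_cor$removed$name,
        removed_vif = rp$filter_vif$removed$name,
        retained = rp$filter_vif$retained)
    }
    p <- file.path(config$out_dir, "metrics.json")
    jsonlite::write_json(metrics, p, auto_unbox = TRUE, digits = 10)
    paths <- c(paths, p)
  }
  list(descriptive = desc, models = models, paths = paths)
}
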