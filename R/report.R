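#' Run the full excess-cost pipeline
#'
#' Orchestrates simulate (optional) -> cohort filter -> coding -> costing ->
#' above-average selection -> two-step regression -> summary tables, with a
#' run log that accounts for every excluded episode (input rows = retained +
#' sum of exclusions, mirroring the cohort-waterfall style of administrative
#' studies). Deterministic given the configuration and seed.
#'
#' @param config Named list (or path to a JSON file) with entries:
#'   \describe{
#'     \item{episodes, drg_reference}{paths to CSVs or data.frames. Ignored
#'       when `simulate` is given.}
#'     \item{simulate}{optional list of [simulate_config()] arguments; when
#'       present the pipeline generates its own input data (the ground-truth
#'       sidecar is returned but never consumed by later stages).}
#'     \item{rules}{optional complication rule table or path; defaults to the
#'       packaged rules.}
#'     \item{min_age, max_los, lookback_years}{filter and linkage
#'       parameters; defaults 50, 90, 2.}
#'     \item{back_transform_method, complication_coding}{passed to
#'       [fit_excess_cost()].}
#'     \item{out_dir}{optional directory; when set, the coded table, excess
#'       table, regression result (JSON), both summary tables, the run log
#'       and the effect chart are written there.}
#'   }
#' @return Invisibly, a list with `coded`, `excess`, `analysis` (the merged
#'   above-average modelling table), `fit`, `table1`, `table2`, `log`, and
#'   `truth` when simulated.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  cfg <- config
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim_cfg <- do.call(simulate_config, as.list(cfg$simulate))
    ref <- generate_drg_reference(sim_cfg)
    sim <- generate_episodes(sim_cfg, ref)
    episodes <- sim$episodes
    truth <- sim$truth
  } else {
    episodes <- cfg$episodes
    if (is.character(episodes)) episodes <- read_episodes(episodes)
    ref <- cfg$drg_reference
    if (is.character(ref)) ref <- read_drg_reference(ref)
  }
  rules <- cfg$rules
  if (is.null(rules)) rules <- default_complication_rules()
  if (is.character(rules)) rules <- default_complication_rules(rules)

  min_age <- if (is.null(cfg$min_age)) 50 else cfg$min_age
  max_los <- if (is.null(cfg$max_los)) 90 else cfg$max_los
  lookback <- if (is.null(cfg$lookback_years)) 2 else cfg$lookback_years

  n_input <- nrow(episodes)
  filtered <- filter_cohort(episodes, min_age = min_age, max_los = max_los)
  coded <- code_episodes(filtered$episodes, rules = rules,
                         lookback_years = lookback)
  excess <- compute_excess_cost(coded, ref)
  coded$cost_weight <- ref$cost_weight[match(coded$drg, ref$drg)]
  analysis <- cbind(coded,
                    excess[, c("above_average", "extra_days",
                               "daily_variable_cost", "extra_cost")])
  analysis <- select_above_average(analysis)

  log <- rbind(
    data.frame(reason = "input", n = n_input, stringsAsFactors = FALSE),
    filtered$exclusions,
    data.frame(reason = "not_above_average",
               n = nrow(coded) - nrow(analysis), stringsAsFactors = FALSE),
    data.frame(reason = "retained", n = nrow(analysis),
               stringsAsFactors = FALSE)
  )

  bt <- if (is.null(cfg$back_transform_method)) "mean_multiplicative" else
    cfg$back_transform_method
  ccod <- if (is.null(cfg$complication_coding)) "count" else
    cfg$complication_coding
  fit <- fit_excess_cost(analysis, back_transform_method = bt,
                         complication_coding = ccod)
  tabs <- render_summary_tables(analysis, fit)

  bundle <- list(coded = coded, excess = excess, analysis = analysis,
                 fit = fit, table1 = tabs$table1, table2 = tabs$table2,
                 log = log, truth = truth)
  if (!is.null(cfg$out_dir)) {
    write_bundle(bundle, cfg$out_dir)
  }
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(bundle$coded, file.path(out_dir, "coded_episodes.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$excess, file.path(out_dir, "excess_cost.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$table1, file.path(out_dir, "table1.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$table2, file.path(out_dir, "table2.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$log, file.path(out_dir, "run_log.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as_result_list(bundle$fit),
                       file.path(out_dir, "regression_result.json"),
                       auto_unbox = TRUE, digits = NA)
  render_effect_chart(bundle$fit, file.path(out_dir, "effect_chart.png"))
  invisible(out_dir)
}

#' Flatten a fit to a plain list for machine-readable output
#'
#' @param fit An `excess_cost_fit`.
#' @return Named list of unrounded coefficients and fit statistics, suitable
#'   for `jsonlite::write_json()`.
#' @export
as_result_list <- function(fit) {
  list(
    coefficients = fit$coefficients,
    r2_step1 = fit$r2_step1,
    r2_step2 = fit$r2_step2,
    adj_r2 = fit$adj_r2,
    f_value = fit$f_value,
    n = fit$n,
    n_dropped = fit$n_dropped,
    mean_extra_cost = fit$mean_extra_cost,
    back_transform_method = fit$back_transform_method,
    complication_coding = fit$complication_coding
  )
}

#' Summary tables for the analysis sample and the fitted model
#'
#' A descriptive table (mean/min/max of admission severity, Charlson index,
#' age, excess cost and complication count over the above-average sample)
#' and a regression table (dollar effect, standardised beta and
#' percentage-of-mean-cost per predictor, with the fit statistics attached
#' as an attribute). Values are unrounded; rounding belongs to rendering.
#'
#' @param analysis The merged above-average modelling table (as produced by
#'   [run_pipeline()]), containing `cost_weight`, `charlson`, `age`,
#'   `extra_cost`, `n_complications`.
#' @param fit The corresponding `excess_cost_fit`.
#' @return List with `table1` and `table2` data.frames; `table2` carries
#'   `attr(, "stats")` with r2/adj r2/F/n.
#' @export
render_summary_tables <- function(analysis, fit) {
  vars <- c("cost_weight", "charlson", "age", "extra_cost",
            "n_complications")
  labels <- c("Admission severity (cost weight)",
              "Comorbidity (Charlson Index)",
              "Age (years)", "Extra cost", "Complications (number of)")
  present <- vars %in% names(analysis)
  table1 <- data.frame(
    variable = labels[present],
    mean = vapply(vars[present], function(v) mean(analysis[[v]]), 0),
    min = vapply(vars[present], function(v) min(analysis[[v]]), 0),
    max = vapply(vars[present], function(v) max(analysis[[v]]), 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  table2 <- fit$coefficients[, c("term", "b_dollars", "beta_std",
                                 "pct_of_mean")]
  attr(table2, "stats") <- data.frame(
    r2_step1 = fit$r2_step1, r2_step2 = fit$r2_step2, adj_r2 = fit$adj_r2,
    f_value = fit$f_value, n = fit$n,
    mean_extra_cost = fit$mean_extra_cost
  )
  list(table1 = table1, table2 = table2)
}

#' Write the effect-size bar chart
#'
#' One bar per predictor at its back-transformed dollar effect. Alongside
#' the image a `*_data.csv` sidecar records the plotted values so the chart
#' content is machine-checkable.
#'
#' @param fit An `excess_cost_fit`.
#' @param file Output image path; `.png` or `.pdf` decides the device. If
#'   the PNG device is unavailable the chart falls back to PDF.
#' @return Invisibly, a list with `file` (the image actually written),
#'   `data_file`, and `data` (term + dollar effect).
#' @export
render_effect_chart <- function(fit, file) {
  dat <- fit$coefficients[, c("term", "b_dollars")]
  ext <- tolower(tools::file_ext(file))
  draw <- function() {
    op <- graphics::par(mar = c(9, 4, 2, 1))
    on.exit(graphics::par(op))
    graphics::barplot(stats::setNames(dat$b_dollars, dat$term),
                      ylab = "Effect on excess cost",
                      main = "Effect of coefficient", las = 2)
  }
  opened <- FALSE
  if (ext == "pdf") {
    grDevices::pdf(file, width = 7, height = 5)
    opened <- TRUE
  } else {
    opened <- tryCatch({
      grDevices::png(file, width = 800, height = 600)
      TRUE
    }, error = function(e) FALSE)
    if (!opened) {
      file <- paste0(tools::file_path_sans_ext(file), ".pdf")
      grDevices::pdf(file, width = 7, height = 5)
      opened <- TRUE
    }
  }
  draw()
  grDevices::dev.off()
  data_file <- paste0(tools::file_path_sans_ext(file), "_data.csv")
  utils::write.csv(dat, data_file, row.names = FALSE)
  invisible(list(file = file, data_file = data_file, data = dat))
}
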