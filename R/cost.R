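#' Validate a DRG reference table
#'
#' A DRG reference has one row per Diagnosis Related Group with the average
#' overnight length of stay (day-stays removed), the cost weight (estimated
#' average episode cost relative to the all-separations average, used here as
#' the admission-severity proxy) and sixteen treatment-expense subcategory
#' amounts partitioned into eleven variable and five fixed categories.
#'
#' @param ref Data.frame with columns `drg`, `avg_overnight_los`,
#'   `cost_weight` and all sixteen subcategory columns (exact labels from
#'   [variable_subcategories()] and [fixed_subcategories()]).
#' @return The validated reference (invisibly classed `drg_reference`).
#' @export
validate_drg_reference <- function(ref) {
  subcats <- c(variable_subcategories(), fixed_subcategories())
  missing <- setdiff(c("drg", "avg_overnight_los", "cost_weight", subcats),
                     names(ref))
  if (length(missing)) {
    stop("DRG reference is missing columns: ",
         paste(sQuote(missing), collapse = ", "))
  }
  extra <- setdiff(names(ref), c("drg", "avg_overnight_los", "cost_weight",
                                 subcats))
  if (length(extra)) {
    stop("unclassified subcategory column(s) in DRG reference: ",
         paste(sQuote(extra), collapse = ", "))
  }
  if (anyDuplicated(ref$drg)) stop("duplicated DRG codes in reference")
  if (any(!is.finite(ref$avg_overnight_los)) || any(ref$avg_overnight_los <= 0)) {
    stop("avg_overnight_los must be > 0 for every DRG")
  }
  if (any(!is.finite(ref$cost_weight)) || any(ref$cost_weight <= 0)) {
    stop("cost_weight must be > 0 for every DRG")
  }
  amounts <- as.matrix(ref[, subcats, drop = FALSE])
  if (any(!is.finite(amounts)) || any(amounts < 0)) {
    stop("subcategory amounts must be non-negative")
  }
  class(ref) <- unique(c("drg_reference", class(ref)))
  invisible(ref)
}

#' Split DRG costs into variable and fixed totals
#'
#' Variable costs accrue per day in hospital (ward nursing, pharmacy, hotel,
#' ...); fixed costs are one-off per episode (operating rooms, emergency
#' departments, ...). Their totals partition the episode's full subcategory
#' cost.
#'
#' @param ref DRG reference table (see [validate_drg_reference()]).
#' @return Data.frame with columns `drg`, `variable_total`, `fixed_total`.
#' @export
#' @seealso [daily_variable_cost()]
split_costs <- function(ref) {
  validate_drg_reference(ref)
  vt <- rowSums(as.matrix(ref[, variable_subcategories(), drop = FALSE]))
  ft <- rowSums(as.matrix(ref[, fixed_subcategories(), drop = FALSE]))
  data.frame(drg = ref$drg, variable_total = unname(vt),
             fixed_total = unname(ft), stringsAsFactors = FALSE)
}

#' Daily variable cost per DRG
#'
#' The variable cost total divided by the DRG's average overnight length of
#' stay: the per-day price attached to each extra day beyond the average.
#'
#' @param ref DRG reference table.
#' @return Named numeric vector (names are DRG codes), currency per day.
#' @export
daily_variable_cost <- function(ref) {
  validate_drg_reference(ref)
  s <- split_costs(ref)
  stats::setNames(s$variable_total / ref$avg_overnight_los, ref$drg)
}

#' Excess days and excess (variable) cost per episode
#'
#' An episode is *above average* when it stayed strictly longer than the
#' all-ages overnight average for its DRG. Its extra days are
#' `los_days - avg_overnight_los` (a real number; the average is generally
#' fractional and no rounding is applied), and its extra cost prices those
#' days at the DRG's daily variable cost -- one-off fixed costs do not grow
#' with the stay and are excluded. Episodes at or below the average get zero
#' extra days and zero extra cost.
#'
#' @param episodes Episode data.frame (or any data.frame with `episode_id`,
#'   `drg`, `los_days`).
#' @param ref DRG reference table covering every DRG present.
#' @return Data.frame with columns `episode_id`, `drg`, `los_days`,
#'   `above_average`, `extra_days`, `daily_variable_cost`, `extra_cost`.
#' @export
#' @examples
#' \dontrun{
#' xc <- compute_excess_cost(episodes, drg_ref)
#' summary(xc$extra_cost[xc$above_average])
#' }
compute_excess_cost <- function(episodes, ref) {
  validate_drg_reference(ref)
  idx <- match(episodes$drg, ref$drg)
  if (anyNA(idx)) {
    missing <- sort(unique(episodes$drg[is.na(idx)]))
    stop("episode DRG code(s) not in reference: ",
         paste(missing, collapse = ", "))
  }
  dvc <- unname(daily_variable_cost(ref)[idx])
  extra_days <- pmax(0, episodes$los_days - ref$avg_overnight_los[idx])
  data.frame(
    episode_id = episodes$episode_id,
    drg = episodes$drg,
    los_days = episodes$los_days,
    above_average = extra_days > 0,
    extra_days = extra_days,
    daily_variable_cost = dvc,
    extra_cost = extra_days * dvc,
    stringsAsFactors = FALSE
  )
}

#' Keep only above-average-stay episodes
#'
#' The analysis sample: episodes that stayed strictly longer than their DRG
#' average. Everything downstream (the log-cost regression, the summary
#' tables) uses this subset, since only the excess component of stay is
#' considered modifiable.
#'
#' @param records Output of [compute_excess_cost()].
#' @return The subset of rows with `above_average` TRUE.
#' @export
select_above_average <- function(records) {
  records[records$above_average, , drop = FALSE]
}
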