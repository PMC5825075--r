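#' Apply the cohort filters to an episode table
#'
#' Retains overnight episodes of patients at or above the minimum age with
#' length of stay between one day and the trim point. Day-stays (LOS < 1),
#' under-age episodes and very long stays are excluded, each counted under its
#' own reason so the run log can reproduce the cohort waterfall. Ages at the
#' boundary are retained (age >= `min_age`); stays strictly beyond `max_los`
#' are dropped.
#'
#' @param episodes Episode data.frame; see [read_episodes()] for the layout.
#' @param min_age Minimum age in years, inclusive. Default 50.
#' @param max_los Maximum length of stay in days, inclusive. Default 90,
#'   the usual trim for hospital-acquired-complication analyses.
#' @return List with `episodes` (retained rows) and `exclusions`, a data.frame
#'   of `reason` (`"day_stay"`, `"age_lt_min"`, `"los_gt_max"`) and `n`.
#'   Each excluded episode is counted once, under the first failing rule in
#'   the order day-stay, age, long-stay.
#' @export
#' @examples
#' eps <- data.frame(person_id = "p1", episode_id = c("e1", "e2"),
#'                   age = c(49, 80), sex = "female", los_days = c(3, 95),
#'                   drg = "D001", principal_dx = "I10", additional_dx = "",
#'                   surgical = FALSE, admission_date = as.Date("2006-10-01"))
#' filter_cohort(eps)$exclusions
filter_cohort <- function(episodes, min_age = 50, max_los = 90) {
  validate_episodes(episodes)
  day_stay <- episodes$los_days < 1
  age_lt <- !day_stay & episodes$age < min_age
  los_gt <- !day_stay & !age_lt & episodes$los_days > max_los
  keep <- !(day_stay | age_lt | los_gt)
  exclusions <- data.frame(
    reason = c("day_stay", "age_lt_min", "los_gt_max"),
    n = c(sum(day_stay), sum(age_lt), sum(los_gt)),
    stringsAsFactors = FALSE
  )
  list(episodes = episodes[keep, , drop = FALSE], exclusions = exclusions)
}

episode_columns <- function() {
  c("person_id", "episode_id", "age", "sex", "los_days", "drg",
    "principal_dx", "additional_dx", "surgical", "admission_date")
}

validate_episodes <- function(episodes) {
  missing <- setdiff(episode_columns(), names(episodes))
  if (length(missing)) {
    stop("episode table is missing columns: ", paste(missing, collapse = ", "))
  }
  problems <- character(0)
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      sprintf("row %d: %s", utils::head(idx, 5L), what)
    } else {
      character(0)
    }
  }
  pdx <- normalize_icd10(episodes$principal_dx)
  problems <- c(
    problems,
    bad(is.na(episodes$age) | episodes$age < 0, "invalid age"),
    bad(is.na(episodes$los_days) | episodes$los_days < 0, "invalid los_days"),
    bad(!nzchar(pdx) | !grepl("^[A-Z][0-9]+[A-Z0-9]*$", pdx),
        "principal_dx does not look like an ICD-10 code"),
    bad(!episodes$sex %in% c("male", "female"), "sex must be male/female")
  )
  if (length(problems)) {
    stop("malformed episode rows:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(episodes)
}

#' Person-linked dementia ascertainment
#'
#' Flags a person as having dementia if *any* of their episodes admitted
#' within the lookback window carries a qualifying code as principal or
#' additional diagnosis. The flag then propagates to all episodes of that
#' person: dementia is a person-level attribute, ascertained over a two-year
#' linkage window by default to minimise misclassification from single-stay
#' coding.
#'
#' @param episodes Episode data.frame (must include `admission_date`).
#' @param codes Qualifying ICD-10 prefixes; default [dementia_codes()].
#' @param lookback_years Length of the lookback window in years; default 2.
#' @param window_end Date anchoring the window end; default the latest
#'   admission date present. Episodes admitted in
#'   `[window_end - lookback_years, window_end]` are searched.
#' @return Named logical vector, one element per person_id.
#' @export
flag_dementia <- function(episodes, codes = dementia_codes(),
                          lookback_years = 2,
                          window_end = max(episodes$admission_date)) {
  if (nrow(episodes) == 0L) return(stats::setNames(logical(0), character(0)))
  if (any(is.na(episodes$admission_date))) {
    stop("admission_date must be present for dementia ascertainment")
  }
  window_end <- as.Date(window_end)
  window_start <- window_end - round(lookback_years * 365.25)
  in_window <- episodes$admission_date >= window_start &
    episodes$admission_date <= window_end
  codes <- normalize_icd10(codes)
  hit <- logical(nrow(episodes))
  idx <- which(in_window)
  if (length(idx)) {
    pdx <- normalize_icd10(episodes$principal_dx[idx])
    hit_p <- rep(FALSE, length(idx))
    for (p in codes) hit_p <- hit_p | startsWith(pdx, p)
    hit_a <- codes_match_by_row(episodes$additional_dx[idx], codes)
    hit[idx] <- hit_p | hit_a
  }
  persons <- unique(episodes$person_id)
  flagged <- tapply(hit, episodes$person_id, any)
  out <- as.logical(flagged[as.character(persons)])
  names(out) <- persons
  out
}

# For a character vector of semicolon-joined additional-diagnosis fields,
# returns TRUE per row where any code starts with any prefix. Works on the
# long (row, code) representation so large tables stay vectorised.
codes_match_by_row <- function(additional_dx, prefixes) {
  n <- length(additional_dx)
  out <- logical(n)
  if (n == 0L || length(prefixes) == 0L) return(out)
  additional_dx[is.na(additional_dx)] <- ""
  parts <- strsplit(additional_dx, ";", fixed = TRUE)
  lens <- lengths(parts)
  if (sum(lens) == 0L) return(out)
  row_of <- rep.int(seq_len(n), lens)
  code <- normalize_icd10(unlist(parts, use.names = FALSE))
  keep <- nzchar(code)
  row_of <- row_of[keep]
  code <- code[keep]
  hit <- rep(FALSE, length(code))
  for (p in prefixes) hit <- hit | startsWith(code, p)
  if (any(hit)) out[unique(row_of[hit])] <- TRUE
  out
}

#' Modified Charlson comorbidity index for one diagnosis list
#'
#' Sums condition weights over the *distinct* Charlson conditions present in
#' a set of diagnosis codes. Each condition contributes at most once no
#' matter how many of its codes appear, so the score is idempotent under code
#' duplication and invariant to code order. Dementia is always excluded from
#' the index -- it is modelled as a standalone predictor -- in addition to any
#' conditions named in `exclude`. Codes that map to no condition are ignored.
#'
#' @param dx_codes Character vector of ICD-10 codes (principal + additional).
#' @param map Condition map; default [default_charlson_map()].
#' @param exclude Further condition names to exclude.
#' @return Integer score >= 0.
#' @export
#' @examples
#' compute_charlson(c("E11", "C50"))   # diabetes (1) + any cancer (2) = 3
#' compute_charlson("G30")             # dementia alone scores 0
compute_charlson <- function(dx_codes, map = default_charlson_map(),
                             exclude = character(0)) {
  codes <- normalize_icd10(dx_codes)
  codes <- codes[nzchar(codes)]
  exclude <- union(exclude, "dementia")
  total <- 0L
  for (i in seq_len(nrow(map))) {
    if (map$condition[i] %in% exclude) next
    if (match_any_prefix(codes, split_codes(map$codes[i]))) {
      total <- total + map$weight[i]
    }
  }
  as.integer(total)
}

# Vectorised Charlson over an episode table (principal + additional codes),
# excluding dementia. Long-format prefix matching keeps this O(codes x prefixes).
charlson_scores <- function(episodes, map = default_charlson_map()) {
  n <- nrow(episodes)
  if (n == 0L) return(integer(0))
  map <- map[map$condition != "dementia", , drop = FALSE]
  add <- episodes$additional_dx
  add[is.na(add)] <- ""
  joined <- ifelse(nzchar(add),
                   paste(episodes$principal_dx, add, sep = ";"),
                   as.character(episodes$principal_dx))
  parts <- strsplit(joined, ";", fixed = TRUE)
  lens <- lengths(parts)
  row_of <- rep.int(seq_len(n), lens)
  code <- normalize_icd10(unlist(parts, use.names = FALSE))
  keep <- nzchar(code)
  row_of <- row_of[keep]
  code <- code[keep]
  score <- numeric(n)
  for (i in seq_len(nrow(map))) {
    hit <- rep(FALSE, length(code))
    for (p in split_codes(map$codes[i])) hit <- hit | startsWith(code, p)
    rows_with <- unique(row_of[hit])   # distinct condition: count once
    score[rows_with] <- score[rows_with] + map$weight[i]
  }
  as.integer(score)
}

#' Flag nurse-sensitive hospital-acquired complications
#'
#' A complication is flagged when at least one of its inclusion codes matches
#' an *additional* diagnosis and no exclusion code matches within the rule's
#' scope. Principal-diagnosis matches of inclusion codes never count: a
#' condition the patient was admitted with is not hospital-acquired. The
#' exclusion scope is `"principal_only"` (aetiology blocked only when it is
#' the reason for admission, as for urinary-tract principal diagnoses vs UTI)
#' or `"principal_or_additional"` (blocked anywhere on the record, as for
#' paralysis vs pressure injury).
#'
#' @param episodes Episode data.frame (one or many rows).
#' @param rules Complication rule table; default [default_complication_rules()].
#' @return Logical matrix with one row per episode and one column per
#'   complication, in the rule table's order.
#' @export
flag_complications <- function(episodes, rules = default_complication_rules()) {
  rules <- validate_rules(rules)
  n <- nrow(episodes)
  out <- matrix(FALSE, nrow = n, ncol = nrow(rules),
                dimnames = list(NULL, rules$name))
  if (n == 0L) return(out)
  pdx <- normalize_icd10(episodes$principal_dx)
  for (i in seq_len(nrow(rules))) {
    inc <- split_codes(rules$inclusion_codes[i])
    exc <- split_codes(rules$exclusion_codes[i])
    included <- codes_match_by_row(episodes$additional_dx, inc)
    excluded_p <- rep(FALSE, n)
    for (p in exc) excluded_p <- excluded_p | startsWith(pdx, p)
    excluded <- excluded_p
    if (rules$exclusion_scope[i] == "principal_or_additional") {
      excluded <- excluded | codes_match_by_row(episodes$additional_dx, exc)
    }
    out[, i] <- included & !excluded
  }
  out
}

#' Code an episode table for dementia, comorbidity and complications
#'
#' Composes [flag_dementia()], [charlson_scores()][compute_charlson] and
#' [flag_complications()] into one pass, returning the episode table augmented
#' with a person-level dementia flag, the modified Charlson index, one logical
#' column per complication and the complication count.
#'
#' @param episodes Episode data.frame (already cohort-filtered; see
#'   [filter_cohort()]).
#' @param rules Complication rule table.
#' @param charlson_map Charlson condition map.
#' @param dementia_codes Qualifying dementia code prefixes.
#' @param lookback_years,window_end Passed to [flag_dementia()].
#' @return The episode data.frame with columns `dementia`, `charlson`, one
#'   logical column per complication, and `n_complications` appended.
#' @export
code_episodes <- function(episodes,
                          rules = default_complication_rules(),
                          charlson_map = default_charlson_map(),
                          dementia_codes = excesscost::dementia_codes(),
                          lookback_years = 2,
                          window_end = max(episodes$admission_date)) {
  validate_episodes(episodes)
  coded <- episodes
  if (nrow(episodes)) {
    dem <- flag_dementia(episodes, codes = dementia_codes,
                         lookback_years = lookback_years,
                         window_end = window_end)
    coded$dementia <- unname(dem[as.character(episodes$person_id)])
  } else {
    coded$dementia <- logical(0)
  }
  coded$charlson <- charlson_scores(episodes, charlson_map)
  flags <- flag_complications(episodes, rules)
  for (nm in colnames(flags)) coded[[nm]] <- flags[, nm]
  coded$n_complications <- as.integer(rowSums(flags))
  coded
}
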