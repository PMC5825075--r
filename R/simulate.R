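#' Configuration for the synthetic discharge-data generator
#'
#' Defines the conditions the generator emulates: an administrative
#' episode-level discharge extract for an over-50 overnight hospital
#' population, with person-linked dementia, four independently-assigned
#' nurse-sensitive complications, Charlson comorbidities, and a Gaussian
#' log-linear model for the excess cost of above-average stays. Default
#' prevalences match the study population this pipeline targets (11.9%
#' dementia, 8.2% UTI, 2.6% pressure injury, 3.7% pneumonia, 1.9% delirium,
#' 23.7% surgical, 47% male); default effects are on the natural-log cost
#' scale (e.g. dementia 0.14, 0.13 per complication, 0.05 per cost-weight
#' unit, 0.04 per Charlson point, 0.003 per year of age) with residual SD
#' 0.9. About 37% of episodes are assigned an above-average stay, the rest
#' fall at or below their DRG average.
#'
#' @param n_persons Number of persons. Each person contributes
#'   `episodes_per_person` episodes on average.
#' @param episodes_per_person Mean episodes per person (>= 1). With the
#'   default 1 every person has exactly one episode; larger values add
#'   Poisson-distributed extra episodes.
#' @param n_drgs Number of Diagnosis Related Groups in the reference table.
#' @param window_start,window_end Admission-date window; must span at least
#'   two calendar years so the person-level dementia lookback is exercised.
#' @param prevalence Named list of probabilities: `dementia` (per person),
#'   `urinary_tract_infection`, `pressure_injury`, `pneumonia`, `delirium`,
#'   `surgery` (per episode), `male` (per person).
#' @param true_effects Named list of log-scale coefficients: `intercept`,
#'   `age` (per year), `male`, `surgical`, `dementia`, `cost_weight`,
#'   `charlson`, `n_complications` (per complication).
#' @param noise_sd Residual standard deviation of log excess cost (> 0).
#' @param p_above_average Probability an episode is assigned an
#'   above-average stay.
#' @param comorbidity_rate Poisson mean of Charlson conditions per episode.
#' @param daily_cost_mean Mean daily variable cost across DRGs (currency per
#'   day). Per-day ward costs vary only mildly between DRGs, so severity
#'   loads on the one-off fixed components instead; this also keeps
#'   generated excess stays well clear of the one-day rounding grid.
#' @param fixed_cost_per_weight Fixed (one-off) cost per unit of cost
#'   weight: sicker DRGs spend more on theatres, critical care and
#'   prostheses.
#' @param seed Integer seed governing all randomness.
#' @return A validated list of class `excess_sim_config`.
#' @export
#' @examples
#' cfg <- simulate_config(n_persons = 500, seed = 42)
simulate_config <- function(n_persons = 20000,
                            episodes_per_person = 1,
                            n_drgs = 30,
                            window_start = as.Date("2005-07-01"),
                            window_end = as.Date("2007-06-30"),
                            prevalence = list(
                              dementia = 0.119,
                              urinary_tract_infection = 0.082,
                              pressure_injury = 0.026,
                              pneumonia = 0.037,
                              delirium = 0.019,
                              surgery = 0.237,
                              male = 0.470
                            ),
                            true_effects = list(
                              intercept = 7.87,
                              age = 0.003,
                              male = 0.015,
                              surgical = 0.008,
                              dementia = 0.14,
                              cost_weight = 0.05,
                              charlson = 0.04,
                              n_complications = 0.13
                            ),
                            noise_sd = 0.9,
                            p_above_average = 0.369,
                            comorbidity_rate = 0.55,
                            daily_cost_mean = 600,
                            fixed_cost_per_weight = 1600,
                            seed = 1) {
  cfg <- list(
    n_persons = n_persons, episodes_per_person = episodes_per_person,
    n_drgs = n_drgs,
    window_start = as.Date(window_start), window_end = as.Date(window_end),
    prevalence = prevalence, true_effects = true_effects,
    noise_sd = noise_sd, p_above_average = p_above_average,
    comorbidity_rate = comorbidity_rate, daily_cost_mean = daily_cost_mean,
    fixed_cost_per_weight = fixed_cost_per_weight, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stop_field <- function(field, why) {
    stop("invalid generator configuration: field '", field, "' ", why)
  }
  if (!is.numeric(cfg$n_persons) || cfg$n_persons < 1) {
    stop_field("n_persons", "must be >= 1")
  }
  if (!is.numeric(cfg$n_drgs) || cfg$n_drgs < 1) {
    stop_field("n_drgs", "must be >= 1")
  }
  if (!is.numeric(cfg$episodes_per_person) || cfg$episodes_per_person < 1) {
    stop_field("episodes_per_person", "must be >= 1")
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0) {
    stop_field("noise_sd", "must be > 0")
  }
  need_prev <- c("dementia", "urinary_tract_infection", "pressure_injury",
                 "pneumonia", "delirium", "surgery", "male")
  for (p in need_prev) {
    v <- cfg$prevalence[[p]]
    if (is.null(v) || !is.numeric(v) || v < 0 || v > 1) {
      stop_field(paste0("prevalence$", p), "must be a probability in [0, 1]")
    }
  }
  if (!is.numeric(cfg$p_above_average) ||
      cfg$p_above_average < 0 || cfg$p_above_average > 1) {
    stop_field("p_above_average", "must be a probability in [0, 1]")
  }
  need_eff <- c("intercept", "age", "male", "surgical", "dementia",
                "cost_weight", "charlson", "n_complications")
  for (e in need_eff) {
    v <- cfg$true_effects[[e]]
    if (is.null(v) || !is.numeric(v) || !is.finite(v)) {
      stop_field(paste0("true_effects$", e), "must be a finite number")
    }
  }
  span <- as.numeric(cfg$window_end - cfg$window_start) + 1  # inclusive days
  if (is.na(span) || span < 730) {
    stop_field("window_start/window_end",
               "must span at least 2 calendar years")
  }
  if (!is.numeric(cfg$daily_cost_mean) || cfg$daily_cost_mean <= 0) {
    stop_field("daily_cost_mean", "must be > 0")
  }
  if (!is.numeric(cfg$fixed_cost_per_weight) || cfg$fixed_cost_per_weight < 0) {
    stop_field("fixed_cost_per_weight", "must be >= 0")
  }
  class(cfg) <- "excess_sim_config"
  cfg
}

#' Read a generator configuration from JSON
#'
#' @param path Path to a JSON file whose fields mirror the arguments of
#'   [simulate_config()]; absent fields -- including individual prevalence or
#'   effect entries -- take the defaults.
#' @return A validated `excess_sim_config`.
#' @export
read_simulate_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  defaults <- formals(simulate_config)
  if (!is.null(raw$prevalence)) {
    raw$prevalence <- utils::modifyList(eval(defaults$prevalence),
                                        as.list(raw$prevalence))
  }
  if (!is.null(raw$true_effects)) {
    raw$true_effects <- utils::modifyList(eval(defaults$true_effects),
                                          as.list(raw$true_effects))
  }
  for (d in c("window_start", "window_end")) {
    if (!is.null(raw[[d]])) raw[[d]] <- as.Date(raw[[d]])
  }
  do.call(simulate_config, raw)
}

#' Generate a synthetic DRG reference table
#'
#' One row per DRG with a positive average overnight LOS (lognormal around 4
#' days), a cost weight (lognormal, clamped to the 0.1--46 severity range),
#' and the sixteen treatment-expense subcategory amounts. The variable total
#' is daily cost times average LOS, with per-day cost varying mildly around
#' `daily_cost_mean`; the fixed total scales with the cost weight
#' (`fixed_cost_per_weight`), reflecting that severity is driven by one-off
#' theatre/critical-care/prosthesis spending more than by the daily ward
#' rate. Each block is split across its subcategories by normalised Gamma
#' weights.
#'
#' @param config A [simulate_config()] object.
#' @return A validated DRG reference data.frame.
#' @export
generate_drg_reference <- function(config) {
  config <- validate_sim_config(unclass(config))
  set.seed(config$seed)
  n <- as.integer(config$n_drgs)
  drg <- sprintf("D%03d", seq_len(n))
  avg_los <- pmax(1.5, round(exp(stats::rnorm(n, log(4.2), 0.35)), 2))
  cw <- pmin(46, pmax(0.1, round(exp(stats::rnorm(n, 0.4, 0.55)), 4)))
  daily <- config$daily_cost_mean * exp(stats::rnorm(n, 0, 0.15))
  vt <- daily * avg_los
  ft <- config$fixed_cost_per_weight * cw
  vm <- matrix(stats::rgamma(n * 11L, shape = 1), nrow = n)
  vm <- vm / rowSums(vm) * vt
  fm <- matrix(stats::rgamma(n * 5L, shape = 1), nrow = n)
  fm <- fm / rowSums(fm) * ft
  ref <- data.frame(drg = drg, avg_overnight_los = avg_los, cost_weight = cw,
                    stringsAsFactors = FALSE, check.names = FALSE)
  vm <- round(vm, 2); fm <- round(fm, 2)
  for (j in seq_along(variable_subcategories())) {
    ref[[variable_subcategories()[j]]] <- vm[, j]
  }
  for (j in seq_along(fixed_subcategories())) {
    ref[[fixed_subcategories()[j]]] <- fm[, j]
  }
  validate_drg_reference(ref)
  ref
}

# neutral principal diagnoses: common presentations that belong to no
# Charlson condition, no complication inclusion set and no exclusion set
neutral_principal_pool <- function() {
  c("I10", "J44", "M17", "R07", "S72", "K59", "H25", "A09", "M54", "E66")
}

round_half_up <- function(x) floor(x + 0.5)

#' Generate synthetic episodes with ground truth
#'
#' Draws person-level attributes (age uniform on 50--107, sex, dementia),
#' episode-level attributes (DRG, surgery, complications, Charlson
#' conditions), then generates excess log-cost as
#' `intercept + true_effects . covariates + Normal(0, noise_sd)` and
#' back-derives an integer length of stay through the cost model's own
#' daily-variable-cost arithmetic, so that re-running the costing stage on
#' the observable table reproduces the intended excess cost up to day
#' rounding. Diagnosis codes are planted so the coding stage can recover
#' every latent flag: dementia persons carry a qualifying code on an episode
#' inside the two-year lookback, complication episodes carry an inclusion
#' code and never a matching exclusion code (in particular the
#' hemiplegia/paraplegia comorbidity is never co-assigned with a generated
#' pressure injury).
#'
#' Episodes not assigned an above-average stay receive a LOS at or below
#' their DRG average and fall out at [select_above_average()].
#'
#' @param config A [simulate_config()] object.
#' @param drg_reference DRG reference to price against; defaults to
#'   [generate_drg_reference()] under the same config.
#' @return List with `episodes` (the observable table) and `truth` (the
#'   ground-truth sidecar; never an input to the coding/cost/regression
#'   stages). `truth` carries the generating coefficients in
#'   `attr(truth, "true_effects")`.
#' @export
generate_episodes <- function(config,
                              drg_reference = generate_drg_reference(config)) {
  config <- validate_sim_config(unclass(config))
  validate_drg_reference(drg_reference)
  set.seed((config$seed + 1000003L) %% 2147483647L)

  n_p <- as.integer(config$n_persons)
  prev <- config$prevalence
  eff <- config$true_effects

  n_ep_per <- if (config$episodes_per_person > 1) {
    1L + stats::rpois(n_p, config$episodes_per_person - 1)
  } else {
    rep(1L, n_p)
  }
  n <- sum(n_ep_per)
  pid <- rep.int(seq_len(n_p), n_ep_per)

  age_p <- sample(50:107, n_p, replace = TRUE)
  male_p <- stats::runif(n_p) < prev$male
  dem_p <- stats::runif(n_p) < prev$dementia

  drg_i <- sample.int(nrow(drg_reference), n, replace = TRUE)
  surgical <- stats::runif(n) < prev$surgery
  comp_names <- c("urinary_tract_infection", "pressure_injury", "pneumonia",
                  "delirium")
  comp <- vapply(comp_names, function(cn) stats::runif(n) < prev[[cn]],
                 logical(n))
  if (n == 1L) comp <- matrix(comp, nrow = 1L, dimnames = list(NULL, comp_names))

  # Charlson conditions sampled per episode; dementia handled separately and
  # hemiplegia never co-assigned with a generated pressure injury so the
  # coding stage can recover the flag.
  cmap <- default_charlson_map()
  cmap <- cmap[cmap$condition != "dementia", , drop = FALSE]
  n_cond <- stats::rpois(n, config$comorbidity_rate)
  m <- sum(n_cond)
  ep_of_cond <- rep.int(seq_len(n), n_cond)
  cond_idx <- sample.int(nrow(cmap), m, replace = TRUE)
  dup <- duplicated(cbind(ep_of_cond, cond_idx))
  clash <- cmap$condition[cond_idx] == "hemiplegia_paraplegia" &
    comp[ep_of_cond, "pressure_injury"]
  keep <- !dup & !clash
  ep_of_cond <- ep_of_cond[keep]
  cond_idx <- cond_idx[keep]
  charlson <- numeric(n)
  if (length(ep_of_cond)) {
    agg <- rowsum(cmap$weight[cond_idx], group = ep_of_cond)
    charlson[as.integer(rownames(agg))] <- agg[, 1L]
  }
  charlson <- as.integer(charlson)

  span <- as.numeric(config$window_end - config$window_start)
  admission_date <- config$window_start +
    sample.int(span + 1L, n, replace = TRUE) - 1L

  # dementia code on one randomly chosen episode per dementia person; force
  # that episode's admission into the final two years of the window so the
  # default lookback always sees it
  ep_start <- cumsum(n_ep_per) - n_ep_per
  chosen <- ep_start + sample.int(max(n_ep_per), n_p, replace = TRUE) %% n_ep_per + 1L
  dem_ep <- chosen[dem_p]
  lb_start <- config$window_end - round(2 * 365.25)
  if (lb_start < config$window_start) lb_start <- config$window_start
  late <- as.numeric(config$window_end - lb_start)
  redraw <- dem_ep[admission_date[dem_ep] < lb_start]
  if (length(redraw)) {
    admission_date[redraw] <- lb_start +
      sample.int(late + 1L, length(redraw), replace = TRUE) - 1L
  }

  age <- age_p[pid]
  male <- male_p[pid]
  dementia <- dem_p[pid]
  cw <- drg_reference$cost_weight[drg_i]
  n_comp <- as.integer(rowSums(comp))

  eta <- eff$intercept + eff$age * age + eff$male * male +
    eff$surgical * surgical + eff$dementia * dementia +
    eff$cost_weight * cw + eff$charlson * charlson +
    eff$n_complications * n_comp
  log_excess <- eta + stats::rnorm(n, 0, config$noise_sd)
  dvc <- unname(daily_variable_cost(drg_reference)[drg_i])
  extra_days_true <- exp(log_excess) / dvc
  if (any(!is.finite(extra_days_true)) || any(extra_days_true < 0)) {
    stop("generation error: effect/prevalence configuration produced ",
         "non-finite or negative excess days")
  }
  avg_los <- drg_reference$avg_overnight_los[drg_i]
  above <- stats::runif(n) < config$p_above_average
  los_above <- pmax(1L, as.integer(round_half_up(avg_los + extra_days_true)))
  los_below <- pmax(1L, as.integer(floor(avg_los * stats::runif(n))))
  los <- ifelse(above, los_above, los_below)

  # assemble additional diagnoses: comorbidity codes + complication
  # inclusion codes + the planted dementia code
  first_code <- function(x) split_codes(x)[1L]
  ep_all <- ep_of_cond
  code_all <- vapply(cmap$codes[cond_idx], first_code, "", USE.NAMES = FALSE)
  rules <- default_complication_rules()
  for (cn in comp_names) {
    rows <- which(comp[, cn])
    if (!length(rows)) next
    inc <- split_codes(rules$inclusion_codes[rules$name == cn])
    ep_all <- c(ep_all, rows)
    code_all <- c(code_all, inc[sample.int(length(inc), length(rows),
                                           replace = TRUE)])
  }
  if (length(dem_ep)) {
    ep_all <- c(ep_all, dem_ep)
    code_all <- c(code_all, sample(dementia_codes(), length(dem_ep),
                                   replace = TRUE))
  }
  additional_dx <- rep("", n)
  if (length(ep_all)) {
    sp <- split(code_all, factor(ep_all, levels = seq_len(n)))
    nonempty <- lengths(sp) > 0L
    additional_dx[nonempty] <- vapply(sp[nonempty], paste, "",
                                      collapse = ";")
  }
  principal_dx <- sample(neutral_principal_pool(), n, replace = TRUE)

  episodes <- data.frame(
    person_id = sprintf("p%06d", pid),
    episode_id = sprintf("e%07d", seq_len(n)),
    age = age,
    sex = ifelse(male, "male", "female"),
    los_days = los,
    drg = drg_reference$drg[drg_i],
    principal_dx = principal_dx,
    additional_dx = additional_dx,
    surgical = surgical,
    admission_date = admission_date,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    episode_id = episodes$episode_id,
    person_id = episodes$person_id,
    dementia = dementia,
    charlson = charlson,
    urinary_tract_infection = comp[, "urinary_tract_infection"],
    pressure_injury = comp[, "pressure_injury"],
    pneumonia = comp[, "pneumonia"],
    delirium = comp[, "delirium"],
    n_complications = n_comp,
    surgical = surgical,
    male = male,
    age = age,
    cost_weight = cw,
    eta = eta,
    log_excess_cost = log_excess,
    extra_days_true = extra_days_true,
    above_average = above,
    stringsAsFactors = FALSE
  )
  attr(truth, "true_effects") <- eff
  list(episodes = episodes, truth = truth)
}

#' Write a synthetic fixture to delimited text
#'
#' Writes `episodes.csv`, `drg_reference.csv` and (when supplied) the
#' `ground_truth.csv` sidecar under `path`. Files round-trip losslessly
#' through [read_episodes()], [read_drg_reference()] and
#' [read_ground_truth()]. The sidecar exists only for parameter-recovery
#' tests; the coding, costing and regression stages never read it.
#'
#' @param path Output directory (created if needed).
#' @param episodes Episode table.
#' @param drg_reference Optional DRG reference table.
#' @param truth Optional ground-truth sidecar.
#' @return Invisibly, the named vector of files written.
#' @export
write_fixture <- function(path, episodes, drg_reference = NULL, truth = NULL) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(path)) stop("cannot create fixture directory: ", path)
  }
  files <- c(episodes = file.path(path, "episodes.csv"))
  utils::write.csv(episodes, files[["episodes"]], row.names = FALSE)
  if (!is.null(drg_reference)) {
    files["drg_reference"] <- file.path(path, "drg_reference.csv")
    utils::write.csv(drg_reference, files[["drg_reference"]],
                     row.names = FALSE)
  }
  if (!is.null(truth)) {
    files["ground_truth"] <- file.path(path, "ground_truth.csv")
    tt <- truth
    eff <- attr(truth, "true_effects")
    utils::write.csv(tt, files[["ground_truth"]], row.names = FALSE)
    if (!is.null(eff)) {
      files["true_effects"] <- file.path(path, "true_effects.json")
      jsonlite::write_json(eff, files[["true_effects"]], auto_unbox = TRUE,
                           digits = NA)
    }
  }
  invisible(files)
}

#' Read an episode table from CSV
#'
#' @param path Path to a CSV written by [write_fixture()] (or any file with
#'   the same columns).
#' @return Episode data.frame with `admission_date` parsed as `Date`.
#' @export
read_episodes <- function(path) {
  eps <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(person_id = "character",
                                        episode_id = "character",
                                        additional_dx = "character",
                                        principal_dx = "character",
                                        drg = "character"))
  eps$additional_dx[is.na(eps$additional_dx)] <- ""
  eps$admission_date <- as.Date(eps$admission_date)
  eps$surgical <- as.logical(eps$surgical)
  validate_episodes(eps)
  eps
}

#' Read a DRG reference table from CSV
#'
#' Expects the sixteen subcategory columns under their exact labels
#' ([variable_subcategories()], [fixed_subcategories()]).
#'
#' @param path Path to the CSV.
#' @return Validated DRG reference data.frame.
#' @export
read_drg_reference <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = c(drg = "character"))
  validate_drg_reference(ref)
  ref
}

#' Read a ground-truth sidecar from CSV
#'
#' @param path Path to `ground_truth.csv`; a `true_effects.json` beside it is
#'   attached as the `true_effects` attribute when present.
#' @return Ground-truth data.frame.
#' @export
read_ground_truth <- function(path) {
  tt <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(person_id = "character",
                                       episode_id = "character"))
  eff_path <- file.path(dirname(path), "true_effects.json")
  if (file.exists(eff_path)) {
    attr(tt, "true_effects") <- jsonlite::fromJSON(eff_path)
  }
  tt
}
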