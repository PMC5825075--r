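# Small in-code fixtures shared across the suite.

make_drg_ref <- function(drg = "D001", avg_los = 5, cost_weight = 1,
                         amounts = list()) {
  ref <- data.frame(drg = drg, avg_overnight_los = avg_los,
                    cost_weight = cost_weight,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (s in c(variable_subcategories(), fixed_subcategories())) ref[[s]] <- 0
  for (nm in names(amounts)) ref[[nm]] <- amounts[[nm]]
  ref
}

make_episode <- function(episode_id = "e1", person_id = "p1", age = 70,
                         sex = "female", los_days = 5, drg = "D001",
                         principal_dx = "I10", additional_dx = "",
                         surgical = FALSE,
                         admission_date = as.Date("2006-10-01")) {
  data.frame(person_id = person_id, episode_id = episode_id, age = age,
             sex = sex, los_days = los_days, drg = drg,
             principal_dx = principal_dx, additional_dx = additional_dx,
             surgical = surgical, admission_date = admission_date,
             stringsAsFactors = FALSE)
}

# random episodes drawing codes from a pool that mixes complication
# inclusion/exclusion codes, Charlson codes, dementia codes and neutral noise
random_code_pool <- function() {
  rules <- default_complication_rules()
  cmap <- default_charlson_map()
  split_many <- function(x) unlist(lapply(x, function(s)
    strsplit(s, ";", fixed = TRUE)[[1L]]))
  c(split_many(rules$inclusion_codes), split_many(rules$exclusion_codes),
    split_many(cmap$codes), dementia_codes(),
    "I10", "J44", "M17", "R07", "Z501", "K59")
}

random_episodes <- function(n, seed) {
  set.seed(seed)
  pool <- random_code_pool()
  add <- vapply(seq_len(n), function(i) {
    k <- stats::rpois(1, 2)
    paste(sample(pool, k, replace = TRUE), collapse = ";")
  }, "")
  data.frame(
    person_id = sprintf("p%03d", sample.int(max(1L, n %/% 2L), n, TRUE)),
    episode_id = sprintf("e%04d", seq_len(n)),
    age = sample(40:100, n, TRUE),
    sex = sample(c("male", "female"), n, TRUE),
    los_days = sample(1:30, n, TRUE),
    drg = "D001",
    principal_dx = sample(pool, n, TRUE),
    additional_dx = add,
    surgical = sample(c(TRUE, FALSE), n, TRUE),
    admission_date = as.Date("2006-01-01") + sample.int(300, n, TRUE),
    stringsAsFactors = FALSE
  )
}

# brute-force oracles, deliberately structured as plain per-element loops
naive_match <- function(code, prefixes) {
  any(vapply(prefixes, function(p) startsWith(code, p), TRUE))
}

naive_flag_episode <- function(principal_dx, additional_dx, rule) {
  inc <- strsplit(rule$inclusion_codes, ";", fixed = TRUE)[[1L]]
  exc <- strsplit(rule$exclusion_codes, ";", fixed = TRUE)[[1L]]
  norm <- function(x) gsub("[. ]", "", toupper(trimws(x)))
  adds <- norm(strsplit(additional_dx, ";", fixed = TRUE)[[1L]])
  adds <- adds[nzchar(adds)]
  p <- norm(principal_dx)
  included <- FALSE
  for (a in adds) if (naive_match(a, norm(inc))) included <- TRUE
  excluded <- naive_match(p, norm(exc))
  if (rule$exclusion_scope == "principal_or_additional") {
    for (a in adds) if (naive_match(a, norm(exc))) excluded <- TRUE
  }
  included && !excluded
}

naive_charlson <- function(codes, map) {
  norm <- function(x) gsub("[. ]", "", toupper(trimws(x)))
  codes <- norm(codes)
  codes <- codes[nzchar(codes)]
  total <- 0
  for (i in seq_len(nrow(map))) {
    if (map$condition[i] == "dementia") next
    prefixes <- norm(strsplit(map$codes[i], ";", fixed = TRUE)[[1L]])
    present <- FALSE
    for (cd in codes) if (naive_match(cd, prefixes)) present <- TRUE
    if (present) total <- total + map$weight[i]
  }
  total
}

# normal-equations OLS, the independent oracle for the lm-based fit
normal_equations_ols <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))[, 1L]
}
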