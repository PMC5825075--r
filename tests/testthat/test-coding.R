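test_that("cohort filter applies age and LOS rules with an exclusion log", {
  eps <- rbind(
    make_episode("e1", age = 50, los_days = 5),     # boundary age: retained
    make_episode("e2", age = 49, los_days = 5),     # under age
    make_episode("e3", age = 80, los_days = 91),    # beyond trim
    make_episode("e4", age = 80, los_days = 90),    # at trim: retained
    make_episode("e5", age = 80, los_days = 0),     # day-stay
    make_episode("e6", age = 70, los_days = 1),
    make_episode("e7", age = 95, los_days = 89),
    make_episode("e8", age = 51, los_days = 30),
    make_episode("e9", age = 60, los_days = 2),
    make_episode("e10", age = 77, los_days = 40)
  )
  out <- filter_cohort(eps, min_age = 50, max_los = 90)
  expect_equal(nrow(out$episodes), 7)
  expect_equal(sum(out$exclusions$n), 3)
  get_n <- function(r) out$exclusions$n[out$exclusions$reason == r]
  expect_equal(get_n("los_gt_max"), 1)
  expect_equal(get_n("age_lt_min"), 1)
  expect_equal(get_n("day_stay"), 1)
  expect_true("e1" %in% out$episodes$episode_id)
  expect_false("e3" %in% out$episodes$episode_id)
})

test_that("malformed episode rows abort with row-level messages", {
  eps <- make_episode("e1", principal_dx = "not a code")
  expect_error(filter_cohort(eps), "row 1")
  eps2 <- make_episode("e1", sex = "unknown")
  expect_error(filter_cohort(eps2), "sex")
})

test_that("dementia flag is person-level, code-driven and window-bound", {
  eps <- rbind(
    make_episode("e1", "p1", additional_dx = "K59;G30",
                 admission_date = as.Date("2006-03-01")),
    make_episode("e2", "p1", additional_dx = "",
                 admission_date = as.Date("2006-09-01")),
    make_episode("e3", "p2", additional_dx = "K59;I10",
                 principal_dx = "J44",
                 admission_date = as.Date("2006-05-01")),
    # p3's only qualifying episode predates the two-year lookback
    make_episode("e4", "p3", principal_dx = "G30",
                 admission_date = as.Date("2004-01-01")),
    make_episode("e5", "p3", principal_dx = "I10",
                 admission_date = as.Date("2006-06-01"))
  )
  flags <- flag_dementia(eps, window_end = as.Date("2006-12-31"))
  expect_true(flags[["p1"]])    # additional dx counts, propagates to e2
  expect_false(flags[["p2"]])
  expect_false(flags[["p3"]])   # outside window
  # principal dx counts too
  eps_p <- make_episode("e1", "p9", principal_dx = "F01.1",
                        admission_date = as.Date("2006-06-01"))
  expect_true(flag_dementia(eps_p, window_end = as.Date("2006-12-31"))[["p9"]])
})

test_that("dementia flag is invariant to episode ordering within a person", {
  eps <- random_episodes(40, seed = 21)
  f1 <- flag_dementia(eps, window_end = as.Date("2006-12-31"))
  perm <- sample(nrow(eps))
  f2 <- flag_dementia(eps[perm, ], window_end = as.Date("2006-12-31"))
  expect_equal(f1[sort(names(f1))], f2[sort(names(f2))])
})

test_that("Charlson score sums distinct condition weights, dementia excluded", {
  expect_equal(compute_charlson(character(0)), 0L)
  # diabetes (1) + any cancer (2)
  expect_equal(compute_charlson(c("E11", "C50")), 3L)
  # dementia alone scores zero: excluded from the index by design
  expect_equal(compute_charlson("G30"), 0L)
  expect_equal(compute_charlson(c("G30", "F00.1")), 0L)
  # duplicated codes count once
  expect_equal(compute_charlson(c("E11", "E11", "E113")), 1L)
  # unknown codes ignored
  expect_equal(compute_charlson(c("Z99", "I10")), 0L)
})

test_that("Charlson equals a brute-force implementation and is order-invariant", {
  map <- default_charlson_map()
  set.seed(33)
  pool <- random_code_pool()
  for (i in 1:30) {
    codes <- sample(pool, rpois(1, 4), replace = TRUE)
    expect_equal(compute_charlson(codes, map),
                 as.integer(naive_charlson(codes, map)))
    expect_equal(compute_charlson(codes, map),
                 compute_charlson(rev(codes), map))
    expect_equal(compute_charlson(codes, map),
                 compute_charlson(c(codes, codes), map))
  }
})

test_that("vectorised per-episode Charlson matches the scalar function", {
  eps <- random_episodes(50, seed = 8)
  coded <- code_episodes(eps, window_end = as.Date("2006-12-31"))
  for (i in seq_len(nrow(eps))) {
    codes <- c(eps$principal_dx[i],
               strsplit(eps$additional_dx[i], ";", fixed = TRUE)[[1L]])
    expect_equal(coded$charlson[i], compute_charlson(codes))
  }
})

test_that("complication flags respect inclusion codes and aetiology exclusions", {
  rules <- default_complication_rules()
  # UTI code among additional dx, but urinary-tract principal dx blocks it
  uti_blocked <- make_episode(principal_dx = "N30", additional_dx = "N390")
  expect_false(flag_complications(uti_blocked, rules)[1, "urinary_tract_infection"])
  uti_ok <- make_episode(principal_dx = "I10", additional_dx = "N390")
  expect_true(flag_complications(uti_ok, rules)[1, "urinary_tract_infection"])
  # paralysis anywhere on the record blocks pressure injury
  pi_blocked <- make_episode(principal_dx = "I10", additional_dx = "L89;G81")
  expect_false(flag_complications(pi_blocked, rules)[1, "pressure_injury"])
  pi_blocked2 <- make_episode(principal_dx = "G82", additional_dx = "L89")
  expect_false(flag_complications(pi_blocked2, rules)[1, "pressure_injury"])
  pi_ok <- make_episode(principal_dx = "I10", additional_dx = "L89")
  expect_true(flag_complications(pi_ok, rules)[1, "pressure_injury"])
  # principal-diagnosis matches of inclusion codes never count
  pneu_principal <- make_episode(principal_dx = "J18", additional_dx = "")
  expect_false(any(flag_complications(pneu_principal, rules)))
  # no inclusion codes at all
  none <- make_episode(principal_dx = "I10", additional_dx = "K59;I10")
  expect_false(any(flag_complications(none, rules)))
})

test_that("flags equal a naive brute-force matcher on random fixtures", {
  rules <- default_complication_rules()
  for (seed in c(101, 202)) {
    eps <- random_episodes(50, seed = seed)
    flags <- flag_complications(eps, rules)
    for (i in seq_len(nrow(eps))) {
      for (j in seq_len(nrow(rules))) {
        expect_identical(
          unname(flags[i, rules$name[j]]),
          naive_flag_episode(eps$principal_dx[i], eps$additional_dx[i],
                             rules[j, ]),
          label = sprintf("episode %d rule %s", i, rules$name[j])
        )
      }
    }
  }
})

test_that("adding an exclusion code never turns a flag on (monotonicity)", {
  rules <- default_complication_rules()
  eps <- random_episodes(30, seed = 55)
  before <- flag_complications(eps, rules)
  for (j in seq_len(nrow(rules))) {
    exc <- strsplit(rules$exclusion_codes[j], ";", fixed = TRUE)[[1L]]
    worse <- eps
    worse$additional_dx <- paste(eps$additional_dx, exc[1L], sep = ";")
    after <- flag_complications(worse, rules)
    expect_true(all(after[, j] <= before[, j]))
    worse2 <- eps
    worse2$principal_dx <- exc[1L]
    after2 <- flag_complications(worse2, rules)
    expect_true(all(after2[, j] <= before[, j]))
  }
})

test_that("rule validation rejects overlapping or incomplete tables", {
  rules <- default_complication_rules()
  bad <- rules
  bad$exclusion_codes[bad$name == "pressure_injury"] <- "L89;G81"
  expect_error(validate_rules(bad), "overlap")
  expect_error(validate_rules(rules[-1, ]), "exactly once")
  bad2 <- rules
  bad2$exclusion_scope[1] <- "sometimes"
  expect_error(validate_rules(bad2), "exclusion_scope")
})

test_that("code_episodes composes flags, Charlson and counts deterministically", {
  eps <- rbind(
    make_episode("e1", "p1", additional_dx = "N390;J18"),      # UTI + pneumonia
    make_episode("e2", "p1", additional_dx = "E11;C50"),       # comorbidity only
    make_episode("e3", "p2", additional_dx = "G30;L89"),       # dementia + PI
    make_episode("e4", "p3", additional_dx = "")
  )
  coded <- code_episodes(eps, window_end = as.Date("2006-12-31"))
  expect_equal(coded$n_complications,
               rowSums(coded[, c("urinary_tract_infection", "pressure_injury",
                                 "pneumonia", "delirium")]) |> as.integer())
  expect_equal(coded$n_complications[1], 2L)
  expect_equal(coded$charlson[2], 3L)
  expect_true(all(coded$dementia[coded$person_id == "p2"]))
  expect_false(any(coded$dementia[coded$person_id != "p2"]))
  coded2 <- code_episodes(eps, window_end = as.Date("2006-12-31"))
  expect_identical(coded, coded2)
})

test_that("population rates on a hand-enumerated fixture match hand counts", {
  # 20 episodes: 4 UTI (one blocked), 3 pneumonia, 2 dementia persons of 10
  eps <- rbind(
    make_episode("e01", "p01", additional_dx = "N390"),
    make_episode("e02", "p02", additional_dx = "N390"),
    make_episode("e03", "p03", additional_dx = "N390"),
    make_episode("e04", "p04", principal_dx = "N30", additional_dx = "N390"),
    make_episode("e05", "p05", additional_dx = "J15"),
    make_episode("e06", "p06", additional_dx = "J18"),
    make_episode("e07", "p07", additional_dx = "J13"),
    make_episode("e08", "p08", additional_dx = "G30"),
    make_episode("e09", "p09", additional_dx = "F01"),
    make_episode("e10", "p10", additional_dx = ""),
    make_episode("e11", "p01", additional_dx = ""),
    make_episode("e12", "p02", additional_dx = ""),
    make_episode("e13", "p03", additional_dx = ""),
    make_episode("e14", "p04", additional_dx = ""),
    make_episode("e15", "p05", additional_dx = ""),
    make_episode("e16", "p06", additional_dx = ""),
    make_episode("e17", "p07", additional_dx = ""),
    make_episode("e18", "p08", additional_dx = ""),
    make_episode("e19", "p09", additional_dx = ""),
    make_episode("e20", "p10", additional_dx = "")
  )
  coded <- code_episodes(eps, window_end = as.Date("2006-12-31"))
  expect_equal(sum(coded$urinary_tract_infection), 3)   # e04 blocked
  expect_equal(sum(coded$pneumonia), 3)
  expect_equal(sum(coded$dementia), 4)                  # both episodes of p08, p09
  expect_equal(mean(coded$n_complications > 0), 6 / 20)
})
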