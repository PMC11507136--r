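# Synthetic cohort generator: event mechanics, determinism, and convergence
# of generated demographics and event frequencies to their targets.

urban <- load_profile("urban")

test_that("degenerate event probabilities give full panels with constant modality", {
  cfg <- generation_config(n_persons = 40, n_years = 5, seed = 1,
                           p_switch = 0, p_death = 0)
  rec <- generate_cohort(urban, cfg)
  expect_equal(nrow(rec), 200L)
  expect_equal(as.vector(table(rec$person_id)), rep(5L, 40))
  expect_false(any(rec$switched_this_year))
  expect_false(any(rec$died_this_year))
  per_person_modalities <- tapply(rec$modality_at_start, rec$person_id,
                                  function(x) length(unique(x)))
  expect_true(all(per_person_modalities == 1L))
})

test_that("certain death truncates every person after one record", {
  cfg <- generation_config(n_persons = 25, n_years = 5, seed = 2, p_death = 1)
  rec <- generate_cohort(urban, cfg)
  expect_equal(nrow(rec), 25L)
  expect_true(all(rec$died_this_year))
  expect_true(all(rec$year_index == 1L))
})

test_that("certain switching alternates the modality every year", {
  cfg <- generation_config(n_persons = 10, n_years = 4, seed = 3,
                           p_switch = 1, p_death = 0)
  rec <- generate_cohort(urban, cfg)
  expect_true(all(rec$switched_this_year))
  mods <- tapply(rec$modality_at_start, rec$person_id,
                 function(x) all(x[-1] != x[-length(x)]))
  expect_true(all(mods))
})

test_that("a dead person contributes no later person-years", {
  cfg <- generation_config(n_persons = 500, n_years = 6, seed = 4,
                           p_death = 0.3, p_switch = 0.2)
  rec <- generate_cohort(urban, cfg)
  last_year <- tapply(rec$year_index, rec$person_id, max)
  death_year <- tapply(rec$year_index[rec$died_this_year],
                       rec$person_id[rec$died_this_year], min)
  expect_equal(unname(last_year[names(death_year)]), unname(death_year))
  expect_false(any(rec$switched_this_year & rec$died_this_year))
})

test_that("generation is deterministic under a fixed seed and varies across seeds", {
  cfg1 <- generation_config(n_persons = 200, n_years = 2, seed = 7,
                            p_switch = 0.2, p_death = 0.1, ed_mean = 1.5)
  rec_a <- generate_cohort(urban, cfg1)
  rec_b <- generate_cohort(urban, cfg1)
  expect_identical(rec_a, rec_b)
  dis_a <- generate_discharges(rec_a, cfg1)
  dis_b <- generate_discharges(rec_b, cfg1)
  expect_identical(dis_a, dis_b)
  cfg2 <- generation_config(n_persons = 200, n_years = 2, seed = 8,
                            p_switch = 0.2, p_death = 0.1, ed_mean = 1.5)
  expect_false(identical(generate_cohort(urban, cfg2), rec_a))
})

test_that("generated demographics converge to the profile distributions", {
  cfg <- generation_config(n_persons = 5000, seed = 11)
  rec <- generate_cohort(urban, cfg)
  expect_true(all(rec$age >= urban$age_min & rec$age <= urban$age_max))
  se_age <- sd(rec$age) / sqrt(nrow(rec))
  expect_lt(abs(mean(rec$age) - urban$age_mean), 3 * se_age)

  gender_obs <- table(factor(rec$gender, levels = names(urban$gender_probs)))
  expect_gt(chisq.test(gender_obs, p = urban$gender_probs)$p.value, 0.01)
  race_obs <- table(factor(rec$race, levels = names(urban$race_probs)))
  expect_gt(chisq.test(race_obs, p = urban$race_probs)$p.value, 0.01)
})

test_that("event frequencies match the configured probabilities and means", {
  cfg <- generation_config(
    n_persons = 5000, seed = 12,
    p_switch = c(in_person = 0.3137, telehealth = 0.1829),
    p_death = c(in_person = 0.1147, telehealth = 0.0810),
    ed_mean = c(in_person = 2.24, telehealth = 1.52),
    hosp_mean = c(in_person = 1.86, telehealth = 0.74)
  )
  rec <- generate_cohort(urban, cfg)
  for (mod in c("in_person", "telehealth")) {
    at_risk <- rec[rec$modality_at_start == mod, ]
    n <- nrow(at_risk)
    p_d <- cfg$p_death[[mod]]
    expect_lt(abs(mean(at_risk$died_this_year) - p_d),
              3 * sqrt(p_d * (1 - p_d) / n))
    # switching is drawn among survivors, so condition on surviving
    surv <- at_risk[!at_risk$died_this_year, ]
    p_s <- cfg$p_switch[[mod]]
    expect_lt(abs(mean(surv$switched_this_year) - p_s),
              3 * sqrt(p_s * (1 - p_s) / nrow(surv)))
    lam <- cfg$ed_mean[[mod]]
    expect_lt(abs(mean(at_risk$ed_visit_count) - lam), 3 * sqrt(lam / n))
    lam <- cfg$hosp_mean[[mod]]
    expect_lt(abs(mean(at_risk$hospitalization_count) - lam),
              3 * sqrt(lam / n))
  }
  expect_true(all(rec$zbi12_raw >= 0 & rec$zbi12_raw <= 48))
})

test_that("discharge generation conserves event counts", {
  one <- make_person_years("telehealth", ed = 2, hosp = 1)
  cfg <- generation_config(n_persons = 1, seed = 5)
  dis <- generate_discharges(one, cfg)
  expect_equal(nrow(dis), 3L)
  expect_equal(sum(dis$setting == "ED"), 2L)
  expect_true(all(dis$los_days[dis$setting == "ED"] == 1L))

  cfg2 <- generation_config(n_persons = 800, seed = 6, ed_mean = 1.2,
                            hosp_mean = 0.7, p_death = 0.1)
  rec <- generate_cohort(urban, cfg2)
  dis2 <- generate_discharges(rec, cfg2)
  expect_equal(nrow(dis2),
               sum(rec$ed_visit_count) + sum(rec$hospitalization_count))
  expect_true(all(dis2$los_days >= 1L))
  expect_true(all(dis2$daily_charge > 0))
})

test_that("contamination controls the non-ADRD code share", {
  rec <- make_person_years(rep("in_person", 2000), ed = 2, hosp = 0)
  cfg0 <- generation_config(n_persons = 2000, seed = 9, contamination_frac = 0)
  dis0 <- generate_discharges(rec, cfg0)
  expect_true(all(grepl("^F0[123]", dis0$principal_dx)))

  cfg5 <- generation_config(n_persons = 2000, seed = 9,
                            contamination_frac = 0.5)
  dis5 <- generate_discharges(rec, cfg5)
  share <- mean(!grepl("^F0[123]", dis5$principal_dx))
  expect_lt(abs(share - 0.5), 3 * sqrt(0.25 / nrow(dis5)))
})

test_that("the ADRD filter keeps exactly the F01/F02/F03 prefixes", {
  d <- make_discharges("ED", principal_dx = c("F01.50", "F03.90", "I10",
                                              "G30.9"))
  expect_equal(select_adrd_records(d)$principal_dx, c("F01.50", "F03.90"))
  # case-insensitive and whitespace-tolerant
  d2 <- make_discharges("ED", principal_dx = c(" f02.81 ", "E11.9"))
  expect_equal(nrow(select_adrd_records(d2)), 1L)
  # empty input maps to empty output
  expect_equal(nrow(select_adrd_records(d[0, ])), 0L)
  # malformed codes are excluded with a message, not an error
  d3 <- make_discharges("ED", principal_dx = c("F01.50", "", NA))
  expect_message(out <- select_adrd_records(d3), "excluding 2")
  expect_equal(nrow(out), 1L)
  # brute-force count check
  d4 <- make_discharges("ED", principal_dx = c(rep("F02.80", 40),
                                               rep("I63.9", 60)))
  expect_equal(nrow(select_adrd_records(d4)), 40L)
})

test_that("sample size follows the finite-population-corrected formula", {
  expect_equal(sample_size(0.95, 0.05, 1e9), 385L)
  expect_equal(sample_size(0.95, 0.99, 1e6), 1L)
  # independent oracle: two-sided quantile + FPC computed inline
  z <- qnorm((1 + 0.85) / 2)
  n0 <- z^2 * 0.25 / 0.10^2
  expect_equal(sample_size(0.85, 0.10, 473),
               as.integer(ceiling(n0 / (1 + (n0 - 1) / 473))))
  expect_equal(sample_size(0.85, 0.10, 473), 47L)
  expect_error(sample_size(1.2, 0.1, 100), "confidence")
  expect_error(sample_size(0.9, 0, 100), "margin")
})

test_that("invalid generator settings are rejected at construction", {
  expect_error(generation_config(n_persons = 10, seed = 1, p_death = 1.2),
               "probability")
  expect_error(generation_config(n_persons = 10, seed = 1, ed_mean = -1),
               "nonnegative")
  expect_error(generation_config(n_persons = 10), "seed")
  expect_error(generation_config(n_persons = 10, seed = 1,
                                 contamination_frac = 1), "< 1")
})
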