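# Estimators: event probabilities with Wilson intervals, utilization rates,
# standardized event costs, ZBI-12 rescaling, delivery costs, inflation, and
# full parameter recovery from generated data.

test_that("annual probabilities are events over person-years at risk", {
  rec <- make_person_years(rep("telehealth", 50),
                           switched = c(rep(TRUE, 8), rep(FALSE, 42)))
  est <- estimate_annual_probability(rec, "switch", "telehealth")
  expect_equal(est$estimate, 0.16)
  expect_equal(est$person_years, 50L)
  # Wilson interval brackets the estimate and matches prop.test
  expect_lt(est$ci_low, 0.16)
  expect_gt(est$ci_high, 0.16)
  pt <- prop.test(8, 50, correct = FALSE)$conf.int
  expect_equal(c(est$ci_low, est$ci_high), as.numeric(pt))

  none <- make_person_years(rep("in_person", 10))
  expect_equal(estimate_annual_probability(none, "death", "in_person")$estimate, 0)
  expect_error(estimate_annual_probability(none, "death", "telehealth"),
               "at risk")
})

test_that("event rates are total events over person-years", {
  rec <- make_person_years(rep("in_person", 4), ed = c(0, 1, 2, 3))
  expect_equal(estimate_event_rate(rec, "ed", "in_person")$estimate, 1.5)
  expect_equal(estimate_event_rate(rec, "hosp", "in_person")$estimate, 0)
})

test_that("event costs combine LOS with group mean daily charges under weights", {
  w1 <- costing_weights("80+", "female", 1)
  # one cell, same diagnosis: charges average to 500; LOS 2 and 4 -> 1500
  d <- make_discharges("inpatient", los = c(2, 4), charge = c(500, 500))
  expect_equal(estimate_event_cost(d, "inpatient", w1), 1500)
  # all weight on one cell equals that cell's unweighted mean
  d2 <- make_discharges("inpatient", los = c(1, 3), charge = c(800, 800))
  expect_equal(estimate_event_cost(d2, "inpatient", w1), 2 * 800)
  # two cells, means 1000 and 3000, weights 0.5/0.5 -> 2000
  w2 <- costing_weights(c("<=79", "80+"), c("female", "female"), c(0.5, 0.5))
  d3 <- make_discharges("inpatient", los = c(2, 6), charge = 500,
                        age_band = c("<=79", "80+"))
  expect_equal(estimate_event_cost(d3, "inpatient", w2), 2000)
})

test_that("event costs are invariant to record order and batch structure", {
  set.seed(31)
  d <- make_discharges(rep("inpatient", 60),
                       principal_dx = sample(c("F01.50", "F03.90"), 60, TRUE),
                       los = sample(1:9, 60, TRUE),
                       charge = runif(60, 300, 900),
                       age_band = sample(c("<=79", "80+"), 60, TRUE),
                       gender = sample(c("male", "female"), 60, TRUE))
  w <- costing_weights(rep(c("<=79", "80+"), each = 2),
                       rep(c("male", "female"), 2), rep(0.25, 4))
  base <- estimate_event_cost(d, "inpatient", w)
  shuffled <- d[sample(nrow(d)), ]
  expect_equal(estimate_event_cost(shuffled, "inpatient", w), base)
})

test_that("empty weight cells are dropped with renormalization and a warning", {
  w <- costing_weights(c("<=79", "80+"), c("female", "female"), c(0.4, 0.6))
  d <- make_discharges("inpatient", los = 2, charge = 500, age_band = "80+")
  expect_warning(est <- estimate_event_cost(d, "inpatient", w), "renormalizing")
  expect_equal(est, 1000)
})

test_that("ZBI-12 rescaling is the stated linear bijection", {
  expect_equal(rescale_zbi(0), 100)
  expect_equal(rescale_zbi(48), 0)
  expect_equal(rescale_zbi(24), 50)
  raw <- seq(0, 48, by = 0.5)
  expect_true(all(diff(rescale_zbi(raw)) < 0))
  expect_equal(zbi_raw_from_modified(rescale_zbi(raw)), raw)
  expect_error(rescale_zbi(-1), "0, 48")
  expect_error(rescale_zbi(49), "0, 48")
  expect_error(zbi_raw_from_modified(101), "0, 100")
})

test_that("time savings follow the roundtrip-plus-visit-difference formula", {
  expect_equal(time_savings(60, 30, 15), 75)
  expect_equal(time_savings(0, 25, 25), 0)
  expect_equal(time_savings(0, 10, 40), -30)
  expect_error(time_savings(-5, 10, 10), "nonnegative")
})

test_that("delivery costs assemble training, travel and productivity components", {
  inp <- delivery_cost_inputs(
    trainer_wage = 50, training_hours_per_conversion = 4,
    conversion_probability = 1,
    roundtrip_drive_time = 60, in_person_visit_time = 30,
    telehealth_visit_time = 15,
    wage_rate = 20, distance_roundtrip = 30, mileage_rate = 0.5,
    visits_per_year = 4)
  dc <- delivery_costs(inp)
  expect_equal(dc$c_delivery_tele, 200)
  # 4 * (30 * 0.5 + (75/60) * 20) = 4 * (15 + 25) = 160
  expect_equal(dc$c_delivery_in, 160)

  inp0 <- inp; inp0$conversion_probability <- 0
  expect_equal(delivery_costs(inp0)$c_delivery_tele, 0)
  inp1 <- inp; inp1$visits_per_year <- 0
  expect_equal(delivery_costs(inp1)$c_delivery_in, 0)

  # degree-one homogeneity in wage and mileage rates
  inp2 <- inp
  inp2$trainer_wage <- inp$trainer_wage * 3
  inp2$wage_rate <- inp$wage_rate * 3
  inp2$mileage_rate <- inp$mileage_rate * 3
  dc2 <- delivery_costs(inp2)
  expect_equal(dc2$c_delivery_tele, 3 * dc$c_delivery_tele)
  expect_equal(dc2$c_delivery_in, 3 * dc$c_delivery_in)
})

test_that("inflation adjustment compounds the yearly rates", {
  expect_equal(adjust_inflation(250, 2022, 2022), 250)
  expect_equal(adjust_inflation(100, 2021, 2022, c("2021" = 0.05)), 105)
  expect_equal(adjust_inflation(100, 2020, 2022,
                                c("2020" = 0.03, "2021" = 0.04)), 107.12)
  expect_error(adjust_inflation(100, 2020, 2022, c("2020" = 0.03)),
               "missing healthcare inflation")
})

test_that("estimate_all recovers the generator settings within 3 SE", {
  urban <- load_profile("urban")
  cfg <- model_generation_config("model_a", n_persons = 6000, seed = 21)
  rec <- generate_cohort(urban, cfg)
  dis <- generate_discharges(rec, cfg)
  w <- default_costing_weights(urban)
  est <- suppressMessages(estimate_all(
    rec, dis, w, delivery_cost_values = list(c_delivery_in = 230,
                                             c_delivery_tele = 202)))

  within3se_prob <- function(value, target, n) {
    abs(value - target) < 3 * sqrt(target * (1 - target) / n)
  }
  n_in <- sum(rec$modality_at_start == "in_person")
  n_te <- sum(rec$modality_at_start == "telehealth")
  # switch estimates condition on survivors, matching the model's ordering
  expect_true(within3se_prob(est$p_switch_in_to_tele, 0.3137, n_in))
  expect_true(within3se_prob(est$p_switch_tele_to_in, 0.1829, n_te))
  expect_true(within3se_prob(est$m_in, 0.1147, n_in))
  expect_true(within3se_prob(est$m_tele, 0.0810, n_te))
  expect_lt(abs(est$ed_rate_in - 2.24), 3 * sqrt(2.24 / n_in))
  expect_lt(abs(est$ed_rate_tele - 1.52), 3 * sqrt(1.52 / n_te))
  expect_lt(abs(est$hosp_rate_in - 1.86), 3 * sqrt(1.86 / n_in))
  expect_lt(abs(est$hosp_rate_tele - 0.74), 3 * sqrt(0.74 / n_te))
  # ZBI-derived effectiveness: SE of the mean on the modified scale
  z_in <- rescale_zbi(rec$zbi12_raw[rec$modality_at_start == "in_person"])
  z_te <- rescale_zbi(rec$zbi12_raw[rec$modality_at_start == "telehealth"])
  expect_lt(abs(est$e_in - 70.28), 3 * sd(z_in) / sqrt(n_in))
  expect_lt(abs(est$e_tele - 67.35), 3 * sd(z_te) / sqrt(n_te))
  # per-event costs match the scenario unit costs to within a few percent
  expect_lt(abs(est$c_ed - 6177) / 6177, 0.05)
  expect_lt(abs(est$c_hosp - 34950) / 34950, 0.05)
  expect_equal(est$c_delivery_in, 230)
})

test_that("disjoint half-samples give mutually consistent estimates", {
  urban <- load_profile("urban")
  cfg <- model_generation_config("model_a", n_persons = 4000, seed = 22)
  rec <- generate_cohort(urban, cfg)
  half <- rec$person_id <= 2000
  e1 <- estimate_annual_probability(rec[half, ], "death", "telehealth")
  e2 <- estimate_annual_probability(rec[!half, ], "death", "telehealth")
  joint_hw <- (e1$ci_high - e1$ci_low) / 2 + (e2$ci_high - e2$ci_low) / 2
  expect_lt(abs(e1$estimate - e2$estimate), joint_hw)
})

test_that("an empty stratum is an undefined-estimate error", {
  rec <- make_person_years(rep("in_person", 5))
  d <- make_discharges("ED")
  w <- costing_weights("80+", "female", 1)
  expect_error(estimate_all(rec, d, w, delivery_cost_values = list(
    c_delivery_in = 1, c_delivery_tele = 1), stratum = "rural"),
    "no person-year records")
})
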