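# Parameter estimation: turns person-year and discharge records into the
# model inputs of the cost-effectiveness analysis — annual transition and
# mortality probabilities, utilization rates, per-event costs standardized by
# age and gender, delivery-mode costs, and caregiver-burden effectiveness.

#' Estimate an annual event probability from person-year records
#'
#' Events divided by person-years at risk. A person-year is at risk for a
#' modality when the year *starts* in that modality (a person who switches
#' contributes the year to the origin modality), consistent with the annual
#' cycles of the Markov engine. Because the model applies death first and
#' switching only among survivors, the switch probability is conditional on
#' surviving the year: its denominator is the at-risk person-years that
#' survive, so the estimator is consistent with the transition probability
#' the Markov matrix uses. A Wilson 95% score interval accompanies the point
#' estimate.
#'
#' @param records Person-year records (see [generate_cohort()]).
#' @param event `"switch"` or `"death"`.
#' @param modality `"in_person"` or `"telehealth"`.
#' @return List with `estimate`, `ci_low`, `ci_high` (Wilson 95%), `events`,
#'   and `person_years`.
#' @export
estimate_annual_probability <- function(records,
                                        event = c("switch", "death"),
                                        modality = MODALITIES) {
  event <- match.arg(event)
  modality <- match.arg(modality)
  at_risk <- records[records$modality_at_start == modality, , drop = FALSE]
  if (event == "switch") {
    # conditional on surviving the year (death-first event ordering)
    at_risk <- at_risk[!at_risk$died_this_year, , drop = FALSE]
  }
  n <- nrow(at_risk)
  if (n == 0L) {
    abort_param("no person-years at risk in modality `%s`: estimate undefined",
                modality)
  }
  x <- sum(if (event == "switch") at_risk$switched_this_year
           else at_risk$died_this_year)
  ci <- if (x %in% c(0L, n)) {
    # prop.test degenerates at the boundary; Wilson closed form still applies
    wilson_ci(x, n)
  } else {
    as.numeric(stats::prop.test(x, n, correct = FALSE)$conf.int)
  }
  list(estimate = x / n, ci_low = ci[1], ci_high = ci[2],
       events = x, person_years = n)
}

# Wilson score interval at 95%; used only where prop.test is degenerate.
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, mid - half), min(1, mid + half))
}

#' Estimate a mean annual utilization rate
#'
#' Total event count divided by person-years observed in the modality.
#'
#' @param records Person-year records.
#' @param event `"ed"` (emergency department visits) or `"hosp"`
#'   (hospitalizations).
#' @param modality `"in_person"` or `"telehealth"`.
#' @return List with `estimate` (events/person-year), `se` (standard error of
#'   the mean), `events`, and `person_years`.
#' @export
estimate_event_rate <- function(records,
                                event = c("ed", "hosp"),
                                modality = MODALITIES) {
  event <- match.arg(event)
  modality <- match.arg(modality)
  at_risk <- records[records$modality_at_start == modality, , drop = FALSE]
  n <- nrow(at_risk)
  if (n == 0L) {
    abort_param("no person-years observed in modality `%s`: estimate undefined",
                modality)
  }
  counts <- if (event == "ed") at_risk$ed_visit_count
            else at_risk$hospitalization_count
  list(estimate = mean(counts),
       se = stats::sd(counts) / sqrt(n),
       events = sum(counts), person_years = n)
}

#' Age-and-gender standardization weights for cost estimation
#'
#' @param age_band Character vector of age bands (`"<=79"`, `"80+"`).
#' @param gender Character vector of genders (`"male"`, `"female"`).
#' @param weight Nonnegative weights summing to 1.
#' @return A `costing_weights` data frame.
#' @seealso [default_costing_weights()] to derive weights from a profile.
#' @export
costing_weights <- function(age_band, gender, weight) {
  check_nonneg(weight, "weight")
  if (abs(sum(weight) - 1) > 1e-6) {
    abort_param("costing weights must sum to 1 (got %.6f)", sum(weight))
  }
  out <- data.frame(age_band = age_band, gender = gender,
                    weight = weight / sum(weight), stringsAsFactors = FALSE)
  if (anyDuplicated(paste(out$age_band, out$gender))) {
    abort_param("duplicate (age_band, gender) cells in costing weights")
  }
  class(out) <- c("costing_weights", "data.frame")
  out
}

#' Costing weights implied by a demographic profile
#'
#' Builds the `{<=79, 80+} x {male, female}` standardization cells as the
#' product of the profile's age-band share (computed from its calibrated
#' truncated-normal age distribution) and its gender distribution. The
#' `other` gender category is pooled with the cohort-majority gender
#' (female) for weighting, since the discharge data are stratified by binary
#' gender.
#'
#' @param profile A [demographic_profile()].
#' @return A [costing_weights()] object with four cells.
#' @export
default_costing_weights <- function(profile) {
  p_young <- truncnorm_p_below(profile, 80)
  p_male <- profile$gender_probs[["male"]]
  p_female <- profile$gender_probs[["female"]] + profile$gender_probs[["other"]]
  g <- c(male = p_male, female = p_female)
  g <- g / sum(g)
  costing_weights(
    age_band = rep(c("<=79", "80+"), each = 2),
    gender = rep(c("male", "female"), 2),
    weight = c(p_young * g, (1 - p_young) * g)
  )
}

truncnorm_p_below <- function(profile, cut) {
  lo <- stats::pnorm(profile$age_min, profile$age_latent_mu,
                     profile$age_latent_sigma)
  hi <- stats::pnorm(profile$age_max, profile$age_latent_mu,
                     profile$age_latent_sigma)
  (stats::pnorm(min(cut, profile$age_max), profile$age_latent_mu,
                profile$age_latent_sigma) - lo) / (hi - lo)
}

#' Estimate the mean cost per ED visit or hospitalization
#'
#' Combines lengths of stay with average daily charges per principal
#' diagnosis, directly standardized by age and gender: within each
#' `(age_band, gender)` cell, each event is priced as its length of stay
#' times the mean daily charge of its cell-and-principal-diagnosis group;
#' cell-level mean event costs are then combined with the supplied
#' standardization weights. Weight cells with no observed events are dropped
#' with a warning and the remaining weights renormalized.
#'
#' @param discharges Discharge records (see [generate_discharges()]).
#' @param setting `"ED"` or `"inpatient"`.
#' @param weights A [costing_weights()] object.
#' @return Mean cost per event, USD.
#' @export
estimate_event_cost <- function(discharges, setting = c("ED", "inpatient"),
                                weights) {
  setting <- match.arg(setting)
  if (!inherits(weights, "costing_weights")) {
    abort_param("`weights` must be a costing_weights object")
  }
  d <- discharges[discharges$setting == setting, , drop = FALSE]
  if (nrow(d) == 0L) {
    abort_param("no discharges in setting `%s`: estimate undefined", setting)
  }
  gender <- ifelse(d$gender %in% c("male", "female"), d$gender, "female")
  cell <- paste(d$age_band, gender, sep = "|")
  grp <- paste(cell, d$principal_dx, sep = "|")
  grp_mean_charge <- tapply(d$daily_charge, grp, mean)
  event_cost <- d$los_days * as.numeric(grp_mean_charge[grp])
  cell_mean <- tapply(event_cost, cell, mean)

  wcell <- paste(weights$age_band, weights$gender, sep = "|")
  observed <- wcell %in% names(cell_mean)
  if (!all(observed)) {
    warning(sprintf("no %s events in weight cell(s) %s; renormalizing remaining weights",
                    setting, paste(wcell[!observed], collapse = ", ")),
            call. = FALSE)
  }
  w <- weights$weight[observed]
  if (sum(w) == 0) {
    abort_param("all observed %s events fall in zero-weight cells", setting)
  }
  w <- w / sum(w)
  sum(w * as.numeric(cell_mean[wcell[observed]]))
}

#' Assemble all model inputs from person-level records
#'
#' Composes the component estimators into one set of model inputs: annual
#' switch and mortality probabilities per modality, ED and hospitalization
#' rates, age-and-gender standardized per-event costs, annual delivery-mode
#' costs, and mean modified ZBI-12 effectiveness per modality. Each
#' probability estimate is reported with its Wilson 95% interval via
#' `message()`.
#'
#' @param records Person-year records.
#' @param discharges Discharge records; the ADRD principal-diagnosis filter
#'   ([select_adrd_records()]) is applied before costing.
#' @param weights A [costing_weights()] object.
#' @param delivery_inputs Optional [delivery_cost_inputs()]; when supplied,
#'   annual delivery costs are built with [delivery_costs()].
#' @param delivery_cost_values Optional named list with `c_delivery_in` and
#'   `c_delivery_tele` (USD/year), used verbatim when the underlying cost
#'   construction inputs are not available (as with the published totals).
#' @param stratum Optional stratum label to subset `records` by.
#' @return An `estimated_parameters` object: a named list of the model
#'   inputs, with an attached data frame of component estimates and
#'   confidence intervals (`attr(x, "components")`).
#' @export
estimate_all <- function(records, discharges, weights,
                         delivery_inputs = NULL,
                         delivery_cost_values = NULL,
                         stratum = NULL) {
  if (!is.null(stratum)) {
    records <- records[records$stratum == stratum, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    abort_param("no person-year records%s: estimates undefined",
                if (is.null(stratum)) "" else sprintf(" in stratum `%s`", stratum))
  }
  discharges <- select_adrd_records(discharges)

  comp <- list()
  probe <- function(name, est) {
    comp[[name]] <<- est
    if (!is.null(est$ci_low)) {
      message(sprintf("  %-22s %.4f (95%% CI %.4f-%.4f, %d/%d person-years)",
                      name, est$estimate, est$ci_low, est$ci_high,
                      est$events, est$person_years))
    }
    est$estimate
  }

  p_it <- probe("p_switch_in_to_tele",
                estimate_annual_probability(records, "switch", "in_person"))
  p_ti <- probe("p_switch_tele_to_in",
                estimate_annual_probability(records, "switch", "telehealth"))
  m_in <- probe("m_in", estimate_annual_probability(records, "death", "in_person"))
  m_te <- probe("m_tele", estimate_annual_probability(records, "death", "telehealth"))
  ed_in <- probe("ed_rate_in", estimate_event_rate(records, "ed", "in_person"))
  ed_te <- probe("ed_rate_tele", estimate_event_rate(records, "ed", "telehealth"))
  h_in <- probe("hosp_rate_in", estimate_event_rate(records, "hosp", "in_person"))
  h_te <- probe("hosp_rate_tele", estimate_event_rate(records, "hosp", "telehealth"))

  c_ed <- estimate_event_cost(discharges, "ED", weights)
  c_hosp <- estimate_event_cost(discharges, "inpatient", weights)

  if (!is.null(delivery_inputs)) {
    dc <- delivery_costs(delivery_inputs)
  } else if (!is.null(delivery_cost_values)) {
    dc <- delivery_cost_values
  } else {
    abort_param("supply either `delivery_inputs` or `delivery_cost_values`")
  }

  e_by_mod <- function(mod) {
    z <- records$zbi12_raw[records$modality_at_start == mod]
    mean(rescale_zbi(z))
  }

  out <- structure(list(
    p_switch_in_to_tele = p_it,
    p_switch_tele_to_in = p_ti,
    m_in = m_in, m_tele = m_te,
    ed_rate_in = ed_in, ed_rate_tele = ed_te,
    hosp_rate_in = h_in, hosp_rate_tele = h_te,
    c_ed = c_ed, c_hosp = c_hosp,
    c_delivery_in = dc$c_delivery_in,
    c_delivery_tele = dc$c_delivery_tele,
    e_in = e_by_mod("in_person"),
    e_tele = e_by_mod("telehealth")
  ), class = "estimated_parameters")
  attr(out, "components") <- comp
  out
}

#' Write estimated parameters to a structured parameter file
#'
#' @param params An `estimated_parameters` object (or any named list of the
#'   same fields, probabilities as decimals).
#' @param path Output file path (YAML).
#' @export
write_parameters <- function(params, path) {
  fields <- unclass(params)
  fields <- fields[!vapply(fields, is.null, logical(1))]
  yaml::write_yaml(lapply(fields, as.numeric), path, precision = 15)
  invisible(path)
}

#' Read a structured parameter file
#'
#' @param path Path to a YAML parameter file written by
#'   [write_parameters()] (or a packaged scenario fixture).
#' @return A named list of parameter values.
#' @export
read_parameters <- function(path) {
  yaml::read_yaml(path)
}
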