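# Packaged scenario fixtures: the published model inputs for the three
# cost-effectiveness scenarios (urban non-Hispanic White, urban racial
# minorities, rural), stored exactly as printed (percent converted to
# decimals, USD as given).

#' Names of the packaged scenario models
#'
#' @return Character vector: `"model_a"`, `"model_b"`, `"model_c"`.
#' @export
list_models <- function() {
  names(read_model_fixtures())
}

read_model_fixtures <- function() {
  yaml::read_yaml(system.file("extdata", "models.yaml",
                              package = "teleCEA", mustWork = TRUE))
}

#' Load the Markov parameters of a packaged scenario
#'
#' @param model `"model_a"` (urban non-Hispanic White), `"model_b"` (urban
#'   racial minorities) or `"model_c"` (rural residents).
#' @param include_utilization_costs Passed to [markov_parameters()].
#' @param discount_rate,horizon Override the scenario's defaults (3%/year,
#'   10 cycles).
#' @return A [markov_parameters()] object. The published ICER for the
#'   scenario is attached as `attr(x, "icer_printed")` for deviation
#'   reporting only; it enters no computation.
#' @export
model_parameters <- function(model,
                             include_utilization_costs = FALSE,
                             discount_rate = NULL, horizon = NULL) {
  fixtures <- read_model_fixtures()
  if (!is.character(model) || length(model) != 1L ||
      !(model %in% names(fixtures))) {
    abort_param("unknown model `%s`; available fixtures: %s",
                as.character(model)[1],
                paste(names(fixtures), collapse = ", "))
  }
  f <- fixtures[[model]]
  params <- markov_parameters(
    p_switch_in_to_tele = f$p_switch_in_to_tele,
    p_switch_tele_to_in = f$p_switch_tele_to_in,
    m_in = f$m_in, m_tele = f$m_tele,
    c_delivery_in = f$c_delivery_in, c_delivery_tele = f$c_delivery_tele,
    e_in = f$e_in, e_tele = f$e_tele,
    ed_rate_in = f$ed_rate_in, ed_rate_tele = f$ed_rate_tele,
    hosp_rate_in = f$hosp_rate_in, hosp_rate_tele = f$hosp_rate_tele,
    c_ed = f$c_ed, c_hosp = f$c_hosp,
    discount_rate = discount_rate %||% f$discount_rate,
    horizon = horizon %||% f$horizon,
    include_utilization_costs = include_utilization_costs,
    label = f$label
  )
  attr(params, "icer_printed") <- f$icer_printed
  attr(params, "stratum") <- f$stratum
  params
}

#' Generator configuration matching a packaged scenario
#'
#' Builds a [generation_config()] whose event probabilities, utilization
#' means and caregiver-burden targets are the scenario's published model
#' inputs, so that re-estimating parameters from the generated records
#' recovers the scenario settings. Charge calibration: the mean daily charge
#' equals the scenario's cost per ED visit (ED stays last 1 day), and the
#' mean inpatient length of stay is the ratio of the hospitalization cost to
#' the ED cost, so that mean per-event costs reproduce the published unit
#' costs.
#'
#' @param model Scenario name, see [list_models()].
#' @param n_persons,n_years,seed Passed to [generation_config()].
#' @param ... Further overrides passed to [generation_config()].
#' @return A [generation_config()] object.
#' @export
model_generation_config <- function(model, n_persons, n_years = 1L, seed, ...) {
  p <- model_parameters(model)
  defaults <- list(
    n_persons = n_persons, n_years = n_years, seed = seed,
    p_switch = c(in_person = p$p_switch_in_to_tele,
                 telehealth = p$p_switch_tele_to_in),
    p_death = c(in_person = p$m_in, telehealth = p$m_tele),
    ed_mean = c(in_person = p$ed_rate_in, telehealth = p$ed_rate_tele),
    hosp_mean = c(in_person = p$hosp_rate_in, telehealth = p$hosp_rate_tele),
    zbi_raw_mean = c(in_person = zbi_raw_from_modified(p$e_in),
                     telehealth = zbi_raw_from_modified(p$e_tele)),
    los_mean = p$c_hosp / p$c_ed,
    daily_charge_mean = p$c_ed,
    daily_charge_sd = 0.25 * p$c_ed
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(generation_config, defaults)
}
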