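# Delivery-mode costing: the two annual cost components the model attaches to
# a year of primary care in each modality. Telehealth carries a caregiver
# training labor cost; in-person care carries travel plus caregiver labor
# productivity loss.

#' Caregiver time saved by a telehealth visit
#'
#' Minutes saved per visit relative to attending in person:
#' `roundtrip_drive + (in_person_visit - telehealth_visit)`. The result can be
#' negative when the telehealth visit runs longer than the drive and the
#' in-person visit combined.
#'
#' @param roundtrip_drive Roundtrip drive time, minutes (>= 0).
#' @param in_person_visit In-person visit duration, minutes (>= 0).
#' @param telehealth_visit Telehealth visit duration, minutes (>= 0).
#' @return Time savings in minutes per visit.
#' @examples
#' time_savings(60, 30, 15)  # 75
#' @export
time_savings <- function(roundtrip_drive, in_person_visit, telehealth_visit) {
  check_nonneg(roundtrip_drive, "roundtrip_drive")
  check_nonneg(in_person_visit, "in_person_visit")
  check_nonneg(telehealth_visit, "telehealth_visit")
  roundtrip_drive + (in_person_visit - telehealth_visit)
}

#' Inputs for the annual delivery-mode cost construction
#'
#' @param trainer_wage Telehealth trainer hourly wage, USD/hour.
#' @param training_hours_per_conversion Trainer hours spent per conversion of
#'   one patient/caregiver dyad from in-person to telehealth care.
#' @param conversion_probability Annual probability of converting from
#'   in-person to telehealth visits, in `[0, 1]`.
#' @param roundtrip_drive_time Roundtrip home-to-clinic drive time, minutes.
#' @param in_person_visit_time In-person visit duration, minutes.
#' @param telehealth_visit_time Telehealth visit duration, minutes.
#' @param wage_rate Caregiver opportunity-cost wage, USD/hour.
#' @param distance_roundtrip Roundtrip distance, miles.
#' @param mileage_rate Vehicle cost per mile, USD/mile.
#' @param visits_per_year Primary care visits per year.
#' @return A validated `delivery_cost_inputs` list.
#' @export
delivery_cost_inputs <- function(trainer_wage,
                                 training_hours_per_conversion,
                                 conversion_probability,
                                 roundtrip_drive_time,
                                 in_person_visit_time,
                                 telehealth_visit_time,
                                 wage_rate,
                                 distance_roundtrip,
                                 mileage_rate,
                                 visits_per_year) {
  inputs <- list(
    trainer_wage = trainer_wage,
    training_hours_per_conversion = training_hours_per_conversion,
    conversion_probability = conversion_probability,
    roundtrip_drive_time = roundtrip_drive_time,
    in_person_visit_time = in_person_visit_time,
    telehealth_visit_time = telehealth_visit_time,
    wage_rate = wage_rate,
    distance_roundtrip = distance_roundtrip,
    mileage_rate = mileage_rate,
    visits_per_year = visits_per_year
  )
  for (nm in names(inputs)) check_nonneg(inputs[[nm]], nm)
  check_prob(conversion_probability, "conversion_probability")
  structure(inputs, class = "delivery_cost_inputs")
}

#' Annual delivery-mode costs for the two strategies
#'
#' Telehealth: expected training labor per person-year,
#' `trainer_wage * training_hours_per_conversion * conversion_probability`.
#' In-person: per-visit travel cost (`distance_roundtrip * mileage_rate`) plus
#' the caregiver's labor productivity loss valued at the wage rate over the
#' time a telehealth visit would have saved, scaled by visits per year.
#'
#' Both components are homogeneous of degree one in the wage and mileage
#' rates.
#'
#' @param inputs A [delivery_cost_inputs()] object.
#' @return Named list with `c_delivery_in` and `c_delivery_tele` (USD/year).
#' @export
delivery_costs <- function(inputs) {
  if (!inherits(inputs, "delivery_cost_inputs")) {
    inputs <- do.call(delivery_cost_inputs, as.list(inputs))
  }
  ts <- time_savings(inputs$roundtrip_drive_time,
                     inputs$in_person_visit_time,
                     inputs$telehealth_visit_time)
  c_tele <- inputs$trainer_wage * inputs$training_hours_per_conversion *
    inputs$conversion_probability
  c_in <- inputs$visits_per_year *
    (inputs$distance_roundtrip * inputs$mileage_rate +
       (ts / 60) * inputs$wage_rate)
  list(c_delivery_in = c_in, c_delivery_tele = c_tele)
}

#' Convert a cost to a later year's dollars with healthcare inflation
#'
#' Compounds annual healthcare inflation rates over
#' `[from_year, to_year)`: `cost * prod(1 + rate_y)`. Identity when
#' `from_year == to_year`.
#'
#' @param cost Cost in `from_year` dollars.
#' @param from_year Calendar year of the input cost.
#' @param to_year Target calendar year (default 2022, the analysis baseline).
#' @param rates Named numeric vector of annual healthcare inflation rates as
#'   decimals; names are calendar years. Every year in
#'   `[from_year, to_year)` must be present.
#' @return Cost in `to_year` dollars.
#' @examples
#' adjust_inflation(100, 2021, 2022, c("2021" = 0.05))  # 105
#' @export
adjust_inflation <- function(cost, from_year, to_year = 2022, rates = NULL) {
  check_nonneg(cost, "cost")
  if (from_year > to_year) {
    abort_param("`from_year` (%d) must not be after `to_year` (%d)",
                from_year, to_year)
  }
  if (from_year == to_year) return(cost)
  years <- as.character(seq(from_year, to_year - 1L))
  missing <- setdiff(years, names(rates %||% numeric()))
  if (length(missing)) {
    abort_param("missing healthcare inflation rate(s) for year(s): %s",
                paste(missing, collapse = ", "))
  }
  cost * prod(1 + unlist(rates)[years])
}
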