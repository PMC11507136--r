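# Generation configuration: every stochastic knob of the synthetic cohort and
# discharge generators. Per-modality quantities are named vectors over
# c("in_person", "telehealth").

MODALITIES <- c("in_person", "telehealth")
ADRD_CODES <- c("F01", "F02", "F03")

per_modality <- function(x, name) {
  if (length(x) == 1L && is.null(names(x))) {
    x <- stats::setNames(rep(x, 2L), MODALITIES)
  }
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)) || !setequal(names(x), MODALITIES)) {
    abort_param("`%s` must be a single value or named over %s", name,
                paste(MODALITIES, collapse = ", "))
  }
  x[MODALITIES]
}

#' Configuration for the synthetic cohort and discharge generators
#'
#' @param n_persons Number of persons to simulate.
#' @param n_years Maximum follow-up years per person (default 1).
#' @param seed Integer random seed; mandatory so every run is reproducible.
#' @param p_switch Annual probability of switching delivery modality, a
#'   single value or named vector over `in_person`/`telehealth`.
#' @param p_death Annual death probability, same shape as `p_switch`.
#' @param ed_mean Annual Poisson mean of emergency department visits, per
#'   modality.
#' @param hosp_mean Annual Poisson mean of hospitalizations, per modality.
#' @param zbi_raw_mean Target mean raw ZBI-12 score (0-48 scale), per
#'   modality. The latent truncated-normal location is calibrated so the
#'   realised mean matches this target exactly.
#' @param zbi_raw_sd Target SD of raw ZBI-12 scores.
#' @param los_mean Mean inpatient length of stay in days (>= 1); inpatient
#'   LOS is drawn as `1 + Poisson(los_mean - 1)`, ED stays are fixed at 1 day.
#' @param daily_charge_mean,daily_charge_sd Daily hospital charge
#'   distribution, USD/day (normal truncated at zero).
#' @param adrd_code_probs Named probabilities over the ADRD ICD-10-CM
#'   chapters `F01`, `F02`, `F03` for the principal diagnosis.
#' @param contamination_frac Fraction of discharge records given a non-ADRD
#'   principal diagnosis, in `[0, 1)`.
#' @param p_telehealth_start Probability that a person starts follow-up in
#'   the telehealth modality (default 0.5).
#' @return A validated `generation_config` object.
#' @export
generation_config <- function(n_persons,
                              n_years = 1L,
                              seed,
                              p_switch = 0,
                              p_death = 0,
                              ed_mean = 0,
                              hosp_mean = 0,
                              zbi_raw_mean = 24,
                              zbi_raw_sd = 9,
                              los_mean = 5,
                              daily_charge_mean = 6000,
                              daily_charge_sd = 1500,
                              adrd_code_probs = c(F01 = 0.15, F02 = 0.15,
                                                  F03 = 0.70),
                              contamination_frac = 0,
                              p_telehealth_start = 0.5) {
  n_persons <- check_count(n_persons, "n_persons")
  n_years <- check_count(n_years, "n_years")
  if (n_years < 1L) abort_param("`n_years` must be at least 1")
  if (missing(seed) || is.null(seed)) {
    abort_param("`seed` is mandatory: every generator run must be reproducible")
  }
  seed <- as.integer(seed)

  p_switch <- check_prob(per_modality(p_switch, "p_switch"), "p_switch")
  p_death <- check_prob(per_modality(p_death, "p_death"), "p_death")
  ed_mean <- check_nonneg(per_modality(ed_mean, "ed_mean"), "ed_mean")
  hosp_mean <- check_nonneg(per_modality(hosp_mean, "hosp_mean"), "hosp_mean")
  zbi_raw_mean <- per_modality(zbi_raw_mean, "zbi_raw_mean")
  if (any(zbi_raw_mean < 0) || any(zbi_raw_mean > 48)) {
    abort_param("`zbi_raw_mean` must lie in [0, 48]")
  }
  check_nonneg(zbi_raw_sd, "zbi_raw_sd")
  check_nonneg(los_mean, "los_mean")
  if (los_mean < 1) abort_param("`los_mean` must be at least 1 day")
  check_nonneg(daily_charge_mean, "daily_charge_mean")
  check_nonneg(daily_charge_sd, "daily_charge_sd")
  adrd_code_probs <- normalize_probs(adrd_code_probs, ADRD_CODES,
                                     "adrd_code_probs")
  check_prob(contamination_frac, "contamination_frac")
  if (contamination_frac >= 1) abort_param("`contamination_frac` must be < 1")
  check_prob(p_telehealth_start, "p_telehealth_start")

  # Calibrate latent ZBI locations so realised truncated means hit targets.
  zbi_latent <- vapply(zbi_raw_mean, function(m) {
    if (m <= 0 || m >= 48) m else solve_truncnorm_mu(m, zbi_raw_sd, 0, 48)
  }, numeric(1))

  structure(list(
    n_persons = n_persons, n_years = n_years, seed = seed,
    p_switch = p_switch, p_death = p_death,
    ed_mean = ed_mean, hosp_mean = hosp_mean,
    zbi_raw_mean = zbi_raw_mean, zbi_raw_sd = zbi_raw_sd,
    zbi_latent_mu = zbi_latent,
    los_mean = los_mean,
    daily_charge_mean = daily_charge_mean,
    daily_charge_sd = daily_charge_sd,
    adrd_code_probs = adrd_code_probs,
    contamination_frac = contamination_frac,
    p_telehealth_start = p_telehealth_start
  ), class = "generation_config")
}

#' @export
print.generation_config <- function(x, ...) {
  cat(sprintf("<generation_config: %d persons x up to %d year(s), seed %d>\n",
              x$n_persons, x$n_years, x$seed))
  cat(sprintf("  p_switch in/tele: %.4f / %.4f; p_death: %.4f / %.4f\n",
              x$p_switch[1], x$p_switch[2], x$p_death[1], x$p_death[2]))
  cat(sprintf("  ED mean: %.2f / %.2f; hosp mean: %.2f / %.2f\n",
              x$ed_mean[1], x$ed_mean[2], x$hosp_mean[1], x$hosp_mean[2]))
  cat(sprintf("  ZBI-12 raw mean: %.2f / %.2f (sd %.1f)\n",
              x$zbi_raw_mean[1], x$zbi_raw_mean[2], x$zbi_raw_sd))
  invisible(x)
}
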