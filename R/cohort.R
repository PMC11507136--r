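# Synthetic cohort generator. Emulates the person-year structure behind the
# published utilization tables: annual death and modality-switch events,
# Poisson ED / hospitalization counts, and integer ZBI-12 caregiver burden
# scores, for a cohort drawn from a demographic profile.

PERSON_YEAR_FIELDS <- c(
  "person_id", "year_index", "stratum", "age", "gender", "race",
  "modality_at_start", "switched_this_year", "died_this_year",
  "ed_visit_count", "hospitalization_count", "zbi12_raw"
)

DISCHARGE_FIELDS <- c(
  "record_id", "person_id", "setting", "principal_dx", "los_days",
  "daily_charge", "age_band", "gender"
)

# Dotted ICD-10-CM codes used for synthetic principal diagnoses.
ADRD_DX_CODES <- list(
  F01 = c("F01.50", "F01.51"),
  F02 = c("F02.80", "F02.81"),
  F03 = c("F03.90", "F03.91")
)
NON_ADRD_DX_CODES <- c("G30.9", "I10", "E11.9", "J18.9", "N39.0", "I63.9")

derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + stage * 1000003) %% 2147483647)
}

#' Generate a synthetic person-year cohort
#'
#' Simulates `n_persons` forward for up to `n_years` annual cycles or until
#' death. Each year, death is evaluated first with the modality-specific
#' annual probability; modality switching is evaluated among survivors
#' (matching the transition ordering of the cohort Markov engine); ED and
#' hospitalization counts are drawn from modality-specific Poisson means and
#' accrue regardless of same-year death. Ages are truncated-normal draws
#' calibrated to the profile's target moments; raw ZBI-12 scores are
#' truncated-normal draws on `[0, 48]` rounded to integers.
#'
#' @param profile A [demographic_profile()].
#' @param config A [generation_config()].
#' @return A data frame of person-year records with columns `person_id`,
#'   `year_index`, `stratum`, `age`, `gender`, `race`, `modality_at_start`,
#'   `switched_this_year`, `died_this_year`, `ed_visit_count`,
#'   `hospitalization_count`, `zbi12_raw`. Deterministic given
#'   `config$seed`.
#' @export
generate_cohort <- function(profile, config) {
  if (!inherits(profile, "demographic_profile")) {
    abort_param("`profile` must be a demographic_profile")
  }
  if (!inherits(config, "generation_config")) {
    abort_param("`config` must be a generation_config")
  }
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_persons
  if (n == 0L) {
    return(empty_frame(PERSON_YEAR_FIELDS))
  }

  age0 <- rtruncnorm(n, profile$age_latent_mu, profile$age_latent_sigma,
                     profile$age_min, profile$age_max)
  gender <- sample(names(profile$gender_probs), n, replace = TRUE,
                   prob = profile$gender_probs)
  race <- sample(names(profile$race_probs), n, replace = TRUE,
                 prob = profile$race_probs)
  modality <- ifelse(stats::runif(n) < config$p_telehealth_start,
                     "telehealth", "in_person")

  alive <- rep(TRUE, n)
  years <- vector("list", config$n_years)
  for (y in seq_len(config$n_years)) {
    idx <- which(alive)
    if (!length(idx)) break
    mod <- modality[idx]
    died <- stats::runif(length(idx)) < config$p_death[mod]
    switched <- !died & (stats::runif(length(idx)) < config$p_switch[mod])
    ed <- stats::rpois(length(idx), config$ed_mean[mod])
    hosp <- stats::rpois(length(idx), config$hosp_mean[mod])
    zbi <- round(rtruncnorm(length(idx), config$zbi_latent_mu[mod],
                            config$zbi_raw_sd, 0, 48))
    years[[y]] <- data.frame(
      person_id = idx,
      year_index = y,
      stratum = profile$stratum,
      age = age0[idx] + (y - 1),
      gender = gender[idx],
      race = race[idx],
      modality_at_start = mod,
      switched_this_year = switched,
      died_this_year = died,
      ed_visit_count = ed,
      hospitalization_count = hosp,
      zbi12_raw = as.integer(zbi),
      stringsAsFactors = FALSE
    )
    alive[idx[died]] <- FALSE
    flip <- idx[switched]
    modality[flip] <- ifelse(modality[flip] == "in_person",
                             "telehealth", "in_person")
  }
  out <- do.call(rbind, years)
  out <- out[order(out$person_id, out$year_index), PERSON_YEAR_FIELDS]
  rownames(out) <- NULL
  out
}

empty_frame <- function(fields) {
  out <- as.data.frame(stats::setNames(rep(list(logical(0)), length(fields)),
                                       fields))
  out
}

#' Generate synthetic ED / hospital discharge records
#'
#' Expands the counted events of a person-year cohort into one discharge
#' record per ED visit or hospitalization, in the style of statewide
#' emergency-department / inpatient discharge data: a principal ICD-10-CM
#' diagnosis, a length of stay (fixed at 1 day for ED visits, `1 +
#' Poisson(los_mean - 1)` for inpatient stays), and a daily charge drawn from
#' a positive-truncated normal. A configurable fraction of records receives
#' a non-ADRD principal diagnosis to exercise the cohort selection filter.
#'
#' @param records Person-year records from [generate_cohort()].
#' @param config The same [generation_config()] used for the cohort.
#' @return A data frame of discharge records with columns `record_id`,
#'   `person_id`, `setting`, `principal_dx`, `los_days`, `daily_charge`,
#'   `age_band`, `gender`. The number of rows equals the total ED plus
#'   hospitalization count of `records`.
#' @export
generate_discharges <- function(records, config) {
  if (!inherits(config, "generation_config")) {
    abort_param("`config` must be a generation_config")
  }
  if (!is.data.frame(records)) {
    abort_param("`records` must be a person-year data frame")
  }
  set.seed(derive_seed(config$seed, 2L))
  if (nrow(records) == 0L ||
      sum(records$ed_visit_count) + sum(records$hospitalization_count) == 0L) {
    return(empty_frame(DISCHARGE_FIELDS))
  }

  expand <- function(counts, setting) {
    data.frame(
      person_id = rep(records$person_id, counts),
      setting = rep(setting, sum(counts)),
      age = rep(records$age, counts),
      gender = rep(records$gender, counts),
      stringsAsFactors = FALSE
    )
  }
  src <- rbind(expand(records$ed_visit_count, "ED"),
               expand(records$hospitalization_count, "inpatient"))
  m <- nrow(src)
  los <- ifelse(src$setting == "ED", 1L,
                1L + stats::rpois(m, max(config$los_mean - 1, 0)))
  charge <- rtruncnorm(m, config$daily_charge_mean, config$daily_charge_sd,
                       .Machine$double.eps, Inf)
  chapter <- sample(names(config$adrd_code_probs), m, replace = TRUE,
                    prob = config$adrd_code_probs)
  dx <- character(m)
  for (ch in names(ADRD_DX_CODES)) {
    i <- chapter == ch
    if (any(i)) dx[i] <- sample(ADRD_DX_CODES[[ch]], sum(i), replace = TRUE)
  }
  contam <- stats::runif(m) < config$contamination_frac
  if (any(contam)) {
    dx[contam] <- sample(NON_ADRD_DX_CODES, sum(contam), replace = TRUE)
  }
  out <- data.frame(
    record_id = seq_len(m),
    person_id = src$person_id,
    setting = src$setting,
    principal_dx = dx,
    los_days = as.integer(los),
    daily_charge = charge,
    age_band = age_band(src$age),
    gender = src$gender,
    stringsAsFactors = FALSE
  )
  out
}

# Age bands used for cost standardization, mirroring the published cohort
# table's split at 79/80.
age_band <- function(age) {
  ifelse(age < 80, "<=79", "80+")
}

#' Select records with an ADRD principal diagnosis
#'
#' Keeps exactly the records whose principal ICD-10-CM code, after trimming
#' whitespace and ignoring case, begins with F01, F02, or F03 (any sub-code
#' digits allowed). Malformed or empty code strings are excluded with a
#' message, never an error.
#'
#' @param records A data frame with a `principal_dx` column.
#' @return The subset of `records` carrying an ADRD principal diagnosis.
#' @examples
#' df <- data.frame(principal_dx = c("F01.50", "F03.90", "I10", "G30.9"))
#' select_adrd_records(df)  # keeps the first two
#' @export
select_adrd_records <- function(records) {
  if (!is.data.frame(records) || !("principal_dx" %in% names(records))) {
    abort_param("`records` must be a data frame with a `principal_dx` column")
  }
  if (nrow(records) == 0L) return(records)
  code <- trimws(as.character(records$principal_dx))
  bad <- is.na(code) | code == ""
  if (any(bad)) {
    message(sprintf("select_adrd_records: excluding %d record(s) with empty or malformed diagnosis codes",
                    sum(bad)))
  }
  keep <- !bad & grepl("^F0[123]", code, ignore.case = TRUE)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
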