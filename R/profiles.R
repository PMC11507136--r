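# Demographic profiles: the age / gender / race distributions the synthetic
# cohort generator draws from. Packaged profiles mirror the published cohort
# description of the Nevada urban (n = 58) and rural (n = 33) ADRD telehealth
# users, plus the two urban race strata used by the scenario models.

GENDERS <- c("male", "female", "other")
RACES <- c("nh_white", "nh_black", "hispanic_latino", "nh_asian", "other_mixed")
STRATA <- c("urban", "urban_nhw", "urban_minority", "rural")

#' Construct a demographic profile
#'
#' A demographic profile describes the population a synthetic cohort is drawn
#' from: a truncated-normal age distribution (the latent normal is calibrated
#' so the *realised* truncated mean equals `age_mean` exactly and the realised
#' SD is as close to `age_sd` as the truncation allows) and categorical
#' gender and race distributions.
#'
#' @param stratum One of `"urban"`, `"urban_nhw"`, `"urban_minority"`,
#'   `"rural"`.
#' @param age_mean,age_sd Target mean and standard deviation of age, years.
#' @param age_min,age_max Age range bounds, years (`age_min <= age_max`).
#' @param gender_probs Named probabilities over `male`, `female`, `other`;
#'   must sum to 1.
#' @param race_probs Named probabilities over `nh_white`, `nh_black`,
#'   `hispanic_latino`, `nh_asian`, `other_mixed`; must sum to 1.
#' @return A `demographic_profile` object.
#' @seealso [load_profile()] for the packaged profiles.
#' @export
demographic_profile <- function(stratum, age_mean, age_sd, age_min, age_max,
                                gender_probs, race_probs) {
  check_choice(stratum, STRATA, "stratum")
  check_nonneg(age_sd, "age_sd")
  if (age_min > age_max) abort_param("`age_min` must be <= `age_max`")
  if (age_mean <= age_min || age_mean >= age_max) {
    abort_param("`age_mean` must lie strictly inside [age_min, age_max]")
  }
  gender_probs <- normalize_probs(gender_probs, GENDERS, "gender_probs")
  race_probs <- normalize_probs(race_probs, RACES, "race_probs")
  fit <- fit_truncnorm(age_mean, age_sd, age_min, age_max)
  structure(list(
    stratum = stratum,
    age_mean = age_mean, age_sd = age_sd,
    age_min = age_min, age_max = age_max,
    gender_probs = gender_probs, race_probs = race_probs,
    age_latent_mu = fit$mu, age_latent_sigma = fit$sigma,
    age_realised_sd = fit$sd
  ), class = "demographic_profile")
}

# Validate a named probability vector over a fixed category set; tolerate
# rounding in stored fixtures (<= 1e-4 off) and renormalise exactly.
normalize_probs <- function(p, categories, name) {
  if (is.list(p)) p <- unlist(p)
  if (is.null(names(p)) || !setequal(names(p), categories)) {
    abort_param("`%s` must be named with exactly: %s", name,
                paste(categories, collapse = ", "))
  }
  p <- p[categories]
  check_prob(p, name)
  if (abs(sum(p) - 1) > 1e-4) {
    abort_param("`%s` must sum to 1 (got %.6f)", name, sum(p))
  }
  p / sum(p)
}

#' Load a packaged demographic profile
#'
#' @param name Profile name: `"urban"` (full urban cohort), `"urban_nhw"`,
#'   `"urban_minority"`, or `"rural"`.
#' @return A [demographic_profile()] object.
#' @export
load_profile <- function(name = c("urban", "urban_nhw", "urban_minority",
                                  "rural")) {
  name <- match.arg(name)
  all <- yaml::read_yaml(system.file("extdata", "profiles.yaml",
                                     package = "teleCEA", mustWork = TRUE))
  p <- all[[name]]
  demographic_profile(
    stratum = p$stratum,
    age_mean = p$age_mean, age_sd = p$age_sd,
    age_min = p$age_min, age_max = p$age_max,
    gender_probs = unlist(p$gender_probs),
    race_probs = unlist(p$race_probs)
  )
}

#' @export
print.demographic_profile <- function(x, ...) {
  cat(sprintf("<demographic_profile: %s>\n", x$stratum))
  cat(sprintf("  age: mean %.1f, target sd %.1f (realised %.2f), range [%g, %g]\n",
              x$age_mean, x$age_sd, x$age_realised_sd, x$age_min, x$age_max))
  cat("  gender:", paste(sprintf("%s %.1f%%", names(x$gender_probs),
                                 100 * x$gender_probs), collapse = ", "), "\n")
  cat("  race:", paste(sprintf("%s %.1f%%", names(x$race_probs),
                               100 * x$race_probs), collapse = ", "), "\n")
  invisible(x)
}
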