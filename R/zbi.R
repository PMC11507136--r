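#' Rescale raw ZBI-12 caregiver burden onto the modified 0-100 scale
#'
#' The 12-item short-form Zarit Burden Interview (ZBI-12) scores caregiver
#' burden from 0 (minimum burden) to 48 (maximum burden). The analysis uses a
#' modified scale running from 0 (maximum burden) to 100 (minimum burden) as
#' its effectiveness measure, so that larger values are better, in analogy
#' with utility weights. The map is linear:
#' `modified = 100 * (1 - raw / 48)`.
#'
#' @param raw Numeric vector of raw ZBI-12 scores in `[0, 48]`.
#' @return Numeric vector of modified scores in `[0, 100]`, strictly
#'   decreasing in `raw`.
#' @examples
#' rescale_zbi(c(0, 24, 48))  # 100, 50, 0
#' @seealso [zbi_raw_from_modified()] for the inverse map.
#' @export
rescale_zbi <- function(raw) {
  if (!is.numeric(raw) || anyNA(raw) || any(raw < 0) || any(raw > 48)) {
    abort_param("raw ZBI-12 scores must lie in [0, 48]")
  }
  100 * (1 - raw / 48)
}

#' Invert the modified ZBI-12 rescaling
#'
#' @param modified Numeric vector of modified scores in `[0, 100]`.
#' @return Raw ZBI-12 scores in `[0, 48]`.
#' @export
zbi_raw_from_modified <- function(modified) {
  if (!is.numeric(modified) || anyNA(modified) ||
      any(modified < 0) || any(modified > 100)) {
    abort_param("modified ZBI-12 scores must lie in [0, 100]")
  }
  48 * (1 - modified / 100)
}
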