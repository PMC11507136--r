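# Independent oracles used across the suite.

# Individual-level microsimulation of the three-state process. Walkers are
# advanced by simulating the yearly events directly (death first, then
# switching among survivors), not by the cohort engine's transition matrix,
# so it is an independent check of the cohort trace.
microsim_trace <- function(params, start_state, n_walkers = 1e5, seed = 4242) {
  set.seed(seed)
  state <- rep(start_state, n_walkers)
  m <- c(in_person = params$m_in, telehealth = params$m_tele)
  s <- c(in_person = params$p_switch_in_to_tele,
         telehealth = params$p_switch_tele_to_in)
  other <- c(in_person = "telehealth", telehealth = "in_person")
  trace <- matrix(0, nrow = params$horizon + 1L, ncol = 3L,
                  dimnames = list(NULL, c("in_person", "telehealth", "dead")))
  tally <- function(st) c(mean(st == "in_person"), mean(st == "telehealth"),
                          mean(st == "dead"))
  trace[1L, ] <- tally(state)
  for (t in seq_len(params$horizon)) {
    live <- state != "dead"
    idx <- which(live)
    dies <- runif(length(idx)) < m[state[idx]]
    state[idx[dies]] <- "dead"
    idx2 <- idx[!dies]
    switches <- runif(length(idx2)) < s[state[idx2]]
    state[idx2[switches]] <- other[state[idx2[switches]]]
    trace[t + 1L, ] <- tally(state)
  }
  trace
}

# Compare a cohort-trace column with its microsimulated counterpart. The
# per-cell tolerance is 3 binomial SEs; across the dozens of cells of a full
# trace the expected number of ~3-SE exceedances from sampling noise alone is
# of order 0.2, so a single cell is allowed past 3 SE provided every cell
# stays within 4.5 SE (a per-cell chance below 1e-5).
expect_trace_matches_microsim <- function(trace, microsim, n_walkers) {
  for (state in colnames(trace)) {
    q <- trace[, state]
    se <- sqrt(pmax(q * (1 - q), 1e-12) / n_walkers)
    z <- abs(microsim[, state] - q) / se
    testthat::expect_lte(sum(z > 3), 1)
    testthat::expect_true(all(z <= 4.5),
                          info = sprintf("state %s", state))
  }
}

# Small hand-built person-year frame for estimator unit tests.
make_person_years <- function(modality, switched = FALSE, died = FALSE,
                              ed = 0, hosp = 0, zbi = 24,
                              stratum = "urban") {
  n <- max(length(modality), length(switched), length(died), length(ed),
           length(hosp), length(zbi))
  data.frame(
    person_id = seq_len(n), year_index = 1L, stratum = stratum,
    age = 80, gender = "female", race = "nh_white",
    modality_at_start = rep_len(modality, n),
    switched_this_year = rep_len(switched, n),
    died_this_year = rep_len(died, n),
    ed_visit_count = rep_len(ed, n),
    hospitalization_count = rep_len(hosp, n),
    zbi12_raw = rep_len(zbi, n),
    stringsAsFactors = FALSE
  )
}

make_discharges <- function(setting, principal_dx = "F03.90", los = 1,
                            charge = 500, age_band = "80+",
                            gender = "female") {
  n <- max(length(setting), length(principal_dx), length(los),
           length(charge), length(age_band), length(gender))
  data.frame(
    record_id = seq_len(n), person_id = seq_len(n),
    setting = rep_len(setting, n),
    principal_dx = rep_len(principal_dx, n),
    los_days = rep_len(los, n),
    daily_charge = rep_len(charge, n),
    age_band = rep_len(age_band, n),
    gender = rep_len(gender, n),
    stringsAsFactors = FALSE
  )
}

# Parameters with no dynamics: useful for closed-form reward checks.
static_params <- function(c_in = 230, c_te = 202, e_in = 70.28, e_te = 67.35,
                          discount = 0, horizon = 10L, ...) {
  markov_parameters(
    p_switch_in_to_tele = 0, p_switch_tele_to_in = 0,
    m_in = 0, m_tele = 0,
    c_delivery_in = c_in, c_delivery_tele = c_te,
    e_in = e_in, e_tele = e_te,
    discount_rate = discount, horizon = horizon, ...
  )
}

# Random valid Markov parameters for property-style loops.
random_params <- function() {
  markov_parameters(
    p_switch_in_to_tele = runif(1), p_switch_tele_to_in = runif(1),
    m_in = runif(1), m_tele = runif(1),
    c_delivery_in = runif(1, 0, 1000), c_delivery_tele = runif(1, 0, 1000),
    e_in = runif(1, 0, 100), e_tele = runif(1, 0, 100),
    discount_rate = runif(1, 0, 0.1),
    horizon = sample(1:15, 1)
  )
}
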