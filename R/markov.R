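# The decision-analytic core: a three-state Markov cohort model of primary
# care delivery for people living with ADRD. States are the delivery modality
# in use (in-person, telehealth) plus death; the cohort advances in yearly
# cycles over a 10-year horizon, and per-cycle costs and caregiver-burden
# effectiveness (modified ZBI-12) are discounted at 3% per year.

STATES <- c("in_person", "telehealth", "dead")

#' Parameters of the three-state Markov cohort model
#'
#' @param p_switch_in_to_tele,p_switch_tele_to_in Annual probability of
#'   switching delivery modality, conditional on surviving the cycle.
#' @param m_in,m_tele Annual death probability in each modality.
#' @param c_delivery_in,c_delivery_tele Annual delivery-mode cost, USD/cycle
#'   (travel + caregiver productivity loss for in-person; training labor for
#'   telehealth).
#' @param e_in,e_tele Per-cycle effectiveness: mean modified ZBI-12 on the
#'   0 (maximum burden) to 100 (minimum burden) scale.
#' @param ed_rate_in,ed_rate_tele,hosp_rate_in,hosp_rate_tele Annual ED and
#'   hospitalization rates, events/cycle.
#' @param c_ed,c_hosp Cost per ED visit / hospitalization, USD/event.
#' @param discount_rate Per-cycle discount rate (default 0.03).
#' @param horizon Number of cycles (default 10).
#' @param include_utilization_costs If `TRUE`, each live state's per-cycle
#'   cost also includes expected utilization spending
#'   (`ed_rate * c_ed + hosp_rate * c_hosp`). Off by default: the base-case
#'   comparison uses the delivery-mode costs alone.
#' @param half_cycle_correction If `TRUE`, rewards accrue on the average of
#'   start- and end-of-cycle occupancy. Off by default: rewards accrue at
#'   cycle start (cycle 0 undiscounted).
#' @param label Optional scenario label carried through to results.
#' @return A validated `markov_parameters` object.
#' @export
markov_parameters <- function(p_switch_in_to_tele, p_switch_tele_to_in,
                              m_in, m_tele,
                              c_delivery_in, c_delivery_tele,
                              e_in, e_tele,
                              ed_rate_in = 0, ed_rate_tele = 0,
                              hosp_rate_in = 0, hosp_rate_tele = 0,
                              c_ed = 0, c_hosp = 0,
                              discount_rate = 0.03, horizon = 10L,
                              include_utilization_costs = FALSE,
                              half_cycle_correction = FALSE,
                              label = NULL) {
  check_prob(p_switch_in_to_tele, "p_switch_in_to_tele")
  check_prob(p_switch_tele_to_in, "p_switch_tele_to_in")
  check_prob(m_in, "m_in")
  check_prob(m_tele, "m_tele")
  for (nm in c("c_delivery_in", "c_delivery_tele", "ed_rate_in",
               "ed_rate_tele", "hosp_rate_in", "hosp_rate_tele",
               "c_ed", "c_hosp", "discount_rate")) {
    check_nonneg(get(nm), nm)
  }
  for (nm in c("e_in", "e_tele")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 100) {
      abort_param("`%s` must lie on the modified ZBI-12 scale [0, 100]", nm)
    }
  }
  horizon <- check_count(horizon, "horizon")
  if (horizon < 1L) abort_param("`horizon` must be at least 1 cycle")
  structure(list(
    p_switch_in_to_tele = p_switch_in_to_tele,
    p_switch_tele_to_in = p_switch_tele_to_in,
    m_in = m_in, m_tele = m_tele,
    c_delivery_in = c_delivery_in, c_delivery_tele = c_delivery_tele,
    e_in = e_in, e_tele = e_tele,
    ed_rate_in = ed_rate_in, ed_rate_tele = ed_rate_tele,
    hosp_rate_in = hosp_rate_in, hosp_rate_tele = hosp_rate_tele,
    c_ed = c_ed, c_hosp = c_hosp,
    discount_rate = discount_rate, horizon = horizon,
    include_utilization_costs = isTRUE(include_utilization_costs),
    half_cycle_correction = isTRUE(half_cycle_correction),
    label = label
  ), class = "markov_parameters")
}

params_signature <- function(params) {
  num <- unlist(params[vapply(params, is.numeric, logical(1))])
  paste(format(num, digits = 15), collapse = "|")
}

#' Build the annual transition matrix
#'
#' Row-stochastic 3x3 matrix over (in_person, telehealth, dead). Within a
#' cycle death is applied first and switching only among survivors: for a
#' live state with mortality `m` and switch probability `s`,
#' `P(state -> dead) = m`, `P(state -> other live) = s * (1 - m)`,
#' `P(state -> state) = (1 - s) * (1 - m)`. Death is absorbing.
#'
#' @param params A [markov_parameters()] object.
#' @return A 3x3 matrix with rows summing exactly to 1.
#' @export
build_transition_matrix <- function(params) {
  if (!inherits(params, "markov_parameters")) {
    abort_param("`params` must be a markov_parameters object")
  }
  with(params, {
    P <- rbind(
      c((1 - p_switch_in_to_tele) * (1 - m_in),
        p_switch_in_to_tele * (1 - m_in),
        m_in),
      c(p_switch_tele_to_in * (1 - m_tele),
        (1 - p_switch_tele_to_in) * (1 - m_tele),
        m_tele),
      c(0, 0, 1)
    )
    dimnames(P) <- list(STATES, STATES)
    P
  })
}

#' Advance the cohort and return its trace
#'
#' Starts 100% of the cohort in `start_state` at cycle 0 and advances it
#' through the transition matrix for `horizon` cycles. Occupancy
#' conservation (rows sum to 1) and monotonicity of the dead state are
#' asserted on every run.
#'
#' @param params A [markov_parameters()] object.
#' @param start_state `"in_person"` or `"telehealth"`.
#' @return A `cohort_trace`: a `(horizon + 1) x 3` matrix of state-occupancy
#'   fractions, one row per cycle `0..horizon`.
#' @export
run_cohort <- function(params, start_state = c("in_person", "telehealth")) {
  start_state <- match.arg(start_state)
  P <- build_transition_matrix(params)
  T_ <- params$horizon
  trace <- matrix(0, nrow = T_ + 1L, ncol = 3L,
                  dimnames = list(cycle = 0:T_, state = STATES))
  trace[1L, start_state] <- 1
  for (t in seq_len(T_)) {
    trace[t + 1L, ] <- trace[t, ] %*% P
  }
  stopifnot(
    all(abs(rowSums(trace) - 1) < 1e-12),
    all(diff(trace[, "dead"]) >= -1e-15)
  )
  structure(trace, class = c("cohort_trace", "matrix"),
            start_state = start_state,
            signature = params_signature(params))
}

#' Accrue discounted cost and effectiveness over a cohort trace
#'
#' For each cycle `t = 0..horizon-1`, each live state contributes
#' `occupancy * reward`, discounted by `(1 + discount_rate)^(-t)`. The cost
#' reward of a live state is its annual delivery-mode cost (plus expected
#' utilization spending when `include_utilization_costs` is on); the
#' effectiveness reward is its mean modified ZBI-12. Death contributes zero
#' cost and zero effectiveness. Discounted person-years alive are
#' accumulated alongside, so results can also be expressed per person-year
#' lived.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param params The same [markov_parameters()] the trace was run with.
#' @return A `strategy_outcome`: discounted and undiscounted totals of cost,
#'   effectiveness and person-years alive, plus the trace.
#' @export
accrue <- function(trace, params) {
  if (!inherits(trace, "cohort_trace")) {
    abort_param("`trace` must be a cohort_trace from run_cohort()")
  }
  if (nrow(trace) != params$horizon + 1L) {
    abort_param("trace has %d rows but params specify horizon %d",
                nrow(trace), params$horizon)
  }
  util_in <- if (params$include_utilization_costs) {
    params$ed_rate_in * params$c_ed + params$hosp_rate_in * params$c_hosp
  } else 0
  util_te <- if (params$include_utilization_costs) {
    params$ed_rate_tele * params$c_ed + params$hosp_rate_tele * params$c_hosp
  } else 0
  cost_r <- c(params$c_delivery_in + util_in,
              params$c_delivery_tele + util_te, 0)
  eff_r <- c(params$e_in, params$e_tele, 0)
  live_r <- c(1, 1, 0)

  T_ <- params$horizon
  occ <- if (params$half_cycle_correction) {
    (trace[1:T_, , drop = FALSE] + trace[2:(T_ + 1L), , drop = FALSE]) / 2
  } else {
    trace[1:T_, , drop = FALSE]
  }
  disc <- (1 + params$discount_rate)^(-(0:(T_ - 1L)))

  total <- function(reward, d) sum(d * (occ %*% reward))
  structure(list(
    strategy = paste0(attr(trace, "start_state"), "_start"),
    discounted_cost = total(cost_r, disc),
    discounted_effect = total(eff_r, disc),
    discounted_life_years = total(live_r, disc),
    undiscounted_cost = total(cost_r, rep(1, T_)),
    undiscounted_effect = total(eff_r, rep(1, T_)),
    undiscounted_life_years = total(live_r, rep(1, T_)),
    trace = trace,
    signature = attr(trace, "signature"),
    label = params$label
  ), class = "strategy_outcome")
}

#' Run one strategy through the Markov model
#'
#' Convenience wrapper: [run_cohort()] then [accrue()]. A strategy is the
#' delivery modality the cohort starts in; switching thereafter follows the
#' transition matrix.
#'
#' @inheritParams run_cohort
#' @return A `strategy_outcome`.
#' @export
run_strategy <- function(params, start_state = c("in_person", "telehealth")) {
  start_state <- match.arg(start_state)
  accrue(run_cohort(params, start_state), params)
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome: %s%s>\n", x$strategy,
              if (is.null(x$label)) "" else paste0(" (", x$label, ")")))
  cat(sprintf("  discounted cost:   %12.2f USD (undiscounted %12.2f)\n",
              x$discounted_cost, x$undiscounted_cost))
  cat(sprintf("  discounted effect: %12.2f ZBI point-years (undiscounted %12.2f)\n",
              x$discounted_effect, x$undiscounted_effect))
  cat(sprintf("  discounted person-years alive: %.4f\n", x$discounted_life_years))
  invisible(x)
}

#' Trace as a data frame
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return Data frame with columns `cycle`, `in_person`, `telehealth`,
#'   `dead`.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(cycle = as.integer(rownames(unclass(x))),
             in_person = x[, "in_person"],
             telehealth = x[, "telehealth"],
             dead = x[, "dead"],
             row.names = NULL)
}
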