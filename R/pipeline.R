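# Pipeline orchestration: reproducible file-based stages (simulate ->
# estimate -> run -> report) over the package's computational core. Every
# output file carries a provenance header (package version, seed, config
# hash) and contains no timestamps, so a fixed-seed rerun is byte-identical.

PIPELINE_VERSION <- "teleCEA pipeline v1"

# 32-bit FNV-1a hash of a deparse()d R object; cheap content fingerprint for
# provenance headers (not cryptographic).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

provenance_header <- function(seed, hash) {
  c(sprintf("# %s", PIPELINE_VERSION),
    sprintf("# seed: %s", format(seed)),
    sprintf("# config_hash: %s", hash))
}

#' Write a pipeline output table with a provenance header
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @param hash Configuration hash recorded in the header.
#' @export
write_output_csv <- function(df, path, seed = NA, hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline output table, skipping the provenance header
#'
#' @param path Path written by [write_output_csv()].
#' @return A data frame.
#' @export
read_output_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Simulate stage: write synthetic person-year and discharge CSVs
#'
#' @param profile A [demographic_profile()] or the name of a packaged
#'   profile (see [load_profile()]).
#' @param config A [generation_config()]; its mandatory seed drives all
#'   draws.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the two data frames and the file paths
#'   (`person_years.csv`, `discharges.csv`, `manifest.yaml`).
#' @export
run_simulate <- function(profile, config, out_dir) {
  if (is.character(profile)) profile <- load_profile(profile)
  if (!inherits(config, "generation_config")) {
    abort_param("`config` must be a generation_config (seed mandatory)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- generate_cohort(profile, config)
  discharges <- generate_discharges(records, config)
  hash <- config_hash(list(profile = unclass(profile),
                           config = unclass(config)))
  py_path <- file.path(out_dir, "person_years.csv")
  dc_path <- file.path(out_dir, "discharges.csv")
  write_output_csv(records, py_path, config$seed, hash)
  write_output_csv(discharges, dc_path, config$seed, hash)
  manifest <- list(stage = "simulate", version = PIPELINE_VERSION,
                   seed = config$seed, config_hash = hash,
                   n_persons = config$n_persons,
                   n_person_years = nrow(records),
                   n_discharges = nrow(discharges))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  message(sprintf("simulate: %d person-years, %d discharges -> %s",
                  nrow(records), nrow(discharges), out_dir))
  invisible(list(records = records, discharges = discharges,
                 person_years = py_path, discharges_path = dc_path))
}

#' Estimate stage: model inputs from simulated CSVs
#'
#' @param in_dir Directory holding `person_years.csv` and `discharges.csv`
#'   from [run_simulate()].
#' @param weights A [costing_weights()] object, or a profile (name or
#'   object) from which [default_costing_weights()] derives them.
#' @param delivery_inputs,delivery_cost_values Passed to [estimate_all()].
#' @param out_path Output parameter file (YAML); default
#'   `parameters.yaml` inside `in_dir`.
#' @return The `estimated_parameters`, invisibly.
#' @export
run_estimate <- function(in_dir, weights,
                         delivery_inputs = NULL,
                         delivery_cost_values = NULL,
                         out_path = file.path(in_dir, "parameters.yaml")) {
  records <- read_output_csv(file.path(in_dir, "person_years.csv"))
  discharges <- read_output_csv(file.path(in_dir, "discharges.csv"))
  if (nrow(records) == 0L) {
    abort_param("empty person-year input: nothing to estimate")
  }
  if (is.character(weights)) weights <- load_profile(weights)
  if (inherits(weights, "demographic_profile")) {
    weights <- default_costing_weights(weights)
  }
  message("estimate: component estimates (95% Wilson CIs)")
  est <- estimate_all(records, discharges, weights,
                      delivery_inputs = delivery_inputs,
                      delivery_cost_values = delivery_cost_values)
  write_parameters(est, out_path)
  message(sprintf("estimate: parameters -> %s", out_path))
  invisible(est)
}

#' Run stage: Markov strategies and CEA for one scenario
#'
#' @param parameters A [markov_parameters()] object, the name of a packaged
#'   fixture (`"model_a"`, `"model_b"`, `"model_c"`), or the path of a
#'   parameter file written by [run_estimate()].
#' @param out_dir Optional output directory; when given, cohort traces (one
#'   row per cycle) and a machine-readable results file are written there.
#' @param per_life_year,include_utilization_costs,discount_rate,horizon
#'   Analysis options; see [compute_icer()] and [markov_parameters()].
#' @return A list with both `strategy_outcome`s and the `cea_result`.
#' @export
run_cea <- function(parameters, out_dir = NULL,
                    per_life_year = TRUE,
                    include_utilization_costs = FALSE,
                    discount_rate = NULL, horizon = NULL) {
  params <- resolve_parameters(parameters, include_utilization_costs,
                               discount_rate, horizon)
  o_in <- run_strategy(params, "in_person")
  o_te <- run_strategy(params, "telehealth")
  res <- compute_icer(o_te, o_in, per_life_year = per_life_year)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hash <- config_hash(unclass(params))
    write_output_csv(as.data.frame(o_in$trace),
                     file.path(out_dir, "trace_in_person.csv"), NA, hash)
    write_output_csv(as.data.frame(o_te$trace),
                     file.path(out_dir, "trace_telehealth.csv"), NA, hash)
    yaml::write_yaml(list(
      version = PIPELINE_VERSION, config_hash = hash,
      label = params$label,
      strategies = list(
        in_person_start = outcome_fields(o_in),
        telehealth_start = outcome_fields(o_te)),
      cea = list(per_life_year = per_life_year,
                 delta_cost = res$delta_cost,
                 delta_effect = res$delta_effect,
                 icer_standard = res$icer_standard,
                 icer_reported = res$icer_reported,
                 dominance = res$dominance)
    ), file.path(out_dir, "results.yaml"))
  }
  list(in_person = o_in, telehealth = o_te, cea = res)
}

outcome_fields <- function(o) {
  o[c("discounted_cost", "discounted_effect", "discounted_life_years",
      "undiscounted_cost", "undiscounted_effect", "undiscounted_life_years")]
}

resolve_parameters <- function(parameters, include_utilization_costs,
                               discount_rate, horizon) {
  if (inherits(parameters, "markov_parameters")) return(parameters)
  if (is.character(parameters) && length(parameters) == 1L) {
    if (parameters %in% list_models()) {
      return(model_parameters(parameters,
                              include_utilization_costs =
                                include_utilization_costs,
                              discount_rate = discount_rate,
                              horizon = horizon))
    }
    if (file.exists(parameters)) {
      p <- read_parameters(parameters)
      return(markov_parameters(
        p_switch_in_to_tele = p$p_switch_in_to_tele,
        p_switch_tele_to_in = p$p_switch_tele_to_in,
        m_in = p$m_in, m_tele = p$m_tele,
        c_delivery_in = p$c_delivery_in, c_delivery_tele = p$c_delivery_tele,
        e_in = p$e_in, e_tele = p$e_tele,
        ed_rate_in = p$ed_rate_in %||% 0,
        ed_rate_tele = p$ed_rate_tele %||% 0,
        hosp_rate_in = p$hosp_rate_in %||% 0,
        hosp_rate_tele = p$hosp_rate_tele %||% 0,
        c_ed = p$c_ed %||% 0, c_hosp = p$c_hosp %||% 0,
        discount_rate = discount_rate %||% p$discount_rate %||% 0.03,
        horizon = horizon %||% p$horizon %||% 10L,
        include_utilization_costs = include_utilization_costs))
    }
    abort_param("unknown parameters `%s`: not a fixture (%s) and not a file",
                parameters, paste(list_models(), collapse = ", "))
  }
  abort_param("`parameters` must be markov_parameters, a fixture name, or a file path")
}

#' Report stage: published-scenario reproduction to disk
#'
#' Runs [reproduce_paper_models()] and, when `out_dir` is given, writes the
#' scenario table (`scenario_table.csv`, two delivery-type rows per model)
#' and the deviation log (`icer_deviation.csv`).
#'
#' @inheritParams reproduce_paper_models
#' @param out_dir Optional output directory.
#' @return The `paper_reproduction` object, invisibly.
#' @export
run_reproduce_paper <- function(out_dir = NULL,
                                per_life_year = TRUE,
                                include_utilization_costs = FALSE) {
  rep <- reproduce_paper_models(per_life_year = per_life_year,
                                include_utilization_costs =
                                  include_utilization_costs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hash <- config_hash(rep$table)
    write_output_csv(rep$table, file.path(out_dir, "scenario_table.csv"),
                     NA, hash)
    write_output_csv(rep$deviation, file.path(out_dir, "icer_deviation.csv"),
                     NA, hash)
  }
  invisible(rep)
}
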