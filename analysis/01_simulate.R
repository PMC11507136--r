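#!/usr/bin/env Rscript
# Stage 1 — simulate the study data.
#
# The real person-level delivery, utilization and discharge records behind
# the analysis are not publicly available, so this stage generates synthetic
# cohorts with the same statistical structure: urban and rural person-year
# panels with annual modality switches, deaths, Poisson ED/hospitalization
# counts and integer ZBI-12 caregiver-burden scores, plus one discharge
# record (principal diagnosis, length of stay, daily charge) per counted
# event. Event probabilities and utilization means are the published
# scenario settings, so stage 2 can try to recover them.

suppressPackageStartupMessages(library(teleCEA))

SEED <- 20221231
n_urban <- 6000   # person-years scale for stable parameter recovery
n_rural <- 6000

message("-- simulating urban cohort at the urban non-Hispanic-White scenario settings")
cfg_urban <- model_generation_config("model_a", n_persons = n_urban,
                                     n_years = 1, seed = SEED,
                                     contamination_frac = 0.10)
run_simulate("urban_nhw", cfg_urban, "results/sim/urban")

message("-- simulating rural cohort at the rural scenario settings")
cfg_rural <- model_generation_config("model_c", n_persons = n_rural,
                                     n_years = 1, seed = SEED + 1,
                                     contamination_frac = 0.10)
run_simulate("rural", cfg_rural, "results/sim/rural")

# A tenth of the discharge records deliberately carry non-ADRD principal
# diagnoses; stage 2 must filter them out the same way the cohort definition
# does (ICD-10-CM F01/F02/F03 prefixes).
for (arm in c("urban", "rural")) {
  d <- read_output_csv(file.path("results/sim", arm, "discharges.csv"))
  kept <- select_adrd_records(d)
  message(sprintf("%s: %d discharges, %d with ADRD principal diagnosis (%.1f%%)",
                  arm, nrow(d), nrow(kept), 100 * nrow(kept) / nrow(d)))
}
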