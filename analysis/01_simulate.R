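#!/usr/bin/env Rscript
# Synthesize the three stimulation-site cohorts (reduced trial counts so the
# whole workflow runs in minutes) and persist them as delimited matrices with
# JSON sidecars plus the ground-truth models.
library(tmslandscape)

networks <- default_networks()
head <- make_head_model(78, seed = derive_seed(20260919L, 777L), networks = networks)
truth <- ground_truth(networks, seed = derive_seed(20260919L, 778L),
                      planted_network = "sensorimotor", planted_delta_j = 0.5)
dir.create("scratch/cohorts", recursive = TRUE, showWarnings = FALSE)

for (site in c("left_motor", "left_prefrontal", "vermis")) {
  spec <- cohort_spec(site, n_trials_per_subject = 12,
                      seed = derive_seed(20260919L, match(site, c(
                        "left_motor", "left_prefrontal", "vermis"))))
  cohort <- synthesize_cohort(spec, truth, head)
  write_cohort(cohort, file.path("scratch/cohorts", site))
  message(sprintf("%s: %d patients + %d controls, %d trials each",
                  site, spec$n_patients, spec$n_controls,
                  spec$n_trials_per_subject))
}
message("cohorts written under scratch/cohorts/<site>/")
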