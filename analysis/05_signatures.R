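#!/usr/bin/env Rscript
# Run the four comparisons on the subject energies, apply the per-network
# Bonferroni and relevance gates, and emit the signature tables.
library(tmslandscape)

energies <- read.csv("results/subject_energies.csv")
records <- bonferroni_gate(run_comparisons(energies))
write.csv(records, "results/records.csv", row.names = FALSE)
sig <- build_signature_table(records, default_networks())
write.csv(sig, "results/signatures.csv", row.names = FALSE)
passing <- records[records$passes_bonferroni, ]
message(sprintf("%d of %d comparison records pass the per-network alpha/n gate",
                nrow(passing), nrow(records)))
if (nrow(passing)) {
  print(passing[, c("site", "network", "pattern_string", "comparison",
                    "p_value", "bonferroni_threshold", "cohens_d")])
}
message(sprintf("%d records additionally pass the 5e-5 relevance gate",
                sum(records$passes_relevance)))
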