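#!/usr/bin/env Rscript
# Fit group and subject energy landscapes per network and site; write the
# subject-wise energies of the selected stable states and print each
# network's stable states with their disconnectivity barriers.
library(tmslandscape)

cfg <- default_config()
networks <- default_networks()
head <- make_head_model(78, seed = derive_seed(20260919L, 777L), networks = networks)
energies <- list()
for (site_dir in list.dirs("scratch/cohorts", recursive = FALSE)) {
  man <- read.csv(file.path(site_dir, "manifest.csv"))
  rsl <- lapply(seq_len(nrow(man)), function(i) {
    subject_to_roi_series(read_subject(file.path(site_dir, man$file[i])),
                          head, cfg)
  })
  res <- landscape_stats_site(rsl, networks, cfg)
  energies[[basename(site_dir)]] <- res$energies
  for (nw in names(res$landscapes)) {
    ls <- res$landscapes[[nw]]$landscapes$control_pre
    message(sprintf("%s / %s: %d stable states in the controls' pre-TMS landscape",
                    basename(site_dir), nw, length(ls$local_minima)))
  }
}
energies <- do.call(rbind, energies)
write.csv(energies, "results/subject_energies.csv", row.names = FALSE)
message(sprintf("wrote %d subject-energy rows", nrow(energies)))
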