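#!/usr/bin/env Rscript
# Source-localize every subject's ERP with sLORETA, reduce to alpha-band ROI
# power, and write the tidy ROI activation table per site.
library(tmslandscape)

cfg <- default_config()
networks <- default_networks()
head <- make_head_model(78, seed = derive_seed(20260919L, 777L), networks = networks)
for (site_dir in list.dirs("scratch/cohorts", recursive = FALSE)) {
  man <- read.csv(file.path(site_dir, "manifest.csv"))
  rsl <- lapply(seq_len(nrow(man)), function(i) {
    subject_to_roi_series(read_subject(file.path(site_dir, man$file[i])),
                          head, cfg)
  })
  names(rsl) <- man$subject_id
  write_roi_table(rsl, file.path(site_dir, "roi_activations.csv"))
  message(sprintf("%s: wrote ROI activations for %d subjects (%d ROIs)",
                  basename(site_dir), length(rsl), nrow(rsl[[1]]$values)))
}
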