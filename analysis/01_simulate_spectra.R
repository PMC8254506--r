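#!/usr/bin/env Rscript
# Step 1: simulate UPLC/TOF peak lists for a wild-type chemotype and three
# biosynthetic knockouts (rhamnosylation, glucosylation, precursor supply),
# with ground truth, as the instrument-side inputs for the rest of the
# workflow. Run from the repository root.

suppressPackageStartupMessages(library(hgldtg))
out_dir <- "results/spectra"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- spectra_sim_config(seed = 101)  # 2 ppm mass error, 5 noise peaks/scan

wt <- gen_peaklists(cfg, n_samples = 1, group_labels = "control")
truth <- wt$truth
samples <- wt$peaklists
for (ko in c("rhamnosylation", "glucosylation", "precursor")) {
  cfg_ko <- cfg
  cfg_ko$seed <- cfg$seed + match(ko, c("rhamnosylation", "glucosylation",
                                        "precursor"))
  sim <- gen_knockout_profile(cfg_ko, ko)
  sim$peaklists[[1]]$sample_id <- paste0("S_", substr(ko, 1, 4))
  sim$truth$sample_id <- paste0("S_", substr(ko, 1, 4))
  samples <- c(samples, sim$peaklists)
  truth <- rbind(truth, sim$truth)
}

for (pl in samples) {
  f <- file.path(out_dir, paste0("peaks_", pl$sample_id, "_", pl$group, ".tsv"))
  write_peak_table(pl, f)
  message("wrote ", f, " (", nrow(pl$peaks), " peaks)")
}
write_dtg_tsv(truth, file.path(out_dir, "truth.tsv"))
message("planted ", nrow(truth), " ions across ", length(samples),
        " samples; ground truth in results/spectra/truth.tsv")
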