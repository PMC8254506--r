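#!/usr/bin/env Rscript
# Step 2: dereplicate the simulated peak lists by accurate mass (4 mDa
# tolerance, three positive-mode adducts), attach chemotype classes and
# reference names, and score recovery against the generator's ground truth.
# Requires analysis/01_simulate_spectra.R to have run.

suppressPackageStartupMessages(library(hgldtg))
in_dir <- "results/spectra"
out_dir <- "results/dereplication"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- dtg_config()  # tol 4 mDa, bounds hex<=4 dhex<=3 mal<=4
files <- list.files(in_dir, pattern = "^peaks_.*\\.tsv$", full.names = TRUE)
stopifnot(length(files) > 0)

ann <- do.call(rbind, lapply(files, function(f) {
  parts <- strsplit(sub("^peaks_(.*)\\.tsv$", "\\1", basename(f)), "_(?=[^_]+$)",
                    perl = TRUE)[[1]]
  pl <- read_peak_table(f, sample_id = parts[1], group = parts[2])
  dereplicate_peaklist(pl, config = cfg)
}))
write_dtg_tsv(ann, file.path(out_dir, "annotations.tsv"))

truth <- utils::read.delim(file.path(in_dir, "truth.tsv"))
rec <- recovery_rate(ann, truth)
message(sprintf("annotated %d peaks; recovered %.1f%% of %d planted ions",
                nrow(ann), 100 * rec, nrow(truth)))

per_sample <- do.call(rbind, lapply(split(truth, truth$sample_id), function(t) {
  data.frame(sample_id = t$sample_id[1], n_planted = nrow(t),
             recovery = recovery_rate(ann, t))
}))
write_dtg_tsv(per_sample, file.path(out_dir, "recovery.tsv"))
message("per-sample recovery written to results/dereplication/recovery.tsv")
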