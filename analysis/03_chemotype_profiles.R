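#!/usr/bin/env Rscript
# Step 3: chemotype profiling. The m/z 271.2420 in-source fragment trace
# visualizes the whole HGL-DTG complement of each sample in one chromatogram;
# integrated per-compound signal feeds a log2 fold-change matrix versus the
# control group and a per-class summary that shows each knockout's chemotype
# shift. Requires steps 01-02.

suppressPackageStartupMessages(library(hgldtg))
in_dir <- "results/spectra"
out_dir <- "results/chemotype"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

files <- list.files(in_dir, pattern = "^peaks_.*\\.tsv$", full.names = TRUE)
core <- fragment_mz_aglycone_core()
ann <- utils::read.delim("results/dereplication/annotations.tsv")

eic_areas <- do.call(rbind, lapply(files, function(f) {
  parts <- strsplit(sub("^peaks_(.*)\\.tsv$", "\\1", basename(f)), "_(?=[^_]+$)",
                    perl = TRUE)[[1]]
  pl <- read_peak_table(f, sample_id = parts[1], group = parts[2])
  tr <- compute_eic(pl, core, tol = 0.01)
  data.frame(sample_id = parts[1], group = parts[2],
             core_eic_area = integrate_peak(tr))
}))
write_dtg_tsv(eic_areas, file.path(out_dir, "core_eic_areas.tsv"))
message("core-fragment EIC areas (total chemotype per sample):")
for (i in seq_len(nrow(eic_areas))) {
  message(sprintf("  %-10s %-15s %12.0f", eic_areas$sample_id[i],
                  eic_areas$group[i], eic_areas$core_eic_area[i]))
}

# per-compound signal matrix (summed annotated intensity) and fold changes
ann$compound <- ifelse(is.na(ann$name),
                       paste0("hex", ann$n_hex, "_dhex", ann$n_dhex,
                              "_mal", ann$n_mal),
                       ann$name)
areas <- tapply(ann$intensity, list(ann$compound, ann$sample_id), sum,
                default = 0)
groups <- ann$group[match(colnames(areas), ann$sample_id)]
fc <- fold_change_matrix(areas, groups, control_group = "control", pseudo = 1)
write_dtg_tsv(data.frame(compound = rownames(fc), round(fc, 3),
                         check.names = FALSE),
              file.path(out_dir, "fold_change_matrix.tsv"))

summary <- chemotype_summary(ann)
write_dtg_tsv(summary, file.path(out_dir, "chemotype_summary.tsv"))
rham_ctrl <- summary$rhamnosylated[summary$sample_id == "S01"]
rham_ko <- summary$rhamnosylated[summary$sample_id == "S_rham"]
message(sprintf(paste0("rhamnosylated signal in the rhamnosylation knockout: ",
                       "%.1f%% of control"), 100 * rham_ko / rham_ctrl))
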