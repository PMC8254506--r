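#!/usr/bin/env Rscript
# Step 4: simulate the transcriptomic side -- a tissue x time x treatment
# microarray compendium (162 profiles) carrying a 5-gene co-regulated
# pathway module (two baits + three glycosyltransferases) over 104
# independent background genes, plus a synthetic UGT proteome with planted
# C-terminal PSPG boxes for the motif scan.

suppressPackageStartupMessages(library(hgldtg))
out_dir <- "results/expression"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

sim <- gen_expression(expr_sim_config(seed = 301))
m <- data.frame(gene = rownames(sim$compendium$expr),
                round(sim$compendium$expr, 2), check.names = FALSE)
write_dtg_tsv(m, file.path(out_dir, "expression_matrix.tsv"))
write_dtg_tsv(sim$compendium$samples, file.path(out_dir, "sample_annotation.tsv"))
write_dtg_tsv(sim$truth, file.path(out_dir, "expression_truth.tsv"))
message(sprintf("simulated %d genes x %d profiles (module: %s)",
                nrow(sim$compendium$expr), ncol(sim$compendium$expr),
                paste(sim$truth$gene[sim$truth$is_module], collapse = ", ")))

prot <- gen_proteome(n_with_motif = 107, n_without = 20, seed = 302)
fasta <- file.path(out_dir, "proteome_synthetic.fasta")
writeLines(paste0(">", prot$id, "\n", prot$sequence), fasta)
message("wrote ", fasta, " (", nrow(prot), " proteins, ",
        sum(prot$has_motif), " with a planted PSPG box)")
write_dtg_tsv(prot[, c("id", "has_motif")],
              file.path(out_dir, "proteome_truth.tsv"))
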