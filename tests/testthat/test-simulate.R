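test_that("generators are pure functions of config and seed", {
  cfg <- spectra_sim_config(seed = 101)
  a <- gen_peaklists(cfg)
  b <- gen_peaklists(cfg)
  expect_identical(a, b)
  c_ <- gen_peaklists(spectra_sim_config(seed = 102))
  expect_false(identical(a$truth$observed_mz, c_$truth$observed_mz))

  e1 <- gen_expression(expr_sim_config(seed = 55))
  e2 <- gen_expression(expr_sim_config(seed = 55))
  expect_identical(e1$compendium$expr, e2$compendium$expr)
})

test_that("planted spectra carry the designed structure", {
  cfg <- spectra_sim_config(mass_error_ppm_sd = 0, noise_peaks_per_scan = 0,
                            seed = 2)
  sim <- gen_peaklists(cfg, n_samples = 2, group_labels = c("wt", "ko"))
  expect_length(sim$peaklists, 2)
  expect_identical(unique(sim$truth$group), c("wt", "ko"))
  # at zero ppm error, every observed m/z is exactly theoretical
  expect_equal(sim$truth$observed_mz, sim$truth$theoretical_mz)
  # the diagnostic in-source core fragment is present in every DTG scan
  eic <- compute_eic(sim$peaklists[[1]], fragment_mz_aglycone_core(), 0.01)
  apex <- which.max(eic$intensity)
  expect_gt(eic$intensity[apex], 0)
  # and disabling it removes the trace
  cfg_off <- spectra_sim_config(mass_error_ppm_sd = 0, noise_peaks_per_scan = 0,
                                emit_core_fragment = FALSE, seed = 2)
  eic_off <- compute_eic(gen_peaklists(cfg_off)$peaklists[[1]],
                         fragment_mz_aglycone_core(), 0.01)
  expect_true(all(eic_off$intensity == 0))
})

test_that("knockout modes reshape abundances as documented", {
  cfg <- spectra_sim_config(mass_error_ppm_sd = 0, noise_peaks_per_scan = 0,
                            seed = 13)
  ctrl <- gen_peaklists(cfg)
  none <- gen_knockout_profile(cfg, "none")
  expect_identical(ctrl$truth$observed_mz, none$truth$observed_mz)

  gluc <- gen_knockout_profile(cfg, "glucosylation")
  expect_true(all(c("17-HGL", "G-17-HGL", "RGHGL") %in% gluc$truth$name))

  prec <- gen_knockout_profile(cfg, "precursor")
  s_ctrl <- chemotype_summary(dereplicate_peaklist(ctrl$peaklists[[1]]))
  s_prec <- chemotype_summary(dereplicate_peaklist(prec$peaklists[[1]]))
  expect_lt(s_prec$total, 0.2 * s_ctrl$total)
})

test_that("expression generator reproduces the compendium design and module", {
  cfg <- expr_sim_config(seed = 77)
  sim <- gen_expression(cfg)
  ann <- sim$compendium$samples
  expect_identical(nrow(ann), 3L * 6L * 3L * 3L)
  expect_setequal(unique(ann$tissue), c("treated_leaf", "systemic_leaf", "root"))
  expect_setequal(unique(ann$time_h), c(1, 5, 9, 13, 17, 21))
  expect_setequal(unique(ann$treatment),
                  c("control", "wounding", "simulated_herbivory"))
  expect_identical(nrow(sim$compendium$expr), 109L)

  # noise -> 0 drives module-gene correlation to 1 (the tiny residual comes
  # from gene-specific root suppression, not noise)
  quiet <- gen_expression(expr_sim_config(noise_sd_log2 = 0, seed = 78))
  expect_equal(pearson_cc(quiet$compendium$expr["GGPPS", ],
                          quiet$compendium$expr["UGT91T1", ]), 1,
               tolerance = 1e-3)

  # default noise separates module from background near-perfectly (AUC)
  aucs <- vapply(1:5, function(i) {
    s <- gen_expression(expr_sim_config(seed = 200 + i))
    pcc <- correlate_to_baits(s$compendium, "GGPPS")
    lab <- pcc$gene %in% s$truth$gene[s$truth$is_module]
    r <- rank(pcc$pcc_GGPPS)
    (sum(r[lab]) - sum(lab) * (sum(lab) + 1) / 2) / (sum(lab) * sum(!lab))
  }, numeric(1))
  expect_gte(mean(aucs), 0.99)
})
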