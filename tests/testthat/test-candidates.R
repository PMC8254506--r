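test_that("the PSPG scan hits planted boxes only at the C-terminus", {
  model <- pspg_model()
  set.seed(31)
  aa <- rownames(model$pwm)
  prefix <- paste(sample(aa, 150, TRUE), collapse = "")
  cterm <- data.frame(id = "cterm", sequence = paste0(prefix, model$consensus))
  hit <- scan_pspg(cterm, model)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$start, 151L)

  # the same consensus at the N-terminus of a long protein fails the filter
  tail_seq <- paste(sample(aa, 300, TRUE), collapse = "")
  nterm <- data.frame(id = "nterm", sequence = paste0(model$consensus, tail_seq))
  expect_identical(nrow(scan_pspg(nterm, model)), 0L)

  expect_warning(scan_pspg(data.frame(id = "short", sequence = "MKV"), model),
                 "skipped")
})

test_that("random-composition proteins rarely reach the score threshold", {
  model <- pspg_model()
  null_best <- pspg_null_scores(model, n = 1000, length = 300, seed = 5)
  expect_gte(mean(null_best < model$score_threshold), 0.99)
  # and every planted, PWM-sampled box clears it comfortably
  prot <- gen_proteome(50, 0, model = model, seed = 6)
  expect_identical(nrow(scan_pspg(prot, model)), 50L)
})

test_that("pearson_cc handles the standard and degenerate cases", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  expect_equal(pearson_cc(x, x), 1)
  expect_equal(pearson_cc(x, -x + 7), -1)
  expect_equal(pearson_cc(c(1, 2, 3), c(1, 2, 4)), 0.9820, tolerance = 1e-4)
  expect_warning(r <- pearson_cc(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_true(is.na(r))
  expect_error(pearson_cc(c(1, 2), c(1, 2)), "at least 3")
  # invariance under positive affine transforms
  set.seed(41)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(pearson_cc(2 * a + 3, b), pearson_cc(a, b), tolerance = 1e-12)
  expect_equal(pearson_cc(a, 0.5 * b - 1), pearson_cc(a, b), tolerance = 1e-12)
})

test_that("bait correlations separate the planted module from background", {
  sim <- gen_expression(expr_sim_config(seed = 17))
  comp <- sim$compendium
  # bait against itself through the same code path
  self <- correlate_to_baits(comp, "GGPPS", candidates = "GGPPS")
  expect_equal(self$pcc_GGPPS, 1)

  pcc <- correlate_to_baits(comp, c("GGPPS", "GLS"))
  mod <- pcc$gene %in% c("UGT91T1", "UGT74P3", "UGT74P5")
  expect_true(all(pcc$pcc_GGPPS[mod] >= 0.8))
  expect_true(all(abs(pcc$pcc_GGPPS) <= 1, na.rm = TRUE))
  # background genes are uncorrelated on average
  expect_lt(abs(mean(pcc$pcc_GGPPS[!mod])), 0.1)
  expect_error(correlate_to_baits(comp, "NOSUCH"), "absent")
})

test_that("tissue specificity and induction folds recover programmed effects", {
  cfg <- expr_sim_config(seed = 23,
                         root_suppression = c(GGPPS = 100, GLS = 100,
                                              UGT91T1 = 100, UGT74P3 = 100,
                                              UGT74P5 = 100))
  comp <- gen_expression(cfg)$compendium
  for (g in c("GGPPS", "UGT74P3")) {
    fold <- tissue_specificity(comp, g, treatment = "control", pseudo = 1e-9)
    expect_gt(fold, 100 / 1.5)
    expect_lt(fold, 100 * 1.5)
    ind <- induction_fold(comp, g, time_h = 5, pseudo = 1e-9)
    expect_gt(ind, 8 / 1.5)
    expect_lt(ind, 8 * 1.5)
  }
  # a flat background gene shows neither signal
  expect_equal(tissue_specificity(comp, "BG001"), 1, tolerance = 0.5)
  folds <- vapply(c(1, 5, 9, 13, 17, 21), function(t) {
    induction_fold(comp, "BG002", time_h = t)
  }, numeric(1))
  expect_true(all(folds > 0.5 & folds < 2))  # no systematic induction
  expect_equal(mean(folds), 1, tolerance = 0.3)
  expect_lt(tissue_specificity(
    expr_compendium(matrix(c(rep(1, 4), rep(100, 2)), 1,
                           dimnames = list("g", paste0("s", 1:6))),
                    data.frame(sample_id = paste0("s", 1:6),
                               tissue = rep(c("treated_leaf", "systemic_leaf",
                                              "root"), each = 2),
                               time_h = 5, treatment = "control")), "g"), 1)
  expect_error(tissue_specificity(comp, "NOSUCH"), "absent")
})

test_that("candidate ranking is a filtered permutation with monotone filters", {
  sim <- gen_expression(expr_sim_config(seed = 29))
  comp <- sim$compendium
  rep_default <- rank_candidates(comp, baits = c("GGPPS", "GLS"))
  expect_identical(sort(rep_default$rank), seq_len(nrow(rep_default)))
  expect_identical(sort(rep_default$gene[1:3]),
                   c("UGT74P3", "UGT74P5", "UGT91T1"))
  # impossible thresholds empty the report
  expect_identical(nrow(rank_candidates(comp, c("GGPPS", "GLS"), min_pcc = 1.1)),
                   0L)
  # single passing candidate ranks first
  solo <- rank_candidates(comp, c("GGPPS", "GLS"), candidates = "UGT91T1")
  expect_identical(solo$rank, 1L)
  # loosening every threshold never removes a survivor
  loose <- rank_candidates(comp, c("GGPPS", "GLS"), min_pcc = 0.3,
                           min_shoot_root = 2, min_induction = 1.5)
  expect_true(all(rep_default$gene %in% loose$gene))
})

test_that("planted-module recovery is sensitive and specific across replicates", {
  n_rep <- 25
  sens <- spec <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    sim <- gen_expression(expr_sim_config(seed = 1000 + i))
    rep_i <- rank_candidates(sim$compendium, baits = c("GGPPS", "GLS"))
    planted <- c("UGT91T1", "UGT74P3", "UGT74P5")
    sens[i] <- mean(planted %in% rep_i$gene)
    spec[i] <- 1 - mean(grepl("^BG", rep_i$gene))
  }
  expect_gte(mean(sens), 0.95)
  expect_gte(mean(spec), 0.95)
})
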