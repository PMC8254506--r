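test_that("composition enumeration matches the brute-force oracle", {
  expect_equal(enumerate_compositions(c(hex = 2, dhex = 1, mal = 0)),
               data.frame(n_hex = c(0L, 1L, 1L, 2L, 2L),
                          n_dhex = c(0L, 0L, 1L, 0L, 1L),
                          n_mal = 0L),
               ignore_attr = TRUE)
  expect_equal(nrow(enumerate_compositions(c(hex = 0, dhex = 0, mal = 0))), 1L)
  # deoxyhexoses without a glucose are excluded entirely
  expect_equal(enumerate_compositions(c(hex = 0, dhex = 3, mal = 0)),
               data.frame(n_hex = 0L, n_dhex = 0L, n_mal = 0L),
               ignore_attr = TRUE)
  for (h in 0:6) for (d in 0:6) for (m in 0:6) {
    got <- enumerate_compositions(c(hex = h, dhex = d, mal = m))
    want <- oracle_enumerate(h, d, m)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})

test_that("composition invariants are enforced by the constructor", {
  expect_error(dtg_composition(0, 1, 0), "glucosylation")
  expect_error(dtg_composition(1, 0, 2), "C'-6")
  expect_error(dtg_composition(-1, 0, 0), "non-negative")
  expect_equal(format_formula(composition_formula(dtg_composition(2, 0, 0))),
               "C32H54O12")
})

test_that("classification is a total partition with the documented labels", {
  expect_identical(classify_composition(dtg_composition(0, 0, 0)), "aglycone")
  expect_identical(classify_composition(dtg_composition(1, 0, 0)), "intermediate")
  expect_identical(classify_composition(dtg_composition(2, 1, 0)), "rhamnosylated")
  expect_identical(classify_composition(dtg_composition(2, 0, 0)),
                   "non-rhamnosylated")
  # positional evidence overrides for multi-sugar compositions
  expect_identical(classify_composition(dtg_composition(2, 0, 0), TRUE),
                   "intermediate")
  comps <- enumerate_compositions(c(hex = 6, dhex = 6, mal = 6))
  labels <- vapply(seq_len(nrow(comps)), function(i) {
    classify_composition(comps[i, ])
  }, character(1))
  expect_true(all(labels %in% c("aglycone", "intermediate", "rhamnosylated",
                                "non-rhamnosylated")))
  expect_identical(sum(labels == "aglycone"), 1L)
})

test_that("accurate-mass matching finds and ranks the right candidates", {
  top <- match_mz(653.3507, adducts = "sodiated", tol_da = 0.004)
  expect_identical(unlist(top[1, c("n_hex", "n_dhex", "n_mal")]),
                   c(n_hex = 2L, n_dhex = 0L, n_mal = 0L))
  expect_match(top$name[1], "lyciumoside I")
  expect_identical(nrow(match_mz(100.0, tol_da = 0.004)), 0L)
  expect_error(match_mz(653.35, tol_da = -1), "positive")

  # round-trip: an exact theoretical ion is recovered as the unique top hit
  set.seed(21)
  for (i in 1:20) {
    cmp <- random_composition()
    ad <- sample(c("protonated", "sodiated", "ammoniated"), 1)
    mz <- ion_mz(composition_formula(cmp), ad)
    hits <- match_mz(mz, adducts = c("protonated", "sodiated", "ammoniated"),
                     tol_da = 0.004)
    expect_identical(unlist(hits[1, c("n_hex", "n_dhex", "n_mal")]),
                     c(n_hex = cmp$n_hex, n_dhex = cmp$n_dhex, n_mal = cmp$n_mal))
    expect_identical(hits$adduct[1], ad)
    expect_lt(abs(hits$error_da[1]), 1e-9)
  }
})

test_that("annotation is monotone in tolerance and bounds", {
  mz <- ion_mz("C32H54O12", "sodiated") + 0.003
  narrow <- match_mz(mz, tol_da = 0.0035)
  wide <- match_mz(mz, tol_da = 0.02)
  expect_true(nrow(wide) >= nrow(narrow))
  key <- function(df) paste(df$n_hex, df$n_dhex, df$n_mal, df$adduct)
  expect_true(all(key(narrow) %in% key(wide)))
  small_b <- match_mz(mz, bounds = c(hex = 2, dhex = 1, mal = 1), tol_da = 0.02)
  expect_true(all(key(small_b) %in% key(wide)))
})

test_that("fragments are explained as composition-limited neutral-loss chains", {
  prec <- match_mz(653.3507, adducts = "sodiated")[1, ]
  frags <- annotate_fragments(prec, c(491.2979, 271.2420, 400.0), tol_da = 0.004)
  expect_identical(frags$explained_as, c("-hex", "aglycone_core", "unexplained"))
  expect_true(attr(frags, "core_confirmed"))
  # mass conservation for every explained loss chain
  loss_mass <- c(hex = monoisotopic_mass("C6H10O5"),
                 dhex = monoisotopic_mass("C6H10O4"),
                 mal = monoisotopic_mass("C3H2O3"),
                 water = monoisotopic_mass("H2O"))
  prec2 <- match_mz(ion_mz(composition_formula(dtg_composition(3, 1, 1)),
                           "protonated"))[1, ]
  losses <- c(hex = 2, dhex = 1, mal = 1, water = 1)
  frag_mz <- prec2$observed_mz - sum(loss_mass * losses)
  out <- annotate_fragments(prec2, frag_mz, tol_da = 0.004)
  expect_equal(unlist(out[1, c("loss_hex", "loss_dhex", "loss_mal", "loss_water")]),
               losses, ignore_attr = TRUE)
  expect_equal(prec2$observed_mz - sum(loss_mass * losses), out$expected_mz[1],
               tolerance = 1e-9)
  # a chain cannot exceed the precursor composition
  prec3 <- match_mz(ion_mz(composition_formula(dtg_composition(1, 0, 0)),
                           "protonated"))[1, ]
  too_deep <- prec3$observed_mz - 2 * loss_mass[["hex"]]
  expect_identical(annotate_fragments(prec3, too_deep)$explained_as,
                   "unexplained")
})

test_that("peak-list dereplication recovers planted ions and ignores noise", {
  sim <- gen_peaklists(spectra_sim_config(mass_error_ppm_sd = 0,
                                          noise_peaks_per_scan = 0, seed = 7))
  ann <- dereplicate_peaklist(sim$peaklists[[1]])
  expect_equal(recovery_rate(ann, sim$truth), 1)
  expect_true(all(!is.na(ann$class)))

  # pure noise far from any candidate m/z annotates nothing
  noise <- peak_list(data.frame(rt = 1:5, mz = seq(1000, 1400, 100),
                                intensity = 10))
  expect_identical(nrow(dereplicate_peaklist(noise)), 0L)

  # planting only the aglycone yields a single aglycone-class annotation
  agl <- peak_list(data.frame(rt = 100, mz = ion_mz("C20H34O2", "protonated"),
                              intensity = 500))
  out <- dereplicate_peaklist(agl)
  expect_identical(nrow(out), 1L)
  expect_identical(out$class, "aglycone")
  expect_warning(
    dereplicate_peaklist(peak_list(data.frame(rt = numeric(0), mz = numeric(0),
                                              intensity = numeric(0)))),
    "empty")
})
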