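test_that("EIC extraction is windowed, per-scan, and max-aggregated", {
  pl <- toy_peak_list()
  eic <- compute_eic(pl, 271.2420, tol = 0.01)
  expect_identical(nrow(eic), length(pl$scan_rt))
  expect_equal(eic$intensity, c(100, 80, 0))  # 653 peak outside window

  # no peaks in window -> all-zero trace
  expect_true(all(compute_eic(pl, 900, 0.01)$intensity == 0))

  # co-eluting peaks in-window report the max, not the sum
  two <- peak_list(data.frame(rt = c(5, 5), mz = c(271.241, 271.243),
                              intensity = c(40, 60)))
  expect_equal(compute_eic(two, 271.242, 0.01)$intensity, 60)

  # invariance to peaks outside the m/z window
  extra <- peak_list(rbind(pl$peaks, data.frame(rt = 20, mz = 800, intensity = 1e6)))
  expect_equal(compute_eic(extra, 271.2420, 0.01)$intensity, eic$intensity)
})

test_that("trapezoidal integration matches geometry and is additive", {
  tri <- data.frame(rt = c(0, 5, 10), intensity = c(0, 100, 0))
  expect_equal(integrate_peak(tri, c(0, 10)), 100 * 10 / 2, tolerance = 0.01)
  flat <- data.frame(rt = 0:10, intensity = 0)
  expect_equal(integrate_peak(flat, c(0, 10)), 0)

  g <- gaussian_trace(A = 1000, mu = 100, sigma = 5)
  expect_equal(integrate_peak(g, range(g$rt)), 1000 * 5 * sqrt(2 * pi),
               tolerance = 0.02)

  # additivity over adjacent windows
  a <- integrate_peak(g, c(60, 100))
  b <- integrate_peak(g, c(100, 140))
  expect_equal(a + b, integrate_peak(g, c(60, 140)), tolerance = 1e-9)
  expect_error(integrate_peak(g, c(100, 100)), "empty")
})

test_that("internal-standard quantification is linear and homogeneous", {
  expect_equal(quantify_by_internal_standard(1e5, 1e5, 10, 0.1), 100)
  expect_equal(quantify_by_internal_standard(0, 1e5, 10, 0.1), 0)
  base <- quantify_by_internal_standard(3e4, 1e5, 10, 0.1)
  expect_equal(quantify_by_internal_standard(6e4, 1e5, 10, 0.1), 2 * base)
  # scaling both areas leaves the concentration unchanged
  expect_equal(quantify_by_internal_standard(3e4 * 7, 1e5 * 7, 10, 0.1), base)
  expect_error(quantify_by_internal_standard(1e5, 0, 10, 0.1), "spike")
})

test_that("fold-change matrices are zero-centred on the control", {
  areas <- rbind(cmpA = c(10, 20, 40), cmpB = c(5, 5, 5), absent = c(0, 0, 0))
  colnames(areas) <- c("ctrl", "s1", "s2")
  fc <- fold_change_matrix(areas, c("control", "treat", "treat"),
                           pseudo = 1e-6)
  expect_equal(fc["cmpA", "ctrl"], 0)            # single control vs itself
  expect_equal(fc["cmpA", "s1"], 1, tolerance = 1e-4)   # twice the control
  expect_equal(unname(fc["absent", ]), c(0, 0, 0))      # pseudo-count limit
  expect_error(fold_change_matrix(areas, c("a", "b", "b"), "control"),
               "control")
})

test_that("chemotype summaries conserve total annotated signal", {
  agl <- peak_list(data.frame(rt = 100, mz = ion_mz("C20H34O2", "protonated"),
                              intensity = 500), sample_id = "A")
  s <- chemotype_summary(dereplicate_peaklist(agl))
  expect_equal(s$aglycone, s$total)
  expect_equal(s$total, 500)

  sim <- gen_peaklists(spectra_sim_config(mass_error_ppm_sd = 0,
                                          noise_peaks_per_scan = 0, seed = 3))
  ann <- dereplicate_peaklist(sim$peaklists[[1]])
  s2 <- chemotype_summary(ann)
  expect_equal(s2$aglycone + s2$intermediate + s2$`non-rhamnosylated` +
                 s2$rhamnosylated, s2$total)
  expect_identical(nrow(chemotype_summary(ann[0, ])), 0L)
})

test_that("a rhamnosylation knockout shifts the chemotype as silenced lines do", {
  cfg <- spectra_sim_config(mass_error_ppm_sd = 0, noise_peaks_per_scan = 0,
                            seed = 9)
  ctrl <- gen_peaklists(cfg)
  ko <- gen_knockout_profile(cfg, "rhamnosylation")
  s_ctrl <- chemotype_summary(dereplicate_peaklist(ctrl$peaklists[[1]]))
  s_ko <- chemotype_summary(dereplicate_peaklist(ko$peaklists[[1]]))
  expect_lt(s_ko$rhamnosylated, 0.05 * s_ctrl$rhamnosylated)
  expect_gt(s_ko$`non-rhamnosylated`, s_ctrl$`non-rhamnosylated`)
})
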