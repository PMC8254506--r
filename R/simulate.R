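# Default planted compound panel: abundant named HGL-DTGs with distinct
# retention times, amplitudes in detector counts.
.default_sim_compounds <- function() {
  data.frame(
    name = c("nicotianoside III", "attenoside", "lyciumoside II",
             "lyciumoside I", "lyciumoside IV", "nicotianoside IX",
             "nicotianoside I"),
    n_hex  = c(2, 3, 3, 2, 2, 2, 2),
    n_dhex = c(2, 1, 0, 0, 1, 0, 1),
    n_mal  = c(0, 0, 0, 0, 0, 1, 1),
    abundance = c(4000, 5000, 6000, 10000, 12000, 3000, 8000),
    rt = c(140, 150, 160, 180, 200, 220, 230),
    rt_width = rep(8, 7),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the spectra simulator
#'
#' Describes the planted ion content of a synthetic chromatographic run:
#' which compositions elute where and how abundantly, how the signal is
#' split across adducts, the instrument's ppm-scale mass error, the noise
#' floor, the scan grid, and whether each DTG co-emits the diagnostic
#' in-source aglycone-core fragment.
#'
#' @param compounds data.frame with columns `name`, `n_hex`, `n_dhex`,
#'   `n_mal`, `abundance` (apex amplitude), `rt` (s), `rt_width` (Gaussian
#'   sigma, s).
#' @param adduct_mix Named proportions over the adduct registry (summing
#'   to 1); each compound's signal is split deterministically across them.
#' @param mass_error_ppm_sd SD of the Normal per-ion mass error (ppm).
#' @param noise_peaks_per_scan Uniform-m/z noise peaks added per scan.
#' @param noise_mz_range m/z range the noise is uniform over.
#' @param noise_intensity_mean Mean of the exponential noise intensity.
#' @param scan_grid `c(start, end, step)` in seconds.
#' @param emit_core_fragment Co-emit the in-source C20H31+ fragment
#'   (m/z 271.2420) in every scan where planted DTG signal is present?
#' @param core_fraction Core-fragment intensity as a fraction of the summed
#'   planted DTG intensity in the scan.
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return List of class `spectra_sim_config`.
#' @export
spectra_sim_config <- function(compounds = .default_sim_compounds(),
                               adduct_mix = c(protonated = 0.2, sodiated = 0.5,
                                              ammoniated = 0.3),
                               mass_error_ppm_sd = 2,
                               noise_peaks_per_scan = 5,
                               noise_mz_range = c(100, 1600),
                               noise_intensity_mean = 50,
                               scan_grid = c(start = 0, end = 600, step = 5),
                               emit_core_fragment = TRUE,
                               core_fraction = 0.2,
                               seed = 1) {
  stopifnot(all(compounds$abundance > 0), all(compounds$rt_width > 0),
            scan_grid[3] > 0, mass_error_ppm_sd >= 0,
            abs(sum(adduct_mix) - 1) < 1e-8)
  structure(list(compounds = compounds, adduct_mix = adduct_mix,
                 mass_error_ppm_sd = mass_error_ppm_sd,
                 noise_peaks_per_scan = noise_peaks_per_scan,
                 noise_mz_range = noise_mz_range,
                 noise_intensity_mean = noise_intensity_mean,
                 scan_grid = scan_grid,
                 emit_core_fragment = emit_core_fragment,
                 core_fraction = core_fraction, seed = seed),
            class = "spectra_sim_config")
}

#' Simulate centroided peak lists with known ground truth
#'
#' Each planted compound elutes as a Gaussian peak at each adduct m/z, with a
#' per-ion mass error drawn from Normal(0, `mass_error_ppm_sd`) ppm (held
#' fixed across the elution, like a calibration offset). The in-source
#' aglycone-core fragment is co-emitted per scan when flagged, uniform-m/z /
#' exponential-intensity noise peaks are added, and a ground-truth table
#' records every planted ion. Reproducible: the same config and seed give
#' byte-identical output.
#'
#' @param config A [spectra_sim_config()].
#' @param n_samples Number of samples to simulate.
#' @param group_labels Group label(s), recycled over samples.
#' @return List with `peaklists` (list of [peak_list()]) and `truth`
#'   (data.frame: `sample_id`, `group`, `name`, `n_hex`, `n_dhex`, `n_mal`,
#'   `adduct`, `theoretical_mz`, `observed_mz`, `rt`, `abundance`), plus
#'   attribute `seed`.
#' @export
gen_peaklists <- function(config = spectra_sim_config(), n_samples = 1,
                          group_labels = "control") {
  set.seed(config$seed)
  group_labels <- rep_len(group_labels, n_samples)
  scans <- seq(config$scan_grid[1], config$scan_grid[2], by = config$scan_grid[3])
  cmp <- config$compounds
  mix <- config$adduct_mix[config$adduct_mix > 0]
  core_mz <- fragment_mz_aglycone_core()
  registry <- default_adducts()

  peaklists <- vector("list", n_samples)
  truth <- list()
  for (s in seq_len(n_samples)) {
    sid <- sprintf("S%02d", s)
    pk <- list()
    dtg_total <- numeric(length(scans))  # planted DTG signal per scan
    for (i in seq_len(nrow(cmp))) {
      elution <- cmp$abundance[i] *
        exp(-(scans - cmp$rt[i])^2 / (2 * cmp$rt_width[i]^2))
      for (a in names(mix)) {
        theo <- ion_mz(composition_formula(cmp[i, ]), a, registry)
        err_ppm <- stats::rnorm(1, 0, config$mass_error_ppm_sd)
        obs <- theo * (1 + err_ppm * 1e-6)
        inten <- elution * mix[[a]]
        keep <- inten >= 1
        if (any(keep)) {
          pk[[length(pk) + 1]] <- data.frame(rt = scans[keep], mz = obs,
                                             intensity = inten[keep])
        }
        truth[[length(truth) + 1]] <- data.frame(
          sample_id = sid, group = group_labels[s], name = cmp$name[i],
          n_hex = cmp$n_hex[i], n_dhex = cmp$n_dhex[i], n_mal = cmp$n_mal[i],
          adduct = a, theoretical_mz = theo, observed_mz = obs,
          rt = cmp$rt[i], abundance = cmp$abundance[i] * mix[[a]],
          stringsAsFactors = FALSE)
      }
      dtg_total <- dtg_total + elution
    }
    if (config$emit_core_fragment && any(dtg_total > 0)) {
      err_ppm <- stats::rnorm(1, 0, config$mass_error_ppm_sd)
      obs <- core_mz * (1 + err_ppm * 1e-6)
      inten <- dtg_total * config$core_fraction
      keep <- inten >= 1
      if (any(keep)) {
        pk[[length(pk) + 1]] <- data.frame(rt = scans[keep], mz = obs,
                                           intensity = inten[keep])
      }
    }
    if (config$noise_peaks_per_scan > 0) {
      n_noise <- config$noise_peaks_per_scan * length(scans)
      pk[[length(pk) + 1]] <- data.frame(
        rt = rep(scans, each = config$noise_peaks_per_scan),
        mz = stats::runif(n_noise, config$noise_mz_range[1],
                          config$noise_mz_range[2]),
        intensity = stats::rexp(n_noise, 1 / config$noise_intensity_mean))
    }
    peaks <- if (length(pk)) do.call(rbind, pk) else
      data.frame(rt = numeric(0), mz = numeric(0), intensity = numeric(0))
    peaklists[[s]] <- peak_list(peaks, sample_id = sid,
                                group = group_labels[s], scan_rt = scans)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(peaklists = peaklists, truth = truth), seed = config$seed)
}

#' Simulate a biosynthetic knockout chemotype
#'
#' Rewrites the planted compound panel to mimic silencing one pathway step,
#' then simulates as [gen_peaklists()]:
#' \describe{
#'   \item{rhamnosylation}{all deoxyhexose-bearing compounds suppressed
#'     (x0.01) and rhamnose-free compounds boosted (x2) -- the chemotype
#'     shift of a rhamnosyltransferase knockout.}
#'   \item{glucosylation}{one/two-sugar biosynthetic intermediates and the
#'     free aglycone appear; complete compounds are reduced (x0.2).}
#'   \item{precursor}{everything scaled down (x0.1) -- loss of the
#'     diterpene precursor supply.}
#' }
#'
#' @param config A [spectra_sim_config()]; multipliers above are taken from
#'   `multipliers` so they remain documented, inspectable settings.
#' @param knockout One of `"rhamnosylation"`, `"glucosylation"`,
#'   `"precursor"`, or `"none"` (panel unchanged).
#' @param n_samples,group_labels As in [gen_peaklists()].
#' @param multipliers Named list of the effect sizes described above.
#' @return As [gen_peaklists()].
#' @export
gen_knockout_profile <- function(config = spectra_sim_config(),
                                 knockout = c("rhamnosylation", "glucosylation",
                                              "precursor", "none"),
                                 n_samples = 1, group_labels = knockout,
                                 multipliers = list(rham_suppress = 0.01,
                                                    rham_boost = 2,
                                                    gluc_reduce = 0.2,
                                                    precursor_scale = 0.1)) {
  knockout <- match.arg(knockout)
  cmp <- config$compounds
  if (knockout == "rhamnosylation") {
    cmp$abundance <- ifelse(cmp$n_dhex > 0,
                            cmp$abundance * multipliers$rham_suppress,
                            cmp$abundance * multipliers$rham_boost)
  } else if (knockout == "glucosylation") {
    cmp$abundance <- cmp$abundance * multipliers$gluc_reduce
    cmp <- rbind(cmp, data.frame(
      name = c("17-HGL", "G-17-HGL", "RGHGL"),
      n_hex = c(0, 1, 1), n_dhex = c(0, 0, 1), n_mal = c(0, 0, 0),
      abundance = c(3000, 6000, 4000), rt = c(280, 250, 215),
      rt_width = rep(8, 3), stringsAsFactors = FALSE))
  } else if (knockout == "precursor") {
    cmp$abundance <- cmp$abundance * multipliers$precursor_scale
  }
  cfg <- config
  cfg$compounds <- cmp
  gen_peaklists(cfg, n_samples = n_samples,
                group_labels = rep_len(group_labels, n_samples))
}

#' Score annotation recovery against generator ground truth
#'
#' Fraction of planted ions for which the dereplication output contains an
#' annotation with the matching composition, adduct and observed m/z in the
#' same sample.
#'
#' @param annotations Annotation table (rows from [dereplicate_peaklist()],
#'   possibly concatenated over samples).
#' @param truth Ground-truth table from [gen_peaklists()].
#' @param mz_window m/z agreement window (Th) between the truth ion and the
#'   annotated peak.
#' @return Recovery fraction in `[0, 1]`.
#' @export
recovery_rate <- function(annotations, truth, mz_window = 0.01) {
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    t <- truth[i, ]
    any(annotations$sample_id == t$sample_id &
          annotations$n_hex == t$n_hex &
          annotations$n_dhex == t$n_dhex &
          annotations$n_mal == t$n_mal &
          annotations$adduct == t$adduct &
          abs(annotations$observed_mz - t$observed_mz) <= mz_window)
  }, logical(1))
  mean(hit)
}

#' Configuration for the expression-compendium simulator
#'
#' Encodes the herbivory-induction microarray design the co-expression
#' procedure assumes: tissues x time points x treatments with replication, a
#' co-regulated pathway module whose leaf expression follows a shared
#' induction profile (peaking ~8-fold at 5 h under simulated herbivory,
#' intermediate under wounding) and whose root expression is suppressed
#' 20-3000-fold gene-specifically, over an independent lognormal background.
#'
#' @param n_background Number of independent background genes.
#' @param module_genes Ids of the co-regulated module genes (first entries
#'   conventionally the baits, e.g. `GGPPS`, `GLS`).
#' @param induction_profile Named fold vector over `times` for simulated
#'   herbivory in leaves.
#' @param root_suppression Named folds for module genes present in the name
#'   set; others are drawn log-uniformly from `root_suppression_range`.
#' @param root_suppression_range Range for unnamed module genes.
#' @param treatment_exponent Exponent applied to the induction fold per
#'   treatment (control 0, wounding intermediate, simulated herbivory 1).
#' @param tissues,times,treatments Design levels.
#' @param replicates Replicates per stratum (default 3: 3 x 6 x 3 x 3 = 162
#'   columns, emulating a ~150-profile compendium).
#' @param noise_sd_log2 SD of the additive log2-scale noise.
#' @param baseline_log2_mean,baseline_log2_sd Background gene baselines.
#' @param module_baseline_log2_mean Module gene leaf baseline mean (higher:
#'   the pathway is highly expressed in leaves).
#' @param seed Integer seed.
#' @return List of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_background = 104,
                            module_genes = c("GGPPS", "GLS", "UGT91T1",
                                             "UGT74P3", "UGT74P5"),
                            induction_profile = c("1" = 2, "5" = 8, "9" = 4,
                                                  "13" = 2.5, "17" = 1.5,
                                                  "21" = 1.2),
                            root_suppression = c(GGPPS = 50, GLS = 3225,
                                                 UGT91T1 = 2190, UGT74P3 = 127,
                                                 UGT74P5 = 20),
                            root_suppression_range = c(20, 3000),
                            treatment_exponent = c(control = 0, wounding = 0.5,
                                                   simulated_herbivory = 1),
                            tissues = c("treated_leaf", "systemic_leaf", "root"),
                            times = c(1, 5, 9, 13, 17, 21),
                            treatments = c("control", "wounding",
                                           "simulated_herbivory"),
                            replicates = 3,
                            noise_sd_log2 = 0.5,
                            baseline_log2_mean = 8, baseline_log2_sd = 1.5,
                            module_baseline_log2_mean = 10,
                            seed = 1) {
  stopifnot(all(induction_profile > 0), all(root_suppression > 0),
            noise_sd_log2 >= 0, replicates >= 1)
  structure(list(n_background = n_background, module_genes = module_genes,
                 induction_profile = induction_profile,
                 root_suppression = root_suppression,
                 root_suppression_range = root_suppression_range,
                 treatment_exponent = treatment_exponent,
                 tissues = tissues, times = times, treatments = treatments,
                 replicates = replicates, noise_sd_log2 = noise_sd_log2,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 module_baseline_log2_mean = module_baseline_log2_mean,
                 seed = seed),
            class = "expr_sim_config")
}

#' Simulate an annotated expression compendium with truth labels
#'
#' Module genes share one induction x tissue x treatment mean structure (on
#' the log2 scale) times gene-specific baseline and root suppression, with
#' independent additive log2 noise; background genes are i.i.d. lognormal
#' around gene-specific constant baselines. Values are returned on the raw
#' (linear) scale.
#'
#' @param config An [expr_sim_config()].
#' @return List with `compendium` (an [expr_compendium()]) and `truth`
#'   (data.frame: `gene`, `is_module`, `baseline_log2`, `root_suppression`),
#'   plus attribute `seed`.
#' @export
gen_expression <- function(config = expr_sim_config()) {
  set.seed(config$seed)
  design <- expand.grid(rep = seq_len(config$replicates),
                        treatment = config$treatments,
                        time_h = config$times,
                        tissue = config$tissues,
                        stringsAsFactors = FALSE)
  design <- design[, c("tissue", "time_h", "treatment", "rep")]
  design$sample_id <- sprintf("A%03d_%s_%02dh_%s_r%d", seq_len(nrow(design)),
                              design$tissue, design$time_h,
                              substr(design$treatment, 1, 4), design$rep)
  mod <- config$module_genes
  bg <- sprintf("BG%03d", seq_len(config$n_background))
  genes <- c(mod, bg)

  base <- c(stats::rnorm(length(mod), config$module_baseline_log2_mean, 1),
            stats::rnorm(length(bg), config$baseline_log2_mean,
                         config$baseline_log2_sd))
  names(base) <- genes
  supp <- exp(stats::runif(length(mod),
                           log(config$root_suppression_range[1]),
                           log(config$root_suppression_range[2])))
  names(supp) <- mod
  known <- intersect(mod, names(config$root_suppression))
  supp[known] <- config$root_suppression[known]

  is_leaf <- design$tissue != "root"
  fold <- config$induction_profile[as.character(design$time_h)]
  texp <- config$treatment_exponent[design$treatment]
  induction_log2 <- ifelse(is_leaf, texp * log2(fold), 0)

  mu <- matrix(rep(base, each = nrow(design)), nrow = length(genes),
               ncol = nrow(design), byrow = TRUE,
               dimnames = list(genes, design$sample_id))
  for (g in mod) {
    mu[g, ] <- base[g] + induction_log2 - ifelse(is_leaf, 0, log2(supp[g]))
  }
  noise <- matrix(stats::rnorm(length(mu), 0, config$noise_sd_log2),
                  nrow = nrow(mu))
  expr <- 2^(mu + noise)

  truth <- data.frame(gene = genes,
                      is_module = genes %in% mod,
                      baseline_log2 = unname(base),
                      root_suppression = unname(supp[match(genes, mod)]),
                      stringsAsFactors = FALSE)
  comp <- expr_compendium(expr, design[, c("sample_id", "tissue", "time_h",
                                           "treatment")])
  structure(list(compendium = comp, truth = truth), seed = config$seed)
}

#' Simulate a UGT proteome with planted PSPG boxes
#'
#' Synthetic protein sequences for exercising the motif scan: random
#' sequences, a subset of which carry a PSPG-box window (sampled from the
#' model's position probabilities) planted near the C-terminus.
#'
#' @param n_with_motif,n_without Counts of motif-bearing and motif-free
#'   proteins.
#' @param length_range Protein length range (uniform integer draw).
#' @param model A [pspg_model()] supplying the motif length and position
#'   probabilities.
#' @param seed Integer seed.
#' @return data.frame with columns `id`, `sequence`, `has_motif`.
#' @export
gen_proteome <- function(n_with_motif = 107, n_without = 20,
                         length_range = c(420, 520), model = pspg_model(),
                         seed = 1) {
  set.seed(seed)
  aa <- rownames(model$pwm)
  p <- 2^model$pwm / 20  # back-transform log2 odds to position probabilities
  n <- n_with_motif + n_without
  lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  has_motif <- rep(c(TRUE, FALSE), c(n_with_motif, n_without))
  seqs <- vapply(seq_len(n), function(i) {
    chars <- sample(aa, lens[i], replace = TRUE)
    if (has_motif[i]) {
      box <- vapply(seq_len(model$length), function(j) {
        sample(aa, 1, prob = p[, j])
      }, character(1))
      start <- lens[i] - model$length - 3L  # a short C-terminal tail remains
      chars[start:(start + model$length - 1L)] <- box
    }
    paste(chars, collapse = "")
  }, character(1))
  data.frame(id = c(sprintf("UGT%03d", seq_len(n_with_motif)),
                    sprintf("NONUGT%03d", seq_len(n_without))),
             sequence = seqs, has_motif = has_motif, stringsAsFactors = FALSE)
}
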