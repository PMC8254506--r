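#' Candidate ion search space
#'
#' Every (composition, adduct) pair within bounds with its theoretical m/z.
#' Precompute it once when matching many peaks against one search space.
#'
#' @param bounds Composition bounds, see [enumerate_compositions()].
#' @param adducts Character vector of adduct names or list of adduct objects.
#' @param registry Adduct registry, see [default_adducts()].
#' @return data.frame with columns `n_hex`, `n_dhex`, `n_mal`, `adduct`,
#'   `theoretical_mz`, `neutral_formula`.
#' @export
candidate_ion_table <- function(bounds = c(hex = 4, dhex = 3, mal = 4),
                                adducts = c("protonated", "sodiated", "ammoniated"),
                                registry = default_adducts()) {
  comps <- enumerate_compositions(bounds)
  rows <- lapply(adducts, function(a) {
    ad <- resolve_adduct(a, registry)
    mz <- vapply(seq_len(nrow(comps)), function(i) {
      ion_mz(composition_formula(comps[i, ]), ad)
    }, numeric(1))
    data.frame(comps, adduct = ad$name, theoretical_mz = mz,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$neutral_formula <- vapply(seq_len(nrow(out)), function(i) {
    format_formula(composition_formula(out[i, ]))
  }, character(1))
  rownames(out) <- NULL
  out
}

# Empty annotation table with the stable column order.
.empty_annotation <- function() {
  data.frame(observed_mz = numeric(0), adduct = character(0),
             n_hex = integer(0), n_dhex = integer(0), n_mal = integer(0),
             neutral_formula = character(0), theoretical_mz = numeric(0),
             error_da = numeric(0), error_mda = numeric(0),
             error_ppm = numeric(0), class = character(0), name = character(0),
             stringsAsFactors = FALSE)
}

#' Match an observed m/z against candidate HGL-DTG ions
#'
#' Finds every (composition, adduct) pair whose theoretical m/z lies within
#' the tolerance of the observed value. The default tolerance is 4 mDa, the
#' accurate-mass window used for formula determination on the Q-TOF
#' instruments this workflow targets; a ppm-mode tolerance is available
#' because mass error scales with m/z on such instruments.
#'
#' @param observed_mz Observed m/z (Th), length 1.
#' @param bounds Composition bounds, see [enumerate_compositions()].
#' @param adducts Character vector of adduct names, or list of adduct objects.
#' @param tol_da Absolute tolerance in Da (default 0.004). Ignored when
#'   `tol_ppm` is given.
#' @param tol_ppm Optional relative tolerance in ppm.
#' @param candidates Optional precomputed [candidate_ion_table()]; supply it
#'   when matching many peaks against the same search space.
#' @param reference Reference compound table used to attach names, see
#'   [reference_compounds()].
#' @return Annotation data.frame sorted by absolute mass error (ties: fewer
#'   total residues, then lexicographic composition) with columns
#'   `observed_mz`, `adduct`, `n_hex`, `n_dhex`, `n_mal`, `neutral_formula`,
#'   `theoretical_mz`, `error_da`, `error_mda`, `error_ppm`, `class`, `name`.
#'   Zero rows when nothing matches.
#' @export
#' @examples
#' match_mz(653.3507, adducts = "sodiated")
match_mz <- function(observed_mz,
                     bounds = c(hex = 4, dhex = 3, mal = 4),
                     adducts = c("protonated", "sodiated", "ammoniated"),
                     tol_da = 0.004, tol_ppm = NULL,
                     candidates = NULL,
                     reference = reference_compounds()) {
  stopifnot(is.numeric(observed_mz), length(observed_mz) == 1L)
  tol <- if (is.null(tol_ppm)) tol_da else tol_ppm * 1e-6 * observed_mz
  if (!is.numeric(tol) || tol <= 0) stop("tolerance must be positive")
  if (is.null(candidates)) {
    candidates <- candidate_ion_table(bounds, adducts)
  }
  err <- observed_mz - candidates$theoretical_mz
  hit <- abs(err) <= tol
  if (!any(hit)) return(.empty_annotation())
  out <- candidates[hit, , drop = FALSE]
  out$observed_mz <- observed_mz
  out$error_da <- err[hit]
  out$error_mda <- out$error_da * 1000
  out$error_ppm <- out$error_da / out$theoretical_mz * 1e6
  n_res <- out$n_hex + out$n_dhex + out$n_mal
  ord <- order(abs(out$error_da), n_res, out$n_hex, out$n_dhex, out$n_mal)
  out <- out[ord, , drop = FALSE]
  out$class <- vapply(seq_len(nrow(out)), function(i) {
    classify_composition(out[i, ])
  }, character(1))
  out$name <- vapply(seq_len(nrow(out)), function(i) {
    .resolve_name(out$n_hex[i], out$n_dhex[i], out$n_mal[i], out$class[i], reference)
  }, character(1))
  rownames(out) <- NULL
  out[, names(.empty_annotation())]
}

# Names from the reference table for a (composition, class); isomer series
# sharing one composition are joined with ";".
.resolve_name <- function(n_hex, n_dhex, n_mal, class, reference) {
  m <- reference$n_hex == n_hex & reference$n_dhex == n_dhex &
    reference$n_mal == n_mal & reference$class == class
  if (!any(m)) return(NA_character_)
  paste(reference$name[m], collapse = ";")
}

#' Assign MS/MS fragments to neutral-loss chains
#'
#' Each fragment is explained, where possible, as the precursor minus an
#' ordered multiset of residue neutral losses (hexose 162.0528, deoxyhexose
#' 146.0579, malonyl 86.0004 and up to two waters 18.0106) that does not
#' exceed the precursor composition. Loss chains are searched greedily
#' longest-first with the deterministic residue order hexose > deoxyhexose >
#' malonyl > water; among chains matching within tolerance the smallest
#' absolute error wins. A fragment at the aglycone-core m/z (271.2420) is
#' flagged `aglycone_core`, and the precursor annotation is "core-confirmed"
#' when that diagnostic fragment is present.
#'
#' @param precursor One-row annotation (from [match_mz()] or
#'   [dereplicate_peaklist()]): needs `observed_mz`, `n_hex`, `n_dhex`,
#'   `n_mal`.
#' @param fragments Numeric vector of fragment m/z values.
#' @param tol_da Matching tolerance in Da.
#' @return data.frame with columns `fragment_mz`, `explained_as` (loss chain
#'   such as `"-hex-hex"`, `"aglycone_core"` or `"unexplained"`), `loss_hex`,
#'   `loss_dhex`, `loss_mal`, `loss_water`, `expected_mz`, `error_da`, and
#'   attribute `core_confirmed` (logical).
#' @export
annotate_fragments <- function(precursor, fragments, tol_da = 0.004) {
  stopifnot(tol_da > 0, nrow(precursor) == 1L)
  loss_mass <- c(hex = monoisotopic_mass(.RESIDUES$hex),
                 dhex = monoisotopic_mass(.RESIDUES$dhex),
                 mal = monoisotopic_mass(.RESIDUES$mal),
                 water = monoisotopic_mass("H2O"))
  # all loss multisets within the precursor composition, up to 2 waters
  grid <- expand.grid(loss_water = 0:2,
                      loss_mal = 0:precursor$n_mal,
                      loss_dhex = 0:precursor$n_dhex,
                      loss_hex = 0:precursor$n_hex)
  grid <- grid[, c("loss_hex", "loss_dhex", "loss_mal", "loss_water")]
  total <- rowSums(grid)
  # greedy longest-first: larger chains take precedence at equal error
  grid <- grid[order(-total, -grid$loss_hex, -grid$loss_dhex,
                     -grid$loss_mal, -grid$loss_water), ]
  expected <- precursor$observed_mz -
    as.matrix(grid) %*% loss_mass[c("hex", "dhex", "mal", "water")]
  core_mz <- fragment_mz_aglycone_core()
  rows <- lapply(fragments, function(fz) {
    if (abs(fz - core_mz) <= tol_da) {
      return(data.frame(fragment_mz = fz, explained_as = "aglycone_core",
                        loss_hex = NA_integer_, loss_dhex = NA_integer_,
                        loss_mal = NA_integer_, loss_water = NA_integer_,
                        expected_mz = core_mz, error_da = fz - core_mz,
                        stringsAsFactors = FALSE))
    }
    err <- fz - expected
    hit <- which(abs(err) <= tol_da & rowSums(grid) > 0)
    if (!length(hit)) {
      return(data.frame(fragment_mz = fz, explained_as = "unexplained",
                        loss_hex = NA_integer_, loss_dhex = NA_integer_,
                        loss_mal = NA_integer_, loss_water = NA_integer_,
                        expected_mz = NA_real_, error_da = NA_real_,
                        stringsAsFactors = FALSE))
    }
    best <- hit[order(abs(err[hit]))][1]
    g <- grid[best, ]
    chain <- paste0(
      strrep("-hex", g$loss_hex), strrep("-dhex", g$loss_dhex),
      strrep("-mal", g$loss_mal), strrep("-H2O", g$loss_water))
    data.frame(fragment_mz = fz, explained_as = chain,
               loss_hex = g$loss_hex, loss_dhex = g$loss_dhex,
               loss_mal = g$loss_mal, loss_water = g$loss_water,
               expected_mz = expected[best], error_da = err[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "core_confirmed") <- any(out$explained_as == "aglycone_core")
  out
}

#' Dereplicate a peak list
#'
#' Runs [match_mz()] over every peak at or above the intensity floor, keeps
#' the best-matching candidate per peak, and attaches chemotype class and
#' reference names. Deterministic for fixed input and settings.
#'
#' @param peaks A `peak_list` (see [peak_list()]) or a data.frame with
#'   columns `mz`, `intensity`, `rt_seconds`.
#' @param config Settings list from [dtg_config()]: uses `bounds`, `adducts`,
#'   `tol_mda`/`tol_ppm` and `intensity_floor`.
#' @param reference Reference compound table.
#' @return Annotation data.frame (one row per annotated peak) with the
#'   [match_mz()] columns plus `rt_seconds`, `intensity`, `sample_id`,
#'   `group`. Empty (with a warning) for an empty peak list.
#' @export
dereplicate_peaklist <- function(peaks, config = dtg_config(),
                                 reference = reference_compounds()) {
  pl <- as_peak_list(peaks)
  df <- pl$peaks
  if (!nrow(df)) {
    warning("empty peak list: returning empty annotation table")
    out <- .empty_annotation()
    out$rt_seconds <- numeric(0); out$intensity <- numeric(0)
    out$sample_id <- character(0); out$group <- character(0)
    return(out)
  }
  df <- df[df$intensity >= config$intensity_floor, , drop = FALSE]
  cand <- candidate_ion_table(config$bounds, config$adducts)
  tol_da <- if (is.null(config$tol_ppm)) config$tol_mda / 1000 else NULL
  rows <- lapply(seq_len(nrow(df)), function(i) {
    hits <- match_mz(df$mz[i],
                     tol_da = if (is.null(tol_da)) 0.004 else tol_da,
                     tol_ppm = config$tol_ppm,
                     candidates = cand, reference = reference)
    if (!nrow(hits)) return(NULL)
    top <- hits[1, , drop = FALSE]
    top$rt_seconds <- df$rt[i]
    top$intensity <- df$intensity[i]
    top
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    out <- .empty_annotation()
    out$rt_seconds <- numeric(0); out$intensity <- numeric(0)
    out$sample_id <- character(0); out$group <- character(0)
  } else {
    out <- do.call(rbind, rows)
    out$sample_id <- pl$sample_id
    out$group <- pl$group
  }
  rownames(out) <- NULL
  out
}
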