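#' Centroided peak list
#'
#' Container for one sample's centroided spectra: a long table of
#' (rt, mz, intensity) peaks plus the scan grid (sorted unique retention
#' times), a sample identifier and a group label (genotype/treatment).
#'
#' @param peaks data.frame with numeric columns `rt`, `mz`, `intensity`
#'   (intensities must be non-negative).
#' @param sample_id Sample label.
#' @param group Group label.
#' @param scan_rt Optional full scan grid (seconds); defaults to the sorted
#'   unique `rt` values present. Supplying it keeps empty scans (all peaks
#'   filtered out or pure-noise removal) on the chromatogram grid.
#' @return Object of class `peak_list`: list with `peaks` (sorted by rt then
#'   mz), `scan_rt`, `sample_id`, `group`.
#' @export
peak_list <- function(peaks, sample_id = "sample", group = "control",
                      scan_rt = NULL) {
  stopifnot(is.data.frame(peaks), all(c("rt", "mz", "intensity") %in% names(peaks)))
  if (nrow(peaks) && any(peaks$intensity < 0)) {
    stop("intensities must be non-negative")
  }
  peaks <- peaks[order(peaks$rt, peaks$mz), c("rt", "mz", "intensity")]
  rownames(peaks) <- NULL
  if (is.null(scan_rt)) scan_rt <- sort(unique(peaks$rt))
  structure(list(peaks = peaks, scan_rt = scan_rt,
                 sample_id = sample_id, group = group),
            class = "peak_list")
}

# Accept a peak_list, or a bare data.frame with mz/intensity/rt_seconds or
# rt columns.
as_peak_list <- function(x, sample_id = "sample", group = "control") {
  if (inherits(x, "peak_list")) return(x)
  stopifnot(is.data.frame(x))
  if ("rt_seconds" %in% names(x) && !"rt" %in% names(x)) {
    x$rt <- x$rt_seconds
  }
  peak_list(x[, c("rt", "mz", "intensity")], sample_id = sample_id, group = group)
}

#' @export
print.peak_list <- function(x, ...) {
  cat("<peak_list> sample", x$sample_id, "group", x$group, "-",
      nrow(x$peaks), "peaks over", length(x$scan_rt), "scans\n")
  invisible(x)
}

#' Extracted ion chromatogram
#'
#' Per-scan intensity trace for a narrow m/z window: at each scan the maximum
#' intensity over peaks within `target_mz +/- tol`, 0 if none. The per-scan
#' maximum (rather than sum) is robust to split centroids in centroided
#' Q-TOF data.
#'
#' @param peaks `peak_list` or compatible data.frame.
#' @param target_mz Window center (Th).
#' @param tol Half-width of the window (Th); default 0.01.
#' @return data.frame with columns `rt`, `intensity` (one row per scan) and
#'   attributes `target_mz`, `tol`.
#' @export
#' @examples
#' pl <- peak_list(data.frame(rt = c(1, 2), mz = c(271.242, 400),
#'                            intensity = c(10, 5)))
#' compute_eic(pl, 271.2420, 0.01)
compute_eic <- function(peaks, target_mz, tol = 0.01) {
  if (tol <= 0) stop("tolerance must be positive")
  pl <- as_peak_list(peaks)
  df <- pl$peaks
  inside <- df[abs(df$mz - target_mz) <= tol, , drop = FALSE]
  intensity <- vapply(pl$scan_rt, function(t) {
    v <- inside$intensity[inside$rt == t]
    if (length(v)) max(v) else 0
  }, numeric(1))
  structure(data.frame(rt = pl$scan_rt, intensity = intensity),
            target_mz = target_mz, tol = tol)
}

#' Integrate an EIC peak area
#'
#' Trapezoidal area of the trace restricted to a retention-time window. No
#' baseline subtraction by default; `baseline = "linear"` subtracts the
#' chord between the window endpoints (negative contributions truncated
#' at 0).
#'
#' @param trace data.frame with columns `rt`, `intensity` (as from
#'   [compute_eic()]).
#' @param rt_window Numeric length-2 `(start, end)`, `start < end`.
#' @param baseline `"none"` (default) or `"linear"`.
#' @return Non-negative area (intensity x seconds). Additive over disjoint
#'   adjacent windows.
#' @export
integrate_peak <- function(trace, rt_window = range(trace$rt),
                           baseline = c("none", "linear")) {
  baseline <- match.arg(baseline)
  stopifnot(length(rt_window) == 2L)
  if (!(rt_window[1] < rt_window[2])) stop("empty rt window")
  rt <- trace$rt
  y <- trace$intensity
  # interpolate the window endpoints so adjacent windows tile exactly
  keep <- rt > rt_window[1] & rt < rt_window[2]
  xs <- c(rt_window[1], rt[keep], rt_window[2])
  xs <- xs[xs >= min(rt) & xs <= max(rt)]
  if (length(xs) < 2L) return(0)
  ys <- stats::approx(rt, y, xout = xs, rule = 2)$y
  if (baseline == "linear") {
    base <- ys[1] + (ys[length(ys)] - ys[1]) *
      (xs - xs[1]) / (xs[length(xs)] - xs[1])
    ys <- pmax(ys - base, 0)
  }
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Single-point internal-standard quantification
#'
#' Concentration from the ratio of analyte to internal-standard peak area,
#' scaled by the spiked internal-standard amount and the extracted tissue
#' fresh weight. This mirrors spiking each extraction with a fixed amount of
#' a standard (e.g. testosterone) and assuming equal response linearity.
#'
#' @param analyte_area Analyte peak area (>= 0).
#' @param is_area Internal-standard peak area (> 0; 0 signals a failed
#'   spike and is an error).
#' @param is_amount Spiked internal-standard amount (nmol).
#' @param sample_mass Extracted tissue mass (g fresh weight, > 0).
#' @return Concentration in nmol per g fresh weight.
#' @export
#' @examples
#' quantify_by_internal_standard(1e5, 1e5, 10, 0.1)  # 100 nmol/g FW
quantify_by_internal_standard <- function(analyte_area, is_area, is_amount,
                                          sample_mass) {
  if (any(is_area <= 0)) stop("internal-standard area must be positive (failed spike?)")
  if (any(sample_mass <= 0)) stop("sample mass must be positive")
  if (any(analyte_area < 0)) stop("analyte area must be non-negative")
  analyte_area / is_area * is_amount / sample_mass
}

#' Log2 fold-change matrix versus a control group
#'
#' `log2((area + pseudo) / (mean control area + pseudo))` per compound and
#' sample. The pseudo-count keeps rows finite when a compound is absent from
#' a genotype (a knockout then shows a large negative value rather than
#' -Inf), and makes an all-absent compound an exact zero row.
#'
#' @param areas Numeric matrix or data.frame, compounds x samples.
#' @param sample_groups Character vector of group labels, one per column.
#' @param control_group Label of the control group (must be present).
#' @param pseudo Pseudo-count added to every area (> 0, default 1).
#' @return Matrix of log2 fold changes with the input dimnames.
#' @export
fold_change_matrix <- function(areas, sample_groups, control_group = "control",
                               pseudo = 1) {
  areas <- as.matrix(areas)
  stopifnot(length(sample_groups) == ncol(areas), pseudo > 0)
  ctrl <- sample_groups == control_group
  if (!any(ctrl)) stop("control group '", control_group, "' has no samples")
  ctrl_mean <- rowMeans(areas[, ctrl, drop = FALSE])
  log2((areas + pseudo) / (ctrl_mean + pseudo))
}

#' Per-class chemotype summary
#'
#' Sums annotated signal by chemotype class for each sample. Class totals
#' sum exactly to the per-sample grand total (conservation), because
#' classification is a total partition.
#'
#' @param annotations Annotation data.frame (from [dereplicate_peaklist()])
#'   with at least columns `sample_id`, `class` and a signal column.
#' @param value Name of the signal column (default `"intensity"`).
#' @return data.frame with one row per sample: `sample_id`, one column per
#'   class (`aglycone`, `intermediate`, `non-rhamnosylated`,
#'   `rhamnosylated`) and `total`.
#' @export
chemotype_summary <- function(annotations, value = "intensity") {
  classes <- c("aglycone", "intermediate", "non-rhamnosylated", "rhamnosylated")
  samples <- unique(annotations$sample_id)
  if (!length(samples)) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(classes) + 1),
                                  c(classes, "total")))
    return(cbind(data.frame(sample_id = character(0)), out))
  }
  rows <- lapply(samples, function(s) {
    a <- annotations[annotations$sample_id == s, , drop = FALSE]
    tot <- vapply(classes, function(cl) {
      sum(a[[value]][a$class == cl])
    }, numeric(1))
    cbind(data.frame(sample_id = s, stringsAsFactors = FALSE),
          as.data.frame(as.list(tot), check.names = FALSE),
          data.frame(total = sum(tot)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
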