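# Conventions fixed package-wide: retention time in seconds, m/z in Th,
# masses in Da, concentrations in nmol per g fresh weight. TSV output uses
# '.' decimals and LF line endings with stable column order.

#' Read a centroided peak table
#'
#' CSV/TSV (by extension) with required header columns `mz`, `intensity`,
#' `rt_seconds`. Rows are sorted by retention time then m/z; a missing column
#' or a non-numeric cell is an error naming the offender.
#'
#' @param path File path.
#' @param sample_id,group Labels attached to the returned peak list.
#' @return A [peak_list()]. An empty file with a valid header gives an empty
#'   peak list with a warning.
#' @export
read_peak_table <- function(path, sample_id = basename(path), group = "control") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("mz", "intensity", "rt_seconds")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("peak table lacks column '", missing[1], "'")
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at line ", bad[1] + 1L)
    }
    df[[col]] <- v
  }
  if (!nrow(df)) warning("empty peak table: ", path)
  df$rt <- df$rt_seconds
  peak_list(df[, c("rt", "mz", "intensity")], sample_id = sample_id, group = group)
}

#' Write a peak list back to TSV
#'
#' Inverse of [read_peak_table()]: columns `mz`, `intensity`, `rt_seconds`.
#'
#' @param pl A [peak_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(pl, path) {
  df <- data.frame(mz = pl$peaks$mz, intensity = pl$peaks$intensity,
                   rt_seconds = pl$peaks$rt)
  write_dtg_tsv(df, path)
}

#' Read protein records from FASTA
#'
#' Sequences are upper-cased; duplicate ids are made unique by suffixing
#' (with a warning); a file with no records is an error.
#'
#' @param path FASTA path.
#' @return data.frame with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs)) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids made unique by suffixing")
    ids <- make.unique(ids, sep = "_dup")
  }
  data.frame(id = ids, sequence = toupper(as.character(seqs)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read an expression matrix with its sample-annotation sidecar
#'
#' The matrix is a TSV with gene ids in the first column and samples across;
#' the sidecar TSV carries columns `sample_id`, `tissue`, `time_h`,
#' `treatment`.
#'
#' @param matrix_path,annotation_path TSV paths.
#' @return An [expr_compendium()].
#' @export
read_expression <- function(matrix_path, annotation_path) {
  m <- utils::read.delim(matrix_path, row.names = 1, check.names = FALSE)
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  expr_compendium(as.matrix(m), ann)
}

#' Write a table as TSV with package conventions
#'
#' Tab separator, no quoting, no row names, '.' decimal, LF endings, column
#' order as given.
#'
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dtg_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", dec = ".")
  invisible(path)
}

# Known configuration keys and their defaults.
.config_defaults <- function() {
  list(
    tol_mda = 4,                # accurate-mass tolerance, mDa
    tol_ppm = NULL,             # alternative ppm-mode tolerance
    adducts = c("protonated", "sodiated", "ammoniated"),
    bounds = c(hex = 4, dhex = 3, mal = 4),
    eic_tol_th = 0.01,          # EIC half-window, Th
    eic_target_aglycone = 329.2475,  # literal EIC target for the intact
                                     # aglycone; a measured value, not
                                     # computed from a formula here
    foldchange_pseudo = 1,
    intensity_floor = 0,
    min_pcc = 0.6,
    min_shoot_root = 10,
    min_induction = 3,
    induction_time_h = 5,
    seed = 1
  )
}

#' Pipeline run configuration
#'
#' Validated settings list with documented defaults; unknown keys are
#' rejected so typos fail loudly. `read_config()` loads overrides from a
#' YAML or JSON file (top-level keys as in [dtg_config()]; an `adducts` key
#' may also define extra adducts as `name: {formula: ..., charge: 1}`
#' mappings, which extend the registry).
#'
#' @param ... Overrides of the default keys (see `.config_defaults` source
#'   for the full list: `tol_mda`, `tol_ppm`, `adducts`, `bounds`,
#'   `eic_tol_th`, `eic_target_aglycone`, `foldchange_pseudo`,
#'   `intensity_floor`, `min_pcc`, `min_shoot_root`, `min_induction`,
#'   `induction_time_h`, `seed`).
#' @return Named list of settings, class `dtg_config`.
#' @export
#' @examples
#' dtg_config(tol_mda = 2)$tol_mda
dtg_config <- function(...) {
  defaults <- .config_defaults()
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop("unknown config key '", unknown[1], "'")
  cfg <- utils::modifyList(defaults, overrides, keep.null = TRUE)
  stopifnot(is.null(cfg$tol_ppm) || cfg$tol_ppm > 0,
            cfg$tol_mda > 0, cfg$eic_tol_th > 0, cfg$foldchange_pseudo > 0)
  structure(cfg, class = "dtg_config")
}

#' @rdname dtg_config
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$bounds)) raw$bounds <- unlist(raw$bounds)
  if (!is.null(raw$adducts)) raw$adducts <- unlist(raw$adducts)
  do.call(dtg_config, raw)
}

#' Run one pipeline stage end to end
#'
#' Programmatic pipeline driver: executes one named stage with the given
#' configuration, writes its artifacts as TSV under `out_dir`, and appends a
#' JSON log line recording the package version, command, seed and a hash of
#' the configuration, so any stochastic run is reproducible from the log.
#' Outputs are deterministic for fixed inputs, config and seed.
#'
#' @param command One of `"simulate-spectra"`, `"annotate"`, `"eic"`,
#'   `"chemotype"`, `"simulate-expression"`, `"candidates"`.
#' @param config A [dtg_config()].
#' @param out_dir Output directory (created if needed).
#' @param input For `annotate`/`eic`/`chemotype`: path(s) to peak tables.
#'   For `candidates`: list with `matrix` and `annotation` paths (and
#'   optionally `fasta`). Ignored by the simulators.
#' @param ... Extra arguments passed to the underlying stage (e.g.
#'   `n_samples`, `baits`, `target_mz`).
#' @return Named character vector of written file paths, invisibly.
#' @export
run_dtg <- function(command, config = dtg_config(), out_dir = ".",
                    input = NULL, ...) {
  commands <- c("simulate-spectra", "annotate", "eic", "chemotype",
                "simulate-expression", "candidates")
  if (!is.character(command) || length(command) != 1L || !command %in% commands) {
    stop("unknown command '", paste(command, collapse = " "),
         "'; usage: run_dtg(<command>, ...) with command one of: ",
         paste(commands, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  dots <- list(...)

  if (command == "simulate-spectra") {
    cfg <- spectra_sim_config(seed = config$seed)
    if (!is.null(dots$sim_config)) cfg <- dots$sim_config
    n <- if (is.null(dots$n_samples)) 1L else dots$n_samples
    sim <- gen_peaklists(cfg, n_samples = n)
    for (pl in sim$peaklists) {
      f <- file.path(out_dir, paste0("peaks_", pl$sample_id, ".tsv"))
      write_peak_table(pl, f)
      written[paste0("peaks_", pl$sample_id)] <- f
    }
    f <- file.path(out_dir, "truth.tsv")
    write_dtg_tsv(sim$truth, f)
    written["truth"] <- f
  } else if (command == "annotate") {
    stopifnot(!is.null(input))
    ann <- do.call(rbind, lapply(input, function(p) {
      dereplicate_peaklist(read_peak_table(p), config = config)
    }))
    f <- file.path(out_dir, "annotations.tsv")
    write_dtg_tsv(ann, f)
    written["annotations"] <- f
  } else if (command == "eic") {
    stopifnot(!is.null(input))
    target <- if (is.null(dots$target_mz)) fragment_mz_aglycone_core() else dots$target_mz
    for (p in input) {
      pl <- read_peak_table(p)
      tr <- compute_eic(pl, target, config$eic_tol_th)
      f <- file.path(out_dir, paste0("eic_", pl$sample_id))
      write_dtg_tsv(tr, f)
      written[paste0("eic_", pl$sample_id)] <- f
    }
  } else if (command == "chemotype") {
    stopifnot(!is.null(input))
    ann <- do.call(rbind, lapply(input, function(p) {
      dereplicate_peaklist(read_peak_table(p), config = config)
    }))
    f <- file.path(out_dir, "chemotype_summary.tsv")
    write_dtg_tsv(chemotype_summary(ann), f)
    written["chemotype_summary"] <- f
  } else if (command == "simulate-expression") {
    cfg <- expr_sim_config(seed = config$seed)
    if (!is.null(dots$sim_config)) cfg <- dots$sim_config
    sim <- gen_expression(cfg)
    f1 <- file.path(out_dir, "expression_matrix.tsv")
    m <- data.frame(gene = rownames(sim$compendium$expr),
                    sim$compendium$expr, check.names = FALSE)
    write_dtg_tsv(m, f1)
    f2 <- file.path(out_dir, "sample_annotation.tsv")
    write_dtg_tsv(sim$compendium$samples, f2)
    f3 <- file.path(out_dir, "expression_truth.tsv")
    write_dtg_tsv(sim$truth, f3)
    written[c("expression_matrix", "sample_annotation", "expression_truth")] <-
      c(f1, f2, f3)
  } else if (command == "candidates") {
    stopifnot(!is.null(input), !is.null(dots$baits))
    comp <- read_expression(input$matrix, input$annotation)
    report <- rank_candidates(comp, baits = dots$baits,
                              min_pcc = config$min_pcc,
                              min_shoot_root = config$min_shoot_root,
                              min_induction = config$min_induction,
                              induction_time = config$induction_time_h)
    f <- file.path(out_dir, "candidate_report.tsv")
    write_dtg_tsv(report, f)
    written["candidate_report"] <- f
  }

  log_entry <- list(
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("hgldtg")),
    command = command,
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    outputs = as.list(written))
  log_path <- file.path(out_dir, "run_log.json")
  cat(jsonlite::toJSON(log_entry, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE, sep = "")
  invisible(written)
}
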