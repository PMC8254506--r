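#' HGL-DTG sugar/malonyl composition
#'
#' A composition counts the residues decorating the 17-HGL scaffold: hexoses
#' (glucose), deoxyhexoses (rhamnose) and malonyl groups. Two biosynthetic
#' constraints make the space smaller than a free triple: rhamnose is only
#' ever attached to an existing glucose, so `n_dhex >= 1` requires
#' `n_hex >= 1`; and malonylation esterifies a glucose C'-6 hydroxyl, so
#' `n_mal <= n_hex`.
#'
#' @param n_hex,n_dhex,n_mal Non-negative integer residue counts.
#' @return A one-row data.frame with columns `n_hex`, `n_dhex`, `n_mal`.
#' @export
#' @examples
#' dtg_composition(2, 1, 0)  # lyciumoside IV
dtg_composition <- function(n_hex, n_dhex, n_mal) {
  n_hex <- as.integer(n_hex); n_dhex <- as.integer(n_dhex); n_mal <- as.integer(n_mal)
  if (any(c(n_hex, n_dhex, n_mal) < 0L)) {
    stop("residue counts must be non-negative")
  }
  if (n_dhex >= 1L && n_hex < 1L) {
    stop("rhamnosylation requires prior glucosylation (n_dhex >= 1 needs n_hex >= 1)")
  }
  if (n_mal > n_hex) {
    stop("malonylation is per glucose C'-6: n_mal must not exceed n_hex")
  }
  data.frame(n_hex = n_hex, n_dhex = n_dhex, n_mal = n_mal)
}

# Constraint predicate used by the enumerator (vectorized).
.composition_ok <- function(n_hex, n_dhex, n_mal) {
  n_hex >= 0L & n_dhex >= 0L & n_mal >= 0L &
    (n_dhex == 0L | n_hex >= 1L) &
    n_mal <= n_hex
}

#' Neutral formula of a composition
#'
#' 17-HGL (C20H34O2) plus the dehydrated residues.
#'
#' @param composition One-row data.frame (or list) with `n_hex`, `n_dhex`,
#'   `n_mal`.
#' @return Named integer count vector.
#' @export
#' @examples
#' format_formula(composition_formula(dtg_composition(2, 0, 0)))  # "C32H54O12"
composition_formula <- function(composition) {
  f <- parse_formula(.HGL_AGLYCONE)
  f <- formula_add(f, formula_multiply(parse_formula(.RESIDUES$hex),
                                       composition$n_hex))
  f <- formula_add(f, formula_multiply(parse_formula(.RESIDUES$dhex),
                                       composition$n_dhex))
  formula_add(f, formula_multiply(parse_formula(.RESIDUES$mal),
                                  composition$n_mal))
}

#' Enumerate candidate compositions within bounds
#'
#' All residue triples satisfying the attachment constraints, in
#' lexicographic order of `(n_hex, n_dhex, n_mal)`.
#'
#' @param bounds Named vector or list with `hex`, `dhex`, `mal` maxima.
#' @return data.frame with columns `n_hex`, `n_dhex`, `n_mal`.
#' @export
#' @examples
#' enumerate_compositions(c(hex = 2, dhex = 1, mal = 0))
enumerate_compositions <- function(bounds = c(hex = 4, dhex = 3, mal = 4)) {
  bounds <- as.list(bounds)
  stopifnot(all(c("hex", "dhex", "mal") %in% names(bounds)))
  g <- expand.grid(n_mal = 0:bounds$mal, n_dhex = 0:bounds$dhex,
                   n_hex = 0:bounds$hex)
  g <- g[.composition_ok(g$n_hex, g$n_dhex, g$n_mal), c("n_hex", "n_dhex", "n_mal")]
  g <- g[order(g$n_hex, g$n_dhex, g$n_mal), ]
  rownames(g) <- NULL
  g
}

#' Classify a composition into a chemotype category
#'
#' Total partition of the composition space into the four classes the
#' chemotype is profiled by: `aglycone` (no sugars), `intermediate` (a single
#' sugar, or any composition with positional evidence of a free aglycone
#' hydroxyl), `rhamnosylated` (any deoxyhexose) and `non-rhamnosylated`
#' (everything else). A di-glucoside, composition (2,0,0), is a complete
#' non-rhamnosylated compound by default; only chromatographic/MS2 positional
#' evidence can mark it as an intermediate, which composition alone cannot.
#'
#' @param composition One-row data.frame/list with `n_hex`, `n_dhex`, `n_mal`.
#' @param positional_evidence Logical: curated evidence that an aglycone
#'   hydroxyl is unglycosylated.
#' @return One of `"aglycone"`, `"intermediate"`, `"rhamnosylated"`,
#'   `"non-rhamnosylated"`.
#' @export
#' @examples
#' classify_composition(dtg_composition(2, 1, 0))  # "rhamnosylated"
classify_composition <- function(composition, positional_evidence = FALSE) {
  n_sugar <- composition$n_hex + composition$n_dhex
  if (n_sugar == 0L) return("aglycone")
  if (n_sugar == 1L || isTRUE(positional_evidence)) return("intermediate")
  if (composition$n_dhex >= 1L) return("rhamnosylated")
  "non-rhamnosylated"
}

#' Reference HGL-DTG compound table
#'
#' Seed table of named compounds with their residue compositions and
#' chemotype classes, shipped as editable CSV
#' (`inst/extdata/reference_compounds.csv`). Compositions not stated outright
#' in the primary literature (the nicotianoside malonyl series, the
#' DTG-numbered intermediates) are inferred from nominal adduct masses and
#' flagged `provisional`. Isomer series (e.g. nicotianoside IXa-d) collapse
#' to a single composition row.
#'
#' @param path Optional path to an alternative CSV with the same columns.
#' @return data.frame with columns `name`, `n_hex`, `n_dhex`, `n_mal`,
#'   `class`, `provisional`.
#' @export
reference_compounds <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_compounds.csv", package = "hgldtg")
  }
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "n_hex", "n_dhex", "n_mal", "class", "provisional")
  missing <- setdiff(need, names(ref))
  if (length(missing)) stop("reference table lacks column ", missing[1])
  if (anyDuplicated(ref$name)) stop("reference table names must be unique")
  ok <- .composition_ok(ref$n_hex, ref$n_dhex, ref$n_mal)
  if (!all(ok)) {
    stop("invalid composition in reference table row ", which(!ok)[1])
  }
  ref
}
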