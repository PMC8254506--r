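# Monoisotopic element masses (Da), fixed IUPAC/CODATA values. Immutable:
# every m/z printed by the package derives from this table plus the electron
# mass, so the values are shipped as code, not user data.
.ELEMENT_MASS <- c(
  C  = 12,
  H  = 1.00782503207,
  O  = 15.9949146196,
  N  = 14.0030740048,
  Na = 22.9897692809,
  F  = 18.99840322,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268
)

.ELECTRON_MASS <- 0.00054857990907

#' Monoisotopic element mass table
#'
#' Fixed table of monoisotopic masses (Da) for the elements the package
#' handles, plus the electron mass used for charge bookkeeping. Cation m/z
#' values subtract one electron mass per positive charge; without this
#' correction the package would disagree with calibrated Q-TOF readings by
#' roughly 1 ppm at m/z 600.
#'
#' @return Named numeric vector of element masses in Da, with the electron
#'   mass available as `attr(, "electron_mass")`.
#' @export
#' @examples
#' element_masses()[["C"]]
element_masses <- function() {
  structure(.ELEMENT_MASS, electron_mass = .ELECTRON_MASS)
}

#' Parse a Hill-notation molecular formula
#'
#' Converts a formula string such as `"C20H34O2"` into a named integer vector
#' of element counts. The empty string parses to the empty formula. Element
#' symbols must be present in [element_masses()].
#'
#' @param text Formula string (element symbol followed by an optional integer
#'   count, repeated).
#' @return Named integer vector of counts, in Hill order (C, H, then
#'   alphabetical). The empty formula is a zero-length named integer vector.
#' @export
#' @examples
#' parse_formula("C20H34O2")
#' parse_formula("")
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) {
    return(structure(integer(0), names = character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    covered <- strsplit(paste(tokens, collapse = ""), "")[[1]]
    bad <- setdiff(strsplit(text, "")[[1]], covered)
    stop("malformed formula '", text, "': unparseable token '",
         if (length(bad)) bad[1] else text, "'")
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  unknown <- setdiff(sym, names(.ELEMENT_MASS))
  if (length(unknown)) {
    stop("unknown element symbol '", unknown[1], "' in formula '", text, "'")
  }
  counts <- tapply(cnt, sym, sum)
  as_formula(structure(as.integer(counts), names = names(counts)))
}

# Canonicalize a named count vector: drop zeros, order Hill-style.
as_formula <- function(counts) {
  stopifnot(!is.null(names(counts)) || length(counts) == 0L)
  counts <- counts[counts != 0L]
  if (any(counts < 0L)) {
    stop("formula counts must be non-negative")
  }
  nm <- names(counts)
  rest <- sort(setdiff(nm, c("C", "H")))
  ord <- c(intersect(c("C", "H"), nm), rest)
  structure(as.integer(counts[ord]), names = ord)
}

#' Format a molecular formula in Hill notation
#'
#' @param f Named integer vector of element counts (as from
#'   [parse_formula()]).
#' @return Single string; `""` for the empty formula.
#' @export
format_formula <- function(f) {
  f <- as_formula(f)
  if (!length(f)) return("")
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' Count-wise formula arithmetic
#'
#' `formula_add()` sums counts; `formula_subtract()` subtracts and errors on
#' any negative resulting count; `formula_multiply()` scales all counts by a
#' non-negative integer.
#'
#' @param a,b,f Named integer count vectors.
#' @param n Non-negative integer multiplier.
#' @return Named integer count vector in canonical order.
#' @export
#' @examples
#' format_formula(formula_add(parse_formula("C20H34O2"),
#'                            formula_multiply(parse_formula("C6H10O5"), 2)))
formula_add <- function(a, b) {
  all_el <- union(names(a), names(b))
  out <- setNames(integer(length(all_el)), all_el)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  as_formula(out)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  all_el <- union(names(a), names(b))
  out <- setNames(integer(length(all_el)), all_el)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0L)) {
    neg <- names(out)[out < 0L]
    stop("formula subtraction yields negative count for ", neg[1])
  }
  as_formula(out)
}

#' @rdname formula_add
#' @export
formula_multiply <- function(f, n) {
  stopifnot(length(n) == 1L, n >= 0, n == round(n))
  as_formula(setNames(as.integer(f * n), names(f)))
}

#' Monoisotopic mass of a formula
#'
#' Sum of count times monoisotopic element mass. Additive over
#' [formula_add()]: `monoisotopic_mass(a + b)` equals the sum of the parts.
#'
#' @param f Named integer count vector, or a formula string.
#' @return Mass in Da (0 for the empty formula).
#' @export
#' @examples
#' monoisotopic_mass("C20H34O2")  # 17-HGL aglycone, 306.2559 Da
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (!length(f)) return(0)
  unknown <- setdiff(names(f), names(.ELEMENT_MASS))
  if (length(unknown)) {
    stop("unknown element symbol '", unknown[1], "'")
  }
  sum(.ELEMENT_MASS[names(f)] * f)
}

#' Adduct definitions for positive-mode electrospray
#'
#' An adduct is the charged species formed by attaching a cationizing agent to
#' a neutral molecule. `make_adduct()` builds one; `default_adducts()` returns
#' the registry of the three species relevant here -- protonated `[M+H]+`,
#' sodiated `[M+Na]+` and ammoniated `[M+NH4]+` -- plus `cation`, the identity
#' adduct for species whose formula already includes the ionizing proton
#' (e.g. a tuning-mix lock mass). Only singly positive charges are supported.
#'
#' @param name Adduct label.
#' @param formula_delta Formula (string or count vector) added to the neutral.
#' @param charge Signed integer charge; must be +1 here.
#' @return `make_adduct()`: a list with elements `name`, `formula_delta`,
#'   `charge`. `default_adducts()`: named list of such adducts.
#' @export
#' @examples
#' default_adducts()$sodiated
make_adduct <- function(name, formula_delta, charge = 1L) {
  if (is.character(formula_delta)) formula_delta <- parse_formula(formula_delta)
  charge <- as.integer(charge)
  if (charge == 0L) stop("adduct charge must be non-zero")
  if (charge != 1L) stop("only singly positively charged adducts are supported")
  list(name = name, formula_delta = formula_delta, charge = charge)
}

#' @rdname make_adduct
#' @export
default_adducts <- function() {
  list(
    protonated = make_adduct("protonated", "H"),
    sodiated   = make_adduct("sodiated", "Na"),
    ammoniated = make_adduct("ammoniated", "NH4"),
    cation     = make_adduct("cation", "")
  )
}

# Resolve an adduct given as name or object.
resolve_adduct <- function(adduct, registry = default_adducts()) {
  if (is.character(adduct)) {
    if (!adduct %in% names(registry)) {
      stop("unknown adduct '", adduct, "'")
    }
    return(registry[[adduct]])
  }
  stopifnot(is.list(adduct), all(c("name", "formula_delta", "charge") %in% names(adduct)))
  adduct
}

#' m/z of an ionized neutral species
#'
#' Computes `(mass(neutral) + mass(formula_delta) - charge * m_e) / |charge|`.
#' The electron-mass correction matters at the 4-decimal precision accurate-
#' mass work is reported at.
#'
#' @param neutral Neutral formula (string or count vector).
#' @param adduct Adduct name (looked up in `registry`) or adduct object.
#' @param registry Adduct registry, see [default_adducts()].
#' @return m/z in Th.
#' @export
#' @examples
#' # sodiated di-glucoside of 17-HGL
#' ion_mz("C32H54O12", "sodiated")
ion_mz <- function(neutral, adduct, registry = default_adducts()) {
  if (is.character(neutral)) neutral <- parse_formula(neutral)
  adduct <- resolve_adduct(adduct, registry)
  cation <- formula_add(neutral, adduct$formula_delta) # errors if negative
  m <- monoisotopic_mass(cation) - adduct$charge * .ELECTRON_MASS
  m / abs(adduct$charge)
}

#' Diagnostic in-source fragment of all HGL-DTGs
#'
#' m/z of the C20H31+ cation: the 17-HGL aglycone having lost both hydroxyl
#' groups (as waters), formed in-source during ionization by every HGL-DTG
#' regardless of decoration. Its extracted-ion chromatogram visualizes the
#' whole chemotype in one trace.
#'
#' @return m/z in Th (approximately 271.2420).
#' @export
fragment_mz_aglycone_core <- function() {
  ion_mz(parse_formula("C20H30"), "protonated")
}

# Scaffold and residue formulas: the currency of composition arithmetic.
.HGL_AGLYCONE <- "C20H34O2"
.RESIDUES <- list(
  hex  = "C6H10O5",  # dehydrated hexose (glucose) residue
  dhex = "C6H10O4",  # dehydrated deoxyhexose (rhamnose) residue
  mal  = "C3H2O3"    # malonyl residue
)

#' Scaffold and residue formulas
#'
#' The 17-HGL aglycone (C20H34O2) and the dehydrated residue formulas added
#' per glycosylation/malonylation: hexose C6H10O5, deoxyhexose C6H10O4,
#' malonyl C3H2O3.
#'
#' @return Named list of formula strings with elements `aglycone`, `hex`,
#'   `dhex`, `mal`.
#' @export
dtg_residues <- function() {
  c(list(aglycone = .HGL_AGLYCONE), .RESIDUES)
}
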