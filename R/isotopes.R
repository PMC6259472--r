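the_cache <- new.env(parent = emptyenv())

#' Pinned isotope masses and natural abundances
#'
#' Returns the package's pinned table of isotope masses (Da) and natural
#' abundances for the elements used in cytokinin work (C, H, N, O, P) plus
#' deuterium, which is registered under its own symbol `"D"` with abundance
#' fixed at 1: a label atom introduced by the experimenter is never subject
#' to natural isotopic variation. The table ships as a plain-text file
#' (`extdata/isotopes.tsv`) so that every mass in the package is traceable
#' to one versioned source.
#'
#' @param path Optional path to an alternative isotope table in the same
#'   three-column TSV layout (`element`, `isotope_mass`, `abundance`).
#' @return A tibble with columns `element`, `isotope_mass` (Da) and
#'   `abundance` (fraction), sorted by increasing mass within element.
#' @examples
#' isotope_table()
#' @export
isotope_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the_cache$isotopes)) return(the_cache$isotopes)
    path <- system.file("extdata", "isotopes.tsv", package = "cktrace",
                        mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(tbl), c("element", "isotope_mass", "abundance")))
  tbl <- tibble::as_tibble(tbl)
  tbl <- dplyr::arrange(tbl, .data$element, .data$isotope_mass)
  validate_isotope_table(tbl)
  if (cache) the_cache$isotopes <- tbl
  tbl
}

validate_isotope_table <- function(tbl) {
  sums <- tapply(tbl$abundance, tbl$element, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-9]
  if (length(bad) > 0) {
    stop("isotope abundances do not sum to 1 for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  inc <- tapply(tbl$isotope_mass, tbl$element, function(m) all(diff(m) > 0))
  if (!all(unlist(inc))) stop("isotope masses must increase within element",
                              call. = FALSE)
  if (sum(tbl$element == "D") != 1L || tbl$abundance[tbl$element == "D"] != 1) {
    stop("'D' must have exactly one isotope entry with abundance 1",
         call. = FALSE)
  }
  invisible(tbl)
}

# element -> principal (lightest) isotope mass, and integer mass number
principal_mass <- function(element, iso = isotope_table()) {
  m <- vapply(element, function(el) {
    rows <- iso$isotope_mass[iso$element == el]
    if (length(rows) == 0) stop("unknown element symbol: '", el, "'",
                                call. = FALSE)
    rows[1]
  }, numeric(1))
  unname(m)
}

mass_number <- function(element, iso = isotope_table()) {
  round(principal_mass(element, iso))
}

#' Chemical formulas with explicit deuterium
#'
#' `parse_formula()` turns a formula string such as `"C5H9+"` or
#' `"C5H3D6+"` into a `chem_formula` object: a named count vector with a
#' charge attribute. Deuterium is written only as the symbol `D` (no
#' bracket isotope syntax); a trailing `+` marks the singly charged cation.
#' Whitespace between element blocks is tolerated and repeated symbols are
#' aggregated, so the printed form always round-trips through the parser.
#'
#' @param text A single formula string, e.g. `"C10H13N5"`.
#' @param counts Named integer vector of element counts (for
#'   `chem_formula()`).
#' @param charge Integer charge, 0 or +1 in this package's domain.
#' @return A `chem_formula`: named integer vector of atom counts with a
#'   `charge` attribute.
#' @examples
#' parse_formula("C5H9+")
#' parse_formula("C5 H3 D6 +")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]+", "", text)
  if (s == "") stop("empty formula string", call. = FALSE)
  charge <- 0L
  if (grepl("\\+$", s)) {
    charge <- 1L
    s <- sub("\\+$", "", s)
    if (s == "") stop("empty formula string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s, perl = TRUE)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse formula: '", text, "'", call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", tokens)
  nums <- sub("^[A-Z][a-z]?", "", tokens)
  counts <- ifelse(nums == "", 1L, suppressWarnings(as.integer(nums)))
  known <- unique(isotope_table()$element)
  unknown <- setdiff(syms, known)
  if (length(unknown) > 0) {
    stop("unknown element symbol: '", paste(unknown, collapse = "', '"),
         "'", call. = FALSE)
  }
  agg <- tapply(counts, syms, sum)
  chem_formula(stats::setNames(as.integer(agg), names(agg)), charge = charge)
}

#' @rdname parse_formula
#' @export
chem_formula <- function(counts, charge = 0L) {
  stopifnot(is.numeric(counts), !is.null(names(counts)),
            all(counts == round(counts)), all(counts >= 0))
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- counts[counts > 0]
  if (sum(counts) < 1) stop("formula must contain at least one atom",
                            call. = FALSE)
  charge <- as.integer(charge)
  if (!charge %in% c(0L, 1L)) {
    stop("charge must be 0 or +1 (positive-mode cations only)",
         call. = FALSE)
  }
  structure(counts[order_elements(names(counts))], charge = charge,
            class = "chem_formula")
}

# display order: C, H, D first, then remaining symbols alphabetically
order_elements <- function(syms) {
  lead <- c("C", "H", "D")
  order(match(syms, lead, nomatch = length(lead) + 1L), syms)
}

as_chem_formula <- function(x) {
  if (inherits(x, "chem_formula")) x else parse_formula(x)
}

#' @export
format.chem_formula <- function(x, ...) {
  cnt <- unclass(x)
  body <- paste0(names(cnt), ifelse(cnt == 1L, "", cnt), collapse = "")
  paste0(body, if (attr(x, "charge") == 1L) "+" else "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
`+.chem_formula` <- function(e1, e2) {
  cnt <- merge_counts(unclass(e1), unclass(e2), `+`)
  chem_formula(cnt, charge = attr(e1, "charge") + attr(e2, "charge"))
}

#' @export
`-.chem_formula` <- function(e1, e2) {
  cnt <- merge_counts(unclass(e1), unclass(e2), `-`)
  if (any(cnt < 0)) {
    stop("formula subtraction would give a negative atom count",
         call. = FALSE)
  }
  chem_formula(cnt, charge = max(attr(e1, "charge") - attr(e2, "charge"), 0L))
}

merge_counts <- function(a, b, op) {
  syms <- union(names(a), names(b))
  va <- stats::setNames(rep(0L, length(syms)), syms); va[names(a)] <- a
  vb <- stats::setNames(rep(0L, length(syms)), syms); vb[names(b)] <- b
  op(va, vb)
}

# protonate a neutral formula -> [M+H]+ cation
protonate <- function(f) {
  f <- as_chem_formula(f)
  stopifnot(attr(f, "charge") == 0L)
  cnt <- merge_counts(unclass(f), c(H = 1L), `+`)
  chem_formula(cnt, charge = 1L)
}

#' Exact and nominal mass of a formula
#'
#' `exact_mass()` sums principal-isotope (monoisotopic) atomic masses; for
#' deuterium the sole isotope mass is used. No electron-mass correction is
#' applied to cations: the neutral-atom sum is the convention used for all
#' calculated m/z values in this package, matching unit conventions common
#' in small-molecule MRM work (the difference, about 7 ppm at m/z 69, is
#' absorbed by instrument calibration). `nominal_mass()` sums integer mass
#' numbers (D counts as 2), the quantity a unit-resolution quadrupole
#' reports.
#'
#' @param x A formula string, a `chem_formula`, or a character vector of
#'   formula strings (vectorized).
#' @return Numeric (exact, Da) or integer (nominal) vector.
#' @examples
#' exact_mass("C5H9+")    # 69.0704
#' exact_mass("C5H3D6+")  # 75.1081
#' nominal_mass(c("C10H14N5+", "C5H9+"))
#' @export
exact_mass <- function(x) {
  if (is.character(x) && length(x) > 1L) {
    return(vapply(x, function(s) exact_mass(s), numeric(1), USE.NAMES = FALSE))
  }
  f <- as_chem_formula(x)
  sum(unclass(f) * principal_mass(names(f)))
}

#' @rdname exact_mass
#' @export
nominal_mass <- function(x) {
  if (is.character(x) && length(x) > 1L) {
    return(vapply(x, function(s) nominal_mass(s), integer(1),
                  USE.NAMES = FALSE))
  }
  f <- as_chem_formula(x)
  as.integer(sum(unclass(f) * mass_number(names(f))))
}

#' Mass error in parts per million
#'
#' The standard exact-mass fidelity measure: signed relative deviation of an
#' experimental m/z from the value calculated from a formula, in ppm.
#'
#' @param experimental Observed m/z value(s).
#' @param calculated Calculated m/z value(s); must be positive.
#' @return Signed ppm error, `(experimental - calculated) / calculated * 1e6`.
#' @examples
#' ppm_error(69.0703, 69.0704)  # -1.4 ppm
#' @export
ppm_error <- function(experimental, calculated) {
  if (any(!is.finite(calculated)) || any(calculated <= 0)) {
    stop("calculated m/z must be positive", call. = FALSE)
  }
  (experimental - calculated) / calculated * 1e6
}
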