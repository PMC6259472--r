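# residues used in formula arithmetic
RIBOSE_RESIDUE    <- "C5H8O4"  # ribose condensation residue (riboside - base)
PHOSPHATE_RESIDUE <- "HPO3"    # 5'-monophosphate residue
PROPIONYL_RESIDUE <- "C3H4O"   # propionylation adds +56 nominal per hydroxyl

#' Registry of isoprenoid cytokinins
#'
#' The 11 isoprenoid cytokinins handled by this package: isopentenyladenine
#' (iP), trans-zeatin (tZ), cis-zeatin (cZ) and dihydrozeatin (DHZ), each as
#' free base, riboside (R suffix) and, except DHZ, riboside-5'-monophosphate
#' (MP suffix). Formulas are built from the free-base skeleton by adding the
#' ribose condensation residue (C5H8O4) for ribosides and HPO3 for
#' nucleotides. `sidechain_oh` counts free hydroxyls on the isoprenoid side
#' chain (0 for iP-type, 1 for the hydroxylated zeatin/DHZ types);
#' `ribose_oh` counts free sugar hydroxyls (3 on a riboside, 2 on a
#' 5'-monophosphate). The cis and trans zeatin isomers share formulas and
#' transitions and are distinguished chromatographically, not by mass.
#'
#' @return A tibble with one row per compound: `abbreviation`,
#'   `common_name`, `type` (iP, tZ, cZ, DHZ), `form` (base, riboside,
#'   nucleotide), `formula` (neutral molecule), `sidechain_oh`, `ribose_oh`.
#' @examples
#' cytokinin_registry()
#' @export
cytokinin_registry <- function() {
  if (!is.null(the_cache$registry)) return(the_cache$registry)
  skeletons <- tibble::tribble(
    ~type, ~base_formula, ~base_name,        ~sidechain_oh,
    "iP",  "C10H13N5",    "isopentenyladenine", 0L,
    "tZ",  "C10H13N5O",   "trans-zeatin",       1L,
    "cZ",  "C10H13N5O",   "cis-zeatin",         1L,
    "DHZ", "C10H15N5O",   "dihydrozeatin",      1L
  )
  rows <- purrr::pmap(skeletons, function(type, base_formula, base_name,
                                          sidechain_oh) {
    base <- parse_formula(base_formula)
    riboside <- base + parse_formula(RIBOSE_RESIDUE)
    nucleotide <- riboside + parse_formula(PHOSPHATE_RESIDUE)
    out <- tibble::tibble(
      abbreviation = c(type, paste0(type, "R"), paste0(type, "MP")),
      common_name = c(base_name, paste(base_name, "riboside"),
                      paste(base_name, "riboside-5'-monophosphate")),
      type = type,
      form = c("base", "riboside", "nucleotide"),
      formula = c(format(base), format(riboside), format(nucleotide)),
      sidechain_oh = sidechain_oh,
      ribose_oh = c(0L, 3L, 2L)
    )
    if (type == "DHZ") out <- out[out$form != "nucleotide", ]
    out
  })
  reg <- dplyr::bind_rows(rows)
  the_cache$registry <- reg
  reg
}

# resolve an analyte id ("iPR", "pro-tZR", "ZR", "pro-ZR", ...) to its
# registry row plus derivatization flag; "ZR" is the conventional shorthand
# for trans-zeatin riboside in transition tables
resolve_analyte <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  derivatized <- grepl("^pro-", id)
  abbr <- sub("^pro-", "", id)
  if (abbr %in% c("ZR", "Z", "ZMP")) abbr <- paste0("t", abbr)
  reg <- cytokinin_registry()
  row <- reg[reg$abbreviation == abbr, ]
  if (nrow(row) == 0L) {
    stop("unknown analyte '", id, "'; known: ",
         paste(reg$abbreviation, collapse = ", "), call. = FALSE)
  }
  list(record = row, derivatized = derivatized)
}

#' Propionylate a cytokinin
#'
#' Applies the hydroxyl-propionylation derivatization rule: one propionyl
#' residue (C3H4O, +56 nominal Da) is added per free hydroxyl, i.e. three on
#' a riboside sugar plus one on a hydroxylated (zeatin-type) side chain.
#' iP-type free bases carry no free hydroxyl and are returned unchanged.
#' Nucleotides are rejected: in the workflow this package supports they are
#' dephosphorylated with alkaline phosphatase and measured as ribosides.
#' An already-derivatized id (`"pro-..."`) is rejected rather than
#' propionylated twice.
#'
#' @param analyte Character vector of registry abbreviations
#'   (e.g. `"iPR"`, `"tZR"`, `"tZ"`).
#' @return A tibble with columns `analyte` (the `pro-` id), `formula`
#'   (derivatized neutral molecule), `n_propionyl`, and `precursor_mz`
#'   (nominal m/z of the protonated molecule).
#' @examples
#' propionylate(c("iPR", "tZR", "iP"))
#' @export
propionylate <- function(analyte) {
  purrr::map_dfr(analyte, propionylate_one)
}

propionylate_one <- function(id) {
  if (grepl("^pro-", id)) {
    stop("'", id, "' is already propionylated; the derivatization is ",
         "applied once per free hydroxyl", call. = FALSE)
  }
  res <- resolve_analyte(id)
  rec <- res$record
  if (rec$form == "nucleotide") {
    stop("cannot propionylate the nucleotide '", id, "': dephosphorylate ",
         "with alkaline phosphatase and derivatize the riboside instead",
         call. = FALSE)
  }
  n_prop <- rec$ribose_oh + rec$sidechain_oh
  f <- parse_formula(rec$formula)
  if (n_prop > 0) {
    for (i in seq_len(n_prop)) f <- f + parse_formula(PROPIONYL_RESIDUE)
  }
  tibble::tibble(
    analyte = if (n_prop > 0) paste0("pro-", rec$abbreviation) else
      rec$abbreviation,
    formula = format(f),
    n_propionyl = n_prop,
    precursor_mz = nominal_mass(protonate(f))
  )
}

#' Diagnostic MRM isotopomer transitions
#'
#' Builds the I0..I`j_max` multiple-reaction-monitoring transition ladder
#' used to measure deuterium labeling of a cytokinin riboside. The
#' monoisotopic (I0) transition selects the protonated riboside as
#' precursor and the protonated free-base fragment as product, so the
#' neutral loss is the (propionylated) ribose and signal from sugar
#' labeling is excluded. For derivatized zeatin-type analytes the base
#' fragment retains its side-chain propionyl; the sugar propionyls leave
#' with the neutral loss. Isotopomer I_j shifts both precursor and product
#' by +j Da.
#'
#' @param analyte Character vector of riboside ids (`"iPR"`, `"tZR"`,
#'   `"ZR"`); a `"pro-"` prefix implies `derivatized = TRUE` for that entry.
#' @param derivatized Apply the propionylation rule before building the
#'   ladder.
#' @param j_max Highest isotopomer monitored (default 3).
#' @return A tibble with columns `analyte`, `isotopomer` (0..j_max),
#'   `precursor_mz`, `product_mz` (nominal, unit resolution) and
#'   `product_formula` (the charged base-fragment formula used downstream
#'   for natural-abundance correction).
#' @examples
#' diagnostic_transitions("iPR", derivatized = TRUE)
#' diagnostic_transitions(c("iPR", "ZR"))
#' @export
diagnostic_transitions <- function(analyte, derivatized = FALSE, j_max = 3L) {
  stopifnot(j_max >= 0)
  purrr::map_dfr(analyte, diagnostic_transitions_one,
                 derivatized = derivatized, j_max = as.integer(j_max))
}

diagnostic_transitions_one <- function(id, derivatized, j_max) {
  res <- resolve_analyte(id)
  rec <- res$record
  derivatized <- derivatized || res$derivatized
  if (rec$form != "riboside") {
    stop("transitions are defined for ribosides only; '", id, "' is a ",
         rec$form, if (rec$form == "nucleotide")
           " (measure it as its riboside after alkaline phosphatase)",
         call. = FALSE)
  }
  riboside <- parse_formula(rec$formula)
  base <- riboside - parse_formula(RIBOSE_RESIDUE)
  precursor <- riboside
  product <- base
  if (derivatized) {
    n_prop <- rec$ribose_oh + rec$sidechain_oh
    for (i in seq_len(n_prop)) precursor <- precursor +
        parse_formula(PROPIONYL_RESIDUE)
    if (rec$sidechain_oh > 0) product <- product +
        parse_formula(PROPIONYL_RESIDUE)
  }
  prec_ion <- protonate(precursor)
  prod_ion <- protonate(product)
  label <- if (derivatized) paste0("pro-", rec$abbreviation) else
    rec$abbreviation
  tibble::tibble(
    analyte = label,
    isotopomer = 0:j_max,
    precursor_mz = nominal_mass(prec_ion) + 0:j_max,
    product_mz = nominal_mass(prod_ion) + 0:j_max,
    product_formula = format(prod_ion)
  )
}

#' Isoprenoid side-chain fragment
#'
#' iP-type cytokinins fragment to a diagnostic isoprenyl cation at m/z 69
#' (C5H9+); when the two terminal methyl groups carry six deuterons the
#' analogous fragment appears at m/z 75 (C5H3D6+). Hydroxylated
#' (zeatin/DHZ-type) side chains give no such diagnostic fragment, so those
#' analytes yield no rows.
#'
#' @param analyte Character vector of registry abbreviations.
#' @param labeled If `TRUE`, return the hexadeuterated fragment.
#' @return A tibble with columns `analyte`, `fragment_formula`, `mz`
#'   (nominal); zero rows for analytes without a side-chain fragment.
#' @examples
#' sidechain_fragment("iP")
#' sidechain_fragment("iP", labeled = TRUE)
#' sidechain_fragment("tZ")  # zero rows
#' @export
sidechain_fragment <- function(analyte, labeled = FALSE) {
  rows <- purrr::map(analyte, function(id) {
    res <- resolve_analyte(id)
    if (res$record$type != "iP") return(NULL)
    frag <- if (labeled) "C5H3D6+" else "C5H9+"
    tibble::tibble(analyte = id, fragment_formula = frag,
                   mz = nominal_mass(frag))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(analyte = character(), fragment_formula = character(),
                          mz = integer())
  }
  out
}
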