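#' Natural isotopologue pattern of a formula
#'
#' Computes the natural isotope abundance distribution of a formula,
#' aggregated by integer mass-number shift relative to the monoisotopic
#' species (+0, +1, ... +k), by per-element polynomial convolution. This is
#' the unit-resolution view a quadrupole MRM ladder sees: all isotopologues
#' one mass number up are pooled into one channel, regardless of which
#' element carries the heavy isotope.
#'
#' Deuterium atoms written as `D` are experimenter-introduced labels: they
#' contribute a fixed whole-number offset to the molecule's mass and zero
#' variance, so the pattern returned is that of the remaining natural atoms
#' only. Callers that care about the absolute mass handle the constant D
#' offset themselves.
#'
#' @param formula A formula string or `chem_formula`.
#' @param k Maximum mass shift retained (default 3, the I0-I3 window
#'   monitored in the MRM ladder).
#' @param normalize `"raw"` (default) keeps true probabilities, which sum to
#'   at most 1 over the retained shifts; `"sum1"` rescales the retained
#'   shifts to sum to one.
#' @return An `isotope_pattern`: a tibble with columns `shift` (0..k),
#'   `p` (abundance) and `r` (abundance relative to the monoisotopic peak,
#'   `r = p / p[1]`), carrying the formula as an attribute.
#' @examples
#' natural_pattern("C5H9+")
#' natural_pattern("C10H14N5+", k = 3)
#' @export
natural_pattern <- function(formula, k = 3L, normalize = c("raw", "sum1")) {
  normalize <- match.arg(normalize)
  stopifnot(k >= 0)
  k <- as.integer(k)
  f <- as_chem_formula(formula)
  iso <- isotope_table()

  p <- 1  # delta at shift 0 (empty convolution)
  for (el in names(f)) {
    if (el == "D") next  # fixed label: constant offset, no variance
    p <- convolve_trunc(p, element_pattern(el, unclass(f)[[el]], k, iso), k)
  }
  p <- c(p, rep(0, k + 1L - length(p)))
  if (normalize == "sum1") p <- p / sum(p)
  new_isotope_pattern(f, p, k, normalize)
}

new_isotope_pattern <- function(f, p, k, normalize) {
  out <- tibble::tibble(shift = 0:k, p = p, r = p / p[1])
  structure(out, formula = f, k = k, normalize = normalize,
            class = c("isotope_pattern", class(out)))
}

# distribution of the total mass-number shift for n atoms of one element,
# truncated at shift k: n-fold convolution of the single-atom distribution
element_pattern <- function(el, n, k, iso = isotope_table()) {
  rows <- iso[iso$element == el, ]
  shifts <- round(rows$isotope_mass) - round(rows$isotope_mass[1])
  single <- rep(0, max(shifts) + 1L)
  single[shifts + 1L] <- rows$abundance
  out <- 1
  for (i in seq_len(n)) out <- convolve_trunc(out, single, k)
  out
}

convolve_trunc <- function(a, b, k) {
  n <- min(length(a) + length(b) - 1L, k + 1L)
  out <- numeric(n)
  for (i in seq_along(a)) {
    jmax <- min(length(b), n - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

#' Abundances relative to the monoisotopic peak
#'
#' Rescales an isotopologue pattern so the monoisotopic channel equals 1,
#' the form in which natural-abundance corrections are usually written.
#'
#' @param pattern An `isotope_pattern` from [natural_pattern()].
#' @return Numeric vector `r` with `r[1] = 1` and `r[j+1] = p[j+1] / p[1]`.
#' @examples
#' relative_to_monoisotopic(natural_pattern("C5H9+"))
#' @export
relative_to_monoisotopic <- function(pattern) {
  stopifnot(inherits(pattern, "isotope_pattern"))
  if (pattern$p[1] <= 0) stop("monoisotopic abundance must be positive",
                              call. = FALSE)
  pattern$p / pattern$p[1]
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("Natural isotopologue pattern of ",
      format(attr(x, "formula")), " (k = ", attr(x, "k"), ")\n", sep = "")
  NextMethod()
}

#' Plot an isotopologue pattern
#'
#' @param object An `isotope_pattern`.
#' @param ... Unused.
#' @return A ggplot: abundance per mass-shift channel.
#' @exportS3Method ggplot2::autoplot
autoplot.isotope_pattern <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$shift, y = .data$p)) +
    ggplot2::geom_col(width = 0.1, fill = "grey25") +
    ggplot2::labs(
      x = "mass shift (Da)", y = "relative abundance",
      title = paste0("Natural isotopologue pattern: ",
                     format(attr(object, "formula")))
    ) +
    ggplot2::theme_minimal()
}
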