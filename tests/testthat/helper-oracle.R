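# Independent brute-force oracle for natural isotopologue patterns:
# exhaustive enumeration of isotope assignments per element (multinomial
# compositions), combined across elements by explicit outer enumeration.
# Deliberately shares no code with the package's convolution routine.

# all compositions of n into m non-negative parts
compositions <- function(n, m) {
  if (m == 1L) return(matrix(n, 1L, 1L))
  out <- list()
  for (first in 0:n) {
    rest <- compositions(n - first, m - 1L)
    out[[length(out) + 1L]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

# shift distribution of n atoms of one element by multinomial enumeration
enum_element <- function(shifts, abundances, n) {
  m <- length(shifts)
  comps <- compositions(n, m)
  probs <- apply(comps, 1L, function(kvec) {
    exp(lgamma(n + 1) - sum(lgamma(kvec + 1))) * prod(abundances^kvec)
  })
  total_shift <- as.vector(comps %*% shifts)
  dist <- tapply(probs, total_shift, sum)
  out <- numeric(max(total_shift) + 1L)
  out[as.integer(names(dist)) + 1L] <- dist
  out
}

# full-molecule pattern by outer product over elements, then truncation
enum_pattern <- function(formula, k) {
  f <- cktrace::parse_formula(if (inherits(formula, "chem_formula"))
    format(formula) else formula)
  iso <- cktrace::isotope_table()
  dists <- list(1)
  for (el in names(f)) {
    if (el == "D") next
    rows <- iso[iso$element == el, ]
    shifts <- round(rows$isotope_mass) - round(rows$isotope_mass[1])
    dists[[length(dists) + 1L]] <-
      enum_element(shifts, rows$abundance, unclass(f)[[el]])
  }
  # combine by explicit enumeration over all shift combinations
  total <- dists[[1]]
  for (d in dists[-1]) {
    new_len <- length(total) + length(d) - 1L
    acc <- numeric(new_len)
    for (i in seq_along(total)) {
      for (j in seq_along(d)) {
        acc[i + j - 1L] <- acc[i + j - 1L] + total[i] * d[j]
      }
    }
    total <- acc
  }
  out <- numeric(k + 1L)
  keep <- seq_len(min(k + 1L, length(total)))
  out[keep] <- total[keep]
  out
}

# a small pool of registry analytes measurable by the MRM ladder
riboside_ids <- function() c("iPR", "tZR", "cZR", "DHZR")
all_ladder_ids <- function() {
  c(riboside_ids(), paste0("pro-", riboside_ids()))
}
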