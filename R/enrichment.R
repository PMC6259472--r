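#' Natural-abundance correction matrix
#'
#' Builds the lower-triangular matrix C that maps label-class fractions to
#' observed isotopomer channel intensities: column j is the natural
#' isotopologue pattern of the product-ion fragment, shifted down by j
#' (a molecule carrying j deuterium labels starts its natural pattern at
#' channel I_j). So `C[i, j] = p[i - j]` for `i >= j` and 0 above the
#' diagonal, with every column sharing the fragment's single raw pattern.
#' Solving `C x = I` removes the contribution of natural heavy isotopes
#' (13C, 2H, 15N, 17/18O) from the apparent labeling.
#'
#' The same pattern is reused for every column: the j hydrogens replaced by
#' labels in a j-label molecule change its residual natural pattern only at
#' order of the natural 2H abundance (about 1e-4 relative), which is
#' negligible at MRM precision.
#'
#' @param fragment Product-ion formula (string or `chem_formula`), e.g.
#'   `"C10H14N5+"` for the protonated isopentenyladenine fragment.
#' @param k Window size: channels I0..Ik (default 3).
#' @return A `(k+1) x (k+1)` lower-triangular numeric matrix.
#' @examples
#' correction_matrix("C10H14N5+")
#' @export
correction_matrix <- function(fragment, k = 3L) {
  if (k < 0) stop("window k must be >= 0", call. = FALSE)
  k <- as.integer(k)
  p <- natural_pattern(fragment, k = k)$p
  if (p[1] <= 0) stop("fragment has no monoisotopic abundance", call. = FALSE)
  C <- matrix(0, k + 1L, k + 1L)
  for (j in 0:k) C[(j:k) + 1L, j + 1L] <- p[seq_len(k - j + 1L)]
  dimnames(C) <- list(paste0("I", 0:k), paste0("x", 0:k))
  C
}

#' Deconvolve isotopomer peak areas into label-class fractions
#'
#' Recovers the amounts x_0..x_k of molecules carrying 0..k deuterium
#' labels from the measured MRM channel areas I_0..I_k, removing the
#' natural isotope distribution of the product-ion fragment. The default
#' estimator solves the non-negative least squares problem
#' `min ||C x - I||` subject to `x >= 0`; the `"subtraction"` estimator is
#' the classical ordered correction (forward substitution through the
#' triangular system, equivalent on noiseless data but allowed to go
#' negative under noise). Results are in the arbitrary units of the input
#' areas; only ratios of the x_j are meaningful.
#'
#' @param areas Numeric vector of peak areas, channels I0..Ik in order.
#' @param fragment Product-ion formula used for the correction.
#' @param estimator `"nnls"` (default) or `"subtraction"`.
#' @param k Window size; defaults to `length(areas) - 1`.
#' @return A list with `x` (fractions, length k+1), `residual`
#'   (`||C x - I||`), and `estimator`.
#' @examples
#' C <- correction_matrix("C10H14N5+")
#' deconvolve(as.vector(C %*% c(2, 1, 0, 0)), "C10H14N5+")
#' @export
deconvolve <- function(areas, fragment, estimator = c("nnls", "subtraction"),
                       k = length(areas) - 1L) {
  estimator <- match.arg(estimator)
  areas <- as.numeric(areas)
  if (length(areas) != k + 1L) {
    stop("expected ", k + 1L, " channel areas (I0..I", k, "), got ",
         length(areas), call. = FALSE)
  }
  if (any(!is.finite(areas)) || any(areas < 0)) {
    stop("peak areas must be finite and non-negative", call. = FALSE)
  }
  if (all(areas == 0)) stop("all channel areas are zero", call. = FALSE)
  C <- correction_matrix(fragment, k = k)
  # solve at unit scale (areas span many orders of magnitude; the active-set
  # solver is happier near 1) and restore the input units afterwards
  s <- sum(areas)
  x <- switch(estimator,
    nnls = pracma::lsqnonneg(C, areas / s)$x * s,
    subtraction = forwardsolve(C, areas)
  )
  list(x = stats::setNames(as.numeric(x), paste0("x", 0:k)),
       residual = sqrt(sum((C %*% x - areas)^2)),
       estimator = estimator)
}

#' Tracer:tracee ratio from label-class fractions
#'
#' The t/t ratio is the labeled-to-unlabeled molecular ratio after
#' natural-abundance correction: the summed tracer classes (1 to k labels)
#' over the tracee (unlabeled) class, `(x_1 + ... + x_k) / x_0`. Under
#' in vivo deuterium feeding this is the measure of relative biosynthetic
#' rate: newly made molecules pick up label, pre-existing ones do not.
#'
#' @param x Numeric vector of label-class fractions, x_0 first (e.g. the
#'   `x` component of [deconvolve()]).
#' @return The scalar t/t ratio (>= 0 for non-negative fractions).
#' @examples
#' tracer_tracee_ratio(c(2, 1, 0, 0))  # 0.5
#' @export
tracer_tracee_ratio <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) >= 2L)
  if (x[1] <= 0) {
    stop("tracee fraction x_0 is zero: labeling is saturated and no ",
         "finite t/t ratio exists", call. = FALSE)
  }
  sum(x[-1]) / x[1]
}

#' Replicate mean and standard deviation
#'
#' @param tt Numeric vector of per-replicate t/t values.
#' @return A tibble with `n`, `tt_mean` and `tt_sd` (sample SD, n-1
#'   denominator; `NA` for a single replicate).
#' @examples
#' replicate_stats(c(1.0, 2.0))
#' @export
replicate_stats <- function(tt) {
  tt <- as.numeric(tt)
  stopifnot(length(tt) >= 1L)
  tibble::tibble(n = length(tt), tt_mean = mean(tt),
                 tt_sd = if (length(tt) >= 2L) stats::sd(tt) else NA_real_)
}

#' Estimate tracer:tracee ratios from an isotopomer area table
#'
#' The main analysis entry point: takes a tidy table of MRM isotopomer peak
#' areas (one row per analyte and replicate, channels `I0`..`I3` in
#' columns), deconvolves each replicate against the analyte's product-ion
#' natural isotope pattern, computes the per-replicate t/t ratio, and
#' aggregates replicates to a mean and sample SD per analyte.
#'
#' @param data A data frame with columns `analyte`, `replicate`,
#'   `I0`..`I{k}`. Analyte ids are registry riboside ids, optionally
#'   `pro-`-prefixed for propionylated analytes (e.g. `"pro-iPR"`).
#' @param estimator Passed to [deconvolve()].
#' @param k Isotopomer window (default 3; the table must carry columns
#'   `I0`..`Ik`).
#' @return A `tt_fit` object. Use [tidy()] for per-analyte estimates,
#'   `tidy(fit, "replicates")` for per-replicate detail, [glance()] for a
#'   one-row fit summary, and [autoplot()] to plot estimates with error
#'   bars.
#' @examples
#' sim <- simulate_measurement(sim_config("pro-iPR", tt = 0.5,
#'                                        n_replicates = 3, seed = 1))
#' fit <- estimate_tt(sim)
#' tidy(fit)
#' @export
estimate_tt <- function(data, estimator = c("nnls", "subtraction"), k = 3L) {
  estimator <- match.arg(estimator)
  k <- as.integer(k)
  channels <- paste0("I", 0:k)
  missing_cols <- setdiff(c("analyte", "replicate", channels), names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)

  per_rep <- purrr::map_dfr(seq_len(nrow(data)), function(i) {
    row <- data[i, ]
    frag <- product_fragment_for(row$analyte)
    dec <- deconvolve(as.numeric(row[channels]), frag,
                      estimator = estimator, k = k)
    out <- tibble::tibble(analyte = row$analyte, replicate = row$replicate,
                          tt = tracer_tracee_ratio(dec$x),
                          residual = dec$residual)
    xs <- tibble::as_tibble(as.list(dec$x))
    dplyr::bind_cols(out, xs)
  })
  per_rep <- dplyr::arrange(per_rep, .data$analyte, .data$replicate)

  per_analyte <- per_rep |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(
      n = dplyr::n(),
      tt_mean = mean(.data$tt),
      tt_sd = ifelse(dplyr::n() >= 2L, stats::sd(.data$tt), NA_real_),
      residual = max(.data$residual),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$analyte)

  structure(
    list(estimates = per_analyte, replicates = per_rep,
         estimator = estimator, k = k),
    class = "tt_fit"
  )
}

# product-ion fragment used for natural-abundance correction of an analyte
product_fragment_for <- function(analyte) {
  tr <- diagnostic_transitions_one(analyte, derivatized = FALSE, j_max = 0L)
  tr$product_formula[1]
}

#' @export
print.tt_fit <- function(x, ...) {
  cat("Tracer:tracee ratio fit (", x$estimator, " estimator, I0..I",
      x$k, " window)\n\n", sep = "")
  print(x$estimates)
  invisible(x)
}

#' Tidy a t/t fit
#'
#' @param x A `tt_fit` from [estimate_tt()].
#' @param level `"analytes"` (default) for one row per analyte with mean
#'   and SD, or `"replicates"` for per-replicate t/t values and
#'   deconvolved fractions.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.tt_fit <- function(x, level = c("analytes", "replicates"), ...) {
  level <- match.arg(level)
  if (level == "analytes") x$estimates else x$replicates
}

#' Glance at a t/t fit
#'
#' @param x A `tt_fit` from [estimate_tt()].
#' @param ... Unused.
#' @return A one-row tibble: number of analytes, total replicates,
#'   estimator, window, worst residual.
#' @exportS3Method generics::glance
glance.tt_fit <- function(x, ...) {
  tibble::tibble(
    n_analytes = nrow(x$estimates),
    n_replicates = nrow(x$replicates),
    estimator = x$estimator,
    k = x$k,
    max_residual = max(x$replicates$residual)
  )
}

#' Plot t/t estimates
#'
#' @param object A `tt_fit` from [estimate_tt()].
#' @param ... Unused.
#' @return A ggplot: per-analyte mean t/t with +/- 1 SD error bars and the
#'   per-replicate values overlaid.
#' @exportS3Method ggplot2::autoplot
autoplot.tt_fit <- function(object, ...) {
  est <- object$estimates
  ggplot2::ggplot(est, ggplot2::aes(x = .data$analyte, y = .data$tt_mean)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$tt_mean - .data$tt_sd,
                   ymax = .data$tt_mean + .data$tt_sd),
      width = 0.15, na.rm = TRUE
    ) +
    ggplot2::geom_jitter(
      data = object$replicates,
      ggplot2::aes(x = .data$analyte, y = .data$tt),
      width = 0.05, alpha = 0.4, size = 1
    ) +
    ggplot2::labs(x = NULL, y = "tracer:tracee ratio (t/t)",
                  title = "Deuterium enrichment after natural-abundance correction") +
    ggplot2::theme_minimal()
}
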