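#' Read an isotopomer peak-area CSV
#'
#' Reads and validates a peak-area table: columns `analyte`, `replicate`,
#' `I0`..`I{k}`, one row per analyte and replicate. Validation is
#' collective - every offending row is reported with its line number in a
#' single error, not just the first - because instrument exports tend to
#' fail in batches.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param k Isotopomer window expected (default 3).
#' @return A tibble with columns `analyte`, `replicate` and the channel
#'   columns, validated against the compound registry.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' sim <- simulate_measurement(sim_config("pro-iPR", tt = 0.5,
#'                                        n_replicates = 2, seed = 1))
#' write_area_csv(sim, f)
#' read_area_csv(f)
#' @export
read_area_csv <- function(path, k = 3L) {
  channels <- paste0("I", 0:k)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("analyte", "replicate", channels), names(tbl))
  if (length(missing_cols) > 0) {
    stop("'", path, "': missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl <- tbl[c("analyte", "replicate", channels)]
  line <- seq_len(nrow(tbl)) + 1L  # header is line 1

  problems <- character()
  for (ch in channels) {
    v <- tbl[[ch]]
    bad <- which(!is.numeric(v) | !is.finite(v) | v < 0)
    if (length(bad) > 0) {
      problems <- c(problems, paste0(
        "line ", line[bad], ": ", ch, " is not a non-negative number (",
        v[bad], ")"))
    }
  }
  known <- vapply(tbl$analyte, function(a) {
    tryCatch({ resolve_analyte(a); TRUE }, error = function(e) FALSE)
  }, logical(1))
  if (any(!known)) {
    problems <- c(problems, paste0("line ", line[!known],
                                   ": unknown analyte '",
                                   tbl$analyte[!known], "'"))
  }
  dup <- duplicated(tbl[c("analyte", "replicate")])
  if (any(dup)) {
    problems <- c(problems, paste0("line ", line[dup],
                                   ": duplicate (analyte, replicate) pair '",
                                   tbl$analyte[dup], "', '",
                                   tbl$replicate[dup], "'"))
  }
  if (length(problems) > 0) {
    stop("'", path, "' failed validation:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  tbl
}

#' @rdname read_area_csv
#' @param data A peak-area table (as from [simulate_measurement()]).
#' @export
write_area_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Batch t/t estimation over a peak-area table
#'
#' Runs the enrichment pipeline analyte by analyte over a validated area
#' table. Failures are per-analyte: a compound that cannot be processed is
#' reported in the log and skipped while the rest of the batch continues.
#' Output order is sorted by analyte, so results do not depend on input
#' row order. The log records, per analyte, the product-ion fragment, the
#' condition number of its correction matrix, and the worst deconvolution
#' residual.
#'
#' @param data A table from [read_area_csv()] or [simulate_measurement()].
#' @param estimator,k Passed to [estimate_tt()].
#' @return A tibble with one row per successfully processed analyte
#'   (`analyte`, `n`, `tt_mean`, `tt_sd`, `residual`), with the processing
#'   log as a character vector in attribute `"log"` (also retrievable with
#'   [batch_log()]).
#' @examples
#' sim <- simulate_measurement(sim_config("pro-iPR", tt = 0.5,
#'                                        n_replicates = 3, seed = 1))
#' res <- run_batch(sim)
#' batch_log(res)
#' @export
run_batch <- function(data, estimator = c("nnls", "subtraction"), k = 3L) {
  estimator <- match.arg(estimator)
  data <- tibble::as_tibble(data)
  log <- character()
  if (nrow(data) == 0L) {
    warning("empty area table: no analytes to process", call. = FALSE)
    log <- c(log, "WARN empty input table")
    out <- tibble::tibble(analyte = character(), n = integer(),
                          tt_mean = double(), tt_sd = double(),
                          residual = double())
    return(structure(out, log = log))
  }
  results <- list()
  for (a in sort(unique(data$analyte))) {
    chunk <- data[data$analyte == a, ]
    res <- tryCatch({
      frag <- product_fragment_for(a)
      C <- correction_matrix(frag, k = k)
      fit <- estimate_tt(chunk, estimator = estimator, k = k)
      list(estimates = fit$estimates, msg = sprintf(
        "INFO %s: fragment %s, kappa(C) = %.4f, n = %d, max residual = %.3g",
        a, frag, kappa(C, exact = TRUE), nrow(chunk),
        max(fit$replicates$residual)))
    }, error = function(e) {
      list(estimates = NULL,
           msg = sprintf("ERROR %s: %s (skipped)", a, conditionMessage(e)))
    })
    log <- c(log, res$msg)
    results[[a]] <- res$estimates
  }
  out <- dplyr::bind_rows(results)
  structure(out, log = log)
}

#' @rdname run_batch
#' @param results A result table from [run_batch()].
#' @export
batch_log <- function(results) {
  attr(results, "log")
}

#' Plot a labeling time course
#'
#' Estimates t/t at every time point of a simulated or measured time
#' course and plots enrichment against incubation time, one line per
#' analyte.
#'
#' @param data A table with a `time` column plus the area columns (as from
#'   [simulate_timecourse()]).
#' @param estimator,k Passed to [estimate_tt()].
#' @return A ggplot of mean t/t (+/- 1 SD) versus time.
#' @export
plot_timecourse <- function(data, estimator = "nnls", k = 3L) {
  est <- data |>
    dplyr::group_by(.data$time) |>
    dplyr::group_modify(~ tidy(estimate_tt(.x, estimator = estimator,
                                           k = k))) |>
    dplyr::ungroup()
  ggplot2::ggplot(est, ggplot2::aes(x = .data$time, y = .data$tt_mean,
                                    colour = .data$analyte)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$tt_mean - .data$tt_sd,
                   ymax = .data$tt_mean + .data$tt_sd),
      na.rm = TRUE
    ) +
    ggplot2::labs(x = "incubation time (h)",
                  y = "tracer:tracee ratio (t/t)", colour = NULL) +
    ggplot2::theme_minimal()
}
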