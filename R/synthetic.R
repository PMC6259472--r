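#' Configure an isotopomer measurement simulation
#'
#' Defines the ground truth and noise model for simulated MRM isotopomer
#' measurements. Ground truth is given either as a scalar t/t ratio (split
#' entirely into the single-label class x_1 by default - the dominant class
#' for short incubations in 30% D2O within a 4-channel window - with an
#' optional `tracer_split` to spread it over x_1..x_k) or as an explicit
#' fraction vector `fractions = c(x0, x1, ..., xk)`. Channel intensities
#' are C x scaled to `total_signal` counts in I0..Ik, perturbed per the
#' noise model. A seed is mandatory: simulations are bit-reproducible by
#' construction.
#'
#' @param analyte Registry riboside id, optionally `pro-`-prefixed.
#' @param tt True tracer:tracee ratio (ignored if `fractions` given).
#' @param fractions Optional explicit non-negative label-class fractions
#'   x_0..x_k.
#' @param tracer_split Weights splitting the tracer mass over classes
#'   1..k when `tt` is used (default all in x_1).
#' @param total_signal Total counts across the monitored channels.
#' @param noise `"none"`, `"gaussian"` (multiplicative, relative SD = `cv`),
#'   `"poisson"` (counting noise), or `"both"`.
#' @param cv Coefficient of variation for Gaussian noise.
#' @param n_replicates Number of replicate measurements.
#' @param k Isotopomer window (default 3).
#' @param seed Integer random seed (required).
#' @return A `sim_config` list.
#' @examples
#' sim_config("pro-iPR", tt = 1.68, cv = 0.01, n_replicates = 5, seed = 7)
#' @export
sim_config <- function(analyte, tt = NULL, fractions = NULL,
                       tracer_split = NULL, total_signal = 1e6,
                       noise = c("none", "gaussian", "poisson", "both"),
                       cv = 0, n_replicates = 1L, k = 3L, seed) {
  noise <- match.arg(noise)
  if (missing(seed)) stop("a seed is required: simulations must be ",
                          "reproducible", call. = FALSE)
  k <- as.integer(k)
  resolve_analyte(analyte)  # fail early on unknown ids
  if (is.null(fractions)) {
    if (is.null(tt)) stop("give either 'tt' or 'fractions'", call. = FALSE)
    stopifnot(tt >= 0)
    if (is.null(tracer_split)) tracer_split <- c(1, rep(0, k - 1L))
    stopifnot(length(tracer_split) == k, all(tracer_split >= 0),
              sum(tracer_split) > 0)
    fractions <- c(1, tt * tracer_split / sum(tracer_split))
  }
  stopifnot(length(fractions) == k + 1L, all(fractions >= 0),
            sum(fractions) > 0, total_signal > 0, n_replicates >= 1L,
            cv >= 0)
  structure(
    list(analyte = analyte, fractions = as.numeric(fractions),
         total_signal = total_signal, noise = noise, cv = cv,
         n_replicates = as.integer(n_replicates), k = k,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate MRM isotopomer measurements
#'
#' Generates replicate isotopomer channel areas with known ground truth:
#' the noiseless signal is `C x` (correction matrix of the analyte's
#' product-ion fragment times the true label-class fractions), scaled so
#' the channel sum equals `total_signal`, then perturbed per the
#' configured noise model. Feeding the result to [estimate_tt()] at zero
#' noise recovers the configured fractions exactly, which is the
#' round-trip identity the enrichment pipeline is tested against.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `analyte`, `replicate`, `I0`..`Ik` -
#'   the same layout [estimate_tt()] and [read_area_csv()] use.
#' @examples
#' simulate_measurement(sim_config("pro-iPR", tt = 0.5,
#'                                 n_replicates = 2, seed = 1))
#' @export
simulate_measurement <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  frag <- product_fragment_for(cfg$analyte)
  C <- correction_matrix(frag, k = cfg$k)
  signal <- as.vector(C %*% cfg$fractions)
  signal <- signal / sum(signal) * cfg$total_signal

  withr_seed(cfg$seed, {
    rows <- purrr::map_dfr(seq_len(cfg$n_replicates), function(r) {
      I <- signal
      if (cfg$noise %in% c("poisson", "both")) I <- stats::rpois(length(I), I)
      if (cfg$noise %in% c("gaussian", "both")) {
        I <- I * (1 + stats::rnorm(length(I), 0, cfg$cv))
      }
      I <- pmax(I, 0)
      out <- tibble::tibble(analyte = cfg$analyte, replicate = r)
      out[paste0("I", 0:cfg$k)] <- as.list(I)
      out
    })
    rows
  })
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a labeling time course
#'
#' Simulates replicate isotopomer measurements at a series of incubation
#' times with per-analyte true t/t setpoints, emulating the rising
#' enrichment of newly synthesized cytokinins during deuterium feeding.
#' Each (time, analyte) cell is one [simulate_measurement()] run; a single
#' setpoint row reduces to a plain single-condition simulation.
#'
#' @param setpoints A data frame with columns `time`, `analyte`, `tt`
#'   (true ratio at that time).
#' @param total_signal,noise,cv,n_replicates,k As in [sim_config()].
#' @param seed Integer seed; each cell derives its own sub-seed from it.
#' @return A tibble: `time`, `analyte`, `replicate`, `I0`..`Ik`.
#' @examples
#' sp <- tibble::tibble(time = c(2, 4), analyte = "pro-iPR", tt = c(0.3, 0.9))
#' simulate_timecourse(sp, n_replicates = 2, seed = 1)
#' @export
simulate_timecourse <- function(setpoints, total_signal = 1e6,
                                noise = "gaussian", cv = 0.05,
                                n_replicates = 3L, k = 3L, seed) {
  stopifnot(all(c("time", "analyte", "tt") %in% names(setpoints)),
            all(setpoints$tt >= 0))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  setpoints <- tibble::as_tibble(setpoints)
  purrr::map_dfr(seq_len(nrow(setpoints)), function(i) {
    row <- setpoints[i, ]
    cfg <- sim_config(row$analyte, tt = row$tt, total_signal = total_signal,
                      noise = noise, cv = cv, n_replicates = n_replicates,
                      k = k, seed = (seed + 1009L * i) %% .Machine$integer.max)
    dplyr::bind_cols(tibble::tibble(time = row$time),
                     simulate_measurement(cfg))
  })
}
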