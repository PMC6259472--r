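test_that("configuration validates its inputs and requires a seed", {
  expect_error(sim_config("pro-iPR", tt = 1), "seed")
  expect_error(sim_config("pro-iPR", seed = 1), "tt.*fractions")
  expect_error(sim_config("nope", tt = 1, seed = 1), "unknown analyte")
  expect_error(sim_config("pro-iPR", fractions = c(1, -1, 0, 0), seed = 1))
  cfg <- sim_config("pro-iPR", tt = 0.5, seed = 1)
  expect_equal(cfg$fractions, c(1, 0.5, 0, 0))
  cfg2 <- sim_config("pro-iPR", tt = 0.6, tracer_split = c(1, 1, 1), seed = 1)
  expect_equal(cfg2$fractions, c(1, 0.2, 0.2, 0.2))
})

test_that("noiseless simulation reproduces the scaled natural pattern", {
  cfg <- sim_config("pro-iPR", fractions = c(1, 0, 0, 0), seed = 3)
  sim <- simulate_measurement(cfg)
  I <- as.numeric(sim[1, paste0("I", 0:3)])
  p <- natural_pattern("C10H14N5+", k = 3)$p
  expect_equal(I / sum(I), p / sum(p), tolerance = 1e-12)
  expect_equal(sum(I), 1e6)
})

test_that("simulate then deconvolve is the identity at zero noise", {
  set.seed(42)
  for (id in all_ladder_ids()) {
    x <- c(1, stats::runif(3, 0, 1.5))
    cfg <- sim_config(id, fractions = x, seed = 9)
    sim <- simulate_measurement(cfg)
    est <- tidy(estimate_tt(sim))
    expect_equal(est$tt_mean, sum(x[-1]) / x[1], tolerance = 1e-9)
    # subtraction estimator agrees on noiseless data
    est2 <- tidy(estimate_tt(sim, estimator = "subtraction"))
    expect_equal(est2$tt_mean, est$tt_mean, tolerance = 1e-9)
  }
})

test_that("simulations are bit-reproducible under a fixed seed", {
  cfg <- sim_config("iPR", tt = 1.3, noise = "both", cv = 0.05,
                    n_replicates = 4, seed = 123)
  expect_identical(simulate_measurement(cfg), simulate_measurement(cfg))
  cfg2 <- sim_config("iPR", tt = 1.3, noise = "both", cv = 0.05,
                     n_replicates = 4, seed = 124)
  expect_false(identical(simulate_measurement(cfg),
                         simulate_measurement(cfg2)))
  # the simulator leaves the caller's RNG stream untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(simulate_measurement(cfg)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("moderate-noise recovery lands near the configured setpoint", {
  cfg <- sim_config("iPR", tt = 1.30, noise = "gaussian", cv = 0.10,
                    n_replicates = 5, seed = 2026)
  est <- tidy(estimate_tt(simulate_measurement(cfg)))
  expect_lt(abs(est$tt_mean - 1.30) / 1.30, 0.10)
})

test_that("Poisson counting noise has variance close to the mean", {
  cfg <- sim_config("pro-iPR", fractions = c(1, 0.5, 0, 0),
                    total_signal = 1e5, noise = "poisson",
                    n_replicates = 1000, seed = 55)
  sim <- simulate_measurement(cfg)
  for (ch in paste0("I", 0:2)) {
    v <- sim[[ch]]
    ratio <- stats::var(v) / mean(v)
    n <- length(v)
    # chi-square band for a variance ratio at ~1000 draws
    expect_gt(ratio, stats::qchisq(0.0005, n - 1) / (n - 1))
    expect_lt(ratio, stats::qchisq(0.9995, n - 1) / (n - 1))
  }
})

test_that("a single-row timecourse degenerates to one simulation", {
  sp <- tibble::tibble(time = 6, analyte = "pro-iPR", tt = 1.68)
  tc <- simulate_timecourse(sp, noise = "none", cv = 0, n_replicates = 2,
                            seed = 8)
  expect_identical(nrow(tc), 2L)
  expect_identical(unique(tc$time), 6)
  est <- tidy(estimate_tt(dplyr::select(tc, -"time")))
  expect_equal(est$tt_mean, 1.68, tolerance = 1e-9)
})

test_that("monotone setpoints give a monotone estimated series up to noise", {
  sp <- tidyr::expand_grid(time = c(1, 2, 4, 8, 16, 24),
                           analyte = c("pro-iPR", "pro-tZR"))
  # rising enrichment, iP-type consistently above tZ-type
  sp$tt <- ifelse(sp$analyte == "pro-iPR", 0.08, 0.04) * sp$time
  tc <- simulate_timecourse(sp, noise = "gaussian", cv = 0.05,
                            n_replicates = 3, seed = 31)
  est <- tc |>
    dplyr::group_by(.data$time, .data$analyte) |>
    dplyr::group_modify(~ dplyr::select(
      tidy(estimate_tt(dplyr::mutate(.x, analyte = .y$analyte))),
      -"analyte")) |>
    dplyr::ungroup()
  for (a in unique(est$analyte)) {
    series <- est[est$analyte == a, ]
    series <- series[order(series$time), ]
    expect_gt(stats::cor(series$time, series$tt_mean,
                         method = "spearman"), 0.9)
  }
})

test_that("zero setpoints estimate to zero within solver noise", {
  sp <- tibble::tibble(time = c(1, 2, 3), analyte = "iPR", tt = 0)
  tc <- simulate_timecourse(sp, noise = "gaussian", cv = 0.01,
                            n_replicates = 5, seed = 17)
  est <- tc |>
    dplyr::group_by(.data$time) |>
    dplyr::group_modify(~ tidy(estimate_tt(.x))) |>
    dplyr::ungroup()
  # NNLS folds negative excursions to zero, so estimates sit at or just
  # above zero: within ~3 SD of the replicate scatter
  expect_true(all(est$tt_mean <= pmax(3 * est$tt_sd, 0.05)))
})
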