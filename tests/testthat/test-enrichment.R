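IP_FRAG <- "C10H14N5+"   # protonated isopentenyladenine product ion
ZR_FRAG <- "C13H18N5O2+" # pro-zeatin base fragment with its side-chain propionyl

test_that("correction matrix is the shifted natural pattern, lower triangular", {
  expect_identical(unname(correction_matrix(IP_FRAG, k = 0)),
                   matrix(natural_pattern(IP_FRAG, 0)$p, 1, 1))
  # monoisotopic elements give a delta pattern, hence the identity matrix
  expect_equal(unname(correction_matrix("P", k = 3)), diag(4))
  expect_equal(unname(correction_matrix("D6", k = 2)), diag(3))

  C <- correction_matrix(IP_FRAG, k = 3)
  expect_true(all(C[upper.tri(C)] == 0))
  p_enum <- enum_pattern(IP_FRAG, k = 3)
  for (j in 0:3) {
    expect_equal(unname(C[(j:3) + 1, j + 1]), p_enum[seq_len(4 - j)],
                 tolerance = 1e-10)
  }
  expect_error(correction_matrix(IP_FRAG, k = -1), "window")
})

test_that("noiseless deconvolution is the identity, for both estimators", {
  C <- correction_matrix(IP_FRAG, k = 3)
  for (x in list(c(1, 0, 0, 0), c(2, 1, 0, 0), c(5, 2, 1, 0.5))) {
    I <- as.vector(C %*% x)
    for (est in c("nnls", "subtraction")) {
      dec <- deconvolve(I, IP_FRAG, estimator = est)
      expect_equal(unname(dec$x), x, tolerance = 1e-9)
      expect_lt(dec$residual, 1e-9)
    }
  }
  expect_equal(tracer_tracee_ratio(
    deconvolve(as.vector(C %*% c(2, 1, 0, 0)), IP_FRAG)$x), 0.5,
    tolerance = 1e-9)
})

test_that("deconvolution rejects degenerate measurements", {
  expect_error(deconvolve(c(0, 0, 0, 0), IP_FRAG), "zero")
  expect_error(deconvolve(c(1, -1, 0, 0), IP_FRAG), "non-negative")
  expect_error(deconvolve(c(1, 2, 3), IP_FRAG, k = 3), "expected 4")
})

test_that("noisy deconvolution recovers fractions within a few percent", {
  C <- correction_matrix(IP_FRAG, k = 3)
  set.seed(101)
  rel_err <- replicate(1000, {
    x <- c(stats::runif(1, 0.5, 2), stats::runif(3, 0, 1))
    I <- as.vector(C %*% x)
    I <- pmax(I * (1 + stats::rnorm(4, 0, 0.01)), 0)
    xhat <- deconvolve(I, IP_FRAG)$x
    sqrt(sum((xhat - x)^2)) / sqrt(sum(x^2))
  })
  expect_lt(stats::median(rel_err), 0.03)
})

test_that("tracer:tracee ratio arithmetic and saturation guard", {
  expect_identical(tracer_tracee_ratio(c(1, 0, 0, 0)), 0)
  expect_identical(tracer_tracee_ratio(c(2, 1, 0, 0)), 0.5)
  expect_error(tracer_tracee_ratio(c(0, 1, 0, 0)), "saturated")
})

test_that("replicate statistics use the sample (n-1) standard deviation", {
  expect_equal(replicate_stats(c(1, 1, 1)),
               tibble::tibble(n = 3L, tt_mean = 1, tt_sd = 0))
  rs <- replicate_stats(c(1, 2))
  expect_equal(rs$tt_mean, 1.5)
  expect_equal(rs$tt_sd, sqrt(0.5), tolerance = 1e-12)
  expect_true(is.na(replicate_stats(5)$tt_sd))
})

test_that("replicate SD scales with the injected noise level", {
  # 5 replicates at CV 10%: SD/mean should be of the noise's order
  sim <- simulate_measurement(sim_config(
    "pro-iPR", tt = 1.0, noise = "gaussian", cv = 0.10,
    n_replicates = 20, seed = 77
  ))
  est <- tidy(estimate_tt(sim))
  cv_hat <- est$tt_sd / est$tt_mean
  expect_gt(cv_hat, 0.10 / 2.5)
  expect_lt(cv_hat, 0.10 * 2.5)
})

test_that("t/t is invariant to overall signal scale", {
  C <- correction_matrix(ZR_FRAG, k = 3)
  set.seed(5)
  for (i in 1:50) {
    I <- as.vector(C %*% c(stats::runif(1, 0.5, 2), stats::runif(3)))
    tt1 <- tracer_tracee_ratio(deconvolve(I, ZR_FRAG)$x)
    s <- stats::runif(1, 1e-3, 1e5)
    tt2 <- tracer_tracee_ratio(deconvolve(I * s, ZR_FRAG)$x)
    expect_equal(tt2, tt1, tolerance = 1e-9)
  }
})

test_that("feeding the natural pattern itself gives zero enrichment", {
  for (id in all_ladder_ids()) {
    tr <- diagnostic_transitions(id, j_max = 0)
    frag <- tr$product_formula[1]
    I <- natural_pattern(frag, k = 3)$p * 1e6
    tt <- tracer_tracee_ratio(deconvolve(I, frag)$x)
    expect_lt(abs(tt), 1e-9)
  }
})

test_that("adding signal to labeled channels never decreases t/t", {
  # measurements reachable from non-negative label classes; an extra mass
  # increment on a labeled channel must not lower the estimate
  C <- correction_matrix(IP_FRAG, k = 3)
  set.seed(31)
  for (i in 1:100) {
    x <- c(stats::runif(1, 0.5, 2), stats::runif(3, 0, 1))
    if (i %% 2 == 0) x[sample(2:4, 2)] <- 0
    I <- as.vector(C %*% x) * 1e5
    tt0 <- tracer_tracee_ratio(deconvolve(I, IP_FRAG)$x)
    j <- sample(2:4, 1)
    I2 <- I
    I2[j] <- I2[j] + stats::runif(1, 0, 1e5)
    tt1 <- tracer_tracee_ratio(deconvolve(I2, IP_FRAG)$x)
    expect_gte(tt1, tt0 - 1e-9)
  }
})

test_that("widening the window beyond the label span leaves t/t unchanged", {
  x <- c(2, 0.8, 0.3, 0.1)
  for (k in 4:6) {
    Ck <- correction_matrix(IP_FRAG, k = k)
    Ik <- as.vector(Ck %*% c(x, rep(0, k - 3)))
    ttk <- tracer_tracee_ratio(deconvolve(Ik, IP_FRAG, k = k)$x)
    expect_equal(ttk, tracer_tracee_ratio(x), tolerance = 1e-9)
  }
})

test_that("estimate_tt aggregates per replicate and exposes tidiers", {
  sim <- dplyr::bind_rows(
    simulate_measurement(sim_config("pro-iPR", tt = 0.8,
                                    n_replicates = 3, seed = 1)),
    simulate_measurement(sim_config("pro-tZR", tt = 0.2,
                                    n_replicates = 3, seed = 2))
  )
  fit <- estimate_tt(sim)
  est <- tidy(fit)
  expect_identical(est$analyte, c("pro-iPR", "pro-tZR"))
  expect_identical(est$n, c(3L, 3L))
  expect_equal(est$tt_mean, c(0.8, 0.2), tolerance = 1e-9)
  reps <- tidy(fit, "replicates")
  expect_identical(nrow(reps), 6L)
  expect_true(all(c("tt", "residual", "x0", "x3") %in% names(reps)))
  g <- glance(fit)
  expect_identical(g$n_analytes, 2L)
  expect_identical(g$estimator, "nnls")
  expect_error(estimate_tt(sim[, -3]), "I0")
  expect_s3_class(autoplot(fit), "ggplot")
})
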