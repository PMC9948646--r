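test_that("LUV diameters match the requested mean and polydispersity", {
  pop <- simulate_luv_population(1e4, d_mean = 130, pdi = 0.09, seed = 3)
  expect_equal(mean(pop$diameters), 130, tolerance = 0.02)
  expect_equal(compute_pdi(pop), 0.09, tolerance = 0.01 / 0.09)  # +/- 0.01
  expect_true(all(pop$diameters > 0))

  # degenerate population
  pop0 <- simulate_luv_population(100, pdi = 0, seed = 3)
  expect_true(all(pop0$diameters == 130))
  expect_error(simulate_luv_population(100, pdi = -0.1), "pdi")
})

test_that("channel counts scale linearly with the dimer fraction", {
  p1 <- simulate_luv_population(5e3, dimer_fraction = 0.15, seed = 5)
  p2 <- simulate_luv_population(5e3, dimer_fraction = 0.30, seed = 5)
  expect_equal(p2$lambda, 2 * p1$lambda, tolerance = 1e-12)
  expect_equal(mean(p2$channel_counts) / mean(p1$channel_counts), 2,
               tolerance = 0.05)
})

test_that("zero-channel vesicles exist and feed the unquenchable signal", {
  pop <- simulate_luv_population(5e3, dimer_fraction = 0.02, seed = 5)
  expect_gt(sum(pop$channel_counts == 0), 0)
  tr <- simulate_quench_trace(pop, noise_sd = 0, seed = 1)
  # unquenchable floor: trace never drops to the fully-quenched level
  full_quench <- attr(tr, "true_f0q") / 2.5
  expect_gt(min(tr$signal), full_quench)
})

test_that("identical seeds give identical populations, traces, and libraries", {
  expect_identical(simulate_luv_population(500, seed = 9),
                   simulate_luv_population(500, seed = 9))
  pop <- simulate_luv_population(500, seed = 9)
  expect_identical(simulate_quench_trace(pop, seed = 4),
                   simulate_quench_trace(pop, seed = 4))
  expect_identical(simulate_drug_library(100, seed = 2),
                   simulate_drug_library(100, seed = 2))
})

test_that("a drug-free trace is statistically identical to control", {
  pop <- simulate_luv_population(1000, seed = 2)
  a <- simulate_quench_trace(pop, drug_normrate = 1, seed = 6)
  b <- simulate_quench_trace(pop, seed = 6)
  expect_identical(a, b)
})

test_that("homogeneous populations give beta ~ 1, dispersed ones beta < 1", {
  pop0 <- simulate_luv_population(3000, pdi = 0, seed = 2)
  tr0 <- simulate_quench_trace(pop0, noise_sd = 0,
                               channel_dispersion = "fixed", seed = 7)
  f0 <- fit_trace(tr0)
  expect_gte(f0$params$beta, 0.999)

  popd <- simulate_luv_population(3000, pdi = 0.09, seed = 2)
  trd <- simulate_quench_trace(popd, noise_sd = 0, seed = 7)
  fd <- fit_trace(trd)
  expect_lt(fd$params$beta, 0.95)

  # mixture-of-exponentials oracle: on the dispersed trace the stretched
  # model must beat the best single-exponential (beta fixed at 1) fit
  tt <- trd$time
  sse_stretched <- sum((trd$signal - predict_fluorescence(tt, fd$params))^2)
  single_sse <- function(th) {
    p <- quench_params(tau0 = exp(th[1]), beta = 1, f0q = exp(th[2]),
                       finfq = exp(th[3]))
    sum((trd$signal - predict_fluorescence(tt, p))^2)
  }
  best1 <- optim(log(c(fd$params$tau0 * fd$params$beta, fd$params$f0q,
                       fd$params$finfq)), single_sse)
  expect_lt(sse_stretched, 0.5 * best1$value)
})

test_that("fitted initial rates track the generator's analytic influx rate", {
  pop <- simulate_luv_population(3000, seed = 2)
  errs <- vapply(1:12, function(s) {
    nr <- c(1, 2, 5)[(s %% 3) + 1]
    tr <- simulate_quench_trace(pop, drug_normrate = nr, seed = 200 + s)
    f <- fit_trace(tr)
    abs(f$rate0 - attr(tr, "true_rate0")) / attr(tr, "true_rate0")
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("drug libraries have the configured size, composition, and missingness", {
  lib <- simulate_drug_library(400, seed = 11)
  expect_equal(nrow(lib), 400)
  expect_equal(sum(!is.na(lib$cc20)), 397)
  expect_true(all(lib$cc20 > 0 & lib$cc20 <= 80, na.rm = TRUE))
  expect_true(all(lib$true_normrate > 0))
  expect_true(all(lib$qed >= 0 & lib$qed <= 1))
  # potency composition near the screened library's 50/18/32 split
  cat3 <- table(categorize_normrate(lib$true_normrate)) / 400
  expect_equal(unname(cat3[["low"]]), 0.50, tolerance = 0.15)
  expect_equal(unname(cat3[["high"]]), 0.32, tolerance = 0.25)
})

test_that("zero coupling decouples cytotoxicity from potency", {
  lib <- simulate_drug_library(400, coupling_slope = 0, coupling_intercept = 0.9,
                               missing_cc20 = 0, seed = 13)
  b <- bin_drugs(lib, axis = "normrate")
  tab <- table(b$bin, b$cc20 < 50)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
})

test_that("planted potency-cytotoxicity coupling is recovered by brute-force counting", {
  lib <- simulate_drug_library(400, seed = 17)
  hi <- lib$normrate >= 1.5
  lo <- lib$normrate < 1.25
  tox <- lib$cc20 < 50
  a <- sum(hi & tox, na.rm = TRUE); b <- sum(hi & !tox, na.rm = TRUE)
  c_ <- sum(lo & tox, na.rm = TRUE); d <- sum(lo & !tox, na.rm = TRUE)
  or <- odds_ratio(contingency_table(a, b, c_, d))
  expect_equal(or$oratio, (a * d) / (b * c_))
  expect_gt(or$oratio, 1)
})
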