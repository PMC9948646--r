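test_that("intravesicular Tl+ follows the stretched-exponential influx law", {
  p <- quench_params(tau0 = 0.5, beta = 1, f0q = 1, finfq = 0.4)
  expect_identical(tl_internal(0, p), 0)
  # beta = 1 reduces to single-exponential filling 1 - exp(-t/tau0)
  expect_equal(tl_internal(0.5, p), 0.025 * (1 - exp(-1)), tolerance = 1e-12)

  p2 <- quench_params(tau0 = 0.1, beta = 0.5, f0q = 1, finfq = 0.4)
  expect_equal(tl_internal(0.1, p2), 0.025 * (1 - exp(1 - sqrt(2))),
               tolerance = 1e-12)

  # monotone non-decreasing, saturating at tl_ext
  tt <- seq(0, 50, length.out = 2000)
  v <- tl_internal(tt, p2)
  expect_true(all(diff(v) >= 0))
  expect_equal(v[length(v)], 0.025, tolerance = 1e-6)
  expect_error(tl_internal(-0.1, p), "negative")
})

test_that("model fluorescence interpolates the plateaus and never increases", {
  for (b in c(0.55, 0.8, 1)) {
    p <- quench_params(tau0 = 0.3, beta = b, f0q = 0.9, finfq = 0.4)
    expect_equal(predict_fluorescence(0, p), 0.9, tolerance = 1e-12)
    expect_equal(predict_fluorescence(1e6, p), 0.4, tolerance = 1e-9)
    y <- predict_fluorescence(seq(0, 2, length.out = 1000), p)
    expect_true(all(diff(y) <= 1e-12))
  }
  # beta = 1 equals the closed-form single-exponential model
  p1 <- quench_params(tau0 = 0.3, beta = 1, f0q = 0.9, finfq = 0.4)
  tt <- seq(0, 1, length.out = 500)
  k <- 1.5
  tli <- 0.025 * (1 - exp(-tt / 0.3))
  single <- (0.4 * (1 + k) - 0.9) / k + (1 + k) / k * (0.9 - 0.4) / (1 + 60 * tli)
  expect_equal(predict_fluorescence(tt, p1), single, tolerance = 1e-12)
})

test_that("standard Tl+ conditions give the printed 2.5/1.5 prefactors", {
  p <- quench_params(tau0 = 0.3, beta = 0.8, f0q = 0.9, finfq = 0.4,
                     ksv = 60, tl_ext = 0.025)
  k <- p$ksv * p$tl_ext
  expect_equal(k, 1.5)
  expect_equal(1 + k, 2.5)
  # the model written with the printed coefficients matches
  tt <- c(0.002, 0.05, 0.3, 1)
  g <- 1 - exp(1 - (1 + tt / 0.3)^0.8)
  printed <- (2.5 * 0.4 - 0.9) / 1.5 + 2.5 / 1.5 * (0.9 - 0.4) / (1 + 1.5 * g)
  expect_equal(predict_fluorescence(tt, p), printed, tolerance = 1e-12)
})

test_that("initial rate is (1 + Ksv[Tl+]e) beta / tau0 and matches the slope", {
  expect_equal(initial_rate(quench_params(tau0 = 2.5, beta = 1,
                                          f0q = 1, finfq = 0.4)), 1)
  # inversion of the printed high-potency drug rate
  expect_equal(initial_rate(quench_params(tau0 = 2.5 / 34.6, beta = 1,
                                          f0q = 1, finfq = 0.4)),
               34.6, tolerance = 1e-12)
  # linear in beta at fixed tau0
  rates <- vapply(seq(0.2, 1, by = 0.1), function(b) {
    initial_rate(quench_params(tau0 = 0.4, beta = b, f0q = 1, finfq = 0.4))
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_equal(diff(rates), rep(diff(rates)[1], length(rates) - 1),
               tolerance = 1e-12)

  # agrees with the two-point numerical derivative of the normalized model
  set.seed(11)
  for (i in 1:20) {
    p <- quench_params(tau0 = runif(1, 0.05, 1), beta = runif(1, 0.3, 1),
                       f0q = runif(1, 0.6, 1), finfq = runif(1, 0.1, 0.5))
    h <- 1e-8
    num <- (predict_fluorescence(0, p) - predict_fluorescence(h, p)) / h /
      (p$f0q - p$finfq)
    expect_equal(initial_rate(p), num, tolerance = 1e-6)
  }
  expect_error(quench_params(tau0 = 0, beta = 1, f0q = 1, finfq = 0.4), "tau0")
})

test_that("compartment decomposition reproduces the worked observable cases", {
  # no extravesicular dye when buffer and quencher mixes start equal
  cs <- decompose_compartments(1.0, 1.0, 0.4)
  expect_equal(cs$f_extra, 0)
  # unquenchable vanishes when finfq (1+k) equals f0b
  expect_equal(cs$f_unq, (0.4 * 2.5 - 1.0) / 1.5)
  expect_equal(cs$f_unq, 0)

  cs2 <- decompose_compartments(1.0, 0.9, 0.5)
  expect_equal(cs2$f_extra, 0.1 * 2.5 / 1.5, tolerance = 1e-12)
  expect_equal(cs2$f_intra, 0.4 * 2.5 / 1.5, tolerance = 1e-12)
  expect_equal(cs2$f_unq, (0.5 * 2.5 - 1.0) / 1.5, tolerance = 1e-12)
  expect_equal(cs2$f_extra + cs2$f_intra + cs2$f_unq, 1.0, tolerance = 1e-12)
  expect_false(cs2$nonphysical)
})

test_that("the three compartments conserve the buffer-mix fluorescence", {
  set.seed(7)
  for (i in 1:50) {
    f0b <- runif(1, 0.5, 2)
    f0q <- runif(1, 0.4, 1) * f0b
    finfq <- runif(1, f0b / (1 + 1.5), f0q)  # keeps f_unq >= 0
    cs <- decompose_compartments(f0b, f0q, finfq)
    expect_equal(cs$f_extra + cs$f_intra + cs$f_unq, f0b,
                 tolerance = 1e-10 * f0b)
    expect_true(min(cs$f_extra, cs$f_intra, cs$f_unq) >= -1e-12)
  }
})

test_that("non-physical plateau orderings are preserved and flagged, not clamped", {
  expect_warning(cs <- decompose_compartments(0.9, 1.0, 0.4), "non-physical")
  expect_true(cs$nonphysical)
  expect_lt(cs$f_extra, 0)                      # negative value kept for QC
  expect_equal(cs$f_extra + cs$f_intra + cs$f_unq, 0.9, tolerance = 1e-10)
})
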