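test_that("binning uses half-open intervals and excludes missing values", {
  tab <- toy_drug_table()
  b <- bin_drugs(tab, axis = "normrate")
  expect_equal(as.integer(table(b$bin)), c(3, 3, 2))   # <1.25 | [1.25,1.5) | >=1.5
  expect_identical(as.character(b$bin[b$normrate == 1.25]), "[1.25,1.5)")
  expect_identical(as.character(b$bin[b$normrate == 1.5]), "[1.5, Inf)")

  bc <- bin_drugs(tab, axis = "cc20")
  expect_equal(attr(bc, "n_missing"), 1L)
  expect_equal(nrow(bc), 7)
  expect_identical(as.character(bc$bin[bc$cc20 == 50]), "[50, Inf)")

  bq <- bin_drugs(tab, axis = "alogp_psa_quadrant")
  expect_equal(as.integer(table(bq$bin)), c(3, 1, 1, 3))
  expect_error(bin_drugs(tab, axis = "normrate", edges = c(2, 1)), "increasing")
})

test_that("odds ratios and Woolf intervals match the published quadrant tables", {
  or <- odds_ratio(contingency_table(58, 34, 6, 38))
  expect_equal(or$oratio, 10.80, tolerance = 0.005)
  expect_equal(or$ci_low, 4.14, tolerance = 0.005)
  expect_equal(or$ci_high, 28.19, tolerance = 0.005)
  expect_equal(or$odds_exposed, 58 / 34)
  expect_equal(or$odds_unexposed, 6 / 38)

  expect_equal(odds_ratio(contingency_table(69, 21, 25, 19))$oratio, 2.50,
               tolerance = 0.005)
  expect_equal(odds_ratio(contingency_table(5, 5, 5, 5))$oratio, 1)
})

test_that("odds ratios agree with brute-force arithmetic on random tables", {
  set.seed(31)
  for (i in 1:1000) {
    n <- sample(1:80, 4, replace = TRUE)
    or <- odds_ratio(contingency_table(n[1], n[2], n[3], n[4]))
    expect_identical(or$oratio, (n[1] * n[4]) / (n[2] * n[3]))
    expect_true(or$ci_low <= or$oratio && or$oratio <= or$ci_high)
  }
  # zero-cell handling
  inf_or <- odds_ratio(contingency_table(5, 0, 3, 7))
  expect_identical(inf_or$oratio, Inf)
  expect_true(all(c("infinite_or", "ci_undefined") %in% inf_or$flags))
})

test_that("probability curves reproduce per-bin and overall event fractions", {
  # published cytotoxicity quadrant counts: overall P(CC20 < 50) = 282/397
  cnt <- published_screen_counts()$cytotox
  event <- rep(rep(c(TRUE, FALSE), 4), times = rbind(cnt$positive, cnt$negative))
  bins <- rep(cnt$bin, times = cnt$positive + cnt$negative)
  pc <- probability_curve(bins, event)
  expect_equal(pc$overall, 282 / 397, tolerance = 1e-12)
  expect_equal(round(pc$overall, 2), 0.71)
  expect_equal(pc$curve$p[pc$curve$bin == "ALogP<=3 & PSA<=75"], 25 / 44)

  # all events true
  pc1 <- probability_curve(factor(c("a", "a", "b")), c(TRUE, TRUE, TRUE))
  expect_true(all(pc1$curve$p == 1))

  # zero-coupling library gives a flat curve within binomial error
  lib <- simulate_drug_library(800, coupling_slope = 0,
                               coupling_intercept = 0.85, missing_cc20 = 0,
                               seed = 19)
  b <- bin_drugs(lib, axis = "normrate")
  pc0 <- probability_curve(b$bin, b$cc20 < 50)
  p0 <- stats::plogis(0.85)
  se <- sqrt(p0 * (1 - p0) / pc0$curve$n)
  expect_true(all(abs(pc0$curve$p - p0) < 3.5 * se))
})

test_that("exact Mann-Whitney enumeration matches hand counts and wilcox.test", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p.value, 2 / 6, tolerance = 1e-12)
  expect_identical(mw$method, "exact")

  # identical multisets: p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p.value, 1)

  # cross-check against the reference implementation on tie-free samples
  set.seed(23)
  for (i in 1:20) {
    x <- round(rnorm(sample(3:6, 1)), 4)
    y <- round(rnorm(sample(3:6, 1), 0.5), 4)
    ref <- wilcox.test(x, y, exact = TRUE)
    mine <- mann_whitney(x, y)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
  }

  # large shifted samples through the tie-corrected normal path
  set.seed(29)
  x <- rnorm(40); y <- rnorm(40, 1.2)
  big <- mann_whitney(x, y)
  expect_identical(big$method, "normal approximation")
  expect_lt(big$p.value, 0.001)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(big$p.value, ref$p.value, tolerance = 1e-8)

  # Bonferroni multiplies and caps
  expect_equal(bonferroni(c(0.01, 0.4), 3), c(0.03, 1))
})

test_that("box summaries use interpolated quartiles and 1.5 IQR whiskers", {
  bs <- box_summary(1:100)
  expect_equal(bs$q1, 25.75)
  expect_equal(bs$q3, 75.25)
  expect_equal(bs$median, 50.5)
  expect_length(bs$outliers, 0)
  expect_equal(bs$whisker_low, 1)
  expect_equal(bs$whisker_high, 100)

  one <- box_summary(5)
  expect_equal(one$q1, 5); expect_equal(one$q3, 5)
  expect_equal(one$whisker_low, 5); expect_equal(one$whisker_high, 5)

  out <- box_summary(c(1, 2, 3, 4, 100))
  expect_equal(out$outliers, 100)     # fence: q3 + 1.5 IQR = 4 + 3 = 7
  expect_equal(out$whisker_high, 4)
})

test_that("silhouette scores match a brute-force oracle", {
  # independent naive implementation
  naive_sil <- function(x, labels) {
    x <- scale(x)
    n <- nrow(x)
    s <- numeric(n)
    for (i in seq_len(n)) {
      di <- sqrt(rowSums((x - matrix(x[i, ], n, ncol(x), byrow = TRUE))^2))
      own <- labels == labels[i]
      if (sum(own) == 1) { s[i] <- 0; next }
      a <- mean(di[own & seq_len(n) != i])
      b <- min(tapply(di[!own], labels[!own], mean))
      s[i] <- (b - a) / max(a, b)
    }
    s
  }
  set.seed(37)
  x <- matrix(rnorm(60), ncol = 2)
  labels <- sample(c("a", "b", "c"), 30, replace = TRUE)
  res <- silhouette_scores(x, labels)
  expect_equal(res$scores, naive_sil(x, labels), tolerance = 1e-12)
  expect_equal(res$mean, mean(naive_sil(x, labels)), tolerance = 1e-12)

  # two tight, distant clusters separate almost perfectly
  tight <- rbind(c(0, 0), c(0, 0.1), c(10, 10), c(10, 10.1))
  res2 <- silhouette_scores(tight, c(1, 1, 2, 2), standardize = FALSE)
  expect_gt(res2$mean, 0.95)

  # random labels on one blob: mean near zero
  set.seed(41)
  blob <- matrix(rnorm(400), ncol = 2)
  res3 <- silhouette_scores(blob, sample(1:2, 200, replace = TRUE))
  expect_lt(abs(res3$mean), 0.1)

  expect_error(silhouette_scores(x, rep("a", 30)), "2 clusters")
})

test_that("r-squared is the squared Pearson correlation with degenerate guard", {
  x <- 1:20
  expect_equal(r_squared(x, 2 * x + 1), 1)
  expect_equal(r_squared(x, -x), 1)
  set.seed(43)
  expect_lt(r_squared(rnorm(5000), rnorm(5000)), 0.01)
  expect_warning(v <- r_squared(x, rep(3, 20)), "zero variance")
  expect_true(is.na(v))
})

test_that("quadrant odds analysis recovers structure from a synthetic library", {
  lib <- simulate_drug_library(400, seed = 47)
  qo <- quadrant_odds(lib, lib$normrate >= 1.25)
  expect_equal(sum(qo$counts$positive + qo$counts$negative), 400)
  expect_equal(qo$n, 400)
  # collapsing the PSA split reproduces the marginal table by hand
  hi <- lib$alogp > 3
  pos <- lib$normrate >= 1.25
  or_hand <- (sum(hi & pos) * sum(!hi & !pos)) /
    (sum(hi & !pos) * sum(!hi & pos))
  expect_equal(qo$or_alogp_marginal$oratio, or_hand, tolerance = 1e-12)
})

test_that("conditional event shares are hand-countable on a toy table", {
  tab <- toy_drug_table()
  s <- conditional_event_share(tab$normrate >= 1.5, tab$cc20 < 50)
  # drugs with normrate >= 1.5 and defined cc20: ids D04 (cc20=50), D06 (9)
  expect_equal(s$n, 2)
  expect_equal(s$n_event, 1)
  expect_equal(s$share, 0.5)
})
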