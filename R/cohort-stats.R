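#' Bin drug records along a screening axis
#'
#' Assigns each record to a half-open bin `[lo, hi)` along one of the
#' screen's axes. Default edges follow the screen conventions: NormRate
#' 1.25/1.5, CC20 10/50 uM, QED 0.5, pScore 100/300; the
#' `alogp_psa_quadrant` axis crosses ALogP <= 3 / > 3 with PSA <= 75 / > 75
#' square Angstrom. Records with a missing value on the chosen axis are
#' excluded from the grouping and reported via the `n_missing` attribute
#' (never imputed).
#'
#' @param records A data.frame with the relevant columns (`normrate`,
#'   `cc20`, `alogp`, `psa`, `qed`, `pscore` as needed).
#' @param axis One of `"normrate"`, `"cc20"`, `"alogp_psa_quadrant"`,
#'   `"qed"`, `"pscore"`.
#' @param edges Strictly increasing bin edges (ignored for the quadrant
#'   axis, which uses `alogp_cut` and `psa_cut`).
#' @param alogp_cut,psa_cut Quadrant thresholds. Defaults 3 and 75.
#' @return `records` (rows with a defined axis value) with a `bin` factor
#'   column appended; attribute `n_missing` counts excluded rows.
#' @export
bin_drugs <- function(records,
                      axis = c("normrate", "cc20", "alogp_psa_quadrant",
                               "qed", "pscore"),
                      edges = NULL, alogp_cut = 3, psa_cut = 75) {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(records))
  if (axis == "alogp_psa_quadrant") {
    ok <- !is.na(records$alogp) & !is.na(records$psa)
    out <- records[ok, , drop = FALSE]
    a <- ifelse(out$alogp <= alogp_cut, "ALogP<=3", "ALogP>3")
    p <- ifelse(out$psa <= psa_cut, "PSA<=75", "PSA>75")
    out$bin <- factor(paste(a, p, sep = " & "),
                      levels = c("ALogP<=3 & PSA<=75", "ALogP<=3 & PSA>75",
                                 "ALogP>3 & PSA<=75", "ALogP>3 & PSA>75"))
  } else {
    if (is.null(edges)) {
      edges <- switch(axis, normrate = c(1.25, 1.5), cc20 = c(10, 50),
                      qed = 0.5, pscore = c(100, 300))
    }
    if (is.unsorted(edges, strictly = TRUE)) stop("`edges` must be strictly increasing")
    v <- records[[axis]]
    if (is.null(v)) stop(sprintf("records lack a `%s` column", axis))
    ok <- !is.na(v)
    out <- records[ok, , drop = FALSE]
    out$bin <- cut(v[ok], breaks = c(-Inf, edges, Inf), right = FALSE)
  }
  attr(out, "n_missing") <- sum(!ok)
  out
}

#' 2x2 contingency table
#'
#' Counts for an exposure/outcome cross-classification: `a` exposed-positive,
#' `b` exposed-negative, `c` unexposed-positive, `d` unexposed-negative.
#'
#' @param a,b,c,d Non-negative integer counts, total > 0.
#' @param exposure,outcome Axis labels.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, exposure = "exposed",
                              outcome = "positive") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("table total must be > 0")
  structure(list(a = a, b = b, c = c, d = d,
                 exposure = exposure, outcome = outcome),
            class = "contingency_table")
}

#' Odds ratio with Woolf confidence interval
#'
#' Point estimate `OR = (a d)/(b c)` with the Woolf (log-OR normal) interval
#' `exp(ln OR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`, no continuity correction.
#' When `b c = 0` the OR is infinite and flagged; when any cell is zero the
#' interval is undefined and flagged (`ci_undefined`).
#'
#' @param t A [contingency_table()].
#' @param level Confidence level. Default 0.95.
#' @return An object of class `odds_ratio`: `odds_exposed` (a/b),
#'   `odds_unexposed` (c/d), `oratio`, `ci_low`, `ci_high`, `level`, `flags`.
#' @export
odds_ratio <- function(t, level = 0.95) {
  stopifnot(inherits(t, "contingency_table"), level > 0, level < 1)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  flags <- character(0)
  or <- if (b * c == 0) {
    flags <- c(flags, "infinite_or")
    Inf
  } else (a * d) / (b * c)
  if (min(a, b, c, d) == 0) {
    flags <- c(flags, "ci_undefined")
    lo <- hi <- NA_real_
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    lo <- exp(log(or) - z * se)
    hi <- exp(log(or) + z * se)
  }
  structure(list(odds_exposed = a / b, odds_unexposed = c / d,
                 oratio = or, ci_low = lo, ci_high = hi,
                 level = level, flags = flags),
            class = "odds_ratio")
}

#' @export
print.odds_ratio <- function(x, ...) {
  cat(sprintf("OR = %.3f (%g%% CI %.3f-%.3f); odds %.3f vs %.3f\n",
              x$oratio, 100 * x$level, x$ci_low, x$ci_high,
              x$odds_exposed, x$odds_unexposed))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Per-quadrant odds and the corner odds ratio
#'
#' Reproduces the screen's quadrant analysis: drugs are crossed into the
#' four ALogP/PSA quadrants, the odds of a positive outcome (e.g.
#' NormRate >= 1.25, or CC20 < 50 uM) are computed per quadrant, and the
#' odds ratio contrasts the high-ALogP/high-PSA corner against the
#' low-ALogP/low-PSA corner. Collapsing the PSA split gives the marginal
#' ALogP-only odds ratio.
#'
#' @param records Drug table with `alogp`, `psa`, and the outcome inputs.
#' @param outcome Logical vector (length `nrow(records)`): the positive
#'   outcome per drug; NA rows are excluded.
#' @param alogp_cut,psa_cut Quadrant thresholds. Defaults 3 and 75.
#' @param level Confidence level for the corner OR.
#' @return List with `counts` (data.frame: bin, positive, negative, odds),
#'   `or` (corner [odds_ratio()]), `or_alogp_marginal` (ALogP-only
#'   [odds_ratio()]), `n` (records with defined outcome).
#' @export
quadrant_odds <- function(records, outcome, alogp_cut = 3, psa_cut = 75,
                          level = 0.95) {
  stopifnot(length(outcome) == nrow(records))
  records$..outcome <- outcome
  grp <- bin_drugs(records[!is.na(outcome), , drop = FALSE],
                   axis = "alogp_psa_quadrant",
                   alogp_cut = alogp_cut, psa_cut = psa_cut)
  pos <- tapply(grp$..outcome, grp$bin, function(z) sum(z), default = 0L)
  neg <- tapply(grp$..outcome, grp$bin, function(z) sum(!z), default = 0L)
  counts <- data.frame(bin = names(pos), positive = as.integer(pos),
                       negative = as.integer(neg),
                       odds = as.numeric(pos) / as.numeric(neg))
  hh <- "ALogP>3 & PSA>75"; ll <- "ALogP<=3 & PSA<=75"
  or <- odds_ratio(contingency_table(pos[[hh]], neg[[hh]], pos[[ll]], neg[[ll]],
                                     exposure = "high ALogP & PSA"),
                   level = level)
  hi_a <- grepl("ALogP>3", counts$bin)
  or_marg <- odds_ratio(contingency_table(sum(pos[hi_a]), sum(neg[hi_a]),
                                          sum(pos[!hi_a]), sum(neg[!hi_a]),
                                          exposure = "ALogP>3"),
                        level = level)
  list(counts = counts, or = or, or_alogp_marginal = or_marg, n = nrow(grp))
}

#' Event probability per bin and overall
#'
#' Per-bin fraction of records satisfying an event (e.g. CC20 < 50 uM) along
#' a binned axis, plus the overall fraction over all records with a defined
#' event. Empty bins are reported with `p = NA`.
#'
#' @param bins Factor of bin assignments (e.g. the `bin` column from
#'   [bin_drugs()]).
#' @param event Logical event indicator, same length; NA events are excluded.
#' @return List with `curve` (data.frame: bin, n, n_event, p) and `overall`.
#' @export
probability_curve <- function(bins, event) {
  stopifnot(length(bins) == length(event))
  ok <- !is.na(event) & !is.na(bins)
  bins <- factor(bins[ok]); event <- event[ok]
  n <- tapply(event, bins, length, default = 0L)
  ne <- tapply(event, bins, sum, default = 0L)
  curve <- data.frame(bin = names(n), n = as.integer(n),
                      n_event = as.integer(ne),
                      p = ifelse(n > 0, as.numeric(ne) / as.numeric(n), NA_real_))
  list(curve = curve, overall = mean(event))
}

#' Conditional share of an event within a drug subset
#'
#' Fraction of drugs satisfying `event` among those satisfying `subset`,
#' over records where both are defined. Used for composite-predictor
#' summaries such as "share of drugs with NormRate >= 1.5 that have
#' CC20 < 50 uM".
#'
#' @param subset,event Logical vectors of equal length.
#' @return List with `share`, `n` (subset size with defined event),
#'   `n_event`.
#' @export
conditional_event_share <- function(subset, event) {
  stopifnot(length(subset) == length(event))
  ok <- !is.na(subset) & !is.na(event) & subset
  list(share = mean(event[ok]), n = sum(ok), n_event = sum(event[ok]))
}

#' Two-sided Mann-Whitney test with midranks
#'
#' Rank-sum comparison of two samples using midranks for ties. For
#' `length(x) + length(y) <= exact_max` the null distribution of U is
#' enumerated exactly, conditional on the observed (possibly tied) ranks;
#' the two-sided p-value sums both tails at or beyond the observed U and its
#' reflection about the null mean. For larger samples the tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_max Largest combined size for exact enumeration. Default 12.
#' @return List with `statistic` (U for `x`), `p.value`, `method`.
#' @seealso [bonferroni()]
#' @export
mann_whitney <- function(x, y, exact_max = 12) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 1, length(y) >= 1)
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (n <= exact_max) {
    picks <- utils::combn(n, nx)
    us <- colSums(matrix(r[picks], nrow = nx)) - nx * (nx + 1) / 2
    refl <- 2 * mu - u
    lo <- min(u, refl); hi <- max(u, refl)
    eps <- 1e-9
    p <- (sum(us <= lo + eps) + sum(us >= hi - eps)) / ncol(picks)
    p <- min(p, 1)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- u - mu
    z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)   # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = u, p.value = p, method = method)
}

#' Bonferroni correction
#'
#' Multiplies p-values by the number of comparisons and caps at 1.
#'
#' @param pvals Numeric p-values.
#' @param m Number of comparisons. Default `length(pvals)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  stopifnot(m >= 1)
  pmin(pvals * m, 1)
}

#' Box-plot summary with 1.5 IQR whiskers
#'
#' Quartiles by linear interpolation between order statistics
#' (`quantile(type = 7)`), fences at q1 - 1.5 IQR and q3 + 1.5 IQR, whisker
#' ends snapped to the most extreme data inside the fences, values beyond
#' the fences listed as outliers.
#'
#' @param values Numeric sample (>= 1 value, NAs dropped).
#' @return List with `q1`, `median`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `n`.
#' @export
box_summary <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 1)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  fence_lo <- q[1] - 1.5 * iqr
  fence_hi <- q[3] + 1.5 * iqr
  inside <- values >= fence_lo & values <= fence_hi
  list(q1 = q[1], median = q[2], q3 = q[3],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]),
       n = length(values))
}

#' Silhouette scores for a clustering
#'
#' For each point, `s = (b - a)/max(a, b)` where `a` is the mean Euclidean
#' distance to the other members of its cluster and `b` the smallest mean
#' distance to any other cluster; singletons score 0. Features are
#' standardized to zero mean / unit variance before computing distances
#' (constant features are left unscaled).
#'
#' @param points Numeric matrix (points x features) or data.frame.
#' @param labels Cluster assignment, length `nrow(points)`; >= 2 clusters.
#' @param standardize Standardize features first. Default TRUE.
#' @return List with `scores` (per point), `cluster_means` (named), `mean`.
#' @export
silhouette_scores <- function(points, labels, standardize = TRUE) {
  x <- as.matrix(points)
  labels <- as.factor(labels)
  stopifnot(nrow(x) == length(labels))
  if (nlevels(droplevels(labels)) < 2) stop("need at least 2 clusters")
  labels <- droplevels(labels)
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0] <- 1
    x <- scale(x, center = TRUE, scale = sds)
  }
  dm <- as.matrix(stats::dist(x))
  n <- nrow(x)
  sizes <- table(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    li <- labels[i]
    if (sizes[[li]] == 1) { s[i] <- 0; next }
    a <- sum(dm[i, labels == li]) / (sizes[[li]] - 1)   # excludes self (d=0)
    b <- min(vapply(setdiff(levels(labels), as.character(li)), function(l) {
      mean(dm[i, labels == l])
    }, numeric(1)))
    m <- max(a, b)
    s[i] <- if (m > 0) (b - a) / m else 0
  }
  list(scores = s,
       cluster_means = vapply(levels(labels),
                              function(l) mean(s[labels == l]), numeric(1)),
       mean = mean(s))
}

#' Squared Pearson correlation
#'
#' @param x,y Equal-length samples (>= 3). Zero variance in either yields NA
#'   with a warning.
#' @return r^2 (dimensionless).
#' @export
r_squared <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: r^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)^2
}
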