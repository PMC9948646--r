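#' Published quadrant counts from the 400-compound screen
#'
#' The reported ALogP/PSA quadrant counts from the published gramicidin-based
#' screen of the Pathogen Box (400 antiparasitic drugs and drug-like
#' molecules). Two cross-classifications are reported: bilayer activity
#' (NormRate >= 1.25 vs < 1.25; all 400 drugs) and likely cytotoxicity
#' (HepG2 CC20 < 50 uM vs >= 50 uM; the 397 drugs with CC20 data). Counts
#' are positive/negative within each ALogP (<= 3 / > 3) by PSA (<= 75 /
#' > 75 square Angstrom) quadrant. These printed counts are inputs to the
#' cohort statistics, used to reproduce the published odds and odds ratios.
#'
#' @return List of two data.frames (`bilayer`, `cytotox`) with columns
#'   `bin`, `positive`, `negative` matching the quadrant levels used by
#'   [bin_drugs()].
#' @export
published_screen_counts <- function() {
  bins <- c("ALogP<=3 & PSA<=75", "ALogP<=3 & PSA>75",
            "ALogP>3 & PSA<=75", "ALogP>3 & PSA>75")
  list(
    bilayer = data.frame(bin = bins,
                         positive = c(6L, 32L, 99L, 58L),
                         negative = c(38L, 61L, 72L, 34L)),
    cytotox = data.frame(bin = bins,
                         positive = c(25L, 59L, 129L, 69L),
                         negative = c(19L, 34L, 41L, 21L))
  )
}

#' Published NormRate category counts
#'
#' The reported potency composition of the screened library: 199 drugs with
#' NormRate < 1.25 (low), 74 moderate (1.25 <= NormRate < 1.5), and 127
#' high (NormRate >= 1.5), of 400 total.
#'
#' @return Named integer vector `c(low, moderate, high)`.
#' @export
published_category_counts <- function() {
  c(low = 199L, moderate = 74L, high = 127L)
}

#' Corner and marginal odds ratios from published quadrant counts
#'
#' Convenience wrapper turning one of the [published_screen_counts()]
#' tables into the corner odds ratio (high-ALogP/high-PSA vs
#' low-ALogP/low-PSA) and the ALogP-only marginal odds ratio.
#'
#' @param counts A data.frame with `bin`, `positive`, `negative` as returned
#'   by [published_screen_counts()].
#' @param level Confidence level. Default 0.95.
#' @return List with `odds` (per-quadrant odds, in `counts` order), `or`,
#'   `or_alogp_marginal` (both [odds_ratio()] objects), and `n` (total).
#' @export
counts_to_odds <- function(counts, level = 0.95) {
  stopifnot(all(c("bin", "positive", "negative") %in% names(counts)),
            nrow(counts) == 4)
  hh <- counts$bin == "ALogP>3 & PSA>75"
  ll <- counts$bin == "ALogP<=3 & PSA<=75"
  or <- odds_ratio(contingency_table(counts$positive[hh], counts$negative[hh],
                                     counts$positive[ll], counts$negative[ll],
                                     exposure = "high ALogP & PSA"),
                   level = level)
  hi_a <- grepl("ALogP>3", counts$bin)
  or_marg <- odds_ratio(contingency_table(
    sum(counts$positive[hi_a]), sum(counts$negative[hi_a]),
    sum(counts$positive[!hi_a]), sum(counts$negative[!hi_a]),
    exposure = "ALogP>3"), level = level)
  list(odds = counts$positive / counts$negative,
       or = or, or_alogp_marginal = or_marg,
       n = sum(counts$positive) + sum(counts$negative))
}
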