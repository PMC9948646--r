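#!/usr/bin/env Rscript
# Step 4: library-level statistics.
#
# Two parts. (a) The published quadrant counts of the 400-compound screen are
# pushed through the odds machinery, reproducing the printed odds, odds
# ratios, Woolf intervals, and the overall probability of likely
# cytotoxicity. (b) The same analysis runs on the synthetic library from
# step 1, recovering the planted potency-cytotoxicity coupling, together
# with probability curves, Mann-Whitney group comparisons, box summaries,
# and a silhouette diagnostic of ALogP/PSA clustering.

suppressPackageStartupMessages(library(bilayerscreen))

## (a) published counts -------------------------------------------------------
counts <- published_screen_counts()
bil <- counts_to_odds(counts$bilayer)
cyt <- counts_to_odds(counts$cytotox)
cat("published screen, bilayer activity vs ALogP/PSA quadrants:\n")
cat("  quadrant odds:", paste(round(bil$odds, 2), collapse = " / "), "\n")
cat(sprintf("  corner OR %.1f (95%% CI %.1f-%.1f), n = %d\n",
            bil$or$oratio, bil$or$ci_low, bil$or$ci_high, bil$n))
cat(sprintf("  cytotoxicity corner OR %.1f, ALogP-marginal OR %.1f, n = %d\n",
            cyt$or$oratio, cyt$or_alogp_marginal$oratio, cyt$n))
cnt <- counts$cytotox
event <- rep(rep(c(TRUE, FALSE), 4), times = rbind(cnt$positive, cnt$negative))
overall <- probability_curve(rep(cnt$bin, cnt$positive + cnt$negative),
                             event)$overall
cat(sprintf("  overall P(CC20 < 50 uM) = %.2f\n\n", overall))
write.csv(data.frame(table = rep(c("bilayer", "cytotox"), each = 4),
                     rbind(counts$bilayer, counts$cytotox),
                     odds = c(bil$odds, cyt$odds)),
          "results/published_odds.csv", row.names = FALSE)

## (b) synthetic library ------------------------------------------------------
lib <- read_drug_table("results/drug_library.csv")
b <- bin_drugs(lib, axis = "normrate")
pc <- probability_curve(b$bin, b$cc20 < 50)
cat("synthetic library, P(CC20 < 50 uM) by NormRate bin:\n")
print(pc$curve, digits = 3)
cat(sprintf("  overall %.2f\n", pc$overall))
write.csv(pc$curve, "results/probability_curve.csv", row.names = FALSE)

qo <- quadrant_odds(lib, lib$normrate >= 1.25)
cat(sprintf("\nsynthetic quadrant corner OR (bilayer active): %.2f (95%% CI %.2f-%.2f)\n",
            qo$or$oratio, qo$or$ci_low, qo$or$ci_high))

tox <- lib$cc20 < 50
hi <- lib$normrate >= 1.5; lo <- lib$normrate < 1.25
or_pc <- odds_ratio(contingency_table(
  sum(hi & tox, na.rm = TRUE), sum(hi & !tox, na.rm = TRUE),
  sum(lo & tox, na.rm = TRUE), sum(lo & !tox, na.rm = TRUE)))
cat(sprintf("high- vs low-potency cytotoxicity OR: %.2f (95%% CI %.2f-%.2f)\n",
            or_pc$oratio, or_pc$ci_low, or_pc$ci_high))

mw <- mann_whitney(lib$cc20[hi & !is.na(lib$cc20)],
                   lib$cc20[lo & !is.na(lib$cc20)])
cat(sprintf("Mann-Whitney CC20 high vs low potency: U = %.0f, P = %.2g (%s)\n",
            mw$statistic, mw$p.value, mw$method))

bs_hi <- box_summary(lib$cc20[hi]); bs_lo <- box_summary(lib$cc20[lo])
cat(sprintf("CC20 medians: high potency %.1f uM (%d outliers), low %.1f uM\n",
            bs_hi$median, length(bs_hi$outliers), bs_lo$median))

sil <- silhouette_scores(lib[, c("alogp", "psa")],
                         categorize_normrate(lib$normrate))
cat(sprintf("silhouette of potency classes in ALogP/PSA space: %.2f\n",
            sil$mean))
cat(sprintf("r2(NormRate, ALogP) = %.3f; r2(NormRate, PSA) = %.3f\n",
            r_squared(log(lib$normrate), lib$alogp),
            r_squared(log(lib$normrate), lib$psa)))
cat("wrote results/published_odds.csv and results/probability_curve.csv\n")
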