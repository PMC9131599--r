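#!/usr/bin/env Rscript
# Step 4 — condition comparison.
#
# Reads the per-trial COI table produced by step 2, screens each
# condition-pair sample for normality (Shapiro-Wilk), and compares the four
# feedback conditions with a one-way repeated-measures ANOVA per muscle pair,
# reporting F, p, partial eta squared and the Greenhouse-Geisser correction.

suppressPackageStartupMessages(library(pedalcoi))

out <- "results"
coi_file <- file.path(out, "coi_per_trial.csv")
if (!file.exists(coi_file)) stop("run analysis/02_cocontraction.R first")
coi_tab <- read.csv(coi_file, check.names = FALSE)
prim <- coi_tab[coi_tab$basis == "ensemble", ]

alpha <- 0.05
rows <- NULL
for (pair in unique(prim$pair)) {
  sub <- prim[prim$pair == pair, ]
  wide <- reshape(sub[, c("participant", "condition", "coi_percent")],
                  idvar = "participant", timevar = "condition",
                  direction = "wide")
  m <- as.matrix(wide[, -1])
  colnames(m) <- sub("^coi_percent\\.", "", colnames(m))

  cat(sprintf("\n== %s ==\n", pair))
  for (cond in colnames(m)) {
    sw <- shapiro_wilk(m[, cond])
    cat(sprintf("  Shapiro-Wilk %-8s W = %.3f, p = %.3f%s\n", cond, sw$W,
                sw$p_value, if (sw$p_value < alpha) "  <- non-normal" else ""))
  }
  a <- rm_anova(m)
  print(a)
  verdict <- if (a$p_value < alpha) "differs" else "does not differ"
  cat(sprintf("  At alpha = %.2f, the %s COI %s across feedback conditions.\n",
              alpha, pair, verdict))
  rows <- rbind(rows, data.frame(pair = pair, f = a$f_value,
                                 df1 = a$df_effect, df2 = a$df_error,
                                 p = a$p_value, partial_eta_sq = a$partial_eta_sq,
                                 gg_epsilon = a$gg_epsilon, p_gg = a$p_value_gg))
}
write.csv(rows, file.path(out, "stats_conditions.csv"), row.names = FALSE)
cat("\nWrote", file.path(out, "stats_conditions.csv"), "\n")
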