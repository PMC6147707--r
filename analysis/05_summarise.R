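#!/usr/bin/env Rscript
# Stage 5: recovery summary against ground truth.
#
# Compares fitted slopes, Omega classes and phylogenetic signal with the
# generating parameters, and writes the run summary.

library(canopyresponse)

truth <- read.csv("results/data/truth.csv", stringsAsFactors = FALSE)
fits <- read.csv("results/fits.csv", stringsAsFactors = FALSE)
omega_tab <- read.csv("results/omega.csv", stringsAsFactors = FALSE)
signal <- read.csv("results/signal.csv", stringsAsFactors = FALSE)

loc <- merge(fits[fits$scale == "local", ], truth, by = "species",
             suffixes = c("_hat", "_true"))
cat(sprintf("local-scale slope recovery: cor(C_hat, C_true) = %.3f over %d species\n",
            cor(loc$C_hat, loc$C_true), nrow(loc)))

om <- merge(omega_tab[omega_tab$scale == "local", ], truth, by = "species")
om$expected_class <- ifelse(om$C < 0, "positive",
                            ifelse(om$C > 0, "negative", "neutral"))
nonneutral <- om$response_class != "neutral"
cat(sprintf("class agreement (non-neutral calls): %.0f%% of %d\n",
            100 * mean(om$response_class[nonneutral] ==
                       om$expected_class[nonneutral]), sum(nonneutral)))
cat(sprintf("sign recovery: %.0f%% of informative local fits have sign(Omega) = -sign(C_true)\n",
            100 * mean(sign(om$omega) == -sign(om$C))))

sig_local <- signal[signal$scale == "local" & signal$scope == "all", ]
cat(sprintf("phylogenetic signal in local Omega (all species): median lambda = %.3f, median p = %.3g\n",
            sig_local$median_lambda, sig_local$median_p))

summary_tab <- data.frame(
  quantity = c("n_species_analysed", "cor_C_local",
               "pct_sign_law", "median_lambda_local_all"),
  value = c(nrow(loc), round(cor(loc$C_hat, loc$C_true), 3),
            round(100 * mean(sign(om$omega) == -sign(om$C)), 1),
            round(sig_local$median_lambda, 3)))
write.csv(summary_tab, "results/summary.csv", row.names = FALSE)
cat("written results/summary.csv\n")
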