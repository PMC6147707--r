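#!/usr/bin/env Rscript
# Stage 2: border exclusion and multi-scale canopy cover.
#
# Drops plots within 6.4 km of the domain border, then averages cover in
# concentric lattice circles of radius 1.6, 3.2 and 6.4 km (9, 37 and 129
# possible plots) around every remaining plot.

library(canopyresponse)

plots <- read_plots_csv("results/data/plots.csv")
kept <- exclude_border(plots, margin_km = 6.4)
cat(sprintf("border exclusion: %d of %d plots retained (%d dropped)\n",
            nrow(kept), nrow(plots), nrow(plots) - nrow(kept)))

cover <- multiscale_cover(kept, radii = c(1.6, 3.2, 6.4))
write_plots_csv(kept, "results/data/plots_analysed.csv")
write.csv(cover, "results/cover.csv", row.names = FALSE)

for (tag in c("1p6", "3p2", "6p4"))
  cat(sprintf("radius %s: plots averaged per circle, median %d (max possible %d)\n",
              sub("p", ".", tag), median(cover[[paste0("n_", tag)]]),
              max(cover[[paste0("n_", tag)]])))
cat(sprintf("cover correlation local vs 1.6 km: %.3f; local vs 6.4 km: %.3f\n",
            cor(cover$cover_local, cover$cover_1p6),
            cor(cover$cover_local, cover$cover_6p4)))
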