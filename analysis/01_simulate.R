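#!/usr/bin/env Rscript
# Stage 1: generate the synthetic forest-inventory dataset.
#
# Emulates a national-inventory survey at desk scale: a 100 x 100 lattice of 1-km
# spaced plots carrying a spatially autocorrelated canopy-cover field, a
# 45-species dated phylogeny, and per-species stem counts that are Poisson
# given cover with Brownian-motion-structured slopes. Ground truth (M, C,
# trait) is kept so later stages can be checked against it.

library(canopyresponse)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(grid_nx = 100, grid_ny = 100, n_species = 45,
                        occupancy = 0.5, seed = 42)
d <- simulate_dataset(cfg)

write_plots_csv(d$plots, file.path(out, "plots.csv"))
ape::write.tree(d$tree, file.path(out, "tree.nwk"))
write.csv(d$clades, file.path(out, "clades.csv"), row.names = FALSE)
write.csv(d$truth, file.path(out, "truth.csv"), row.names = FALSE)

occ <- vapply(d$truth$species, function(s) mean(d$plots[[s]] > 0), numeric(1))
cat(sprintf("simulated %d plots, %d species\n", nrow(d$plots), nrow(d$truth)))
cat(sprintf("cover: mean %.1f%%, range %.1f-%.1f%%\n",
            mean(d$plots$cover_pct), min(d$plots$cover_pct),
            max(d$plots$cover_pct)))
cat(sprintf("occupied-plot fraction: median %.2f (target %.2f)\n",
            median(occ), cfg$occupancy))
cat(sprintf("slopes C: %d negative, %d positive\n",
            sum(d$truth$C < 0), sum(d$truth$C > 0)))
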