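# canopyresponse

Quantifying how tree species respond to forest canopy loss — and whether
those responses run in phylogenetic families.

Forest inventories place plots at the intersections of a 1-km grid and
record, per plot, canopy cover `F` (%) and per-species stem counts `ρ`.
`canopyresponse` turns such data into three linked results:

1. **Multi-scale cover.** Besides local plot cover, canopy cover is
   averaged over concentric lattice circles of radius 1.6, 3.2 and 6.4 km
   (holding at most 9, 37 and 129 plots), after excluding plots within
   6.4 km of the domain border.
2. **Species responses (Ω).** Per species and scale, counts are fitted as
   `ρ ~ Pois(M + C·F)` (identity link; a log-link variant is available) by
   maximum likelihood. Models improving on the intercept-only fit by more
   than 10 AICc units are *informative* and yield
   `Ω = ln[P(F = 5) / P(F = 75)]` with `P(F) = 1 − e^(−λ(F))` — the
   log-ratio of occurrence probabilities at low vs high cover. Positive Ω:
   the species gains from forest loss; negative: forest-affiliated. A
   1000-replicate bootstrap gives percentile 95% CIs (ranks 25 and 976),
   classifying each response as negative / neutral / positive.
3. **Phylogenetic signal.** Pagel's λ for Ω across a dated phylogeny,
   estimated by ML on [0, 1] with a χ²₁ likelihood-ratio test, propagating
   Ω uncertainty by re-estimating λ on 1000 draws of Ω from each species'
   CI and reporting medians — for all species and per clade
   (angiosperms / gymnosperms).

A synthetic-data generator emulates the inventory design (autocorrelated
cover field, sparse Poisson counts, Brownian-motion-structured slopes on a
simulated tree) with known ground truth, so every stage has a
parameter-recovery test.

## Worked example

The numbered drivers under `analysis/` run the whole chain on synthetic
data and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # plots.csv, tree.nwk, clades.csv, truth.csv
Rscript analysis/02_landscape.R      # border exclusion + cover.csv
Rscript analysis/03_fit_occurrence.R # fits.csv, omega.csv, best_scale.csv
Rscript analysis/04_phylo_signal.R   # signal.csv, signal_iterations.csv
Rscript analysis/05_summarise.R      # summary.csv
```

On the default 100 × 100-plot lattice with 45 species (seed 42) this prints:

```
border exclusion: 7396 of 10000 plots retained (2604 dropped)
45 species retained (>= 25 occupied plots, on the tree)
local scale: 18/45 species informative (40%)
negative positive
       6       12
...
local-scale slope recovery: cor(C_hat, C_true) = 0.935 over 45 species
class agreement (non-neutral calls): 100% of 18
phylogenetic signal in local Omega (all species): median lambda = 0.734, median p = 0.0396
```

Reading: 18 species had cover-informative occurrence models at the plot
scale; every non-neutral Ω classification matched the sign of the
generating slope (species simulated with density falling as cover rises,
`C < 0`, come out Ω-positive — they gain from forest loss); and the
Brownian structure planted in the slopes is recovered as significant
phylogenetic signal in Ω.

The same computation is available as one call:

```r
library(canopyresponse)
res <- run_pipeline(pipeline_config(seed = 42))   # full study settings
summarize_results(res)
```

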