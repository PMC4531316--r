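# edgefret

Quantifying where and when a signaling activity changes relative to cell
edge motion.

When an endothelial cell is released from a micropatterned constraint (an
elliptic 20 µm × 80 µm well whose confining gel membrane is peeled off),
it spreads, polarizes and protrudes. FRET biosensor movies of such cells
carry two intertwined signals: the donor/acceptor (ECFP/FRET) emission
ratio, reporting kinase activity near the membrane, and the motion of the
cell edge itself. `edgefret` turns a two-channel time-lapse movie into
window-resolved maps of both signals along the cell boundary and measures
their spatiotemporal coordination.

## What the package computes

1. **Ratio movie** — per-frame background subtraction (low percentile) and
   the masked ratio R = donor/acceptor wherever the acceptor exceeds an
   intensity floor.
2. **Boundary detection** — k-means intensity clustering; the union of the
   non-background classes, cleaned morphologically, gives the cell mask
   whose outer boundary is extracted at sub-pixel resolution.
3. **Level-set tracking** — each boundary Γ(t) is represented by its
   signed-distance field φ and evolved onto Γ(t+1) with the
   Hamilton–Jacobi equation φ_t + V|∇φ| = 0, speed V = −φ_next, producing
   intermediate fronts. Reference points are chased through the
   intermediates to build a per-point correspondence, and geometric
   conflicts (missing matches, crossing vectors, direction reversals) are
   corrected — crossings by circular isotonic projection of the 1-D
   arc-length indices.
4. **Edge sampling** — a peripheral band 0.5 µm deep is cut into windows
   1.25 µm wide. Windows propagate across frames through the
   correspondence, sampling the mean ratio S(w, t) and integrating normal
   displacements into the translocation B(w, t) (cumulative motion since
   the release frame).
5. **Classification** — windows whose peak translocation reaches ≥ 75% of
   the cell's maximum form P-regions (minimum 3 windows, 1-window gaps
   merged); a cell with exactly one P-region is polarized.
6. **Cross-correlation** — temporal CC per window,
   ρ(τ) = Cov(S(t), B(t+τ)) / (σ_S σ_B), where σ_S, σ_B are the *maximal*
   standard deviations of the centered time courses over all windows
   (global normalization, highlighting high-change regions); spatial CC of
   circular line scans, normalized analogously over time steps. A negative
   minimum at positive τ means the ratio change precedes edge motion by τ.
7. **Statistics** — bootstrap means with percentile CIs (5000 resamples)
   and Welch t-tests for P vs NP group comparisons.

A synthetic generator (`generate_maps`, `generate_movie`) renders
ground-truthed inputs — window-level maps or full two-channel movies of an
elliptic cell protruding in programmable angular sectors with a
programmable ratio-drop lead time — so the whole pipeline is testable
without microscopy data.

## Worked example

```r
library(edgefret)

# render a polarized synthetic cell: 20 x 80 um ellipse, one end sector
# advancing 30 um after release, ratio dropping to 0.85 with a lead
gen <- generate_movie("POL-C", seed = 11)

cfg <- run_config(pixel_size = 0.5, frame_interval = 2, release_index = 3)
res <- run_pipeline(cfg, movie = gen$movie)
print(res)
#> <edge_analysis> 25 frames, 141 windows; cell polarized (1 P-region(s))
#>   P-window CC lag: mean 2.40 min (95% CI -12.00..16.80, n=5)

max(res$transloc_map$values[, res$transloc_map$frame_times == 10])
#> [1] 29.71667
```

The printout says the movie's 141 edge windows contain a single
protrusive region (the cell is polarized), and the maximum window
translocation 10 minutes after release is ≈ 29.7 µm — the pipeline's
estimate of the programmed 30 µm front advance, recovered through
detection, level-set tracking, correspondence, window propagation and
integration.

Window-level analyses skip the imaging stages:

```r
maps <- generate_maps("POL-A", seed = 7)     # 64 windows, 10-min lead
nm <- global_sigmas(maps$ratio, maps$translocation)
cc <- temporal_cc(maps$ratio$values[25, ], maps$translocation$values[25, ],
                  nm, max_lag = 19)
extract_minimum(cc)
#> $min_value
#> [1] -0.9292917
#> $min_offset
#> [1] 10
#> $flag
#> [1] "ok"
```

The CC minimum is negative (ratio falls as the edge advances) at a lag of
+10 minutes: the ratio change precedes the motion by the scenario's
programmed lead.

## Command line

```sh
Rscript inst/cli/edgefret.R simulate --scenario POL-A --seed 7 --out sim/
Rscript inst/cli/edgefret.R all --donor donor.tif --acceptor acceptor.tif \
    --pixel-size 0.5 --frame-interval 2 --release-index 3 --out results/
```

See `vignettes/edge-tracking-methods.Rmd` for the model, parameter and
design documentation.
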