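# ftcooc

Transcription-factor footprinting and co-occupancy analysis on ATAC-seq
cut-count tracks, with a synthetic-data generator that makes the whole
pipeline testable end to end on a desktop.

## The problem

ATAC-seq measures chromatin accessibility through Tn5 transposase insertion
("cut") counts. Where a transcription factor (TF) is stably bound inside an
accessible region, it shields the DNA and leaves a *footprint*: a local
depletion of cuts over the motif, usually with enriched cuts in the
immediate flanks. Footprinting therefore turns a single accessibility
experiment into a genome-wide, in-vivo binding map for any TF with a known
motif.

A question that binding maps can answer, and expression data alone cannot,
is whether two factors *co-occupy* regulatory DNA: whether the regulatory
regions (promoters, enhancers) footprinted by a focal TF are also
footprinted by a candidate partner far more often than by unrelated
factors. Regulatory co-occupancy is the molecular signature of TFs that
synergize by targeting shared target genes — for example, growth-promoting
factors in developing cortical neurons, where such co-occupancy is
concentrated in growth-relevant gene networks and collapses with age.

`ftcooc` re-implements that analysis chain as a tested, reusable package:

1. **Peak calling** (`call_peaks`) — simplified MACS-style sliding-window
   Poisson test against a local background λ, Benjamini–Hochberg corrected
   (`q ≤ 0.01` by default), emitting ENCODE narrowPeak.
2. **Motif scanning** (`scan_pwm`, `log_odds`, `information_content`) —
   PWM log₂-odds scores on both strands with the min–max *relative score*
   `(s − s_min)/(s_max − s_min)` thresholded at 0.90, and the 8-bit
   specificity (total information content) profile filter.
3. **Footprint model** (`fit_centipede`, `posterior_calls`) — a
   CENTIPEDE-style two-component mixture per candidate site: total cuts
   `t_i ~ NB(μ, α)` times a multinomial positional profile (free λ when
   bound, uniform when unbound), with a logistic prior
   `logit P(bound_i) = β₀ + β₁·score_i`, fit by EM; sites with posterior
   ≥ 0.99 are "deep footprints".
4. **Annotation** (`make_promoters`, `attach_enhancers`,
   `assign_footprints`) — promoters as −2000/+300 bp windows around the
   TSS, intragenic enhancers assigned by gene containment, genes split
   into focal-only vs focal-and-partner categories.
5. **Co-occupancy enrichment** (`cooccupancy_rate`, `background_null`,
   `enrichment_summary`, `age_contrast`) — the co-binding rate
   `100·|focal ∩ partner regions| / |focal regions|`, its fold and
   `z = (rate − mean)/SD` against a ~10-TF background panel, and the
   two-age contrast.
6. **Promoter over-representation** (`enrich_promoters`) — oPOSSUM-style
   per-TF nucleotide-rate Z-scores and one-sided Fisher gene-hit tests
   over −1000/+300 promoter scans.
7. **Synthetic data** (`synthetic_config`, `design_truth`,
   `simulate_cut_track`, `emit_dataset`) — a first-class generator that
   plants motif instances, bound labels with controllable region-level
   co-occupancy, and negative-binomial cut tracks for two "ages".

All coordinates are 0-based half-open throughout (BED convention).

## Worked example

```r
library(ftcooc)
cfg <- default_pipeline_config(seed = 1)   # 680 genes, 340 enhancers, 2 ages
report <- run_all(cfg, "demo_out")
```

prints (seed 1, this package version):

```
P0     peaks 1721 | focal regions 157 | co-rate 19.75% | null 2.36% +/- 1.00 | fold 8.4 | z 17.4 | focal genes 152
adult  peaks 1733 | focal regions  68 | co-rate  7.35% | null 2.06% +/- 1.24 | fold 3.6 | z  4.3 | focal genes  66
decline 56.6% (rounds to 57%), co-gene drop 80.6%
```

Reading: in the "newborn" condition the focal TF footprints 157 regulatory
regions; 19.75% of them also carry a partner footprint, 8.4-fold (z ≈ 17)
above the mean co-occupancy with ten background TFs — the planted synergy
(ρ_co = 0.6 in growth-relevant regions) is recovered. In the "adult"
condition, where the generator halves the focal binding rate, the number of
focal-footprinted genes drops by ~57% and co-occupied genes by ~81%,
mirroring the age-dependent collapse the analysis is designed to detect.
Everything is reproducible byte-for-byte from `(config, seed)`.

A command-line driver with `run`, `simulate`, `callpeaks`, `scan` and
`footprint` subcommands ships in `inst/cli/ftcooc`.

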