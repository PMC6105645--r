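---
title: "Footprinting and co-occupancy: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Footprinting and co-occupancy: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models in `ftcooc`, the
assumptions behind the synthetic data generator, and the design choices
made where the design was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The footprint mixture model

Each candidate motif site $i$ (a PWM hit of width $W$) contributes a
vector of cut counts $x_i$ over the $P = W + 2L$ positions of its window
(motif core $\pm L$, default $L = 100$ bp; minus-strand rows are reversed
so position 1 is always the 5′ flank end). Writing $t_i = \sum_j x_{ij}$,
the two-component model is

* **bound**: $t_i \sim \mathrm{NB}(\mu_b, \alpha_b)$ and
  $x_i \mid t_i \sim \mathrm{Multinomial}(t_i, \lambda)$ with a free
  positional profile $\lambda$;
* **unbound**: $t_i \sim \mathrm{NB}(\mu_u, \alpha_u)$ and
  $x_i \mid t_i \sim \mathrm{Multinomial}(t_i, \mathrm{uniform})$;
* **prior**: $\mathrm{logit}\,P(\text{bound}_i) = \beta_0 + \beta_1 s_i$,
  where $s_i$ is the site's min–max relative PWM score.

NB variance is parameterized as $\mu + \alpha\mu^2$. The EM fit
(`fit_centipede`) alternates exact posteriors with: closed-form $\lambda$;
weighted NB fits where the mean is the weighted average (its MLE at any
dispersion) and the dispersion maximizes the weighted log-likelihood on
$[10^{-3}, 10^{3}]$ by 1-D search; and a weighted logistic regression for
$\beta$ (fractional responses, linear predictor capped at $\pm 30$).
Every step is an exact (or ascent) M-step, so the log-likelihood trace is
non-decreasing — asserted numerically on every fit in the test suite.
Convergence: relative log-likelihood change $< 10^{-6}$ or 200 iterations.

**Profile binning.** By default $\lambda$ is constrained piecewise-constant
over 4-bp bins (`bin_width = 4`; `1` recovers the unconstrained model).
The original genome-wide setting fits a free per-base profile from tens of
thousands of sites; at desk scale (hundreds of sites) the per-base profile
is dominated by estimation noise, and because per-base counts are
overdispersed relative to the multinomial, that noise makes posteriors
overconfident — a few percent of truly unbound sites of sparsely bound TFs
exceed posterior 0.99, which then inflates the co-occupancy background
null. Binning is still a multinomial (so the EM ascent guarantee is
untouched), resolves the ~10 bp flank / 12 bp core structure, and removed
essentially all such false positives in the synthetic experiments encoded
in `test-footprint.R` and `test-acceptance.R`.

**Identification and degenerate inputs.** Posteriors are initialized from
the total-count upper quartile (0.9 above, 0.1 below); after convergence
the component with the larger NB mean is reported as "bound" (footprinted
sites sit in accessible DNA). If every row and score is identical the fit
converges with all posteriors equal — no error. Sites whose window leaves
the chromosome are dropped, not clipped, keeping the matrix rectangular.
A site is a "deep footprint" when its posterior reaches the calling
threshold; 0.99 by default. The published pipeline reports only that
default thresholds were used, so 0.99 is an adopted, configurable default.

**Strand pooling.** Cut counts are strand-pooled; whether the original
analysis used strand-separated profiles is not recoverable, and pooling is
the smaller model.

## 2. Peak calling

`call_peaks` is a deliberately simplified stand-in for MACS2 on cut-count
tracks (point events, so no fragment model or shifting): windows of 300 bp
every 100 bp are tested with an upper-tail Poisson p-value against
$\lambda_{\text{local}} = \max(\text{genome rate}, \text{1 kb rate},
\text{10 kb rate}) \times \text{window}$, BH-corrected over all tested
windows in the run (single global FDR, matching `-q` semantics; threshold
0.01). Significant windows at most 100 bp apart merge; the summit is the
leftmost per-base maximum (determinism tie-break); fold enrichment is
observed/expected in the significant window containing the summit. The
BH step makes the caller conservative under the global null — the
acceptance suite checks zero peaks on homogeneous Poisson(1) tracks in
≥ 45/50 seeds and full recovery of a planted 10× segment.

## 3. Scanning and over-representation

PWMs store base probabilities; JASPAR count matrices get a uniform Laplace
pseudocount of 0.25 per base, Cis-BP probability matrices are floored at
$10^{-4}$ and renormalized. Scores are log₂-odds against a uniform
background (the published background composition is unstated; uniform is
the default and the background is a parameter of `new_pwm`). The
"matrix score threshold of 90%" is implemented as the min–max relative
score, matching oPOSSUM's definition; `N` bases contribute zero so windows
spanning assembly gaps are not discarded. Overlapping same-TF hits are
greedily pruned keeping the higher score (scores quantized to 9 decimals
for ordering; leftmost, then `+` strand, on ties), preventing one
biological site from being counted twice.

`enrich_promoters` applies the published oPOSSUM parameters: promoters
−1000/+300 around the TSS (deliberately distinct from the footprinting
module's −2000/+300 — both are parameters), 8-bit minimum total
information content, relative score ≥ 0.90, results sorted by the
nucleotide-rate Z-score
$z = (h_f - n_f r_b) / \sqrt{n_f r_b (1 - r_b)}$ with a flag at $z \ge
10$, plus a one-sided Fisher exact test on the 2×2 gene-hit table
(upper-tail hypergeometric; an independent direct-summation oracle checks
it to $10^{-12}$ in the tests). The oPOSSUM conservation filter
(cut-off 0.40) is omitted: it requires multi-species alignments the
package does not model.

## 4. Co-occupancy statistics

A TF *occupies* a region when at least one of its bound calls overlaps it
by ≥ 1 bp. The headline statistic is the percentage of focal-occupied
regulatory regions also occupied by the partner. The null is the mean and
sample SD ($n-1$; the panel is a sample of possible background factors)
of the focal TF's co-occupancy with ~10 background TFs;
`enrichment_summary` reports fold = rate/mean and z = (rate − mean)/SD
unrounded, propagating undefined inputs as flagged `NA`s, never silent
zeros. Gene categories follow the two-category scheme: a gene is
focal-and-partner when both TFs are footprinted anywhere in its
promoter/enhancer regions (gene-level union, "irrespective of binding
distance"); region-level co-presence is computed separately because the
co-occupancy rate is defined over regions. Both statistics are exposed.
`age_contrast` reports percentage declines as $100(y - o)/y$ with both
unrounded and nearest-integer-rounded figures, deriving co-occupied gene
counts as $n \cdot \text{rate}/100$ only when integer counts are not
supplied.

## 5. The synthetic world

The generator emulates the statistical structure the analysis runs on,
not the sequence biology of a real genome:

* One chromosome (default 4 Mb) tiled with 680 gene cassettes — a
  promoter (−2000/+300, 2300 bp) followed by a 3 kb body — with
  randomized gaps; 340 bodies carry a 1 kb intragenic enhancer. The
  default sizes make ~1020 regulatory regions, giving the focal TF ~500
  candidate sites (the scale the footprint-recovery acceptance criterion
  presumes).
* A TF panel of a focal factor, a partner, and 10 background factors.
  Each TF plants one motif instance (12 bp, drawn from its PWM columns,
  consensus probability 0.85) per region with probability 0.5. Site
  *presence* is decoupled from *binding* so unbound motifs exist as hard
  negatives. Sites sit ≥ 104 bp from region edges (the footprint window
  stays on the flat peak plateau) and ≥ W+113 bp from each other (one
  site's window never covers another site's perturbed zone; without this,
  neighbouring bound sites induce correlated false-positive calls that
  inflate the co-occupancy null). Where a small region has fewer slots
  than sampled instances, the excess is dropped uniformly at random.
* Binding: the focal TF binds a sited region with marginal probability
  0.3 at "P0" and 0.15 in "adult" (the halving mirrors the reported
  age decline in focal footprints); background TFs bind at 0.05. A
  fraction `co_subset_frac` of focal-bound regions is flagged
  growth-relevant; there the partner binds with probability
  `rho_co` (default 0.6) instead of its marginal 0.05 — co-occupancy is
  planted at the region level, not via inter-site distance, matching the
  region-level statistic. `co_subset_frac = 0.6` was fixed ex ante by a
  power calculation: with ~150 focal-bound regions the expected fold is
  $\approx 0.6\,\rho_{co}/0.05 \cdot \ldots \approx 7.6$, comfortably
  above the fold > 5 power condition, while keeping co-occupied genes a
  strict subset of the focal network as described for the growth-relevant
  subnetworks.
* Cut tracks: per-base negative binomial (dispersion 0.25; ATAC counts
  are overdispersed) with mean 0.2 cuts/bp outside regions, ×8 inside
  regulatory regions, ×0.2 over bound motif cores and ×2.0 over their
  ±10 bp flanks. No quantitative footprint shape is published for this
  setting; depletion/boost are free parameters chosen for clear
  separation, and the parameter-recovery test checks the fitted profile
  reproduces the configured depletion within ±25%.
* Everything derives deterministically from `(config, seed)`;
  regeneration is byte-identical.

**What a green test does not establish.** The generator has no Tn5
sequence bias, no fragment-length structure, no accessibility
heterogeneity between regions, no overlapping or nested genes, and
plants at most one site per TF per region. Real footprint inference is
harder on all those axes; the suite establishes correctness of the
implemented statistics and the qualitative recoverability of planted
structure, not genome-scale performance numbers. Correspondingly, the
published genome-scale figures (692 genes, 6.5%, 0.4%) depend on the real
ENCODE dataset and Cis-BP motifs and are reproduced only as arithmetic
identities, not re-derived.

## 6. Numerical conventions

* Coordinates 0-based half-open everywhere internally; 1-based only in
  prose.
* PWM columns sum to 1 within $10^{-6}$; every entry strictly positive.
* Poisson tails via `stats::ppois(q-1, lower.tail = FALSE)`; tested
  against direct summation to $10^{-10}$ relative.
* EM tolerance $10^{-6}$ relative; trace asserted non-decreasing within
  $10^{-6}$ absolute.
* Summits, pruning and truncation all have deterministic leftmost /
  quantized-score tie-breaks so reruns are byte-identical.
* Report JSON is written with full precision (`digits = NA`) for
  byte-stable reruns.

## 7. Known limitations

* The footprint model pools strands and uses a single prior covariate
  (PWM relative score); conservation and TSS-distance covariates of the
  original genome-wide model are out of scope.
* The peak caller is not MACS2: no control tracks, paired-end model, or
  broad peaks.
* Enhancer–gene assignment is containment plus a nearest-TSS fallback
  within 100 kb; distal linkage by chromatin contact is out of scope.
* The all-vs-all TF co-occupancy matrix is supported only through the
  focal-centric interface.
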