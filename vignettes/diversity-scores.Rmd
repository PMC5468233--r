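---
title: "Quantifying intra-tumour heterogeneity from a single SNP-array sample"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra-tumour heterogeneity from a single SNP-array sample}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpdiv)
```

## The problem

Intra-tumour heterogeneity (ITH) — the coexistence of genetically distinct
subclones within one tumour — fuels drug resistance, yet the multi-region
sampling that measures it directly is rarely available. A single SNP-array
sample, by contrast, is routine: after segmentation by an allele-specific
caller (ASCAT-style output) it provides, per segment, a logR value (log2
ratio of observed to expected total copy number) and a B-allele frequency
(BAF). `snpdiv` estimates clonal diversity from that single sample, without
requiring absolute or allele-specific copy-number calls.

The intuition: segments sharing one clonal copy-number state share one
(logR, BAF) signature, so a clonal genome concentrates into a few "peaks".
Subclonal alterations are carried by only a fraction of cells, produce
intermediate signals, and appear as outliers away from the peaks.

## The two scores

**S — entropy of binned logR.** Segmented logR values of the retained
segments are grouped into $n$ equally sized bins spanning the observed range
(bin width $(\max - \min)/n$, lowest bin anchored at the observed minimum).
With $p_i$ the proportion of *segments* (not base pairs) in bin $i$,

$$S = -\sum_{i=1}^{n} p_i \ln p_i .$$

$S \in [0, \ln n]$; subclonal outliers occupy extra bins and raise it.

**R — spatial homogeneity of the (logR, mBAF) pattern.** BAF is mirrored
about 0.5 (`mBAF = 0.5 + |0.5 - BAF|`) to cancel the arbitrary A/B
labelling. logR and mBAF are each linearly rescaled to $[0,1]$ and every
segment becomes a point on the unit square. Ripley's K, with $\lambda$ the
window area (1 here), $d_{ij}$ the pairwise distance and $e_{ij}$ the
isotropic edge-correction weight,

$$K(r) = \frac{\lambda}{n(n-1)} \sum_{i \neq j} I(d_{ij} \le r)\, e_{ij},
\qquad L(r) = \sqrt{K(r)/\pi},$$

measures clustering at radius $r$: under complete spatial randomness (CSR)
$L(r) \approx r$. The score sums the signed deviations over a fine radius
grid,

$$R = \sum_{r \in \{0,\, \Delta,\, \ldots,\, r_{max}\}} \big(L(r) - r\big),$$

so tightly clustered clonal patterns give large positive $R$ and scattered
subclonal outliers drive it down: **lower R means more diversity**.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_bins` | 10 (12 recommended for real data) | logR bins for S; more bins resolve finer outliers but thin the counts |
| `r_max` | 0.05 | maximum Ripley radius on the unit square; small values restrict attention to same-state clusters |
| `r_step` | 0.001 | radius increment; the grid includes both endpoints (51 radii by default) |
| `min_probes` | 100 | probe-count filter; shorter segments carry unreliable logR/BAF |

The bin/radius defaults come from a calibration on synthetic and cell-line
mixtures: correlation with true diversity improves with more bins and
degrades with larger radii, and 12 bins / 0.05 radius is the recommended
compromise for real cancer data. `calibration_sweep()` re-runs that analysis
(bins 6–24 in steps of 2; radii 0.025, 0.05, 0.075, 0.1, 0.15, 0.2, 0.25)
on any simulated cohort.

```{r score-demo}
profile <- snp_profile("demo", data.frame(
  chromosome = 1L,
  start_bp = seq(1, by = 2e6, length.out = 8),
  end_bp = seq(2e6, by = 2e6, length.out = 8),
  n_probes = 1500L,
  logR = c(0, 0, 0, 0.58, 0.58, -0.5, 0.2, 0.3),
  baf = c(0.5, 0.5, 0.5, 0.33, 0.33, 0.2, 0.45, 0.4)))
score_profile(profile, score_params(n_bins = 10))
```

## What the simulator emulates

`simulate_cohort()` reproduces, end to end, a generative benchmark in which
true clonal diversity is known:

1. **Sets.** Each "set" mimics a cancer-type cohort: baseline-state
   probabilities over (1,1)/(2,1)/(2,2) (Dirichlet-perturbed per set around
   0.65/0.10/0.25), a per-set mean percentage of genome altered drawn from
   U(0.10, 0.40) with sd half the mean, 22 alternative Poisson segmentations
   per chromosome (hg19 autosomes, 25 Mb mean segment length, probes at
   1/1.2 kb), and a catalogue of 2,000 deviant (state, length) entries over
   states (0,0)–(4,4) with log-uniform lengths 0.1–200 Mb.
2. **Clones.** A clone draws its baseline `B` and target altered fraction
   `P ~ N(set mean, set sd)` clamped to ≥ 2%, assembles its genome from one
   template per chromosome, and accumulates randomly chosen segments into
   the altered set until their length exceeds 95% of `P` × genome; each
   receives a catalogue state ≠ `B` length-matched within ±25% (tolerance
   doubling with a warning if the catalogue has no match).
3. **Subclones.** Four per ancestor, sharing its breakpoints, each diverging
   on a fraction `~ N(15%, 5%)` (floor 1%) of the genome, re-assigned by the
   same accumulation rule against the ancestor's states.
4. **Mixtures.** Ordered clone combinations (5 singles, 20 pairs, 60
   triples, 100 sampled 4-tuples and 5-tuples = 285) crossed with
   per-size frequency assortments (1/3/4/4/4) give 1,105 designs per group;
   true diversity is the Shannon index of the frequencies. Per segment the
   mixture's real-valued allele copies are frequency-weighted sums; at
   cellularity $C$ the noiseless channels are
   $L(s) = \log_2\!\big((N C + 2(1-C))/2\big)$ and
   $mB(s) = 0.5 + \big|0.5 - \frac{N_b C + (1-C)}{N C + 2(1-C)}\big|$
   (ratio fixed at 0.5 for bi-allelic loss), plus independent N(0, 0.02)
   noise per channel. Integer CN for the percentage-of-genome-altered
   control is each allele rounded half-away-from-zero, order-normalised.

The default full design (16 sets × 10 groups × 1,105 designs × 4
cellularities) spans 707,200 mixtures; all scales are arguments.

**What it does not emulate.** Real per-cancer-type distributions of segment
boundaries, baseline states and deviant lengths (the stand-ins above are
smooth parametric choices); probe-level noise, wave artifacts and
segmentation error (noise is i.i.d. Gaussian on segment summaries); sex
chromosomes; and sub-2% events. Passing benchmarks therefore show the
scores behave as designed under the stated generative model — they do not
certify accuracy on any particular real cohort, where cellularity and
CNA-burden confounding are stronger.

## Numerical choices and degenerate inputs

- Bin assignment is left-closed/right-open with the top edge closed, so the
  maximum logR lands in bin $n$ and proportions always sum to 1.
- If all retained logR values coincide, S is 0; `unit_normalise()` maps a
  degenerate range to 0.5 so the point pattern stays defined.
- The edge weight $e_{ij}$ is the reciprocal of the circle fraction inside
  the unit square — closed form from the two nearest sides for $d < 0.5$,
  exact arc-union geometry beyond.
- Duplicate points are retained; coincident pairs contribute from $r = 0$.
- The radius grid includes both endpoints (0 and `r_max`).
- $L = \sqrt{K/\pi}$ is slightly biased low at radii where pairs are rare
  (Jensen's inequality), so the CSR expectation of R is a small negative
  number (≈ −0.02 at n = 200), not exactly 0.
- Baseline-state ties break towards the smaller total, then smaller major,
  copy number; allele states are order-normalised (major ≥ minor) before
  comparison.
- Samples with no (S) or fewer than two (R) retained segments raise a typed
  "unscorable" condition; batch interfaces convert it to an `NA` row with a
  reason, never a silent zero.
- Floors on the altered fraction (2%) and divergence (1%) are enforced by
  clamping the normal draw rather than resampling — the simplest reading of
  a minimum acceptable value — and deviant-state draws use the catalogue
  with replacement.
- Every stochastic stage seeds from a named sub-stream of one master seed,
  so any mixture is individually reproducible.

## Benchmark analyses

`benchmark_scores()` reports, per set, the AUC (Mann–Whitney, ties 0.5) for
classifying mixtures as polyclonal versus monoclonal — S and percentage of
genome altered oriented as-is, R negated — within each cellularity and with
all cellularities pooled, plus median-mode and all-points regressions of
each score on true diversity. Medians regressions group mixtures by
diversity level and fit the per-level medians; the all-points fit is
expected to be far weaker since individual mixtures scatter widely. The
orientation is fixed rather than `max(AUC, 1 - AUC)` because each score's
expected direction is part of its definition; p-values are reported but
never used for gating, and no multiple-testing correction is applied.

At desk scale the shipped tests exercise a 2-set × 10-group cohort
(88,400 mixtures, a few minutes on one CPU) and `scripts/acceptance.R` a
4-set × 10-group cohort (176,800 mixtures, under ten minutes); both state
their sizes explicitly and scale linearly.

```{r benchmark-demo, eval = FALSE}
cohort <- simulate_cohort(seed = 1, n_sets = 2, n_groups = 10)
bm <- benchmark_scores(cohort$rows)
bm          # median per-set AUCs and median-mode fits
plot(bm)    # per-set AUC distributions by score and cellularity stratum
```

## Known limitations

- Both scores rise with total CNA burden regardless of clonality: a highly
  altered but clonal genome can mimic a diverse one. The percentage of
  genome altered is computed alongside as the standard control.
- Cellularity compresses logR towards 0 and BAF towards 0.5; the built-in
  range normalisations mitigate but do not remove this, and pooling samples
  of heterogeneous cellularity weakens both scores — quantified by the
  per-stratum versus pooled AUC tables.
- A single biopsy can miss spatially separated subclones entirely, and
  array-resolution data cannot see subclones without private copy-number
  alterations.
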