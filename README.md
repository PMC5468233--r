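# snpdiv

Intra-tumour genetic heterogeneity (ITH) — the coexistence of distinct
subclones in one tumour — drives resistance and relapse, but the multi-region
sampling that measures it directly is rarely available. `snpdiv` estimates
clonal diversity from a **single segmented SNP-array sample** (the
tab-separated segment tables produced by allele-specific copy-number callers
such as ASCAT), for cancer genomicists who want an ITH estimate from routine
single-sample data. It also ships the generative simulator and benchmark
harness used to validate the scores against mixtures of known diversity.

## The scores

Segments that share a clonal copy-number state share a (logR, BAF)
signature; subclonal alterations produce intermediate outliers. Two scores
quantify this, computed on segments with ≥ 100 probes:

- **S** — Shannon entropy of segmented logR values grouped into *n* equally
  sized bins over the observed range (*p*<sub>i</sub> = proportion of
  segments in bin *i*):

  S = −Σ<sub>i</sub> *p*<sub>i</sub> ln *p*<sub>i</sub>,  S ∈ [0, ln *n*].

- **R** — each retained segment becomes a point (unit-normalised logR,
  unit-normalised mirrored BAF) on the unit square; with Ripley's
  K(r) = λ/(n(n−1)) Σ<sub>i≠j</sub> I(d<sub>ij</sub> ≤ r) e<sub>ij</sub>
  (λ = window area, e<sub>ij</sub> = isotropic edge-correction weight) and
  L(r) = √(K(r)/π),

  R = Σ<sub>r ∈ {0, 0.001, …, r<sub>max</sub>}</sub> (L(r) − r).

  Clonal clustering makes R large and positive; subclonal scatter lowers it,
  so **lower R means more diversity**.

Higher S and lower R both indicate more heterogeneity. The percentage of
genome altered (bp fraction off the modal allele-specific state) is computed
alongside as the standard burden control.

## Worked example

```r
library(snpdiv)
profile <- snp_profile("demo", data.frame(
  chromosome = 1L,
  start_bp = seq(1, by = 2e6, length.out = 8),
  end_bp   = seq(2e6, by = 2e6, length.out = 8),
  n_probes = 1500L,
  logR = c(0, 0, 0, 0.58, 0.58, -0.5, 0.2, 0.3),
  baf  = c(0.5, 0.5, 0.5, 0.33, 0.33, 0.2, 0.45, 0.4)))
score_profile(profile, score_params(n_bins = 10))
#> <score_panel> demo: S = 1.4942, R = 9.6004, pga = NA (8 segments, 10 bins, r_max 0.050)
```

Five diploid-like segments plus three outliers occupy several logR bins
(S = 1.49 of a possible ln 10 ≈ 2.30) while the three clonal clusters still
dominate the point pattern (R = 9.6, well above the ~0 expected for a
scattered pattern); `pga` is `NA` because no integer copy numbers were
supplied. For files on disk use `read_segments()` +
`score_profiles()`, or the CLI: `inst/cli/snpdiv score --segments FILE
--out scores.tsv` (defaults: 12 bins, r_max 0.05, 100-probe filter).

The synthetic benchmark end to end:

```r
cohort <- simulate_cohort(seed = 1, n_sets = 2, n_groups = 10)  # 88,400 mixtures
bm <- benchmark_scores(cohort$rows)   # per-set AUCs + diversity regressions
plot(bm)
```

See `vignettes/diversity-scores.Rmd` for the model, the generator's
assumptions, and every numerical choice.

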