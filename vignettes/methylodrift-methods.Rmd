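---
title: "Methods: longitudinal differential methylation with methylodrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal differential methylation with methylodrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylodrift)
```

## The model

The data are methylation proportions (beta values) at `p` CpG probes in
repeated blood samples from `n` individuals, each sampled at a subset of
fixed ages. Betas are bounded and heteroskedastic, so all modelling
happens on the M scale, `M = log2(beta/(1-beta))`: `beta_to_m()` /
`m_to_beta()` are exact inverses away from the clipping bounds, and a
beta of 0.50 sits at M = 0.

For probe `g` we fit, by ordinary least squares,

$$ M_{g,is} = \mu_g + \alpha_{g,a(s)} + u_{g,i} + \varepsilon_{g,is}, $$

with age `a(s)` a **categorical** factor over the visit ages and
individual `i` a **fixed block**. Age is categorical because the target
quantity is a factor-level contrast — methylation at the last age minus
the first (`logfc`) — not a slope; no shape of the trajectory is assumed.
Individual enters as fixed effects rather than random intercepts: with
tens of samples and thousands of probes, per-probe mixed models are
expensive and fragile, while fixed blocks absorb the repeated-sampling
correlation at the cost of a few degrees of freedom. An auxiliary F-test
on the individual block is reported per probe (`p_individual`) to
characterize which CpGs also carry individual signatures, but it never
excludes a probe.

All probes share one design, so the QR decomposition, the residual
degrees of freedom `d = n_samples - rank`, and the contrast
standard-error factor `c = sqrt(c' (X'X)^{-1} c)` are computed once.
Rank-deficient designs fall back to a pseudoinverse and are flagged.

### Variance moderation

Per-probe residual variances `s_g^2` with few degrees of freedom are
noisy; empirical-Bayes moderation borrows strength across probes. We
model `s_g^2 | sigma_g^2 ~ sigma_g^2 chi^2_d / d` with a scaled inverse
chi-square prior `(d_0, s_0^2)` on `sigma_g^2`, and estimate the prior by
the method of moments on the log variances: with
`e_g = log s_g^2 - psi(d/2) + log(d/2)` (`psi` the digamma function),

* `E[e_g] = log s_0^2 + psi(d_0/2) - log(d_0/2)`
* `Var[e_g] = psi'(d/2) + psi'(d_0/2)`.

The excess of the empirical variance of `e_g` over the known sampling
term `psi'(d/2)` is inverted through the trigamma function (Newton
iteration, `trigamma_inverse`) to give `d_0`. When the excess is
non-positive — no detectable dispersion of the true variances — the prior
is degenerate: `d_0 = Inf` and `s_0^2 = mean(s_g^2)`. Probes with zero
variance (all-constant values) are kept in the analysis but excluded
from prior estimation.

The moderated statistic is

$$ \tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}, \qquad
   t_g = \frac{\mathrm{logfc}_g}{\tilde s_g\, c}, $$

referred to Student's t with `d_0 + d` degrees of freedom. Setting
`d_0 = 0` recovers the classical contrast t exactly (a test pins this to
1e-10); `d_0 = Inf` gives full shrinkage to `s_0^2`. Significance is
declared at Bonferroni-corrected p < `alpha` (default 0.01), and the sign
of `logfc` splits the calls into age-methylated and age-demethylated
sites.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `alpha` | 0.01 | corrected p | conservative family-wise control for a catalogue intended to be robust |
| `contrast_ages` | first vs last observed | months | the widest window maximizes the planted/true contrast; configurable |
| `maf_threshold` | 0.01 | allele frequency | a SNP in the probe body distorts hybridization; strictly-above rule, so MAF = 0.01 is retained |
| `min_cpgs` (regions) | 2 | probes | two concordant sites is the weakest evidence of a spatially coherent effect; no maximum span is imposed because region length is genuinely variable (tens of bp to hundreds of kb) |
| enrichment rule | k ≥ 5, p < 0.01, BH < 0.05 | — | the overlap floor prevents small-set artifacts; BH controls FDR across sets |
| `eps` (clipping) | 0.001 | beta | keeps the logit finite; clipped entries are counted and reported |

Both the Yates-corrected and uncorrected chi-square are first-class in
`chi2_2x2()` (default: corrected, the conventional choice for 2x2
tables). Published contingency statistics in this literature mix the two
variants, so the variant is always explicit in results.

## What the generator emulates — and what it does not

`generate_dataset()` draws M values as
`mu_g + beta_g g(age) + u_i + eps` where:

* `g(age)` is linear in `log2(age)`, normalized so
  `g(60) - g(3) = 1`. Early-childhood methylation trajectories are
  smooth, monotone and front-loaded into infancy; log-age encodes that
  without committing to a mechanistic form. The normalization makes the
  planted first-to-last change exactly `effect_delta_m`.
* Baselines `mu_g` come from a bimodal mixture (peaks near M = ±3),
  mimicking the characteristic two-humped beta distribution of
  methylation arrays.
* `u_i ~ N(0, sigma_individual^2)` is a per-individual offset;
  residuals are exchangeable `N(0, sigma_resid^2)`. Within-individual
  autocorrelation beyond the offset is **not** simulated — nothing in the
  emulated design identifies it.
* SNP-affected probes get a per-individual genotype drawn under
  Hardy-Weinberg at a tabulated MAF, mapped to three baseline M levels
  1.5 M apart (heterozygote midway), constant over time: trimodal across
  individuals, flat within.
* Cell-confounded probes load (coefficient 2–4 M, either sign) on a
  granulocyte fraction `0.35 + 0.25 g(age) + noise` — confounding that
  *mimics* an age effect, which is exactly why the classifier filter
  exists.
* Dropout removes interior visits at random (never an individual's first
  or last visit, keeping the contrast estimable per individual); the
  interior removal probability is scaled so the *overall* expected
  removed fraction equals `dropout_rate`.

Defaults are the study conditions used throughout validation: 10
individuals at 3, 6, 12, 24, 36, 48, 60 months, 15% dropout (about 60 of
70 planned samples), 2000 probes with 5% + 5% planted age effects of
ΔM = 2, 2% SNP-affected, 2% cell-confounded, and
`sigma_resid = sigma_individual = 0.5`.

Not simulated: array chemistry and detection p-values, batch/chip
effects, sex chromosomes, cross-hybridizing probes, and any real
linkage between annotation context and effect direction (island vs
open-sea probes are equally likely to carry planted effects). Passing
tests therefore demonstrate that the machinery is correct and calibrated
under the stated generative model — not that the pipeline overcomes
artifacts the generator does not produce. The manifest generator does
emulate the structural features downstream code must handle: multi-gene
(isoform) annotations restricted to local (< 1 Mb) neighbours on a
clustered gene model, intergenic probes, strand, and the island-relation
vocabulary.

## Numerical choices and edge cases

* Quantile normalization runs on the **beta** scale, before the M
  transform (the transform is monotone, so ranks are unchanged; doing it
  on the bounded scale keeps the target distribution interpretable). Ties
  within a column receive the mean of the target values they span;
  normalization is idempotent.
* Missing matrix cells are rejected by default; an explicit
  `impute = TRUE` substitutes column medians and counts the imputations.
  The linear model itself never sees missing values.
* Betas are clipped to `[0.001, 0.999]` before any logit; the clipped
  count is attached to the result.
* In `nearest_tss()`, exact distance ties are broken toward the gene the
  probe is upstream of, then alphabetically — deterministic by
  construction. Distance bins are half-open on absolute distance:
  `[0,5)`, `[5,50)`, `[50,500)`, `[500,1000]` kb; beyond 1,000 kb a probe
  is flagged `no_tss`.
* Region spans use **probe** coordinates (max − min member position), not
  gene coordinates; "the same locus" means the same annotated gene
  symbol, so intergenic probes never form regions and a probe annotated
  to two genes can support two regions.
* The filters run **after** significance calling and only prune the
  called set; the enrichment universe remains all genes on the manifest —
  the reproducible choice, since tool-default universes are opaque.
* Degenerate moderated-t cases: zero posterior variance with a non-zero
  contrast gives p = 0 and a `degenerate` flag; with a zero contrast,
  t = 0.
* Pipeline reruns under the same config are bit-identical; the summary
  carries a content hash of the configuration.

## Problem sizes

Validation runs use the design above (2000 probes × ~60 samples), 5000
draws for prior-recovery checks, and 2000 null probes for the
permutation calibration — sizes at which the whole suite completes in
seconds while leaving the statistical checks well-powered (for the
planted ΔM = 2 against a contrast standard error near 0.22 M, the
expected |t| is far past any Bonferroni threshold, so sensitivity is
expected to be essentially 1 and observed false positives essentially 0).

## Known limitations

* Fixed-block individual effects cost degrees of freedom relative to a
  random-intercept model and do not generalize to unseen individuals;
  they are the deliberate, cheap, robust choice here.
* The method-of-moments prior assumes the scaled-chi-square model for
  variances; heavy-tailed variance distributions will push `d_0` down
  rather than break, but no robust/trended moderation variant is
  implemented.
* Whole-blood cell-composition confounding is *filtered* (classifier
  list), not *adjusted* (no deconvolution); confounded probes missing
  from the classifier list will surface as false positives, as the
  generator demonstrates.
* The SNP filter applies one MAF rule to all in-probe SNPs regardless of
  their distance to the query site.
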