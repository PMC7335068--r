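---
title: "Polygenic architecture from summary statistics: model, projections, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic architecture from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyarch)
```

## The model

`polyarch` treats the standardized log-odds-ratio of each common SNP in a
case-control GWAS as a draw from a spike-and-slab normal mixture:

\[
\beta_m \sim (1-\pi_c)\,\delta_0 + \pi_c \sum_h p_h\,N(0, \sigma_h^2),
\]

with one causal component in the two-component model and two (variances
sorted ascending) in the three-component model, which accommodates a
minority of loci with much larger effects. Three summaries follow directly:

* **polygenicity** \(M\pi_c\) — the expected number of independently
  associated susceptibility SNPs among the \(M\) reference-panel SNPs;
* **GWAS heritability** \(h^2 = M\pi_c\,\mathrm{E}(\beta^2)\), with
  \(\mathrm{E}(\beta^2)=\sum_h p_h\sigma_h^2\) — the variance of the true
  polygenic risk score \(\mathrm{PRS}=\sum_m \beta_m G_m\) on the log-OR
  scale (standardized genotypes \(G_m\));
* **\(\upsilon = p_2\sigma_2^2 / \mathrm{E}(\beta^2)\)** — the share of
  heritability carried by the larger-variance component.

Estimation uses only summary statistics. For a cleaned SNP the z-statistic
is modelled marginally as

\[
z_m \sim (1-\pi_c)\,N(0,1) + \pi_c \sum_h p_h\,N\!\big(0,\ 1 + n_{\mathrm{eff}}\sigma_h^2\big),
\]

the convolution of the effect-size mixture with the Gaussian sampling noise
of a standardized log-OR (\(\hat\beta = z/\sqrt{n_\mathrm{eff}}\),
\(\tau = 1/\sqrt{n_\mathrm{eff}}\)). Treating SNPs as independent makes this
a composite likelihood; an `ld_score` mode replaces
\(n_{\mathrm{eff}}\sigma_h^2\) by \(\ell_m n_{\mathrm{eff}}\sigma_h^2\) with
per-SNP LD scores. Full LD convolution of the original composite-likelihood
estimator is deliberately out of scope; parameter recovery is therefore
guaranteed only when simulator and fitter use matched LD assumptions, which
is how the test battery exercises it.

**Effective sample size.** Everywhere a formula says "n" the package uses
\(n_{\mathrm{eff}} = 4/(1/n_\mathrm{cases} + 1/n_\mathrm{controls})\)
(so a balanced study of \(N\) cases and \(N\) controls has
\(n_{\mathrm{eff}} = 2N\)). Because the simulator and fitter share the one
constant, recovery results are invariant to this convention.

## Quality control

Four filters run in a fixed order, mirroring standard practice for
summary-level architecture estimation:

1. **Panel restriction** — keep SNPs present in the reference panel with
   MAF > 0.05; records whose alleles are swapped relative to the panel are
   kept with the effect sign flipped.
2. **Sample-size filter** — drop SNPs with per-SNP N strictly below
   0.67 × Q90(N). Q90 uses the nearest-rank convention
   (`ceiling(0.9 k)`-th order statistic); a record exactly at the cutoff
   survives.
3. **MHC exclusion** — chromosome 6, 26–34 Mb inclusive at both ends (the
   conservative reading of "between").
4. **Large-effect extraction** — greedy clumping: repeatedly take the
   largest remaining \(\chi^2 = z^2 > 80\) as an independent top SNP and
   remove everything within 1 Mb or with \(r^2 > 0.1\); ties on \(\chi^2\)
   break toward the smaller genomic coordinate for determinism.

The extracted tops are excluded from mixture fitting — they would otherwise
dominate the fitted variances — and added back to the reported totals:
\(h^2 \mathrel{+}= \sum_i(\hat\beta_i^2 - \tau_i^2)\) (negative terms
clamped at 0 with a warning), susceptibility count
\(\mathrel{+}= |\mathrm{tops}|\). The reported average heritability per
susceptibility SNP, \(\mathrm{E}(\beta^2)\), excludes these extreme SNPs.

Filters are idempotent and the pipeline equals the composition of the four
steps; each step logs its drops so record counts are conserved.

## Fitting and model selection

The likelihood is maximized by BFGS on transformed scales (logit for
\(\pi_c\) and \(p_2\), log for variances; the three-component model
parametrizes \(\sigma_2^2 = \sigma_1^2 + e^{t_4}\) so the ascending-variance
convention is structural). Starting values come from a small grid:
\(\pi_c \in \{10^{-4},10^{-3},10^{-2}\}\), variances matched to the
method-of-moments identity \(\mathrm{E}(z^2) = 1 + \pi_c n \mathrm{E}(\beta^2)\)
(for the three-component model, \(p_2 \in \{0.05, 0.2\}\) with variances at
0.5× and 5× the moment value). Standard errors are delta-method transforms
of the inverse observed information at the optimum; when a fit sits on a
boundary (e.g. a three-component fit collapsing onto two components) the
information matrix can be singular and SEs are reported as `NA` with a
warning rather than fabricated.

Model choice uses BIC with the SNP count as sample size; the
three-component fit must win strictly, so identical likelihoods fall back
to the parsimonious model. The rule is exposed as a function
(`select_model`) rather than hidden in the pipeline.

## Projections

Power of a two-sided Wald test at threshold \(\alpha\) is
\(\mathrm{pow}_{\alpha,n}(\beta) = 1 - \Phi(c_{\alpha/2}-\sqrt n\beta) +
\Phi(-c_{\alpha/2}-\sqrt n\beta)\), \(c_\alpha = \Phi^{-1}(1-\alpha)\).
Expected discoveries and expected variance explained integrate power (and
\(\beta^2\cdot\)power) against the fitted mixture, plus the large-effect
add-back terms \(\sum_i \mathrm{pow}(\hat\beta_i)\) and
\(\sum_i(\hat\beta_i^2-\tau_i^2)\mathrm{pow}(\hat\beta_i)\). Integrals are
evaluated per component after standardizing \(\beta = \sigma_h u\), doubling
the half-line integral (the integrand is symmetric); `stats::integrate`
with relative tolerance `1e-10`. Tests pin these against million-draw
Monte-Carlo oracles.

The variance of a *buildable* threshold-PRS uses
\[
h^2_{\mathrm{PRS}} = \frac{A^2}{A + S/n_{\mathrm{eff}}},
\]
where \(A\) is the expected genetic variance captured by selected SNPs and
\(S\) the expected number selected (non-null discoveries plus
\(M(1-\pi_c)\alpha\) null pass-throughs). The published analytic formula
behind the original projections is not restated in the source material;
this form is the package's declared implementation, and it is validated
against an individual-level simulation oracle rather than against published
curves. It has the right limits: \(h^2_\mathrm{PRS}\le A\le h^2\), \(\to h^2\)
as \(n\to\infty\) at fixed \(\alpha\), \(\to 0\) as \(\alpha\to 0\) at fixed
\(n\). The optimized threshold maximizes it over a log-uniform grid on
\([10^{-12}, 0.5]\) (60 points) that always contains \(5\times10^{-8}\), so
optimization can never lose to genome-wide significance.

`sample_size_for_fraction` inverts the fraction-of-\(h^2\) curve by
doubling-then-bisection (cap \(n_{\mathrm{eff}} = 10^8\)); the "fraction of
heritability identified" criterion is evaluated on the EV/\(h^2\) scale at
the optimized threshold by default (the liberal-threshold reading of the
published projection curves), with a `gws` mode as the alternative, since
the source is ambiguous about which scale its curves use.

## Risk models

Discrimination and tail risk follow from normality of the PRS on the
log-OR scale: \(\mathrm{AUC} = \Phi(\sqrt{h^2_\mathrm{PRS}/2})\) and the
relative risk at the \(q\)-th percentile versus the population average
\(\exp(-h^2/2 + \Phi^{-1}(q)\sqrt{h^2})\). One documented quirk: at the
published ovarian heritability \(h^2=0.24\) the formula gives 2.77, while
the source abstract prints 2.5; the formula as stated is implemented and
the discrepancy left unreconciled.

Absolute risk uses a discrete-time cause-specific life-table recursion on
1-year intervals (SEER-style rates are annual): an individual at
standard-normal PRS quantile \(z\) has incidence hazard
\(\lambda(t\mid z) = \lambda_\mathrm{pop}(t)\exp(\sqrt{h^2}z - h^2/2)\);
the \(-h^2/2\) offset is the rare-disease calibration making the
population-average multiplier exactly 1
(\(\mathrm{E}\,e^{r-h^2/2}=1\) for \(r\sim N(0,h^2)\), verified numerically
in the tests). This replaces the full iterative baseline constraint of
absolute-risk tools such as iCARE; it is exact in the low-incidence limit,
which is the regime of annual cancer incidence rates. Residual lifetime
risk to age 80 accumulates \(\lambda(t\mid z)\) against joint survival from
incidence and competing all-cause mortality \(\mu(t)\), with per-interval
probabilities clamped at 1 (with a warning) should a pathological hazard
arise. Risk distributions average over baseline ages in 5-year categories
(lower bounds 30–75, midpoint-age representative) with census-style
weights.

## The synthetic-data generator

Because the real consortium inputs are access-controlled, every stage is
exercised on synthetic data whose structure matches the model:

* **Panel** — ~uniform positions on up to 22 chromosomes, MAF drawn in
  (0.05, 0.5], block-diagonal LD (independent, or AR(1) with correlation
  \(\rho^{|i-j|}\) within fixed-size blocks), and a guaranteed set of SNPs
  inside chr6 26–34 Mb so the MHC filter always has work to do.
* **Effects** — i.i.d. draws from the mixture; component labels retained so
  label frequencies and second moments are testable.
* **Summary statistics** — generated at the z level:
  \(z \sim N(\sqrt{n_\mathrm{eff}}\beta, 1)\) under independence, or block
  means \(R\sqrt{n_\mathrm{eff}}\beta\) with noise covariance \(R\) under
  AR(1) LD. Genotype-level simulation (`simulate_cohort`) is a small-scale
  (\(M\le5000\)) validation mode only.
* **Per-SNP sample sizes** — a fraction `n_jitter` of SNPs report a reduced
  size (\(\times U(0.4,1)\)); the rest report the full total. Real
  meta-analysis sample sizes cluster this way (SNPs are present in fixed
  subsets of cohorts), and the clustering is what makes the 0.67×Q90 filter
  idempotent: after one pass the modal full-N group still anchors Q90. A
  continuous jitter would instead let the recomputed Q90 creep upward on
  each application.
* **Life tables** — ages 30–80 with flat or quadratically increasing
  incidence, increasing mortality, and mildly perturbed decreasing age
  weights summing to 1.

What the generator does *not* emulate: realistic human LD maps, allele
frequency/effect coupling, imputation quality, ancestry structure, or
sample overlap between contributing studies. Passing tests therefore
demonstrate the estimator's correctness under its own sampling model and
the projection formulas' internal consistency — not robustness to the LD
misspecification real data would bring.

## Problem sizes and numerical choices

The test battery fits at \(M = 5\times10^4\)–\(2\times10^5\) SNPs with
\(n_\mathrm{eff} = 10^5\), where the composite likelihood is informative
and a fit takes a few seconds; the parameter-recovery battery runs 50
replicates at \(M=2\times10^5\), \(\pi_c=0.01\), \(\sigma^2=10^{-4}\)
(\(h^2 = 0.2\), in the range of the published per-cancer estimates) and
requires \(\hat h^2\) and \(\hat\pi_c\) within 3 reported SEs of truth in
at least 90% of replicates. Quadrature tolerance is \(10^{-10}\) relative;
optimizer restarts cover the initialization grid; degenerate inputs
(pure-null data, empty large-effect sets, all-missing N) are exercised
explicitly.

## Known limitations

* Composite-likelihood SEs ignore LD-induced dependence between SNPs; on
  real data they would be anti-conservative without LD-aware corrections.
* The \(A^2/(A+S/n)\) PRS-variance form assumes independent selected SNPs
  and ignores winner's-curse effect-size shrinkage in the score weights.
* The rare-disease baseline calibration overstates risk slightly when
  cumulative incidence is large (tens of percent).
* Two- and three-component mixtures cannot represent continuous tails of
  effect-size distributions; \(\upsilon\) is model-dependent.
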