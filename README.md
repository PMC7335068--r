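# polyarch

Estimation of common-variant polygenic architecture from GWAS summary
statistics, and projection of what larger studies — and the polygenic risk
scores (PRS) built from them — would deliver.

`polyarch` is aimed at statistical geneticists and epidemiologists who have
summary-level case-control GWAS data (or want to reason about hypothetical
studies) and ask:

* How many independent susceptibility SNPs underlie this disease, and how
  is their effect-size distribution shaped?
* How much GWAS heritability is there on the log-odds-ratio scale, and how
  much of it would a study of a given size capture?
* What discrimination (AUC), tail relative risk, and absolute lifetime risk
  stratification could the resulting PRS achieve?

## The model

Standardized per-SNP log-odds-ratios follow a spike-and-slab normal
mixture

    beta_m ~ (1 - pi_c) d0 + pi_c [ p1 N(0, s1^2) + p2 N(0, s2^2) ]

(one causal component in the two-component model, two in the
three-component model). Key quantities:

* polygenicity `M * pi_c` — expected number of susceptibility SNPs;
* GWAS heritability `h2 = M * pi_c * E(beta^2)` — the variance of the true
  PRS on the log-OR scale;
* projections at significance threshold `alpha` and effective sample size
  `n_eff = 4 / (1/n_cases + 1/n_controls)`:
  expected discoveries `ED`, expected variance explained `EV`
  (power-weighted integrals over the fitted mixture), the buildable PRS
  variance `h2_PRS = A^2 / (A + S/n_eff)`, `AUC = Phi(sqrt(h2_PRS/2))`,
  and relative risk at the 99th percentile
  `exp(-h2/2 + Phi^-1(0.99) sqrt(h2))`;
* absolute residual lifetime risk to age 80 from age-specific incidence and
  competing mortality, stratified by PRS percentile.

Fitting maximizes the marginal z likelihood
`z ~ (1-pi_c) N(0,1) + pi_c sum_h p_h N(0, 1 + n_eff * s_h^2)` after a
four-step QC (reference-panel restriction with MAF > 0.05, per-SNP
sample-size filter at 0.67 x Q90, MHC exclusion, and greedy clumping of
chi-square > 80 loci, whose contribution `sum(beta^2 - se^2)` is added back
to all totals).

## Worked example

End-to-end on synthetic summary statistics with known truth
(50,000 panel SNPs, `pi_c = 0.01`, `sigma^2 = 2e-4`, so `h2 = 0.1`;
50,000 cases and 50,000 controls):

```r
library(polyarch)

cfg <- run_config(out_dir = "demo",
                  sim = list(m = 50000, pi_c = 0.01, variances = 2e-4,
                             n_cases = 50000, n_controls = 50000,
                             n_jitter = 0.1),
                  n_components = 2L, seed = 7)
bundle <- run_pipeline(cfg)
#> QC: 50000 records in, 46476 out, 3524 dropped, 26 large-effect tops
#> selected model: two-component

bundle$heritability
#> h2 = 0.1010 (SE 0.00579) [mixture 0.0724 + add-back 0.0287]
#> susceptibility SNPs = 571.4 (SE 49.6), 26 large-effect
#> upsilon = 0.000, per-SNP h2 = 0.000133
```

The estimate recovers the generating `h2 = 0.1` within one standard error;
about a quarter of it arrives through the 26 clumped large-effect loci and
their explicit add-back term, mirroring how strong loci are handled for
real traits.

```r
bundle$projections[, c("n_cases","alpha_mode","ED","EV_frac","h2_prs","AUC","RR99")]
#>   n_cases alpha_mode  ED EV_frac h2_prs   AUC RR99
#> 1   5e+04        gws 107   0.661 0.0657 0.572 1.76
#> 2   5e+04  optimized 277   0.912 0.0872 0.583 1.90
#> 3   1e+05        gws 189   0.831 0.0831 0.581 1.88
#> 4   1e+05  optimized 340   0.960 0.0946 0.586 1.95
#> 5   2e+05        gws 276   0.928 0.0931 0.585 1.94
#> 6   2e+05  optimized 402   0.985 0.0981 0.588 1.97
```

Each row is a scenario (current, doubled, quadrupled case counts) at
genome-wide significance or at the PRS-variance-optimizing p-value
threshold: `ED` expected discoveries, `EV_frac` the fraction of `h2`
captured, `h2_prs` the buildable PRS variance with its implied `AUC` and
99th-percentile relative risk. The optimized threshold always captures at
least as much as genome-wide significance, with the gain shrinking as
sample size grows. `run_pipeline()` also writes
`risk_distribution.tsv` — residual-lifetime-risk curves by PRS percentile
for the three scenarios and for the heritability-limited best PRS.

Desk calculations need no simulation at all:

```r
auc_from_h2(c(1.62, 2.81))   # 0.82 0.88  — best-PRS AUC at a given h2
rr_top_percentile(2.81)      # 12.1      — RR at the 99th PRS percentile
```

A thin command-line wrapper with `simulate/qc/fit/project/risk/all`
subcommands ships at `inst/cli/polyarch.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/polyarch.R", package="polyarch"))')" \
    all --m 50000 --n-cases 50000 --n-controls 50000 --seed 7 --out demo
```

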