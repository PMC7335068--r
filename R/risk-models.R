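#' Best-achievable AUC from PRS variance
#'
#' Under a normally distributed PRS on the log-odds-ratio scale with
#' variance `h2`, the area under the ROC curve of the score is
#' `AUC = Phi(sqrt(h2 / 2))`.  With the full GWAS heritability this is the
#' theoretical ceiling for a common-variant PRS; with a projected
#' [prs_variance()] it is the AUC of the buildable score.
#'
#' @param h2_prs PRS variance (log-OR scale), >= 0; vectorized.
#' @return AUC in `[0.5, 1)`.
#' @examples
#' auc_from_h2(c(1.62, 2.81))  # 0.82, 0.88
#' @export
auc_from_h2 <- function(h2_prs) {
  if (any(h2_prs < 0)) stop_arg("h2_prs must be non-negative")
  pnorm(sqrt(h2_prs / 2))
}

#' Relative risk in the upper tail of the PRS distribution
#'
#' Risk for subjects at PRS quantile `q` relative to the population
#' average: `exp(-h2/2 + Phi^{-1}(q) sqrt(h2))`, the ratio of the
#' exponentiated score at its `q`-th quantile to its population mean
#' `E exp(PRS) = exp(h2/2)` under normality.
#'
#' @param h2_prs PRS variance (log-OR scale), >= 0; vectorized.
#' @param q PRS percentile in (0, 1); default the 99th.
#' @return relative risk (1 at `h2_prs = 0`).
#' @examples
#' rr_top_percentile(2.81)  # ~12
#' @export
rr_top_percentile <- function(h2_prs, q = 0.99) {
  if (any(h2_prs < 0)) stop_arg("h2_prs must be non-negative")
  if (q <= 0 || q >= 1) stop_arg("q must be in (0, 1)")
  exp(-h2_prs / 2 + qnorm(q) * sqrt(h2_prs))
}

#' Residual lifetime risk for a given PRS percentile
#'
#' Discrete-time cause-specific risk of developing the disease between
#' `age_start` and age 80, for an individual at standard-normal PRS
#' quantile `prs_z`, under competing all-cause mortality.  The individual
#' hazard is `lambda(t | r) = lambda_pop(t) * exp(r - h2_prs / 2)` with
#' `r = sqrt(h2_prs) * prs_z`; the `-h2/2` offset calibrates the baseline
#' so that the population-average hazard multiplier is 1 (rare-disease
#' approximation, `E exp(r - h2/2) = 1` over `r ~ N(0, h2)`).
#'
#' @param prs_z standard-normal quantile of the PRS (e.g. `qnorm(0.99)`).
#' @param age_start baseline age in `[30, 80)`.
#' @param tables a `life_tables` object.
#' @param h2_prs PRS variance on the log-OR scale.
#' @return probability in `[0, 1]`.
#' @export
residual_lifetime_risk <- function(prs_z, age_start, tables, h2_prs) {
  validate_life_tables(tables)
  if (age_start < 30 || age_start >= 80)
    stop_arg("age_start must be in [30, 80)")
  mult <- exp(sqrt(h2_prs) * prs_z - h2_prs / 2)
  ages <- tables$ages
  surv <- 1
  risk <- 0
  for (t in seq(age_start, 79)) {
    i <- match(t, ages$age)
    lam <- ages$incidence[i] * mult
    if (lam > 1) {
      warning("per-interval incidence probability > 1 at age ", t,
              "; clamped")
      lam <- 1
    }
    mu <- min(ages$mortality[i], 1)
    risk <- risk + surv * lam
    surv <- surv * (1 - lam) * (1 - mu)
  }
  min(risk, 1)
}

#' Distribution of residual lifetime risk across PRS percentiles
#'
#' For each PRS percentile, the residual lifetime risk (to age 80) averaged
#' over baseline ages with the census-style 5-year-category weights in
#' `tables$weights` (each category represented by its midpoint age).
#'
#' @param h2_prs PRS variance on the log-OR scale.
#' @param tables a `life_tables` object.
#' @param percentiles integer percentiles to evaluate (default 1-99).
#' @return data.frame with columns `percentile`, `lifetime_risk`;
#'   nondecreasing in percentile.
#' @export
risk_distribution <- function(h2_prs, tables, percentiles = 1:99) {
  validate_life_tables(tables)
  w <- tables$weights
  mid_age <- floor((w$age_lo + w$age_hi) / 2)
  risks <- vapply(percentiles, function(p) {
    z <- qnorm(p / 100)
    sum(w$weight * vapply(mid_age, function(a)
      residual_lifetime_risk(z, a, tables, h2_prs), numeric(1)))
  }, numeric(1))
  data.frame(percentile = percentiles, lifetime_risk = risks)
}

#' Population marginal residual lifetime risk
#'
#' The baseline-age-weighted residual lifetime risk of a person with no
#' PRS information (`h2_prs = 0`); the mean of [risk_distribution()] over
#' percentiles approximates it when the PRS stratifies risk.
#'
#' @param tables a `life_tables` object.
#' @return probability.
#' @export
marginal_lifetime_risk <- function(tables) {
  validate_life_tables(tables)
  w <- tables$weights
  mid_age <- floor((w$age_lo + w$age_hi) / 2)
  sum(w$weight * vapply(mid_age, function(a)
    residual_lifetime_risk(0, a, tables, 0), numeric(1)))
}
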