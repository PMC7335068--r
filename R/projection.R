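#' Power to detect a standardized log-odds-ratio at threshold alpha
#'
#' Two-sided Wald power for a standardized effect `beta` in a GWAS of
#' effective size `n_eff`:
#' `pow = 1 - Phi(c - sqrt(n) beta) + Phi(-c - sqrt(n) beta)` with
#' `c = Phi^{-1}(1 - alpha/2)`.  Symmetric in the sign of `beta`; equals
#' `alpha` exactly at `beta = 0`.
#'
#' @param beta standardized log-odds-ratio (vectorized).
#' @param n_eff effective sample size.
#' @param alpha two-sided significance threshold in (0, 1).
#' @return detection probability in (0, 1\].
#' @export
gwas_power <- function(beta, n_eff, alpha) {
  if (alpha <= 0 || alpha >= 1) stop_arg("alpha must be in (0, 1)")
  if (n_eff <= 0) stop_arg("n_eff must be positive")
  c_half <- qnorm(1 - alpha / 2)
  s <- sqrt(n_eff) * beta
  pnorm(c_half - s, lower.tail = FALSE) + pnorm(-c_half - s)
}

# integral of f(beta) * pow(beta) against one causal component N(0, s2),
# standardized so the quadrature variable is N(0, 1); f is 1 or beta^2
component_integral <- function(s2, n_eff, alpha, moment = 0,
                               rel.tol = 1e-10) {
  sd_h <- sqrt(s2)
  f <- function(u) {
    w <- gwas_power(sd_h * u, n_eff, alpha) * dnorm(u)
    if (moment == 2) w <- w * (sd_h * u)^2
    w
  }
  # pow is symmetric in beta, so integrate the positive half and double
  r <- integrate(f, 0, Inf, rel.tol = rel.tol, abs.tol = 0,
                 subdivisions = 500L, stop.on.error = FALSE)
  if (r$message != "OK" && r$value > 1e-300)
    stop("quadrature failed: ", r$message)
  2 * r$value
}

large_effect_power <- function(large, n_eff, alpha) {
  if (is.null(large) || nrow(large$top) == 0) return(numeric(0))
  gwas_power(large$top$BETA, n_eff, alpha)
}

#' Expected number of discoveries at a significance threshold
#'
#' `ED = M pi_c sum_h p_h \int pow(beta) N(beta; 0, sigma_h^2) dbeta`
#' plus the add-back `sum_i pow(beta_hat_i)` over the large-effect SNPs.
#' Monotone nondecreasing in both `n_eff` and `alpha`.
#'
#' @param model a `mixture_model` (or `mixture_fit`).
#' @param large a `large_effect_set` or `NULL`.
#' @param n_eff effective sample size of the projected GWAS.
#' @param alpha significance threshold (default genome-wide, 5e-8).
#' @return expected discovery count.
#' @export
expected_discoveries <- function(model, large = NULL, n_eff,
                                 alpha = 5e-8) {
  if (inherits(model, "mixture_fit")) model <- model$model
  mix <- sum(vapply(seq_along(model$weights), function(h) {
    model$weights[h] * component_integral(model$variances[h], n_eff, alpha)
  }, numeric(1)))
  model$M * model$pi_c * mix + sum(large_effect_power(large, n_eff, alpha))
}

#' Expected genetic variance explained at a significance threshold
#'
#' `EV = M pi_c sum_h p_h \int beta^2 pow(beta) N(beta; 0, sigma_h^2) dbeta`
#' plus the add-back `sum_i (beta_hat_i^2 - tau_i^2) pow(beta_hat_i)`.
#'
#' @inheritParams expected_discoveries
#' @return list with `abs` (log-OR-scale variance) and `frac` (fraction of
#'   the total h2 including the large-effect add-back).
#' @export
expected_variance <- function(model, large = NULL, n_eff, alpha = 5e-8) {
  if (inherits(model, "mixture_fit")) model <- model$model
  mix <- sum(vapply(seq_along(model$weights), function(h) {
    model$weights[h] *
      component_integral(model$variances[h], n_eff, alpha, moment = 2)
  }, numeric(1)))
  ev <- model$M * model$pi_c * mix
  h2 <- model$M * model$pi_c * model$e_beta2
  if (!is.null(large) && nrow(large$top) > 0) {
    terms <- pmax(large$top$BETA^2 - large$top$SE^2, 0)
    pw <- large_effect_power(large, n_eff, alpha)
    ev <- ev + sum(terms * pw)
    h2 <- h2 + sum(terms)
  }
  list(abs = ev, frac = if (h2 > 0) ev / h2 else 0)
}

#' Projected variance of a threshold-based PRS
#'
#' The achievable variance of a PRS built from SNPs passing threshold
#' `alpha` in a GWAS of size `n_eff`:
#' `h2_PRS = A^2 / (A + S / n_eff)`, where `A` is the expected genetic
#' variance captured by selected SNPs ([expected_variance()], absolute) and
#' `S` the expected number of selected SNPs (non-null discoveries plus
#' `M (1 - pi_c) alpha` null pass-throughs), whose estimation noise
#' dilutes the score.  Satisfies `0 <= h2_PRS <= EV_abs <= h2` and tends to
#' `h2` as `n_eff` grows at fixed `alpha`.
#'
#' @inheritParams expected_discoveries
#' @return projected PRS variance on the log-OR scale.
#' @export
prs_variance <- function(model, large = NULL, n_eff, alpha = 5e-8) {
  if (inherits(model, "mixture_fit")) model <- model$model
  A <- expected_variance(model, large, n_eff, alpha)$abs
  S <- expected_discoveries(model, large, n_eff, alpha) +
    model$M * (1 - model$pi_c) * alpha
  if (A <= 0) return(0)
  A^2 / (A + S / n_eff)
}

#' Optimize the p-value threshold for PRS construction
#'
#' Maximizes [prs_variance()] over a log-uniform grid of thresholds; the
#' grid always contains the genome-wide-significance point 5e-8, so the
#' optimized PRS variance is never below the genome-wide-significant one.
#'
#' @inheritParams expected_discoveries
#' @param alpha_grid candidate thresholds; default 60 log-uniform points on
#'   `[1e-12, 0.5]` plus 5e-8.
#' @return list with `alpha` (the arg-max), `h2_prs` (its PRS variance) and
#'   `grid` (data.frame of all evaluated points).
#' @export
optimize_threshold <- function(model, large = NULL, n_eff,
                               alpha_grid = NULL) {
  if (is.null(alpha_grid))
    alpha_grid <- 10^seq(-12, log10(0.5), length.out = 60)
  alpha_grid <- sort(unique(c(alpha_grid, 5e-8)))
  v <- vapply(alpha_grid, function(a) prs_variance(model, large, n_eff, a),
              numeric(1))
  i <- which.max(v)
  list(alpha = alpha_grid[i], h2_prs = v[i],
       grid = data.frame(alpha = alpha_grid, h2_prs = v))
}

#' Sample size needed to capture a target fraction of heritability
#'
#' Smallest effective sample size at which the projected fraction of h2
#' (EV/h2 in `"gws"` mode at genome-wide significance, or the optimized
#' PRS variance over h2 in `"optimized"` mode) reaches `fraction`.
#' Doubling search followed by bisection; errors if the fraction is not
#' reached below `n_cap`.
#'
#' @inheritParams expected_discoveries
#' @param fraction target fraction of h2 in (0, 1).
#' @param threshold_mode `"optimized"` (default, the liberal-threshold
#'   reading) or `"gws"`.
#' @param n_cap search ceiling on `n_eff`.
#' @return effective sample size (persons).
#' @export
sample_size_for_fraction <- function(model, large = NULL, fraction,
                                     threshold_mode = c("optimized", "gws"),
                                     n_cap = 1e8) {
  threshold_mode <- match.arg(threshold_mode)
  if (fraction <= 0 || fraction >= 1) stop_arg("fraction must be in (0, 1)")
  if (inherits(model, "mixture_fit")) model <- model$model
  h2 <- total_heritability(model, large)$h2
  if (h2 <= 0) stop_arg("model has zero heritability")
  g <- function(n) {
    if (threshold_mode == "gws") {
      expected_variance(model, large, n, 5e-8)$abs / h2
    } else {
      optimize_threshold(model, large, n)$h2_prs / h2
    }
  }
  lo <- 1000
  hi <- lo
  while (g(hi) < fraction) {
    hi <- hi * 2
    if (hi > n_cap)
      stop("fraction ", fraction, " not reachable below n_eff = ", n_cap)
  }
  if (hi == lo) return(lo)
  lo <- hi / 2
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (g(mid) >= fraction) hi <- mid else lo <- mid
    if ((hi - lo) / hi < 1e-4) break
  }
  hi
}

#' Projection curve over a grid of sample sizes
#'
#' Evaluates discoveries, variance explained, PRS variance, AUC and tail
#' relative risk for each effective sample size, at genome-wide
#' significance and at the optimized threshold.
#'
#' @inheritParams expected_discoveries
#' @param n_eff_grid vector of effective sample sizes.
#' @return data.frame with one row per (n_eff, threshold mode):
#'   `n_eff`, `n_cases` (1:1 design, `n_eff / 2`), `alpha_mode`, `alpha`,
#'   `ED`, `EV_abs`, `EV_frac`, `h2_prs`, `AUC`, `RR99`.
#' @export
projection_curve <- function(model, large = NULL, n_eff_grid) {
  if (inherits(model, "mixture_fit")) model <- model$model
  rows <- lapply(n_eff_grid, function(n) {
    gws <- 5e-8
    opt <- optimize_threshold(model, large, n)
    do.call(rbind, lapply(list(
      list(mode = "gws", alpha = gws),
      list(mode = "optimized", alpha = opt$alpha)), function(th) {
        ev <- expected_variance(model, large, n, th$alpha)
        hp <- if (th$mode == "optimized") opt$h2_prs else
          prs_variance(model, large, n, th$alpha)
        data.frame(n_eff = n, n_cases = n / 2, alpha_mode = th$mode,
                   alpha = th$alpha,
                   ED = expected_discoveries(model, large, n, th$alpha),
                   EV_abs = ev$abs, EV_frac = ev$frac, h2_prs = hp,
                   AUC = auc_from_h2(hp), RR99 = rr_top_percentile(hp))
      }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
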