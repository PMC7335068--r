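# Parameter transform: probabilities on the logit scale, variances on the
# log scale; the three-component model parametrizes the larger variance as
# sigma1^2 + exp(t4) so the ascending-variance convention is built in.
par_to_model <- function(par, M, n_components) {
  if (n_components == 2L) {
    mixture_model(M, plogis(par[1]), 1, exp(par[2]))
  } else {
    p2 <- plogis(par[2])
    s1 <- exp(par[3])
    mixture_model(M, plogis(par[1]), c(1 - p2, p2), c(s1, s1 + exp(par[4])))
  }
}

model_to_par <- function(model) {
  if (model$n_components == 2L) {
    c(qlogis(model$pi_c), log(model$variances[1]))
  } else {
    c(qlogis(model$pi_c), qlogis(model$weights[2]),
      log(model$variances[1]),
      log(model$variances[2] - model$variances[1]))
  }
}

#' Marginal log-likelihood of z-statistics under a mixture model
#'
#' Under independence each cleaned z-statistic has marginal density
#' `(1 - pi_c) N(z; 0, 1) + pi_c sum_h p_h N(z; 0, 1 + n_eff sigma_h^2)`,
#' the convolution of the effect-size mixture with the Gaussian sampling
#' noise of a standardized log-odds-ratio.  In `ld_score` mode the non-null
#' variance inflation becomes `l_m * n_eff * sigma_h^2` with per-SNP LD
#' scores `l_m` (a composite-likelihood approximation to LD convolution).
#'
#' @param model a `mixture_model`.
#' @param records `sumstats` (only `Z` is used), or a numeric vector of z.
#' @param n_eff effective sample size shared by the records.
#' @param ld_mode `"independent"` or `"ld_score"`.
#' @param ld per-SNP LD scores (required in `ld_score` mode).
#' @return scalar log-likelihood (sum over SNPs).
#' @export
marginal_z_loglik <- function(model, records, n_eff,
                              ld_mode = c("independent", "ld_score"),
                              ld = NULL) {
  ld_mode <- match.arg(ld_mode)
  z <- if (is.numeric(records)) records else records$Z
  l <- if (ld_mode == "ld_score") {
    if (is.null(ld)) stop_arg("ld scores required in ld_score mode")
    ld
  } else 1
  dens <- (1 - model$pi_c) * dnorm(z)
  for (h in seq_along(model$weights)) {
    dens <- dens + model$pi_c * model$weights[h] *
      dnorm(z, 0, sqrt(1 + l * n_eff * model$variances[h]))
  }
  ll <- sum(log(dens))
  if (!is.finite(ll))
    stop("non-finite mixture log-likelihood (pi_c = ", model$pi_c,
         ", variances = ", paste(signif(model$variances, 3), collapse = ","),
         ")")
  ll
}

# initialization grid: pi_c on a log ladder, sigma^2 from the
# method-of-moments identity E(z^2) = 1 + pi_c * n_eff * E(beta^2)
init_grid <- function(z, n_eff, n_components,
                      pi_grid = c(1e-4, 1e-3, 1e-2)) {
  excess <- max(mean(z^2) - 1, 1e-8)
  inits <- list()
  for (pi0 in pi_grid) {
    s_mom <- excess / (pi0 * n_eff)
    if (n_components == 2L) {
      inits[[length(inits) + 1L]] <- c(qlogis(pi0), log(s_mom))
    } else {
      for (p2 in c(0.05, 0.2)) {
        s1 <- 0.5 * s_mom
        s2 <- 5 * s_mom
        inits[[length(inits) + 1L]] <-
          c(qlogis(pi0), qlogis(p2), log(s1), log(s2 - s1))
      }
    }
  }
  inits
}

#' Fit a normal-mixture effect-size distribution by maximum likelihood
#'
#' Direct numerical maximization of the marginal z likelihood over a grid of
#' starting values, on transformed scales (logit for probabilities, log for
#' variances).  Standard errors come from the inverse observed information
#' at the optimum, mapped to the natural scale by the delta method.
#'
#' @param records cleaned `sumstats` (or numeric z vector).
#' @param n_eff effective sample size.
#' @param n_components 2 (null + one causal component) or 3 (null + two).
#' @param M panel SNP count the polygenicity refers to; defaults to the
#'   number of records.
#' @param pi_grid starting values for the causal fraction.
#' @param ld_mode,ld see [marginal_z_loglik()].
#' @param maxit maximum optimizer iterations per start.
#' @return a `mixture_fit`: list with `model` (the fitted
#'   [mixture_model()]), `loglik`, `par` (transformed scale), `vcov`
#'   (transformed scale), `se` (natural-scale SEs for `pi_c` and, via the
#'   delta method, `h2`), `n_snps`, `n_eff`, `converged`, `n_components`.
#' @examples
#' \donttest{
#' panel <- make_reference_panel(20000, seed = 1)
#' truth <- mixture_model(20000, 0.01, 1, 1e-3)
#' arch <- simulate_effect_sizes(panel, truth, seed = 2)
#' ss <- simulate_summary_stats(arch, 5e4, 5e4, seed = 3)
#' fit <- fit_mixture(ss, attr(ss, "n_eff"), n_components = 2)
#' fit$model$pi_c
#' }
#' @export
fit_mixture <- function(records, n_eff, n_components = 2L,
                        M = NULL, pi_grid = c(1e-4, 1e-3, 1e-2),
                        ld_mode = c("independent", "ld_score"), ld = NULL,
                        maxit = 500L) {
  ld_mode <- match.arg(ld_mode)
  if (!n_components %in% c(2L, 3L)) stop_arg("n_components must be 2 or 3")
  z <- if (is.numeric(records)) records else records$Z
  M <- M %||% length(z)
  negll <- function(par) {
    m <- try(par_to_model(par, M, n_components), silent = TRUE)
    if (inherits(m, "try-error")) return(1e12)
    ll <- try(marginal_z_loglik(m, z, n_eff, ld_mode, ld), silent = TRUE)
    if (inherits(ll, "try-error") || !is.finite(ll)) return(1e12)
    -ll
  }
  best <- NULL
  for (start in init_grid(z, n_eff, n_components, pi_grid)) {
    o <- try(optim(start, negll, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-10)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop(errorCondition("mixture fit failed from every starting value",
                        class = c("polyarch_convergence_error", "error")))
  converged <- best$convergence == 0
  H <- try(optimHess(best$par, negll), silent = TRUE)
  V <- if (!inherits(H, "try-error")) try(solve(H), silent = TRUE) else H
  if (inherits(V, "try-error") || any(!is.finite(V)) ||
      any(diag(V) < 0)) {
    warning("observed information not positive definite; SEs unavailable")
    V <- matrix(NA_real_, length(best$par), length(best$par))
  }
  model <- par_to_model(best$par, M, n_components)
  h2_of <- function(par) {
    m <- par_to_model(par, M, n_components)
    m$M * m$pi_c * m$e_beta2
  }
  npi_of <- function(par) M * plogis(par[1])
  se <- list(pi_c = delta_se(function(p) plogis(p[1]), best$par, V),
             h2 = delta_se(h2_of, best$par, V),
             n_susceptibility = delta_se(npi_of, best$par, V))
  fit <- structure(list(model = model, loglik = -best$value,
                        par = best$par, vcov = V, se = se,
                        n_snps = length(z), n_eff = n_eff,
                        n_components = n_components,
                        ld_mode = ld_mode, converged = converged),
                   class = "mixture_fit")
  if (!converged)
    stop(errorCondition(
      "mixture fit did not converge within maxit iterations",
      class = c("polyarch_convergence_error", "error"), fit = fit))
  fit
}

delta_se <- function(g, par, V) {
  if (any(!is.finite(V))) return(NA_real_)
  gr <- num_grad(g, par)
  v <- drop(t(gr) %*% V %*% gr)
  if (!is.finite(v) || v < 0) return(NA_real_)
  sqrt(v)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: %d-component, loglik %.2f on %d SNPs (n_eff %g)\n",
              x$n_components, x$loglik, x$n_snps, x$n_eff))
  print(x$model)
  cat(sprintf("  se(pi_c) = %.3g, se(h2) = %.3g\n", x$se$pi_c, x$se$h2))
  invisible(x)
}

#' Choose between the two- and three-component fits
#'
#' Selection by Bayesian information criterion with the SNP count as the
#' sample size (`BIC = -2 loglik + k log(n_snps)`); the three-component fit
#' is returned only when its BIC is strictly smaller, so ties and identical
#' likelihoods fall back to the more parsimonious two-component model.
#'
#' @param fit2,fit3 `mixture_fit` objects fitted to the same records.
#' @param criterion only `"bic"` currently.
#' @return the chosen `mixture_fit`, with attribute `label` set to
#'   `"two-component"` or `"three-component"`.
#' @export
select_model <- function(fit2, fit3, criterion = "bic") {
  stopifnot(identical(fit2$n_snps, fit3$n_snps))
  k2 <- length(fit2$par); k3 <- length(fit3$par)
  bic2 <- -2 * fit2$loglik + k2 * log(fit2$n_snps)
  bic3 <- -2 * fit3$loglik + k3 * log(fit3$n_snps)
  if (bic3 < bic2) {
    attr(fit3, "label") <- "three-component"
    fit3
  } else {
    attr(fit2, "label") <- "two-component"
    fit2
  }
}

#' Total heritability with large-effect add-back
#'
#' `h2 = M pi_c E(beta^2) + sum_i(beta_hat_i^2 - tau_i^2)` over the
#' independent large-effect SNPs extracted during QC; the susceptibility-SNP
#' count is `M pi_c + |large|`.  `upsilon` is the proportion of mixture
#' heritability carried by the larger-variance component (0 for
#' two-component fits).  SEs come from the fit covariance by the delta
#' method (the add-back is treated as fixed).
#'
#' @param fit a `mixture_fit` (or bare `mixture_model`, in which case SEs
#'   are `NA`).
#' @param large a `large_effect_set` or `NULL`.
#' @return a `heritability_estimate` list: `h2`, `se_h2`, `h2_mixture`,
#'   `addback`, `n_susceptibility`, `se_n_susceptibility`, `n_large`,
#'   `upsilon`, `se_upsilon`, `per_snp_h2` (average per susceptibility SNP,
#'   excluding the large-effect SNPs).
#' @export
total_heritability <- function(fit, large = NULL) {
  if (inherits(fit, "mixture_model")) {
    model <- fit; V <- NULL; par <- NULL
  } else {
    stopifnot(inherits(fit, "mixture_fit"))
    model <- fit$model; V <- fit$vcov; par <- fit$par
  }
  addback <- 0
  n_large <- 0L
  if (!is.null(large) && nrow(large$top) > 0) {
    terms <- large$top$BETA^2 - large$top$SE^2
    if (any(terms < 0)) {
      warning(sum(terms < 0),
              " large-effect SNP(s) with beta_hat^2 < tau^2; clamped at 0")
      terms <- pmax(terms, 0)
    }
    addback <- sum(terms)
    n_large <- nrow(large$top)
  }
  h2_mix <- model$M * model$pi_c * model$e_beta2
  ups <- if (model$n_components == 3L) {
    model$weights[2] * model$variances[2] / model$e_beta2
  } else 0
  se_h2 <- se_n <- se_ups <- NA_real_
  if (!is.null(V) && !any(!is.finite(V))) {
    M <- model$M; ncmp <- model$n_components
    se_h2 <- delta_se(function(p) {
      m <- par_to_model(p, M, ncmp); m$M * m$pi_c * m$e_beta2
    }, par, V)
    se_n <- delta_se(function(p) M * plogis(p[1]), par, V)
    if (ncmp == 3L)
      se_ups <- delta_se(function(p) {
        m <- par_to_model(p, M, ncmp)
        m$weights[2] * m$variances[2] / m$e_beta2
      }, par, V)
  }
  structure(list(h2 = h2_mix + addback, se_h2 = se_h2,
                 h2_mixture = h2_mix, addback = addback,
                 n_susceptibility = model$M * model$pi_c + n_large,
                 se_n_susceptibility = se_n, n_large = n_large,
                 upsilon = ups, se_upsilon = se_ups,
                 per_snp_h2 = model$e_beta2),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("h2 = %.4f (SE %.3g) [mixture %.4f + add-back %.4f]\n",
              x$h2, x$se_h2, x$h2_mixture, x$addback))
  cat(sprintf("susceptibility SNPs = %.1f (SE %.3g), %d large-effect\n",
              x$n_susceptibility, x$se_n_susceptibility, x$n_large))
  cat(sprintf("upsilon = %.3f, per-SNP h2 = %.3g\n",
              x$upsilon, x$per_snp_h2))
  invisible(x)
}
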