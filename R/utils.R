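#' Effective sample size of a case-control GWAS
#'
#' The single scalar controlling the sampling variance of a standardized
#' log-odds-ratio estimate: `n_eff = 4 / (1/n_cases + 1/n_controls)`.  For a
#' balanced study of N cases and N controls this equals 2N.  The same
#' convention is used by the simulator and the fitter, so parameter-recovery
#' results do not depend on the choice.
#'
#' @param n_cases,n_controls positive case and control counts.
#' @return effective sample size (persons).
#' @export
effective_sample_size <- function(n_cases, n_controls) {
  stopifnot(n_cases >= 1, n_controls >= 1)
  4 / (1 / n_cases + 1 / n_controls)
}

# central-difference gradient; h scaled per coordinate
num_grad <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    g[i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)
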