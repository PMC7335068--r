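#' Build a synthetic LD reference panel
#'
#' Generates a HapMap3-like panel of common SNPs (MAF > 0.05) with strictly
#' increasing positions per chromosome and block-diagonal LD.  Chromosome 6
#' always carries SNPs inside the MHC-like interval 26-34 Mb so that the
#' exclusion filter is exercised by any downstream run.
#'
#' @param n_snps total number of panel SNPs.
#' @param n_chromosomes number of chromosomes the SNPs are spread over
#'   (chromosome 6 is included whenever `n_chromosomes >= 6`).
#' @param block_size number of consecutive SNPs per LD block (1 =
#'   independent).
#' @param ld_mode `"independent"` or `"ar1"`; under `"ar1"` the within-block
#'   correlation is `rho^|i-j|`.
#' @param rho AR(1) correlation parameter in `[0, 1)`.
#' @param seed integer seed; the panel is deterministic given the seed.
#' @return a `reference_panel`: a data.frame with columns `SNP`, `CHR`, `BP`,
#'   `A1`, `A2`, `MAF`, `BLOCK` and attributes `ld_mode`, `rho`,
#'   `block_size`.
#' @examples
#' p <- make_reference_panel(200, n_chromosomes = 6, block_size = 5,
#'                           ld_mode = "ar1", rho = 0.8, seed = 1)
#' table(p$CHR)
#' @export
make_reference_panel <- function(n_snps, n_chromosomes = 22, block_size = 1,
                                 ld_mode = c("independent", "ar1"),
                                 rho = 0, seed = 1) {
  ld_mode <- match.arg(ld_mode)
  if (n_snps < 1 || n_chromosomes < 1 || block_size < 1)
    stop_arg("n_snps, n_chromosomes and block_size must be positive")
  if (rho < 0 || rho >= 1) stop_arg("rho must be in [0, 1)")
  if (ld_mode == "independent") block_size <- 1L

  set.seed(seed)
  chr_sizes <- rep(n_snps %/% n_chromosomes, n_chromosomes)
  extra <- n_snps %% n_chromosomes
  if (extra > 0) chr_sizes[seq_len(extra)] <- chr_sizes[seq_len(extra)] + 1L

  chrom_len <- 1.2e8
  rows <- vector("list", n_chromosomes)
  for (ch in seq_len(n_chromosomes)) {
    k <- chr_sizes[ch]
    if (k == 0) next
    bp <- sort(sample.int(chrom_len, k))
    if (ch == 6L && k >= 2) {
      # force ~10% of chr6 SNPs (at least 2) into the MHC-like window
      n_mhc <- max(2L, ceiling(0.1 * k))
      n_mhc <- min(n_mhc, k)
      idx <- seq_len(n_mhc)
      bp[idx] <- sort(sample(26000000:34000000, n_mhc))
      bp <- sort(bp)
    }
    bp <- cummax(bp) + (seq_len(k) - 1L)  # guarantee strict increase
    rows[[ch]] <- data.frame(CHR = ch, BP = bp)
  }
  panel <- do.call(rbind, rows)
  n <- nrow(panel)
  alle <- c("A", "C", "G", "T")
  a1 <- sample(alle, n, replace = TRUE)
  a2 <- vapply(a1, function(a) sample(setdiff(alle, a), 1), character(1))
  panel$SNP <- sprintf("rs%d_%d", panel$CHR, panel$BP)
  panel$A1 <- a1
  panel$A2 <- a2
  panel$MAF <- runif(n, 0.05 + 1e-6, 0.5)
  # LD blocks: consecutive runs within a chromosome
  panel$BLOCK <- 0L
  b0 <- 0L
  for (ch in unique(panel$CHR)) {
    i <- which(panel$CHR == ch)
    panel$BLOCK[i] <- b0 + (seq_along(i) - 1L) %/% block_size + 1L
    b0 <- max(panel$BLOCK[i])
  }
  panel <- panel[, c("SNP", "CHR", "BP", "A1", "A2", "MAF", "BLOCK")]
  rownames(panel) <- NULL
  attr(panel, "ld_mode") <- ld_mode
  attr(panel, "rho") <- if (ld_mode == "ar1") rho else 0
  attr(panel, "block_size") <- as.integer(block_size)
  class(panel) <- c("reference_panel", "data.frame")
  panel
}

#' Within-block LD correlation matrix of a panel block
#'
#' @param panel a `reference_panel`.
#' @param block block id.
#' @return correlation matrix (unit diagonal, symmetric PSD).
#' @export
panel_block_cor <- function(panel, block) {
  k <- sum(panel$BLOCK == block)
  rho <- attr(panel, "rho") %||% 0
  if (rho == 0 || k == 1) return(diag(k))
  rho^abs(outer(seq_len(k), seq_len(k), "-"))
}

#' Squared LD between two panel SNPs
#'
#' AR(1) block model: `r2 = rho^(2|i-j|)` within a block, 0 across blocks.
#'
#' @param panel a `reference_panel`.
#' @param snp1,snp2 SNP identifiers.
#' @return squared correlation in `[0, 1]`.
#' @export
panel_r2 <- function(panel, snp1, snp2) {
  i <- match(snp1, panel$SNP)
  j <- match(snp2, panel$SNP)
  if (is.na(i) || is.na(j)) return(0)
  if (panel$BLOCK[i] != panel$BLOCK[j]) return(0)
  rho <- attr(panel, "rho") %||% 0
  if (rho == 0) return(as.numeric(i == j))
  rho^(2 * abs(i - j))
}

#' Per-SNP LD scores of a panel
#'
#' `l_m = sum_j r2(m, j)` over the SNP's block (including itself).
#'
#' @param panel a `reference_panel`.
#' @return numeric vector aligned with `panel$SNP`.
#' @export
ld_scores <- function(panel) {
  rho <- attr(panel, "rho") %||% 0
  out <- numeric(nrow(panel))
  for (b in unique(panel$BLOCK)) {
    i <- which(panel$BLOCK == b)
    if (rho == 0 || length(i) == 1) {
      out[i] <- 1
    } else {
      R <- rho^abs(outer(seq_along(i), seq_along(i), "-"))
      out[i] <- rowSums(R^2)
    }
  }
  out
}

#' Construct a normal-mixture effect-size model
#'
#' The effect-size distribution of standardized log-odds-ratios:
#' `beta_m ~ (1 - pi_c) delta_0 + pi_c sum_h p_h N(0, sigma_h^2)`.
#' One causal component gives the two-component model; two causal components
#' (variances sorted ascending, `sigma_2^2 > sigma_1^2`) give the
#' three-component model.
#'
#' @param M number of reference-panel SNPs the model is defined over.
#' @param pi_c causal fraction in (0, 1]; `M * pi_c` is the polygenicity.
#' @param weights mixture weights of the causal components, summing to 1.
#' @param variances per-component effect variances, strictly positive.
#' @return a `mixture_model` list with fields `M`, `pi_c`, `weights`,
#'   `variances`, `n_components` (2 or 3, counting the null spike) and
#'   `e_beta2 = sum(weights * variances)`.
#' @examples
#' mixture_model(1e5, 0.01, 1, 1e-4)                    # two-component
#' mixture_model(1e5, 0.01, c(0.9, 0.1), c(1e-4, 1e-3)) # three-component
#' @export
mixture_model <- function(M, pi_c, weights, variances) {
  if (M < 1) stop_arg("M must be >= 1")
  if (pi_c < 0 || pi_c > 1) stop_arg("pi_c must be in [0, 1]")
  if (length(weights) != length(variances))
    stop_arg("weights and variances must have equal length")
  if (any(weights < 0) || any(weights > 1) ||
      abs(sum(weights) - 1) > 1e-8)
    stop_arg("weights must lie in [0, 1] and sum to 1")
  if (any(variances <= 0)) stop_arg("variances must be strictly positive")
  o <- order(variances)
  structure(list(M = M, pi_c = pi_c,
                 weights = as.numeric(weights[o]),
                 variances = as.numeric(variances[o]),
                 n_components = length(variances) + 1L,
                 e_beta2 = sum(weights * variances)),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("%d-component normal-mixture effect-size model\n",
              x$n_components))
  cat(sprintf("  M = %g, pi_c = %g  (M*pi_c = %.1f susceptibility SNPs)\n",
              x$M, x$pi_c, x$M * x$pi_c))
  for (h in seq_along(x$weights))
    cat(sprintf("  component %d: weight %.3f, variance %.3g\n",
                h, x$weights[h], x$variances[h]))
  cat(sprintf("  E(beta^2) = %.3g, h2 = %.4f\n",
              x$e_beta2, x$M * x$pi_c * x$e_beta2))
  invisible(x)
}

#' Draw true per-SNP effect sizes from a mixture model
#'
#' Each panel SNP is causal with probability `pi_c`; causal SNPs draw their
#' standardized log-odds-ratio from the normal components, non-causal SNPs
#' have effect exactly 0.  `E(sum beta^2) = M * pi_c * E(beta^2) = h2`.
#'
#' @param panel a `reference_panel`.
#' @param model a `mixture_model`.
#' @param seed integer seed.
#' @return a `true_architecture`: data.frame with columns `SNP`, `CHR`,
#'   `BP`, `BETA`, `CAUSAL`, `COMPONENT` (0 = null, then 1, 2) and attribute
#'   `model`.
#' @export
simulate_effect_sizes <- function(panel, model, seed = 1) {
  stopifnot(inherits(model, "mixture_model"))
  set.seed(seed)
  m <- nrow(panel)
  causal <- runif(m) < model$pi_c
  comp <- integer(m)
  beta <- numeric(m)
  nc <- sum(causal)
  if (nc > 0) {
    h <- sample.int(length(model$weights), nc, replace = TRUE,
                    prob = model$weights)
    comp[causal] <- h
    beta[causal] <- rnorm(nc, 0, sqrt(model$variances[h]))
  }
  arch <- data.frame(SNP = panel$SNP, CHR = panel$CHR, BP = panel$BP,
                     BETA = beta, CAUSAL = causal, COMPONENT = comp)
  attr(arch, "model") <- model
  class(arch) <- c("true_architecture", "data.frame")
  arch
}

#' Simulate GWAS summary statistics from a true architecture
#'
#' Z-statistics follow the standard Gaussian sampling model for a
#' standardized log-odds-ratio: under independence
#' `z_m ~ N(sqrt(n_eff) beta_m, 1)`; with LD blocks the z-mean is the
#' LD-weighted block sum `R %*% (sqrt(n_eff) beta)` and the noise has
#' correlation `R`.  Records are reported on the beta-hat scale with
#' `beta_hat = z / sqrt(n_eff)` and `se = 1 / sqrt(n_eff)`.
#'
#' @param arch a `true_architecture` (carries the panel coordinates).
#' @param n_cases,n_controls case/control counts; the effective size is
#'   `4 / (1/n_cases + 1/n_controls)`.
#' @param seed integer seed.
#' @param n_jitter fraction in `[0, 1)` of SNPs with reduced coverage:
#'   those SNPs report `(n_cases + n_controls) * U(0.4, 1)` while the rest
#'   report the full total, emulating the clustered per-SNP sample sizes of
#'   a meta-analysis so the sample-size filter has something to act on.
#' @param panel optional `reference_panel` supplying LD blocks; if omitted,
#'   SNPs are treated as independent.
#' @return a `sumstats` data.frame with columns `SNP`, `CHR`, `BP`, `A1`,
#'   `A2`, `MAF`, `BETA`, `SE`, `Z`, `P`, `N`.
#' @export
simulate_summary_stats <- function(arch, n_cases, n_controls, seed = 1,
                                   n_jitter = 0, panel = NULL) {
  if (n_cases < 1 || n_controls < 1) stop_arg("need n_cases, n_controls >= 1")
  if (n_jitter < 0 || n_jitter >= 1) stop_arg("n_jitter must be in [0, 1)")
  set.seed(seed)
  m <- nrow(arch)
  n_eff <- effective_sample_size(n_cases, n_controls)
  mu <- sqrt(n_eff) * arch$BETA
  if (!is.null(panel) && (attr(panel, "rho") %||% 0) > 0) {
    stopifnot(identical(panel$SNP, arch$SNP))
    z <- numeric(m)
    for (b in unique(panel$BLOCK)) {
      i <- which(panel$BLOCK == b)
      R <- panel_block_cor(panel, b)
      L <- chol(R)
      z[i] <- as.numeric(R %*% mu[i] + t(L) %*% rnorm(length(i)))
    }
  } else {
    z <- rnorm(m, mu, 1)
  }
  n_tot <- n_cases + n_controls
  reduced <- runif(m) < n_jitter
  n_snp <- rep(n_tot, m)
  n_snp[reduced] <- round(n_tot * runif(sum(reduced), 0.4, 1))
  tau <- 1 / sqrt(n_eff)
  ss <- data.frame(
    SNP = arch$SNP, CHR = arch$CHR, BP = arch$BP,
    A1 = if (!is.null(panel)) panel$A1 else "A",
    A2 = if (!is.null(panel)) panel$A2 else "G",
    MAF = if (!is.null(panel)) panel$MAF else 0.25,
    BETA = z * tau, SE = tau, Z = z,
    P = 2 * pnorm(-abs(z)), N = n_snp)
  attr(ss, "n_eff") <- n_eff
  class(ss) <- c("sumstats", "data.frame")
  ss
}

#' Simulate a small individual-level cohort
#'
#' Validation mode for the summary-level machinery: standardized genotypes
#' (mean 0, variance 1 per SNP), true PRS `sum(beta_m G_m)`, and a binary
#' outcome from a logistic model.  Intended for `M <= 5000`.
#'
#' @param arch a `true_architecture`.
#' @param n_individuals cohort size.
#' @param intercept logistic intercept controlling prevalence.
#' @param seed integer seed.
#' @return list with `G` (n x M matrix), `prs` (length-n true PRS), `y`
#'   (0/1 outcome).
#' @export
simulate_cohort <- function(arch, n_individuals, intercept = -2, seed = 1) {
  m <- nrow(arch)
  if (m > 5000) stop_arg("cohort mode is for M <= 5000 SNPs")
  set.seed(seed)
  G <- matrix(rnorm(n_individuals * m), n_individuals, m)
  prs <- as.numeric(G %*% arch$BETA)
  y <- rbinom(n_individuals, 1, plogis(intercept + prs))
  list(G = G, prs = prs, y = y)
}

#' Build synthetic life tables
#'
#' A SEER-style stand-in: age-specific incidence and all-cause mortality
#' hazards on ages 30-80, plus baseline-age weights over 5-year categories
#' spanning 30-75 (census-style age distribution), normalized to sum to 1.
#'
#' @param peak_incidence incidence hazard per year at age 80 (and at every
#'   age when `shape = "flat"`); must lie in `[0, 0.5]`.
#' @param shape `"flat"` or `"increasing"` (quadratic rise from age 30).
#' @param mortality_level all-cause mortality hazard per year at age 80
#'   (flat-by-age fraction of it below); in `[0, 0.5]`.
#' @param seed integer seed for the small perturbation of the age weights.
#' @return a `life_tables` list: `ages` data.frame (`age`, `incidence`,
#'   `mortality`) on 30-80 and `weights` data.frame (`age_lo`, `age_hi`,
#'   `weight`).
#' @export
make_life_tables <- function(peak_incidence = 0.002,
                             shape = c("increasing", "flat"),
                             mortality_level = 0.02, seed = 1) {
  shape <- match.arg(shape)
  if (peak_incidence < 0 || peak_incidence > 0.5)
    stop_arg("peak_incidence must be in [0, 0.5]")
  if (mortality_level < 0 || mortality_level > 0.5)
    stop_arg("mortality_level must be in [0, 0.5]")
  set.seed(seed)
  age <- 30:80
  if (shape == "flat") {
    inc <- rep(peak_incidence, length(age))
  } else {
    inc <- peak_incidence * ((age - 30) / 50)^2
  }
  mort <- mortality_level * (0.05 + 0.95 * ((age - 30) / 50)^3)
  age_lo <- seq(30, 75, by = 5)
  w <- exp(-0.02 * (age_lo - 30)) * runif(length(age_lo), 0.9, 1.1)
  lt <- list(
    ages = data.frame(age = age, incidence = inc, mortality = mort),
    weights = data.frame(age_lo = age_lo, age_hi = age_lo + 4,
                         weight = w / sum(w)))
  class(lt) <- "life_tables"
  lt
}

#' @export
print.life_tables <- function(x, ...) {
  cat(sprintf("life_tables: ages %d-%d, %d baseline-age categories\n",
              min(x$ages$age), max(x$ages$age), nrow(x$weights)))
  invisible(x)
}

validate_life_tables <- function(tables) {
  stopifnot(inherits(tables, "life_tables"))
  with(tables, {
    if (any(ages$incidence < 0) || any(ages$mortality < 0))
      stop_arg("hazards must be non-negative")
    if (abs(sum(weights$weight) - 1) > 1e-8)
      stop_arg("baseline-age weights must sum to 1")
    if (any(diff(ages$age) != 1))
      stop_arg("age grid must be contiguous in 1-year steps")
  })
  invisible(tables)
}
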