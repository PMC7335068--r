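# shared fixtures, built in code

# tiny deterministic sumstats table with explicit fields
toy_sumstats <- function(snp, chr, bp, beta, se, n = 1000,
                         a1 = "A", a2 = "G", maf = 0.25) {
  df <- data.frame(SNP = snp, CHR = chr, BP = bp, A1 = a1, A2 = a2,
                   MAF = maf, BETA = beta, SE = se, Z = beta / se,
                   P = 2 * pnorm(-abs(beta / se)), N = n)
  class(df) <- c("sumstats", "data.frame")
  df
}

# panel matching a toy sumstats table one-to-one (no LD)
toy_panel <- function(ss, maf = NULL) {
  p <- data.frame(SNP = ss$SNP, CHR = ss$CHR, BP = ss$BP,
                  A1 = ss$A1, A2 = ss$A2,
                  MAF = maf %||% ss$MAF, BLOCK = seq_len(nrow(ss)))
  attr(p, "ld_mode") <- "independent"
  attr(p, "rho") <- 0
  attr(p, "block_size") <- 1L
  class(p) <- c("reference_panel", "data.frame")
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flat life tables with explicit hazards, for hand-computable checks
flat_tables <- function(incidence = 0.001, mortality = 0) {
  lt <- make_life_tables(incidence, "flat", 0, seed = 1)
  lt$ages$mortality <- rep(mortality, nrow(lt$ages))
  lt
}

# simulate z-statistics straight from a mixture truth (independent SNPs)
sim_z_from_truth <- function(truth, n_eff, seed) {
  panel <- the_panel_cache(truth$M)
  arch <- simulate_effect_sizes(panel, truth, seed = seed)
  n <- n_eff / 2  # 1:1 design: n_eff = 2N
  simulate_summary_stats(arch, n, n, seed = seed + 10000L)
}

# build each panel size once per test run
the_panel_cache <- local({
  cache <- list()
  function(m) {
    key <- as.character(m)
    if (is.null(cache[[key]]))
      cache[[key]] <<- make_reference_panel(m, n_chromosomes = 22,
                                            seed = 99L)
    cache[[key]]
  }
})
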