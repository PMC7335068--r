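test_that("read_sumstats parses well-formed files and handles dialects", {
  f <- withr::local_tempfile(fileext = ".tsv")
  ss <- toy_sumstats(c("rs1", "rs2", "rs3"), 1, c(100, 200, 300),
                     c(0.1, -0.2, 0.05), 0.05)
  write_sumstats(ss, f)
  r <- read_sumstats(f)
  expect_equal(nrow(r), 3)
  expect_equal(r$BETA, ss$BETA)
  expect_equal(r$Z, ss$Z)

  # SE = 0 rows are skipped with a warning
  ss$SE[2] <- 0
  write_sumstats(ss, f)
  expect_warning(r2 <- read_sumstats(f), "malformed")
  expect_equal(r2$SNP, c("rs1", "rs3"))

  # OR column instead of BETA
  or_df <- data.frame(SNP = "rs9", CHR = 2, BP = 50, OR = 1.5, SE = 0.1)
  utils::write.table(or_df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  r3 <- read_sumstats(f)
  expect_equal(r3$BETA, log(1.5))

  # dialect remapping
  od <- data.frame(rsid = "rs9", chrom = 2, pos = 50, BETA = 0.1, SE = 0.1)
  utils::write.table(od, f, sep = "\t", quote = FALSE, row.names = FALSE)
  r4 <- read_sumstats(f, dialect = c(rsid = "SNP", chrom = "CHR",
                                     pos = "BP"))
  expect_equal(r4$SNP, "rs9")

  # missing mandatory column and empty file are format errors
  utils::write.table(data.frame(SNP = "rs1", CHR = 1), f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(f), "mandatory")
  writeLines("SNP\tCHR\tBP\tBETA\tSE", f)
  expect_error(read_sumstats(f), "empty|no well-formed")
})

test_that("panel restriction drops absent/rare SNPs and flips swapped alleles", {
  ss <- toy_sumstats(c("rs1", "rs2", "rs3", "rs4"), 1, 1:4 * 100,
                     c(0.1, 0.2, 0.3, 0.4), 0.1)
  panel <- toy_panel(ss[c(1, 2, 3), ], maf = c(0.2, 0.04, 0.3))
  panel$A1[3] <- ss$A2[3]; panel$A2[3] <- ss$A1[3]  # swapped vs records
  out <- restrict_to_panel(ss, panel)
  # rs4 absent, rs2 maf 0.04 <= 0.05 dropped; rs3 kept with flipped sign
  expect_equal(out$SNP, c("rs1", "rs3"))
  expect_equal(out$BETA, c(0.1, -0.3))
  expect_equal(out$Z, out$BETA / out$SE)
  drops <- attr(out, "drops")
  expect_setequal(drops$snp, c("rs2", "rs4"))
})

test_that("sample-size filter uses nearest-rank Q90 and strict inequality", {
  # n = {100 x9, 50}: Q90 = 100, cutoff 67, only the 50 goes
  ss <- toy_sumstats(paste0("rs", 1:10), 1, 1:10 * 1000, 0.01, 0.1,
                     n = c(rep(100, 9), 50))
  out <- filter_low_sample_size(ss)
  expect_equal(nrow(out), 9)
  expect_false("rs10" %in% out$SNP)
  # boundary: n = 67 vs cutoff 67 is kept (strict <)
  ss2 <- toy_sumstats(c("a", "b"), 1, c(1, 2), 0.01, 0.1, n = c(67, 100))
  expect_equal(nrow(filter_low_sample_size(ss2)), 2)
  # all equal: none removed
  ss3 <- toy_sumstats(c("a", "b"), 1, c(1, 2), 0.01, 0.1, n = 500)
  expect_equal(nrow(filter_low_sample_size(ss3)), 2)
  # all missing: no-op with warning
  ss4 <- toy_sumstats(c("a", "b"), 1, c(1, 2), 0.01, 0.1, n = NA)
  expect_warning(out4 <- filter_low_sample_size(ss4), "skipped")
  expect_equal(nrow(out4), 2)
})

test_that("MHC exclusion is inclusive on chr6 26-34 Mb only", {
  ss <- toy_sumstats(c("in1", "lo", "hi", "edge_lo", "edge_hi", "chr7"),
                     c(6, 6, 6, 6, 6, 7),
                     c(30e6, 25999999, 34000001, 26000000, 34000000, 30e6),
                     0.01, 0.1)
  out <- exclude_mhc(ss)
  expect_setequal(out$SNP, c("lo", "hi", "chr7"))
})

test_that("greedy clumping matches brute-force enumeration on a toy fixture", {
  # 7 SNPs on one chromosome; z chosen so z^2 > 80 for four of them
  bp <- c(1e6, 1.4e6, 3e6, 3.3e6, 6e6, 6.2e6, 9e6)
  z  <- c(10,  9.6,   9.8, 2,     11,  9.1,   3)
  ss <- toy_sumstats(paste0("s", 1:7), 1, bp, z * 0.01, 0.01)
  res <- extract_large_effects(ss, chi2_threshold = 80, window = 1e6)

  # independent brute-force oracle for the greedy procedure
  greedy_oracle <- function(bp, z, thr = 80, win = 1e6) {
    act <- rep(TRUE, length(z)); tops <- integer(0)
    repeat {
      c_ <- which(act & z^2 > thr)
      if (!length(c_)) break
      t <- c_[order(-z[c_]^2, bp[c_])][1]
      tops <- c(tops, t); act[t] <- FALSE
      act[act & abs(bp - bp[t]) <= win] <- FALSE
    }
    tops
  }
  tops <- greedy_oracle(bp, z)
  expect_equal(res$large$top$SNP, paste0("s", tops))
  # survivors: never within 1 Mb of a top, all z^2 <= 80
  expect_true(all(res$records$Z^2 <= 80))
  expect_setequal(res$records$SNP,
                  setdiff(paste0("s", which(sapply(seq_along(bp), function(i)
                    all(abs(bp[i] - bp[tops]) > 1e6)))), paste0("s", tops)))
  # two tops 0.5 Mb apart: larger wins, other removed as neighbour
  ss2 <- toy_sumstats(c("a", "b"), 1, c(1e6, 1.5e6), c(0.10, 0.095), 0.01)
  res2 <- extract_large_effects(ss2)
  expect_equal(res2$large$top$SNP, "a")
  expect_equal(res2$large$removed, "b")
  expect_equal(nrow(res2$records), 0)
  # nothing above threshold: records unchanged
  ss3 <- toy_sumstats(c("a", "b"), 1, c(1e6, 5e6), c(0.05, 0.02), 0.01)
  res3 <- extract_large_effects(ss3)
  expect_equal(nrow(res3$large$top), 0)
  expect_equal(res3$records$SNP, ss3$SNP)
})

test_that("clumping removes high-LD neighbours beyond the distance window", {
  p <- make_reference_panel(20, n_chromosomes = 1, block_size = 10,
                            ld_mode = "ar1", rho = 0.95, seed = 1)
  # place block-1 SNPs far apart in bp but in tight LD
  ss <- toy_sumstats(p$SNP, p$CHR, p$BP, 0.01, 0.01)
  ss$BP <- seq(1e6, by = 3e6, length.out = 20)
  ss$BETA[1] <- 0.10  # z = 10, top
  ss$Z <- ss$BETA / ss$SE
  res <- extract_large_effects(ss, panel = p, r2_threshold = 0.1)
  # r2 with SNP 1 is 0.95^(2(i-1)) > 0.1 for i <= 23 within the block
  in_ld <- p$SNP[2:10]
  expect_true(all(in_ld %in% res$large$removed))
  expect_false(any(in_ld %in% res$records$SNP))
})

test_that("filters are idempotent, conserve records and compose in order", {
  set.seed(42)
  panel <- make_reference_panel(3000, n_chromosomes = 8, seed = 11)
  truth <- mixture_model(3000, 0.02, 1, 5e-4)
  arch <- simulate_effect_sizes(panel, truth, seed = 12)
  ss <- simulate_summary_stats(arch, 2e4, 2e4, seed = 13,
                               n_jitter = 0.5, panel = panel)
  f1 <- restrict_to_panel(ss, panel)
  expect_equal(as.data.frame(restrict_to_panel(f1, panel))[names(ss)],
               as.data.frame(f1)[names(ss)])
  f2 <- filter_low_sample_size(f1)
  expect_equal(nrow(filter_low_sample_size(f2)), nrow(f2))
  f3 <- exclude_mhc(f2)
  expect_equal(nrow(exclude_mhc(f3)), nrow(f3))
  ex <- extract_large_effects(f3, panel)
  ex2 <- extract_large_effects(ex$records, panel)
  expect_equal(nrow(ex2$large$top), 0)
  expect_equal(ex2$records$SNP, ex$records$SNP)
  # conservation: |input| = |output| + |dropped| at every step
  qc <- qc_pipeline(ss, panel)
  expect_equal(nrow(ss), nrow(qc$records) + nrow(qc$drops))
  # full pipeline equals the composition of the four steps
  expect_equal(qc$records$SNP, ex$records$SNP)
  expect_equal(qc$large$top$SNP, ex$large$top$SNP)
})
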