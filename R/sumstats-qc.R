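#' Read GWAS summary statistics from a tab-delimited file
#'
#' Reads an LDSC-style tab-delimited file into a `sumstats` data.frame.
#' Column names can be remapped through `dialect`; if an `OR` column is
#' supplied instead of `BETA`, effects are taken as `log(OR)`.  Rows with a
#' non-positive standard error or non-finite effect are counted, skipped and
#' reported with a warning.  `Z` is recomputed as `BETA/SE` when absent and
#' checked when present.
#'
#' @param path file path.
#' @param dialect named character vector mapping the file's column names to
#'   the canonical names `SNP`, `CHR`, `BP`, `A1`, `A2`, `MAF`, `BETA`
#'   (or `OR`), `SE`, `Z`, `P`, `N`, e.g. `c(rsid = "SNP", pos = "BP")`.
#' @return a `sumstats` data.frame.
#' @export
read_sumstats <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop_arg("empty summary-statistics file: ", path)
  if (!is.null(dialect)) {
    i <- match(names(dialect), names(df))
    if (anyNA(i)) stop_arg("dialect names absent from file: ",
                           paste(names(dialect)[is.na(i)], collapse = ", "))
    names(df)[i] <- unname(dialect)
  }
  if (!"BETA" %in% names(df) && "OR" %in% names(df)) {
    df$BETA <- log(df$OR)
  }
  need <- c("SNP", "CHR", "BP", "BETA", "SE")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_arg("missing mandatory column(s): ", paste(miss, collapse = ", "))
  for (opt in c("A1", "A2")) if (!opt %in% names(df)) df[[opt]] <- NA_character_
  if (!"MAF" %in% names(df)) df$MAF <- NA_real_
  if (!"N" %in% names(df)) df$N <- NA_real_

  bad <- !is.finite(df$BETA) | !is.finite(df$SE) | df$SE <= 0
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) skipped (non-finite effect or SE <= 0)")
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0) stop_arg("no well-formed rows in ", path)
  if (!"Z" %in% names(df) || all(is.na(df$Z))) df$Z <- df$BETA / df$SE
  if (!"P" %in% names(df) || all(is.na(df$P))) df$P <- 2 * pnorm(-abs(df$Z))
  df <- df[, c("SNP", "CHR", "BP", "A1", "A2", "MAF", "BETA", "SE",
               "Z", "P", "N")]
  rownames(df) <- NULL
  class(df) <- c("sumstats", "data.frame")
  df
}

#' Write summary statistics as tab-delimited text
#'
#' @param records a `sumstats` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

drop_log <- function(records, kept, filter, reason) {
  dropped <- records$SNP[!kept]
  att <- attr(records, "drops") %||%
    data.frame(snp = character(), filter = character(),
               reason = character())
  if (length(dropped))
    att <- rbind(att, data.frame(snp = dropped, filter = filter,
                                 reason = reason))
  out <- records[kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drops") <- att
  attr(out, "n_eff") <- attr(records, "n_eff")
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Restrict summary statistics to a reference panel
#'
#' Keeps records whose identifier is in the panel and whose panel MAF
#' exceeds 0.05.  Records whose alleles are swapped relative to the panel
#' (A1/A2 exchanged) are kept with the sign of the effect flipped; records
#' whose alleles cannot be reconciled are dropped.
#'
#' @param records a `sumstats` data.frame.
#' @param panel a `reference_panel`.
#' @return filtered `sumstats` (drop log in `attr(, "drops")`).
#' @export
restrict_to_panel <- function(records, panel) {
  if (nrow(panel) == 0) stop_arg("panel is empty")
  i <- match(records$SNP, panel$SNP)
  keep <- !is.na(i)
  out <- drop_log(records, keep, "panel", "not in reference panel")
  i <- i[keep]

  maf <- panel$MAF[i]
  keep2 <- maf > 0.05
  out$MAF <- maf
  out <- drop_log(out, keep2, "panel", "MAF <= 0.05")
  i <- i[keep2]

  same <- is.na(out$A1) | (out$A1 == panel$A1[i] & out$A2 == panel$A2[i])
  swap <- !same & out$A1 == panel$A2[i] & out$A2 == panel$A1[i]
  if (any(swap)) {
    out$BETA[swap] <- -out$BETA[swap]
    out$Z[swap] <- -out$Z[swap]
    out$A1[swap] <- panel$A1[i][swap]
    out$A2[swap] <- panel$A2[i][swap]
  }
  drop_log(out, same | swap, "panel", "allele mismatch")
}

#' Drop SNPs genotyped in too small a fraction of the study
#'
#' Removes records with per-SNP sample size below 0.67 times the 90th
#' percentile of the sample-size distribution (nearest-rank percentile:
#' the `ceiling(0.9 k)`-th order statistic).  The inequality is strict, so a
#' record exactly at the cutoff is kept.
#'
#' @param records a `sumstats` data.frame.
#' @return filtered `sumstats`.
#' @export
filter_low_sample_size <- function(records) {
  n <- records$N
  if (all(is.na(n))) {
    warning("no per-SNP sample sizes; sample-size filter skipped")
    return(records)
  }
  ns <- sort(n[!is.na(n)])
  q90 <- ns[ceiling(0.9 * length(ns))]
  cutoff <- 0.67 * q90
  keep <- is.na(n) | !(n < cutoff)
  drop_log(records, keep, "sample_size",
           sprintf("N < 0.67 * Q90 (= %.1f)", cutoff))
}

#' Exclude the MHC region
#'
#' Removes chromosome-6 records with position in the closed interval
#' \[26,000,000, 34,000,000\] bp, the major histocompatibility complex,
#' whose long-range LD distorts effect-size-distribution fits.
#'
#' @param records a `sumstats` data.frame.
#' @return filtered `sumstats`.
#' @export
exclude_mhc <- function(records) {
  keep <- !(records$CHR == 6 & records$BP >= 26000000 &
              records$BP <= 34000000)
  drop_log(records, keep, "mhc", "chr6 26-34 Mb")
}

#' Extract large-effect loci by greedy clumping
#'
#' Repeatedly takes the largest remaining chi-square (`z^2`) above
#' `chi2_threshold` as an independent top SNP and removes every record
#' within `window` bp of it or with squared LD above `r2_threshold`
#' (ties on `z^2` break toward the smaller genomic coordinate).  The tops
#' are excluded from mixture fitting and later added back to heritability
#' and projection totals as `sum(beta_hat^2 - tau^2)`.
#'
#' @param records a `sumstats` data.frame.
#' @param panel optional `reference_panel` providing LD; without it (or with
#'   an LD-free panel) only the distance window applies.
#' @param chi2_threshold chi-square extraction threshold.
#' @param window clumping distance in bp.
#' @param r2_threshold squared-LD threshold.
#' @return list with `large` (a `large_effect_set`: `$top` data.frame of
#'   independent top SNPs with `SNP`, `CHR`, `BP`, `BETA`, `SE`, `Z`;
#'   `$removed` ids of their clumped neighbours) and `records` (the cleaned
#'   residual `sumstats`, all with `z^2 <= chi2_threshold`).
#' @export
extract_large_effects <- function(records, panel = NULL,
                                  chi2_threshold = 80,
                                  window = 1000000, r2_threshold = 0.1) {
  active <- rep(TRUE, nrow(records))
  top_idx <- integer(0)
  removed <- character(0)
  z2 <- records$Z^2
  repeat {
    cand <- which(active & z2 > chi2_threshold)
    if (!length(cand)) break
    o <- cand[order(-z2[cand], records$CHR[cand], records$BP[cand])]
    t <- o[1]
    top_idx <- c(top_idx, t)
    active[t] <- FALSE
    nb <- which(active & records$CHR == records$CHR[t] &
                  abs(records$BP - records$BP[t]) <= window)
    if (!is.null(panel) && (attr(panel, "rho") %||% 0) > 0) {
      same_blk <- which(active & vapply(
        records$SNP, function(s) panel_r2(panel, s, records$SNP[t]),
        numeric(1)) > r2_threshold)
      nb <- union(nb, same_blk)
    }
    if (length(nb)) {
      removed <- c(removed, records$SNP[nb])
      active[nb] <- FALSE
    }
  }
  top <- records[top_idx, c("SNP", "CHR", "BP", "BETA", "SE", "Z"),
                 drop = FALSE]
  rownames(top) <- NULL
  large <- structure(list(top = top, removed = removed),
                     class = "large_effect_set")
  keep <- active
  out <- drop_log(records, keep, "large_effect",
                  sprintf("top SNP (chi2 > %g) or clumped neighbour",
                          chi2_threshold))
  list(large = large, records = out)
}

#' @export
print.large_effect_set <- function(x, ...) {
  cat(sprintf("large_effect_set: %d independent top SNPs, %d neighbours removed\n",
              nrow(x$top), length(x$removed)))
  invisible(x)
}

#' Run the four-step summary-statistics QC pipeline
#'
#' Applies, in order: restriction to the reference panel (MAF > 0.05),
#' the per-SNP sample-size filter, MHC exclusion, and large-effect
#' extraction with clumping.  Equivalent to composing the four operations.
#'
#' @param records a `sumstats` data.frame.
#' @param panel a `reference_panel`.
#' @param chi2_threshold,window,r2_threshold passed to
#'   [extract_large_effects()].
#' @return list with `records` (cleaned), `large` (a `large_effect_set`)
#'   and `drops` (per-filter drop log).
#' @export
qc_pipeline <- function(records, panel, chi2_threshold = 80,
                        window = 1000000, r2_threshold = 0.1) {
  r <- restrict_to_panel(records, panel)
  r <- filter_low_sample_size(r)
  r <- exclude_mhc(r)
  ex <- extract_large_effects(r, panel, chi2_threshold, window, r2_threshold)
  list(records = ex$records, large = ex$large,
       drops = attr(ex$records, "drops"))
}
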