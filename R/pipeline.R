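#' Build a pipeline run configuration
#'
#' Collects paths, QC parameters, fit options, the projection grid and
#' risk-scenario multipliers into a validated list.  When `sumstats_path`
#' is `NULL` the pipeline simulates its own inputs from `sim` (synthetic
#' mode).  When `h2_override` is given and `fit = FALSE`, the pipeline runs
#' in calculator mode: risk outputs only, from the supplied heritability.
#'
#' @param out_dir output directory for the report files.
#' @param sumstats_path,panel optional real inputs; `panel` may be a
#'   `reference_panel` object.
#' @param sim list of simulation settings: `m` (panel SNPs), `pi_c`,
#'   `weights`, `variances`, `n_cases`, `n_controls`, `n_jitter`,
#'   `block_size`, `rho`.
#' @param chi2_threshold,window,r2_threshold QC parameters.
#' @param fit whether to fit the mixture (disable for calculator mode).
#' @param n_components components to fit and compare (subset of 2:3).
#' @param scenarios sample-size multipliers for the risk scenarios.
#' @param life_tables a `life_tables` object (a default synthetic one is
#'   built when omitted).
#' @param h2_override heritability for calculator mode.
#' @param seed integer seed recorded in, and reproducing, every report.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("polyarch"),
                       sumstats_path = NULL, panel = NULL,
                       sim = list(), chi2_threshold = 80,
                       window = 1000000, r2_threshold = 0.1,
                       fit = TRUE, n_components = c(2L, 3L),
                       scenarios = c(current = 1, doubled = 2,
                                     quadrupled = 4),
                       life_tables = NULL, h2_override = NULL,
                       seed = 1) {
  sim_defaults <- list(m = 50000, pi_c = 0.01, weights = 1,
                       variances = 2e-4, n_cases = 25000,
                       n_controls = 25000, n_jitter = 0.1,
                       block_size = 1, rho = 0)
  sim <- utils::modifyList(sim_defaults, sim)
  if (chi2_threshold <= 0 || window <= 0 || r2_threshold <= 0)
    stop_arg("QC thresholds must be positive")
  structure(list(out_dir = out_dir, sumstats_path = sumstats_path,
                 panel = panel, sim = sim,
                 chi2_threshold = chi2_threshold, window = window,
                 r2_threshold = r2_threshold, fit = fit,
                 n_components = as.integer(n_components),
                 scenarios = scenarios, life_tables = life_tables,
                 h2_override = h2_override, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full architecture-and-projection pipeline
#'
#' Synthetic or file inputs -> four-step QC -> mixture fits and model
#' selection -> heritability with add-back -> projection curves at
#' genome-wide-significant and optimized thresholds over current, doubled
#' and quadrupled sample sizes -> residual-lifetime-risk distributions for
#' the four scenarios (current/doubled/quadrupled/best).  All outputs are
#' written as tab-separated text under `config$out_dir` and returned.
#'
#' @param config a [run_config()].
#' @return invisibly, a report bundle: list with `config`, `qc`
#'   (records/large/drops), `fits`, `fit` (selected), `heritability`,
#'   `table1`, `projections`, `risk`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  s <- config$sim
  n_eff <- effective_sample_size(s$n_cases, s$n_controls)
  tables <- config$life_tables %||% make_life_tables(seed = seed)

  files <- character(0)
  out <- function(name) file.path(config$out_dir, name)

  # calculator mode: heritability supplied, no fitting
  if (!config$fit) {
    if (is.null(config$h2_override))
      stop_arg("calculator mode needs h2_override")
    risk <- risk_scenarios(rep(config$h2_override, length(config$scenarios)),
                           config$h2_override, tables, config$scenarios)
    utils::write.table(risk, out("risk_distribution.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    bundle <- list(config = config, risk = risk,
                   files = out("risk_distribution.tsv"))
    return(invisible(bundle))
  }

  # inputs
  if (is.null(config$sumstats_path)) {
    panel <- config$panel %||% make_reference_panel(
      s$m, n_chromosomes = 22, block_size = s$block_size,
      ld_mode = if (s$rho > 0) "ar1" else "independent",
      rho = s$rho, seed = seed)
    truth <- mixture_model(s$m, s$pi_c, s$weights, s$variances)
    arch <- simulate_effect_sizes(panel, truth, seed = seed + 1L)
    records <- simulate_summary_stats(arch, s$n_cases, s$n_controls,
                                      seed = seed + 2L,
                                      n_jitter = s$n_jitter, panel = panel)
    truth_info <- truth
  } else {
    panel <- config$panel
    if (is.null(panel)) stop_arg("file mode requires a reference panel")
    records <- read_sumstats(config$sumstats_path)
    truth_info <- NULL
  }

  # QC
  qc <- qc_pipeline(records, panel, config$chi2_threshold, config$window,
                    config$r2_threshold)
  utils::write.table(qc$drops, out("qc_drops.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message(sprintf("QC: %d records in, %d out, %d dropped, %d large-effect tops",
                  nrow(records), nrow(qc$records), nrow(qc$drops),
                  nrow(qc$large$top)))

  # fit; M refers to the post-QC record count
  fits <- lapply(config$n_components, function(k)
    fit_mixture(qc$records, n_eff, n_components = k))
  names(fits) <- paste0("c", config$n_components)
  fit <- if (length(fits) == 2) select_model(fits[[1]], fits[[2]])
         else { attr(fits[[1]], "label") <-
                  c("two-component", "three-component")[fits[[1]]$n_components - 1L]
                fits[[1]] }
  message("selected model: ", attr(fit, "label"))
  herit <- total_heritability(fit, qc$large)

  t1 <- table1_analog(fit, qc$large)
  utils::write.table(t1, out("architecture_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # projections over current / doubled / quadrupled effective sizes
  n_grid <- n_eff * config$scenarios
  proj <- projection_curve(fit$model, qc$large, n_grid)
  proj$scenario <- rep(names(config$scenarios), each = 2)
  utils::write.table(proj, out("projection_curve.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # risk distributions: three scenarios at the optimized threshold + best
  h2_prs <- vapply(n_grid, function(n)
    optimize_threshold(fit$model, qc$large, n)$h2_prs, numeric(1))
  risk <- risk_scenarios(h2_prs, herit$h2, tables, config$scenarios)
  utils::write.table(risk, out("risk_distribution.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  files <- c(out("qc_drops.tsv"), out("architecture_report.tsv"),
             out("projection_curve.tsv"), out("risk_distribution.tsv"))
  invisible(list(config = config, truth = truth_info, qc = qc,
                 fits = fits, fit = fit, heritability = herit,
                 table1 = t1, projections = proj, risk = risk,
                 files = files))
}

risk_scenarios <- function(h2_prs_by_scenario, h2_best, tables,
                           scenarios) {
  labs <- c(names(scenarios), "best")
  h2s <- c(h2_prs_by_scenario, h2_best)
  do.call(rbind, lapply(seq_along(labs), function(i) {
    rd <- risk_distribution(h2s[i], tables)
    rd$scenario <- labs[i]
    rd$h2_prs <- h2s[i]
    rd
  }))
}

#' Architecture summary row (Table-1 style)
#'
#' One row summarizing a fitted architecture: susceptibility-SNP count with
#' large-effect tops, total heritability with add-back, average per-SNP
#' heritability excluding the large-effect SNPs, the share of heritability
#' in the larger-variance component (NA when the two-component model was
#' selected), and the best-PRS AUC `Phi(sqrt(h2/2))`.  SEs by the delta
#' method from the fit covariance.
#'
#' @param fit a `mixture_fit` (ideally the output of [select_model()]).
#' @param large a `large_effect_set` or `NULL`.
#' @return one-row data.frame.
#' @export
table1_analog <- function(fit, large = NULL) {
  h <- total_heritability(fit, large)
  three <- fit$n_components == 3L
  data.frame(
    model = attr(fit, "label") %||%
      c("two-component", "three-component")[fit$n_components - 1L],
    n_susceptibility = h$n_susceptibility,
    se_n_susceptibility = h$se_n_susceptibility,
    h2 = h$h2, se_h2 = h$se_h2,
    per_snp_h2 = h$per_snp_h2,
    n_large = h$n_large,
    pct_larger_component = if (three) 100 * h$upsilon else NA_real_,
    auc_best_prs = auc_from_h2(h$h2))
}
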