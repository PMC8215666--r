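#' Analysis configuration
#'
#' Bundles every tunable of a direction analysis. Defaults follow common
#' two-sample MR practice: a suggestive exposure threshold of 5e-6 (use 5e-8
#' for well-powered exposure GWAS), clumping at r² <= 0.001 within 10,000 kb,
#' palindromic variants dropped when their allele frequency is within 0.08 of
#' 0.5, the IVW model chosen automatically (fixed effects for J <= 3,
#' multiplicative random effects otherwise), a 10,000-draw weighted-median
#' bootstrap, and two-sided alpha 0.05.
#'
#' @param p_threshold_exposure Exposure association threshold (strict `<`).
#' @param clump_r2 Clumping r² threshold.
#' @param clump_window_kb Clumping window, kilobases.
#' @param palindromic_eaf_window Frequency half-window for dropping
#'   palindromic variants, see [harmonize()].
#' @param ivw_model `"auto"`, `"fixed"` or `"random"`, see [mr_ivw()].
#' @param n_bootstrap Weighted-median bootstrap draws.
#' @param seed Integer seed for all stochastic steps.
#' @param alpha Two-sided significance level.
#' @param confounder_traits Trait labels treated as confounders by
#'   [exclude_blocklisted()].
#' @param power_effect Absolute causal-effect size (outcome units per
#'   exposure unit) at which [power_estimate()] evaluates the study's power.
#' @return An object of class `mr_config`.
#' @export
mr_config <- function(p_threshold_exposure = 5e-6,
                      clump_r2 = 0.001,
                      clump_window_kb = 10000,
                      palindromic_eaf_window = 0.08,
                      ivw_model = c("auto", "random", "fixed"),
                      n_bootstrap = 10000,
                      seed = 1L,
                      alpha = 0.05,
                      confounder_traits = character(0),
                      power_effect = 1) {
  ivw_model <- match.arg(ivw_model)
  stopifnot(
    p_threshold_exposure > 0, p_threshold_exposure < 1,
    clump_r2 >= 0, clump_r2 <= 1, clump_window_kb > 0,
    palindromic_eaf_window >= 0, palindromic_eaf_window < 0.5,
    n_bootstrap >= 2, alpha > 0, alpha < 1, power_effect >= 0,
    is.numeric(seed), length(seed) == 1L, is.finite(seed)
  )
  structure(list(
    p_threshold_exposure = p_threshold_exposure, clump_r2 = clump_r2,
    clump_window_kb = clump_window_kb,
    palindromic_eaf_window = palindromic_eaf_window, ivw_model = ivw_model,
    n_bootstrap = n_bootstrap, seed = as.integer(seed), alpha = alpha,
    confounder_traits = confounder_traits, power_effect = power_effect
  ), class = "mr_config")
}

#' Read an analysis configuration from JSON
#'
#' @param path Path to a JSON file whose keys are [mr_config()] arguments;
#'   absent keys take the defaults.
#' @return An `mr_config`.
#' @export
read_mr_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(vals), names(formals(mr_config)))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(mr_config, vals)
}

#' Statistical power of a two-sample MR analysis
#'
#' Normal-approximation power for detecting a causal effect of given size
#' with instruments explaining a fraction `r2_instruments` of the exposure
#' variance in an outcome sample of size `n_outcome`. For a continuous
#' outcome the noncentrality is \eqn{|\theta|\sqrt{n r^2}} (effect on the
#' standardized scale) and
#' \deqn{power = 1 - \Phi(z_{1-\alpha/2} - ncp) + \Phi(-z_{1-\alpha/2} - ncp).}
#' For a binary outcome the same formula applies with the noncentrality
#' scaled by \eqn{\sqrt{cf(1-cf)}} for case fraction cf (the effect then
#' being a log odds ratio).
#'
#' @param n_outcome Outcome GWAS sample size.
#' @param r2_instruments Variance of the exposure explained by the
#'   instruments, in (0, 1).
#' @param effect Hypothesized causal effect.
#' @param alpha Two-sided significance level.
#' @param binary Is the outcome binary?
#' @param case_fraction Case fraction of the outcome GWAS; required when
#'   `binary = TRUE`.
#' @return Power, in (0, 1).
#' @examples
#' power_estimate(439303, 0.002, effect = 0.2)
#' @export
power_estimate <- function(n_outcome, r2_instruments, effect, alpha = 0.05,
                           binary = FALSE, case_fraction = NULL) {
  stopifnot(n_outcome >= 1, r2_instruments > 0, r2_instruments < 1,
            alpha > 0, alpha < 1)
  if (binary && is.null(case_fraction)) {
    stop("case_fraction is required for a binary outcome")
  }
  scale2 <- if (binary) case_fraction * (1 - case_fraction) else 1
  ncp <- abs(effect) * sqrt(n_outcome * r2_instruments * scale2)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
}

#' Run one causal direction end to end
#'
#' Applies the selection chain (association threshold, blocklist, LD
#' clumping when an LD matrix is supplied, harmonization, Steiger
#' directionality filtering), then every applicable estimator: per-SNP Wald
#' ratios, IVW, and -- when at least three instruments remain -- the
#' weighted median and MR-Egger, plus Cochran's Q against the IVW estimate
#' and the study's power at `config$power_effect`. Deterministic given
#' `config$seed`.
#'
#' @param exposure_table,outcome_table Association `data.frame`s.
#' @param exposure_meta,outcome_meta [study_meta()] objects.
#' @param config An [mr_config()].
#' @param ld Optional `ld_matrix` for clumping (skipped when `NULL`).
#' @param blocklist Optional blocklist `data.frame` (see
#'   [exclude_blocklisted()]).
#' @return An object of class `direction_report`: a list with `exposure`,
#'   `outcome`, `instrument_set`, `selection` (drop log over all stages),
#'   `per_snp_wald`, `method_results`, `heterogeneity`, `power`,
#'   `r2_instruments` and `config`.
#' @export
run_direction <- function(exposure_table, outcome_table,
                          exposure_meta, outcome_meta,
                          config = mr_config(), ld = NULL, blocklist = NULL) {
  stopifnot(inherits(config, "mr_config"))
  exposure_table <- validate_sumstats(exposure_table, "exposure table")
  outcome_table <- validate_sumstats(outcome_table, "outcome table")
  if (nrow(exposure_table) == 0L) stop("empty exposure table")

  stage <- "pvalue filter"
  res <- tryCatch({
    sel_p <- filter_by_pvalue(exposure_table, config$p_threshold_exposure)
    if (nrow(sel_p$records) == 0L) {
      stop("no instruments pass p < ", config$p_threshold_exposure)
    }
    stage <- "blocklist filter"
    sel_b <- exclude_blocklisted(sel_p$records, blocklist,
                                 config$confounder_traits,
                                 outcome_meta$trait)
    stage <- "LD clumping"
    sel_c <- if (is.null(ld)) {
      new_selection_report(sel_b$records, character(0), "clump", character(0))
    } else {
      ld_clump(sel_b$records, ld, config$clump_r2, config$clump_window_kb)
    }
    if (nrow(sel_c$records) == 0L) stop("no instruments left after clumping")
    stage <- "harmonization"
    iset <- build_instrument_set(sel_c$records, outcome_table,
                                 exposure_meta, outcome_meta,
                                 config$palindromic_eaf_window)
    stage <- "Steiger filtering"
    sel_s <- steiger_filter(iset)
    iset <- subset_instruments(iset, sel_s$retained)
    if (nrow(iset$instruments) == 0L) {
      stop("no instruments left after Steiger filtering")
    }
    dropped <- rbind(sel_p$dropped, sel_b$dropped, sel_c$dropped,
                     iset$drop_log, sel_s$dropped)

    stage <- "estimation"
    J <- nrow(iset$instruments)
    per_snp <- do.call(rbind, lapply(seq_len(J), function(j) {
      r <- wald_ratio(iset$instruments[j, ], config$alpha)
      cbind(SNP = iset$instruments$SNP[j], as.data.frame(r))
    }))
    methods <- mr_ivw(iset, config$ivw_model, config$alpha)
    het <- if (J >= 2L) cochran_q(iset, methods$estimate[1]) else NULL
    if (J >= 3L) {
      methods <- rbind(methods,
                       mr_weighted_median(iset, config$n_bootstrap,
                                          config$seed, config$alpha),
                       mr_egger(iset, config$alpha))
    }
    stage <- "power"
    r2 <- sum(sel_s$records$r2_exposure)
    power <- power_estimate(
      outcome_meta$n_total, r2, config$power_effect, config$alpha,
      binary = !is.null(outcome_meta$n_cases),
      case_fraction = if (!is.null(outcome_meta$n_cases)) {
        outcome_meta$n_cases / outcome_meta$n_total
      } else NULL)

    structure(list(
      exposure = exposure_meta, outcome = outcome_meta,
      instrument_set = iset, selection = dropped, per_snp_wald = per_snp,
      method_results = methods, heterogeneity = het, power = power,
      r2_instruments = r2, config = config, failed = FALSE, error = NULL
    ), class = "direction_report")
  }, error = function(e) {
    stop(sprintf("[%s -> %s, stage: %s] %s", exposure_meta$trait,
                 outcome_meta$trait, stage, conditionMessage(e)),
         call. = FALSE)
  })
  res
}

#' Run the full bidirectional periodontitis/kidney analysis
#'
#' Executes the four causal directions -- CP→eGFR, CP→BUN, eGFR→CP, BUN→CP
#' -- each with [run_direction()]. Directions are independent: a failure in
#' one is captured in its slot (`failed = TRUE` with the error message) and
#' does not abort the others. The exposure p-value threshold may differ
#' between the periodontitis exposure (suggestive, default 5e-6) and the
#' kidney-function exposures (genome-wide, default 5e-8).
#'
#' @param tables Named list of association `data.frame`s: `cp_exposure`,
#'   `egfr_outcome`, `bun_outcome` (outcome statistics for the CP
#'   instruments), `egfr_exposure`, `bun_exposure`, `cp_outcome` (CP outcome
#'   statistics for the kidney instruments). [cpkd_tables()] returns this
#'   structure.
#' @param metas Named list of [study_meta()]: `cp`, `egfr`, `bun`.
#' @param config Base [mr_config()] shared by all directions.
#' @param p_threshold_cp,p_threshold_kidney Per-exposure association
#'   thresholds.
#' @param ld,blocklist Passed to every direction.
#' @return Named list of four `direction_report`s (`cp_egfr`, `cp_bun`,
#'   `egfr_cp`, `bun_cp`), class `bidirectional_report`.
#' @export
run_bidirectional <- function(tables, metas, config = mr_config(),
                              p_threshold_cp = 5e-6,
                              p_threshold_kidney = 5e-8,
                              ld = NULL, blocklist = NULL) {
  need <- c("cp_exposure", "egfr_outcome", "bun_outcome",
            "egfr_exposure", "bun_exposure", "cp_outcome")
  missing_tab <- setdiff(need, names(tables))
  if (length(missing_tab)) {
    stop("missing table(s): ", paste(missing_tab, collapse = ", "))
  }
  stopifnot(all(c("cp", "egfr", "bun") %in% names(metas)))

  with_threshold <- function(cfg, thr) {
    cfg$p_threshold_exposure <- thr
    cfg
  }
  plan <- list(
    cp_egfr = list(exp = "cp_exposure", out = "egfr_outcome",
                   em = "cp", om = "egfr", thr = p_threshold_cp),
    cp_bun = list(exp = "cp_exposure", out = "bun_outcome",
                  em = "cp", om = "bun", thr = p_threshold_cp),
    egfr_cp = list(exp = "egfr_exposure", out = "cp_outcome",
                   em = "egfr", om = "cp", thr = p_threshold_kidney),
    bun_cp = list(exp = "bun_exposure", out = "cp_outcome",
                  em = "bun", om = "cp", thr = p_threshold_kidney)
  )
  reports <- lapply(plan, function(d) {
    tryCatch(
      run_direction(tables[[d$exp]], tables[[d$out]],
                    metas[[d$em]], metas[[d$om]],
                    with_threshold(config, d$thr), ld, blocklist),
      error = function(e) {
        structure(list(exposure = metas[[d$em]], outcome = metas[[d$om]],
                       failed = TRUE, error = conditionMessage(e)),
                  class = "direction_report")
      })
  })
  structure(reports, class = "bidirectional_report")
}

#' @export
print.direction_report <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat(sprintf("<direction_report> %s -> %s: FAILED (%s)\n",
                x$exposure$trait, x$outcome$trait, x$error))
    return(invisible(x))
  }
  cat(sprintf("<direction_report> %s -> %s: J = %d, power = %.3f at effect %g\n",
              x$exposure$trait, x$outcome$trait,
              nrow(x$instrument_set$instruments), x$power,
              x$config$power_effect))
  print(x$method_results)
  invisible(x)
}

#' @export
print.bidirectional_report <- function(x, ...) {
  for (r in x) {
    print(r)
    cat("\n")
  }
  invisible(x)
}

#' Forest-plot data for a direction report
#'
#' One row per instrument (its Wald ratio) followed by one row per combined
#' estimator, each with estimate, confidence bounds and p-value -- the data
#' behind a standard MR forest plot.
#'
#' @param report A `direction_report`.
#' @return `data.frame` with columns `label, type, estimate, ci_low,
#'   ci_high, p`.
#' @export
forest_data <- function(report) {
  stopifnot(inherits(report, "direction_report"))
  if (isTRUE(report$failed)) stop("cannot tabulate a failed direction report")
  snp_rows <- data.frame(
    label = report$per_snp_wald$SNP, type = "snp",
    estimate = report$per_snp_wald$estimate,
    ci_low = report$per_snp_wald$ci_low,
    ci_high = report$per_snp_wald$ci_high,
    p = report$per_snp_wald$p, stringsAsFactors = FALSE)
  m <- report$method_results
  method_rows <- data.frame(
    label = m$method, type = "method", estimate = m$estimate,
    ci_low = m$ci_low, ci_high = m$ci_high, p = m$p,
    stringsAsFactors = FALSE)
  rbind(snp_rows, method_rows)
}

#' Scatter-plot data for a direction report
#'
#' Per-instrument exposure and outcome associations (the points) plus the
#' fitted line of each combined estimator (through the origin for IVW and
#' the weighted median; intercept plus slope for MR-Egger). Slopes are taken
#' from the stored results, never re-estimated.
#'
#' @param report A `direction_report`.
#' @return List with `points` (`data.frame`: `SNP, beta_exposure,
#'   se_exposure, beta_outcome, se_outcome`) and `lines` (`data.frame`:
#'   `method, slope, intercept`).
#' @export
scatter_data <- function(report) {
  stopifnot(inherits(report, "direction_report"))
  if (isTRUE(report$failed)) stop("cannot tabulate a failed direction report")
  ins <- report$instrument_set$instruments
  points <- ins[c("SNP", "beta_exposure", "se_exposure",
                  "beta_outcome", "se_outcome")]
  m <- report$method_results
  slopes <- m[m$method %in% c("ivw", "wm", "egger-slope"), ]
  intercept <- if ("egger-intercept" %in% m$method) {
    m$estimate[m$method == "egger-intercept"]
  } else NA_real_
  lines <- data.frame(
    method = sub("egger-slope", "egger", slopes$method),
    slope = slopes$estimate,
    intercept = ifelse(slopes$method == "egger-slope", intercept, 0),
    stringsAsFactors = FALSE)
  rownames(points) <- rownames(lines) <- NULL
  list(points = points, lines = lines)
}

#' Serialize a direction report
#'
#' Writes the tidy results table
#' (`EXPOSURE OUTCOME METHOD NSNP ESTIMATE SE CI_LOW CI_HIGH P Q SCALE`),
#' a JSON rendering of the full report, the selection drop log, and the
#' forest/scatter tables, into `dir`. File contents are a pure function of
#' the report, so repeated runs with the same inputs and seed are
#' byte-identical.
#'
#' @param report A `direction_report`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; defaults to `exposure_to_outcome`.
#' @return Character vector of the paths written, invisibly.
#' @export
write_direction_report <- function(report, dir, prefix = NULL) {
  stopifnot(inherits(report, "direction_report"))
  if (isTRUE(report$failed)) stop("cannot serialize a failed direction report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(prefix)) {
    prefix <- paste0(report$exposure$trait, "_to_", report$outcome$trait)
  }
  p <- function(suffix) file.path(dir, paste0(prefix, suffix))

  all_rows <- rbind(
    cbind(METHOD_LABEL = report$per_snp_wald$SNP,
          as.data.frame(report$per_snp_wald[-1])),
    cbind(METHOD_LABEL = report$method_results$method,
          as.data.frame(report$method_results)))
  tidy <- data.frame(
    EXPOSURE = report$exposure$trait, OUTCOME = report$outcome$trait,
    METHOD = all_rows$METHOD_LABEL, NSNP = all_rows$n_snps,
    ESTIMATE = round(all_rows$estimate, 3), SE = round(all_rows$se, 3),
    CI_LOW = round(all_rows$ci_low, 3), CI_HIGH = round(all_rows$ci_high, 3),
    P = signif(all_rows$p, 3), Q = round(all_rows$q_statistic, 3),
    SCALE = round(all_rows$scale_factor, 3))
  utils::write.table(tidy, p("_results.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  write_selection_report(
    structure(list(retained = report$instrument_set$instruments$SNP,
                   dropped = report$selection,
                   records = report$instrument_set$instruments),
              class = "selection_report"),
    p("_selection.tsv"))
  utils::write.table(forest_data(report), p("_forest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  sc <- scatter_data(report)
  utils::write.table(sc$points, p("_scatter_points.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(sc$lines, p("_scatter_lines.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  jsonlite::write_json(report_to_list(report), p("_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p("_results.tsv"), p("_selection.tsv"), p("_forest.tsv"),
              p("_scatter_points.tsv"), p("_scatter_lines.tsv"),
              p("_report.json")))
}

# plain-list rendering of a report for JSON serialization
report_to_list <- function(report) {
  meta_list <- function(m) m[!vapply(m, is.null, logical(1))]
  list(
    exposure = meta_list(unclass(report$exposure)),
    outcome = meta_list(unclass(report$outcome)),
    n_instruments = nrow(report$instrument_set$instruments),
    instruments = report$instrument_set$instruments,
    dropped = report$selection,
    per_snp_wald = report$per_snp_wald,
    method_results = as.data.frame(report$method_results),
    heterogeneity = if (!is.null(report$heterogeneity)) {
      report$heterogeneity[c("q", "df", "p")]
    },
    power = report$power,
    r2_instruments = report$r2_instruments,
    config = unclass(report$config)
  )
}
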