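#' Simulation scenario for paired two-sample summary statistics
#'
#' Parameterizes the generative model the estimators assume. For each of J
#' variants a true exposure effect \eqn{\beta_{Xj}} is drawn uniformly from
#' `beta_range` in magnitude with random sign; a direct (pleiotropic) effect
#' \eqn{\alpha_j} is 0 (`"none"`), zero-mean normal (`"balanced"`) or normal
#' with nonzero mean (`"directional"`), carried by a fraction
#' `pleiotropy_frac` of the variants; the true outcome effect is
#' \eqn{\beta_{Yj} = \theta\,\beta_{Xj} + \alpha_j}. Directional pleiotropic
#' effects are aligned with the sign of \eqn{\beta_{Xj}}, so their mean is
#' defined relative to the exposure-increasing allele -- the orientation
#' under which the Egger intercept estimates it -- while allele coding in
#' the emitted tables stays arbitrary. Standard errors follow
#' the standardized-trait model \eqn{se = 1/\sqrt{2\,n\,maf(1-maf)}} at each
#' study's sample size, and observed betas add normal noise with those SEs
#' (scaled by `noise_scale`; 0 gives the noiseless limit).
#'
#' @param n_snps Number of instruments J (>= 1).
#' @param true_effect Causal effect theta of exposure on outcome.
#' @param beta_range Magnitude range (low, high) of true exposure effects.
#' @param n_exposure,n_outcome GWAS sample sizes of the two studies.
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_sd SD of the pleiotropic effects (>= 0).
#' @param pleiotropy_mean Mean pleiotropic effect (directional mode only).
#' @param pleiotropy_frac Fraction of variants carrying a pleiotropic effect.
#' @param maf_range Minor-allele-frequency range, within (0, 0.5].
#' @param noise_scale Multiplier on the sampling noise (default 1).
#' @param seed Integer seed; identical scenarios yield identical data.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_snps, true_effect,
                         beta_range = c(0.05, 0.2),
                         n_exposure = 50000, n_outcome = 50000,
                         pleiotropy = c("none", "balanced", "directional"),
                         pleiotropy_sd = 0, pleiotropy_mean = 0,
                         pleiotropy_frac = 1,
                         maf_range = c(0.1, 0.5),
                         noise_scale = 1, seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(
    n_snps >= 1, length(beta_range) == 2L,
    beta_range[1] > 0, beta_range[2] >= beta_range[1],
    n_exposure >= 1, n_outcome >= 1,
    pleiotropy_sd >= 0, pleiotropy_frac >= 0, pleiotropy_frac <= 1,
    length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[2] >= maf_range[1], noise_scale >= 0,
    is.numeric(seed), length(seed) == 1L, is.finite(seed)
  )
  if (pleiotropy == "directional" && pleiotropy_mean == 0) {
    warning("directional pleiotropy with zero mean is balanced pleiotropy",
            call. = FALSE)
  }
  structure(list(
    n_snps = as.integer(n_snps), true_effect = true_effect,
    beta_range = beta_range, n_exposure = n_exposure, n_outcome = n_outcome,
    pleiotropy = pleiotropy, pleiotropy_sd = pleiotropy_sd,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_frac = pleiotropy_frac,
    maf_range = maf_range, noise_scale = noise_scale,
    seed = as.integer(seed)
  ), class = "sim_scenario")
}

# non-palindromic ordered allele pairs
.allele_pairs <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
)

#' Simulate a paired exposure/outcome summary-statistics table
#'
#' Draws one realization of the scenario's generative model and returns both
#' GWAS tables in the native summary-statistics layout together with the
#' generating truth, so that estimator calibration (bias, coverage, type-I
#' error) is checkable against known parameters.
#'
#' @param scenario A [sim_scenario()].
#' @return An object of class `simulated_pair`: list with `exposure_table`,
#'   `outcome_table` (association `data.frame`s sharing SNP ids and alleles)
#'   and `truth` (list: `true_effect`, `alpha` (per-SNP pleiotropic
#'   effects), `beta_x_true`, `beta_y_true`).
#' @export
simulate_pair <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  s <- scenario
  local_seed(s$seed, {
    J <- s$n_snps
    snp <- sprintf("snp%04d", seq_len(J))
    pair <- .allele_pairs[sample.int(nrow(.allele_pairs), J, replace = TRUE), ,
                          drop = FALSE]
    maf <- stats::runif(J, s$maf_range[1], s$maf_range[2])
    bx_true <- stats::runif(J, s$beta_range[1], s$beta_range[2]) *
      sample(c(-1, 1), J, replace = TRUE)
    alpha <- rep(0, J)
    if (s$pleiotropy != "none" && s$pleiotropy_frac > 0) {
      n_pleio <- ceiling(s$pleiotropy_frac * J)
      idx <- sample.int(J, n_pleio)
      mu <- if (s$pleiotropy == "directional") s$pleiotropy_mean else 0
      alpha[idx] <- stats::rnorm(n_pleio, mu, s$pleiotropy_sd)
      if (s$pleiotropy == "directional") {
        # directional means consistent relative to the exposure-increasing
        # allele: align the direct effect with the sign of the true
        # exposure effect (allele coding in the tables stays arbitrary)
        alpha <- alpha * sign(bx_true)
      }
    }
    by_true <- s$true_effect * bx_true + alpha

    se_x <- 1 / sqrt(2 * s$n_exposure * maf * (1 - maf))
    se_y <- 1 / sqrt(2 * s$n_outcome * maf * (1 - maf))
    bx <- bx_true + s$noise_scale * stats::rnorm(J, 0, se_x)
    by <- by_true + s$noise_scale * stats::rnorm(J, 0, se_y)

    tab <- function(beta, se) {
      validate_sumstats(data.frame(
        SNP = snp, CHR = "1", EA = pair[, 1], OA = pair[, 2], EAF = maf,
        BETA = beta, SE = se, P = pmax(2 * stats::pnorm(-abs(beta / se)),
                                       .Machine$double.xmin),
        stringsAsFactors = FALSE), "simulated table")
    }
    exposure_table <- tab(bx, se_x)
    exposure_table$N <- s$n_exposure
    outcome_table <- tab(by, se_y)
    outcome_table$N <- s$n_outcome
    structure(list(
      exposure_table = exposure_table, outcome_table = outcome_table,
      truth = list(true_effect = s$true_effect, alpha = alpha,
                   beta_x_true = bx_true, beta_y_true = by_true),
      scenario = s
    ), class = "simulated_pair")
  })
}

#' Write a simulated pair with its truth sidecar
#'
#' Writes the exposure and outcome tables in the native dialect plus a JSON
#' sidecar holding the generating parameters and per-SNP truth.
#'
#' @param pair A `simulated_pair`.
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Paths written, invisibly.
#' @export
write_simulated_pair <- function(pair, out_dir, prefix = "sim") {
  stopifnot(inherits(pair, "simulated_pair"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    exposure = file.path(out_dir, paste0(prefix, "_exposure.tsv")),
    outcome = file.path(out_dir, paste0(prefix, "_outcome.tsv")),
    truth = file.path(out_dir, paste0(prefix, "_truth.json"))
  )
  write_sumstats(pair$exposure_table, paths[["exposure"]])
  write_sumstats(pair$outcome_table, paths[["outcome"]])
  jsonlite::write_json(
    c(list(snp = pair$exposure_table$SNP), pair$truth,
      scenario = list(unclass(pair$scenario))),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Simulate an exponential-decay LD block
#'
#' A one-block LD structure with \eqn{r^2_{ij} = \exp(-decay\,|i-j|)}:
#' adjacent variants are strongly correlated and correlation decays with
#' index distance. Deterministic; exercises the clumping stage.
#'
#' @param n_snps Number of variants (>= 1).
#' @param decay_rate Decay rate per index step (>= 0); 0 gives an all-ones
#'   matrix (one clump), large values give near-independence.
#' @param snp_ids Optional identifiers; default `snp0001...`.
#' @return An `ld_matrix`.
#' @export
simulate_ld_block <- function(n_snps, decay_rate, snp_ids = NULL) {
  stopifnot(n_snps >= 1, decay_rate >= 0)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%04d", seq_len(n_snps))
  stopifnot(length(snp_ids) == n_snps)
  idx <- seq_len(n_snps)
  r2 <- exp(-decay_rate * abs(outer(idx, idx, "-")))
  ld_matrix(r2, snp_ids)
}
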