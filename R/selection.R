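#' @title Instrument selection
#' @description Selection stages implementing the three instrumental-variable
#'   assumptions: relevance (association-strength threshold), independence
#'   (confounder/outcome blocklist, LD clumping) and directionality (Steiger
#'   filtering). Each stage partitions its input into retained and dropped
#'   records and returns a `selection_report`.
#' @name selection
NULL

new_selection_report <- function(records, dropped_snps, stage, reason,
                                 prior = NULL) {
  dropped <- data.frame(SNP = dropped_snps,
                        stage = rep_len(stage, length(dropped_snps)),
                        reason = rep_len(reason, length(dropped_snps)),
                        stringsAsFactors = FALSE)
  if (!is.null(prior)) dropped <- rbind(prior, dropped)
  structure(list(records = records, retained = records$SNP, dropped = dropped),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d retained, %d dropped\n",
              length(x$retained), nrow(x$dropped)))
  if (nrow(x$dropped)) print(x$dropped, row.names = FALSE)
  invisible(x)
}

#' Write a selection report to a tab-separated file
#'
#' One row per dropped SNP with columns `SNP STAGE REASON`.
#'
#' @param report A `selection_report`.
#' @param path Output path.
#' @export
write_selection_report <- function(report, path) {
  stopifnot(inherits(report, "selection_report"))
  out <- report$dropped
  names(out) <- c("SNP", "STAGE", "REASON")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Relevance filter: retain associations below a p-value threshold
#'
#' Retains records with `P` strictly below `threshold`. The conventional
#' thresholds are genome-wide significance 5e-8, relaxed to a suggestive
#' 5e-6 for traits (such as periodontitis) whose GWAS yield few
#' genome-wide-significant hits.
#'
#' @param records Association `data.frame`.
#' @param threshold P-value threshold in (0, 1); strict inequality.
#' @return A `selection_report`.
#' @export
filter_by_pvalue <- function(records, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  keep <- records$P < threshold
  new_selection_report(records[keep, , drop = FALSE], records$SNP[!keep],
                       "pvalue", sprintf("p >= %g", threshold))
}

#' Read a variant blocklist
#'
#' Tab-separated file with columns `SNP TRAIT SOURCE`, listing variants with
#' reported associations to other traits (a local stand-in for a trait
#' catalog query, so selection is reproducible offline).
#'
#' @param path Path to the blocklist file.
#' @return `data.frame` with columns `SNP, TRAIT, SOURCE`.
#' @export
read_blocklist <- function(path) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character", check.names = FALSE)
  need <- c("SNP", "TRAIT", "SOURCE")
  if (!all(need %in% names(x))) {
    stop("blocklist must have columns ", paste(need, collapse = " "))
  }
  x[need]
}

#' Independence filter: drop variants associated with the outcome or confounders
#'
#' Drops any record whose SNP appears in the blocklist with a trait equal to
#' the outcome trait or in `confounder_traits` (case-insensitive match),
#' enforcing the assumption that instruments act on the outcome only through
#' the exposure and are unrelated to confounders.
#'
#' @param records Association `data.frame`.
#' @param blocklist `data.frame` with columns `SNP, TRAIT` (and optionally
#'   `SOURCE`), e.g. from [read_blocklist()]; `NULL` for no blocklist.
#' @param confounder_traits Character vector of confounder trait labels.
#' @param outcome_trait Outcome trait label, or `NULL`.
#' @return A `selection_report`.
#' @export
exclude_blocklisted <- function(records, blocklist,
                                confounder_traits = character(0),
                                outcome_trait = NULL) {
  if (is.null(blocklist) || nrow(blocklist) == 0L) {
    return(new_selection_report(records, character(0), "blocklist",
                                character(0)))
  }
  bad_traits <- tolower(c(confounder_traits, outcome_trait))
  hits <- blocklist[tolower(blocklist$TRAIT) %in% bad_traits, , drop = FALSE]
  drop <- records$SNP %in% hits$SNP
  reason <- vapply(records$SNP[drop], function(s) {
    paste0("associated with ",
           paste(unique(hits$TRAIT[hits$SNP == s]), collapse = "/"))
  }, character(1))
  new_selection_report(records[!drop, , drop = FALSE], records$SNP[drop],
                       "blocklist", unname(reason))
}

#' LD matrix constructor
#'
#' @param r2 Square numeric matrix of pairwise squared allelic correlations.
#' @param snp_ids SNP identifiers; defaults to the matrix dimnames.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, snp_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(snp_ids)) stop("snp_ids required when r2 has no dimnames")
  dimnames(r2) <- list(snp_ids, snp_ids)
  validate_ld_matrix(structure(list(snp_ids = snp_ids, r2 = r2),
                               class = "ld_matrix"))
}

validate_ld_matrix <- function(ld) {
  r2 <- ld$r2
  if (!is.matrix(r2) || nrow(r2) != ncol(r2)) {
    stop("LD matrix must be square")
  }
  if (length(ld$snp_ids) != nrow(r2) || anyDuplicated(ld$snp_ids)) {
    stop("LD matrix snp_ids must be unique and match the matrix dimension")
  }
  if (any(is.na(r2)) || any(r2 < 0) || any(r2 > 1)) {
    stop("LD r-squared values must lie in [0, 1]")
  }
  if (any(abs(r2 - t(r2)) > 1e-12)) stop("LD matrix must be symmetric")
  if (any(abs(diag(r2) - 1) > 1e-12)) stop("LD matrix diagonal must be 1")
  ld
}

#' Read an LD matrix from a tab-separated file
#'
#' First row and first column hold SNP identifiers; cells hold pairwise r².
#'
#' @param path Path to the file.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE)
  ld_matrix(as.matrix(x), rownames(x))
}

#' Greedy LD clumping
#'
#' Thins correlated variants so the retained instruments are approximately
#' independent: records are ranked by ascending p-value (ties broken by SNP
#' identifier), the best-ranked unprocessed record is accepted, and every
#' remaining record on the same chromosome with `r² > r2_threshold` to it --
#' and, when base-pair positions are available, within `window_kb` of it --
#' is dropped; the procedure repeats until all records are processed.
#' Records absent from the LD matrix are assumed independent and pass with a
#' warning (summary tables rarely ship LD information).
#'
#' @param records Association `data.frame`.
#' @param ld An `ld_matrix`, e.g. from [read_ld_matrix()] or
#'   [simulate_ld_block()].
#' @param r2_threshold Maximum tolerated squared correlation (default 0.001).
#' @param window_kb Clumping window in kilobases (default 10000); enforced
#'   only when the records carry a `POS` column.
#' @return A `selection_report`.
#' @export
ld_clump <- function(records, ld, r2_threshold = 0.001, window_kb = 10000) {
  ld <- validate_ld_matrix(ld)
  stopifnot(r2_threshold >= 0, r2_threshold <= 1, window_kb > 0)
  missing_ld <- setdiff(records$SNP, ld$snp_ids)
  if (length(missing_ld)) {
    warning("SNP(s) absent from LD matrix assumed independent: ",
            paste(missing_ld, collapse = ", "), call. = FALSE)
  }
  ord <- order(records$P, records$SNP)
  status <- setNames(rep(NA_character_, nrow(records)), records$SNP)
  index_of <- setNames(character(nrow(records)), records$SNP)
  for (i in ord) {
    snp <- records$SNP[i]
    if (!is.na(status[snp])) next
    status[snp] <- "index"
    if (!snp %in% ld$snp_ids) next
    for (j in ord) {
      other <- records$SNP[j]
      if (!is.na(status[other]) || !other %in% ld$snp_ids) next
      if (!identical(records$CHR[j], records$CHR[i])) next
      if ("POS" %in% names(records) &&
          !is.na(records$POS[i]) && !is.na(records$POS[j]) &&
          abs(records$POS[i] - records$POS[j]) > window_kb * 1000) next
      if (ld$r2[snp, other] > r2_threshold) status[other] <- "clumped"
    }
  }
  keep <- status[records$SNP] == "index"
  new_selection_report(
    records[keep, , drop = FALSE], records$SNP[!keep], "clump",
    sprintf("r2 > %g with a retained index SNP", r2_threshold))
}

#' Per-variant variance explained from summary statistics
#'
#' `r² = z² / (z² + n)` with `z = beta / se` -- the squared correlation
#' between variant and trait implied by the association z-score at sample
#' size `n`. Valid for continuous traits and, at this level of approximation,
#' for case-control z-scores.
#'
#' @param beta,se Association estimate and standard error.
#' @param n Sample size of the GWAS.
#' @return Variance explained, in \[0, 1).
#' @export
variance_explained <- function(beta, se, n) {
  stopifnot(all(se > 0), all(n >= 1))
  z2 <- (beta / se)^2
  z2 / (z2 + n)
}

#' Steiger directionality filter
#'
#' For each instrument compares the variance it explains in the exposure with
#' the variance it explains in the outcome ([variance_explained()] with each
#' trait's total sample size). A valid instrument for the stated causal
#' direction should explain more variance in the exposure; instruments
#' explaining at least as much in the outcome are dropped as likely acting in
#' the reverse direction. Exact ties are retained.
#'
#' @param iset An `instrument_set` whose study metadata carry `n_total`.
#' @return A `selection_report` whose `records` are the retained instrument
#'   rows, augmented with `r2_exposure` and `r2_outcome` columns.
#' @export
steiger_filter <- function(iset) {
  stopifnot(inherits(iset, "instrument_set"))
  for (side in c("exposure", "outcome")) {
    if (is.null(iset[[side]]$n_total) || !is.finite(iset[[side]]$n_total)) {
      stop("Steiger filtering needs n_total for the ", side, " trait (",
           iset[[side]]$trait, ")")
    }
  }
  ins <- iset$instruments
  ins$r2_exposure <- variance_explained(ins$beta_exposure, ins$se_exposure,
                                        iset$exposure$n_total)
  ins$r2_outcome <- variance_explained(ins$beta_outcome, ins$se_outcome,
                                       iset$outcome$n_total)
  keep <- ins$r2_exposure >= ins$r2_outcome
  new_selection_report(ins[keep, , drop = FALSE], ins$SNP[!keep],
                       "steiger", "reverse direction")
}
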