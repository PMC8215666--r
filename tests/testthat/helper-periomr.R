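# build a harmonized instrument set directly from effect vectors, for tests
# that exercise the estimators without the harmonization plumbing
make_iset <- function(bx, sx, by, sy,
                      snp = sprintf("rs%03d", seq_along(bx)),
                      n_exposure = 50000, n_outcome = 50000) {
  instruments <- data.frame(
    SNP = snp, CHR = "1", POS = NA_real_,
    effect_allele = "A", other_allele = "G",
    beta_exposure = bx, se_exposure = sx,
    p_exposure = 2 * pnorm(-abs(bx / sx)),
    eaf_exposure = NA_real_,
    beta_outcome = by, se_outcome = sy,
    p_outcome = 2 * pnorm(-abs(by / sy)),
    eaf_outcome = NA_real_,
    palindromic = FALSE, flipped = FALSE,
    stringsAsFactors = FALSE
  )
  periomr:::new_instrument_set(
    study_meta("X", n_exposure), study_meta("Y", n_outcome),
    instruments,
    data.frame(SNP = character(0), stage = character(0),
               reason = character(0)))
}

# instrument set straight from a simulated pair (tables are generated with
# aligned alleles, so harmonization is the identity)
iset_from_pair <- function(pair) {
  e <- pair$exposure_table
  o <- pair$outcome_table
  make_iset(e$BETA, e$SE, o$BETA, o$SE, snp = e$SNP,
            n_exposure = e$N[1], n_outcome = o$N[1])
}

# association record builder
rec <- function(snp = "rs1", chr = "1", ea = "A", oa = "G", eaf = 0.3,
                beta = 0.1, se = 0.02, p = NULL, n = NA_real_) {
  if (is.null(p)) p <- 2 * pnorm(-abs(beta / se))
  data.frame(SNP = snp, CHR = chr, EA = ea, OA = oa, EAF = eaf,
             BETA = beta, SE = se, P = p, N = n, stringsAsFactors = FALSE)
}

fixture_tables <- function() suppressWarnings(cpkd_tables())

fixture_iset <- function(direction = c("cp_egfr", "cp_bun", "egfr_cp",
                                       "bun_cp")) {
  direction <- match.arg(direction)
  tabs <- fixture_tables()
  metas <- cpkd_metas()
  pick <- switch(direction,
    cp_egfr = list(tabs$cp_exposure, tabs$egfr_outcome, metas$cp, metas$egfr),
    cp_bun = list(tabs$cp_exposure, tabs$bun_outcome, metas$cp, metas$bun),
    egfr_cp = list(tabs$egfr_exposure, tabs$cp_outcome, metas$egfr, metas$cp),
    bun_cp = list(tabs$bun_exposure, tabs$cp_outcome, metas$bun, metas$cp))
  suppressWarnings(build_instrument_set(pick[[1]], pick[[2]], pick[[3]],
                                        pick[[4]]))
}

# independent restatement of the clumping rule: enumerate every subset,
# keep those that are pairwise independent and maximal, then pick the one
# that always prefers the lower-p SNP (ties by identifier)
clump_oracle <- function(p, r2, thr) {
  J <- length(p)
  ord <- order(p, sprintf("s%02d", seq_len(J)))
  subsets <- lapply(0:(2^J - 1), function(m) which(bitwAnd(m, 2^(0:(J - 1))) > 0))
  indep <- Filter(function(s) {
    length(s) < 2 || all(r2[s, s][upper.tri(diag(length(s)))] <= thr)
  }, subsets)
  maximal <- Filter(function(s) {
    all(vapply(setdiff(seq_len(J), s), function(j) {
      any(r2[j, s] > thr)
    }, logical(1)))
  }, indep)
  keys <- vapply(maximal, function(s) {
    paste(as.integer(ord %in% s), collapse = "")
  }, character(1))
  sort(maximal[[order(keys, decreasing = TRUE)[1]]])
}
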