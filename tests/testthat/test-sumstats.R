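test_that("reading the CP instrument table yields one record per row", {
  path <- tempfile(fileext = ".tsv")
  write_sumstats(fixture_tables()$cp_exposure, path)
  x <- read_sumstats(path)
  expect_equal(nrow(x), 7L)
  expect_equal(x$SNP[1], "rs13005050")
  expect_equal(x$BETA[1], 0.1432)
  expect_equal(x$SE[1], 0.0310)
  expect_equal(x$P[1], 3.76e-6)
})

test_that("header-only files read as empty tables", {
  path <- tempfile(fileext = ".tsv")
  writeLines("SNP\tCHR\tEA\tOA\tEAF\tBETA\tSE\tP\tN", path)
  x <- read_sumstats(path)
  expect_equal(nrow(x), 0L)
  expect_true(all(periomr:::.sumstats_cols %in% names(x)))
})

test_that("invalid rows are rejected with line numbers", {
  bad <- rec(snp = c("rs1", "rs2"), beta = c(0.1, 0.2), se = c(0.02, 0))
  path <- tempfile(fileext = ".tsv")
  write.table(bad[periomr:::.sumstats_cols[1:9]], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path), "line 3.*rs2.*standard error")

  writeLines(c("SNP\tCHR\tEA\tOA\tEAF\tBETA\tSE\tP",
               "rs1\t1\tA\tG\t0.3\tnot_a_number\t0.02\t0.5"), path)
  expect_error(read_sumstats(path), "line 2.*unparseable BETA")

  writeLines(c("SNP\tCHR\tEA\tOA", "rs1\t1\tA\tG"), path)
  expect_error(read_sumstats(path), "missing mandatory column")
})

test_that("read/write round-trips both fixture table sets at full precision", {
  for (tab in fixture_tables()) {
    path <- tempfile(fileext = ".tsv")
    suppressWarnings(write_sumstats(tab, path))
    back <- suppressWarnings(read_sumstats(path))
    expect_identical(back[names(tab)], tab)
  }
})

test_that("missing eaf serializes as NA and survives the round-trip", {
  x <- rec(eaf = NA_real_)
  path <- tempfile(fileext = ".tsv")
  write_sumstats(x, path)
  line <- strsplit(readLines(path)[2], "\t")[[1]]
  expect_equal(line[5], "NA")
  expect_true(is.na(read_sumstats(path)$EAF))
})

test_that("dialect remapping reads foreign column names", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("rsid\tchrom\tA1\tA2\tfreq\teffect\tstderr\tpval",
               "rs9\t3\tC\tT\t0.2\t0.15\t0.03\t5e-7"), path)
  d <- sumstats_dialect(snp = "rsid", chr = "chrom", ea = "A1", oa = "A2",
                        eaf = "freq", beta = "effect", se = "stderr",
                        p = "pval")
  x <- read_sumstats(path, d)
  expect_equal(x$SNP, "rs9")
  expect_equal(x$BETA, 0.15)
  expect_error(sumstats_dialect(nonsense = "X"), "unknown dialect field")
})

test_that("beta/p disagreement warns but does not error", {
  x <- rec(beta = 0.5, se = 0.1, p = 0.5)  # z = 5 but p says z = 0.67
  expect_warning(validate_sumstats(x), "disagree beyond 10%")
})

test_that("harmonize matches a truth-table oracle over all allele pairs", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ea = bases, oa = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ea != pairs$oa, ]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  exp_rec <- rec(ea = "C", oa = "T", eaf = 0.2, beta = 0.1432)
  for (i in seq_len(nrow(pairs))) {
    out_rec <- rec(ea = pairs$ea[i], oa = pairs$oa[i], eaf = 0.2,
                   beta = -0.0009, se = 6e-4, p = 0.14)
    h <- harmonize(exp_rec, out_rec, palindromic_eaf_window = 0.08)
    # independent statement of the rule: exact label match keeps the beta,
    # exact swap negates it, anything else (incl. strand complements) drops
    expected <- if (pairs$ea[i] == "C" && pairs$oa[i] == "T") "same"
      else if (pairs$ea[i] == "T" && pairs$oa[i] == "C") "swap"
      else "drop"
    if (expected == "drop") {
      expect_equal(h$status, "drop")
      expect_equal(h$reason, "allele mismatch")
    } else {
      expect_equal(h$status, "ok")
      expect_equal(h$instrument$beta_outcome,
                   if (expected == "swap") 0.0009 else -0.0009)
      expect_equal(h$instrument$flipped, expected == "swap")
      expect_false(h$instrument$palindromic)
    }
  }
})

test_that("allele flips preserve magnitude and double-flip is the identity", {
  e <- rec(ea = "C", oa = "T", eaf = 0.2, beta = 0.3)
  o_swapped <- rec(ea = "T", oa = "C", eaf = 0.7, beta = -0.05, se = 0.01,
                   p = 1e-6)
  h1 <- harmonize(e, o_swapped)$instrument
  expect_equal(abs(h1$beta_outcome), 0.05)
  expect_equal(h1$eaf_outcome, 0.3)
  # flipping the outcome record's alleles back reverses the transformation
  o_back <- o_swapped
  o_back$EA <- "C"; o_back$OA <- "T"
  o_back$BETA <- -o_back$BETA; o_back$EAF <- 1 - o_back$EAF
  h2 <- harmonize(e, o_back)$instrument
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$eaf_outcome, h1$eaf_outcome)
  expect_false(h2$flipped)
})

test_that("ambiguous palindromic variants are dropped, unambiguous kept", {
  e <- rec(ea = "A", oa = "T", eaf = 0.50)
  o <- rec(ea = "A", oa = "T", eaf = 0.50, beta = 0.05, se = 0.01, p = 1e-6)
  h <- harmonize(e, o, palindromic_eaf_window = 0.08)
  expect_equal(h$status, "drop")
  expect_equal(h$reason, "ambiguous palindrome")
  # frequency far from 0.5: aligned by labels, flagged palindromic
  e2 <- rec(ea = "C", oa = "G", eaf = 0.10)
  o2 <- rec(ea = "C", oa = "G", eaf = 0.12, beta = 0.05, se = 0.01, p = 1e-6)
  h2 <- harmonize(e2, o2, palindromic_eaf_window = 0.08)
  expect_equal(h2$status, "ok")
  expect_true(h2$instrument$palindromic)
  # window boundary is inclusive
  e3 <- rec(ea = "A", oa = "T", eaf = 0.42)
  o3 <- rec(ea = "A", oa = "T", eaf = 0.42, beta = 0.05, se = 0.01, p = 1e-6)
  expect_equal(harmonize(e3, o3, 0.08)$status, "drop")
  expect_error(harmonize(rec(snp = "rs1"), rec(snp = "rs2")),
               "matching SNP identifiers")
})

test_that("build_instrument_set joins, harmonizes and logs drops", {
  tabs <- fixture_tables()
  metas <- cpkd_metas()
  s <- suppressWarnings(build_instrument_set(
    tabs$cp_exposure, tabs$egfr_outcome, metas$cp, metas$egfr))
  expect_s3_class(s, "instrument_set")
  expect_equal(nrow(s$instruments), 7L)
  expect_false(any(s$instruments$flipped))

  s2 <- suppressWarnings(build_instrument_set(
    tabs$bun_exposure, tabs$cp_outcome, metas$bun, metas$cp))
  expect_equal(nrow(s2$instruments), 9L)

  disjoint <- tabs$cp_exposure
  disjoint$SNP <- paste0(disjoint$SNP, "_x")
  expect_error(
    suppressWarnings(
      build_instrument_set(disjoint, tabs$egfr_outcome, metas$cp,
                           metas$egfr)),
    "no overlapping SNPs")
})

test_that("study_meta enforces case/control consistency", {
  expect_error(study_meta("CP", 100, n_cases = 10, n_controls = 80),
               "must equal n_total")
  m <- study_meta("CP", 34615, 12289, 22326)
  expect_equal(m$n_total, 34615)
  expect_error(study_meta("X", 0), "n_total")
})

test_that("shipped fixture files match the built-in tables", {
  tabs <- fixture_tables()
  for (nm in names(tabs)) {
    path <- system.file("extdata", paste0(nm, ".tsv"), package = "periomr")
    expect_true(nzchar(path))
    expect_identical(suppressWarnings(read_sumstats(path))[names(tabs[[nm]])],
                     tabs[[nm]])
  }
})
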