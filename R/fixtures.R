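#' @title Built-in periodontitis / kidney-function instrument tables
#' @description The GWAS summary statistics behind the bidirectional
#'   periodontitis--kidney analysis, transcribed verbatim at their published
#'   precision. The chronic periodontitis (CP) associations come from the
#'   GLIDE consortium GWAS (12,289 cases, 22,326 controls); the estimated
#'   glomerular filtration rate (eGFR) and blood urea nitrogen (BUN)
#'   associations from the CKDGen consortium GWAS (439,303 participants
#'   analysed here, of whom 41,395 chronic-kidney-disease cases). Seven SNPs
#'   instrument CP (suggestive threshold p < 5e-6); six and nine
#'   genome-wide-significant SNPs instrument eGFR and BUN respectively.
#' @name cpkd_fixtures
NULL

.cpkd_raw <- function() {
  # CP instruments with eGFR and BUN outcome associations
  cp_block <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
SNP CHR EA OA EAF cp_beta cp_se cp_p egfr_beta egfr_se egfr_p bun_beta bun_se bun_p
rs13005050 2 C T 0.14 0.1432 0.0310 3.76E-06 0.0009 0.0006 1.03E-01 -0.0027 0.0014 6.29E-02
rs4956201 4 C A 0.89 0.2406 0.0474 3.89E-07 -0.0006 0.0008 4.42E-01 0.0001 0.0020 9.61E-01
rs6816769 4 C T 0.89 0.1348 0.0294 4.57E-06 0.0004 0.0006 4.81E-01 0.0006 0.0014 6.53E-01
rs78422482 4 A G 0.01 0.2425 0.0510 2.02E-06 -0.0006 0.0010 5.15E-01 0.0024 0.0024 3.10E-01
rs73155039 7 A G 0.99 0.8316 0.1757 2.22E-06 -0.0004 0.0019 8.35E-01 0.0034 0.0052 5.23E-01
rs2976950 8 A G 0.60 0.0963 0.0195 7.99E-07 0.0018 0.0004 4.52E-07 0.0007 0.0010 4.37E-01
rs151226594 11 G T 0.01 0.3671 0.0768 1.75E-06 0.0012 0.0014 3.90E-01 0.0030 0.0034 3.67E-01
")
  # kidney-function instruments with CP outcome associations
  kidney_block <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
SNP CHR EA OA EAF trait beta se p cp_beta cp_se cp_p
rs11694902 2 A G 0.76 eGFR 0.0050 0.0004 3.28E-34 0.0047 0.0257 8.56E-01
rs17462630 2 C G 0.14 eGFR 0.0041 0.0005 2.14E-16 0.0026 0.0189 8.91E-01
rs9868185 3 G A 0.31 eGFR 0.0055 0.0004 4.04E-37 0.0012 0.0182 9.47E-01
rs12920176 16 A C 0.79 eGFR 0.0026 0.0004 1.01E-09 0.0002 0.0186 9.92E-01
rs113445505 19 T C 0.20 eGFR 0.0096 0.0005 1.21E-99 -0.0089 0.0184 6.26E-01
rs6127099 20 T A 0.34 eGFR 0.0034 0.0004 1.53E-20 0.0001 0.0211 9.94E-01
rs10874312 1 A G 0.66 BUN 0.0070 0.0009 1.73E-14 0.0035 0.0187 8.51E-01
rs760077 1 A T 0.41 BUN 0.0134 0.0010 2.10E-44 -0.0124 0.0184 4.99E-01
rs34773350 2 C T 0.86 BUN 0.0083 0.0012 2.90E-11 0.0034 0.0257 8.94E-01
rs9849724 3 G T 0.46 BUN 0.0047 0.0009 4.09E-08 0.0043 0.0180 8.13E-01
rs4976646 5 C T 0.34 BUN 0.0073 0.0009 2.91E-15 0.0033 0.0196 8.67E-01
rs13230625 7 A G 0.70 BUN 0.0134 0.0013 1.08E-26 0.0077 0.0262 7.71E-01
rs6597862 10 C A 0.76 BUN 0.0058 0.0010 8.33E-09 -0.0011 0.0210 9.59E-01
rs3925584 11 T C 0.55 BUN 0.0096 0.0009 9.85E-29 0.0078 0.0183 6.69E-01
rs4886755 15 G A 0.51 BUN 0.0095 0.0009 1.73E-28 -0.0047 0.0175 7.89E-01
")
  list(cp = cp_block, kidney = kidney_block)
}

.cpkd_n <- c(cp = 34615, kidney = 439303)

#' Study metadata for the built-in tables
#'
#' @return Named list of [study_meta()] objects `cp`, `egfr`, `bun`.
#' @export
cpkd_metas <- function() {
  list(
    cp = study_meta("CP", n_total = 34615, n_cases = 12289,
                    n_controls = 22326, ancestry = "European"),
    egfr = study_meta("eGFR", n_total = 439303, ancestry = "European"),
    bun = study_meta("BUN", n_total = 439303, ancestry = "European")
  )
}

#' Built-in instrument association tables
#'
#' Returns the six association tables of the bidirectional analysis in the
#' native summary-statistics layout (see [read_sumstats()]): the CP exposure
#' table with its eGFR and BUN outcome tables (7 SNPs each), and the eGFR
#' (6 SNPs) and BUN (9 SNPs) exposure tables with the shared CP outcome
#' table (15 SNPs). Effect alleles are already matched across the paired
#' tables, so harmonization leaves them unchanged.
#'
#' @return Named list of `data.frame`s: `cp_exposure`, `egfr_outcome`,
#'   `bun_outcome`, `egfr_exposure`, `bun_exposure`, `cp_outcome` --
#'   the `tables` argument of [run_bidirectional()].
#' @examples
#' tabs <- cpkd_tables()
#' nrow(tabs$cp_exposure)  # 7
#' @export
cpkd_tables <- function() {
  raw <- .cpkd_raw()
  mk <- function(block, beta, se, p, n) {
    validate_sumstats(data.frame(
      SNP = block$SNP, CHR = as.character(block$CHR), EA = block$EA,
      OA = block$OA, EAF = block$EAF, BETA = block[[beta]],
      SE = block[[se]], P = block[[p]], N = n,
      stringsAsFactors = FALSE))
  }
  egfr_rows <- raw$kidney[raw$kidney$trait == "eGFR", ]
  bun_rows <- raw$kidney[raw$kidney$trait == "BUN", ]
  list(
    cp_exposure = mk(raw$cp, "cp_beta", "cp_se", "cp_p", .cpkd_n[["cp"]]),
    egfr_outcome = mk(raw$cp, "egfr_beta", "egfr_se", "egfr_p",
                      .cpkd_n[["kidney"]]),
    bun_outcome = mk(raw$cp, "bun_beta", "bun_se", "bun_p",
                     .cpkd_n[["kidney"]]),
    egfr_exposure = mk(egfr_rows, "beta", "se", "p", .cpkd_n[["kidney"]]),
    bun_exposure = mk(bun_rows, "beta", "se", "p", .cpkd_n[["kidney"]]),
    cp_outcome = mk(raw$kidney, "cp_beta", "cp_se", "cp_p", .cpkd_n[["cp"]])
  )
}

#' Write the built-in tables as fixture files
#'
#' Writes the six tables of [cpkd_tables()] as tab-separated files plus a
#' `studies.json` sidecar with the sample sizes, into `out_dir`. Re-reading
#' the files reproduces every table cell exactly.
#'
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_cpkd_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- cpkd_tables()
  paths <- setNames(
    file.path(out_dir, paste0(names(tabs), ".tsv")), names(tabs))
  for (nm in names(tabs)) write_sumstats(tabs[[nm]], paths[[nm]])
  meta_path <- file.path(out_dir, "studies.json")
  metas <- cpkd_metas()
  jsonlite::write_json(
    lapply(metas, function(m) m[!vapply(m, is.null, logical(1))]),
    meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, studies = meta_path))
}
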