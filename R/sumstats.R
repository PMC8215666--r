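#' Column-name mapping for summary-statistics tables
#'
#' The native dialect is a tab-separated table with header
#' `SNP CHR EA OA EAF BETA SE P N` (`NA` for missing values, scientific
#' notation accepted for `P`). Other dialects are handled by remapping the
#' column names; an optional `POS` (base-pair position) column is used by
#' [ld_clump()] to enforce its distance window.
#'
#' @param ... Named overrides, canonical name = file column name, e.g.
#'   `snp = "MarkerName", beta = "Effect"`.
#' @return Named character vector mapping canonical field names to file
#'   column names.
#' @examples
#' sumstats_dialect(snp = "rsid", p = "pval")
#' @export
sumstats_dialect <- function(...) {
  d <- c(
    snp = "SNP", chr = "CHR", ea = "EA", oa = "OA", eaf = "EAF",
    beta = "BETA", se = "SE", p = "P", n = "N", pos = "POS"
  )
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(d))
    if (length(bad)) {
      stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    }
    d[names(over)] <- over
  }
  d
}

# canonical column order of an association table; EAF, N, POS may be NA
.sumstats_cols <- c("SNP", "CHR", "EA", "OA", "EAF", "BETA", "SE", "P", "N", "POS")
.mandatory_cols <- c("snp", "chr", "ea", "oa", "beta", "se", "p")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated table of per-SNP trait associations, remaps column
#' names through `dialect`, coerces types and validates every row. Rows that
#' fail a type or range check are reported with their file line numbers and
#' the read fails; fix or remove the offending rows.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Column-name mapping, see [sumstats_dialect()].
#' @return A `data.frame` with columns `SNP, CHR, EA, OA, EAF, BETA, SE, P, N,
#'   POS` (missing optional fields filled with `NA`), one row per data row.
#' @seealso [write_sumstats()], [validate_sumstats()]
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = "NA", strip.white = TRUE)
  missing_cols <- setdiff(dialect[.mandatory_cols], names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }

  pick <- function(field) {
    col <- dialect[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  blank <- rep(NA_real_, nrow(raw))
  out <- data.frame(
    SNP = pick("snp"), CHR = pick("chr"), EA = toupper(pick("ea")),
    OA = toupper(pick("oa")), EAF = blank, BETA = blank, SE = blank,
    P = blank, N = blank, POS = blank,
    stringsAsFactors = FALSE
  )
  if (nrow(raw) == 0L) return(out)

  # numeric coercion with row-level error reporting (line 1 is the header)
  problems <- character(0)
  num <- function(field, target) {
    x <- pick(field)
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) {
      problems <<- c(problems, sprintf(
        "line %d: unparseable %s value '%s'", bad + 1L, target, x[bad]))
    }
    v
  }
  out$EAF <- num("eaf", "EAF")
  out$BETA <- num("beta", "BETA")
  out$SE <- num("se", "SE")
  out$P <- num("p", "P")
  out$N <- num("n", "N")
  out$POS <- num("pos", "POS")
  if (length(problems)) {
    stop("invalid rows in ", path, ":\n  ", paste(problems, collapse = "\n  "))
  }
  validate_sumstats(out, source = path)
}

#' Validate an association table
#'
#' Checks the per-record invariants: alleles are single bases A/C/G/T with
#' effect allele distinct from the other allele, `SE > 0`, `P` in (0, 1],
#' `EAF` in (0, 1) when present, `N >= 1` when present. Violations raise an
#' error listing the offending rows. Additionally `|BETA/SE|` is compared
#' with the normal quantile implied by `P`; disagreement beyond 10% relative
#' tolerance raises a warning (the two are redundant up to rounding in a
#' well-formed table).
#'
#' @param x Association `data.frame` as returned by [read_sumstats()].
#' @param source Label used in messages.
#' @return `x`, invisibly usable, with columns in canonical order.
#' @export
validate_sumstats <- function(x, source = "sumstats") {
  for (col in setdiff(.sumstats_cols, names(x))) x[[col]] <- NA_real_
  x <- x[.sumstats_cols]
  if (nrow(x) == 0L) return(x)

  line <- seq_len(nrow(x)) + 1L
  problems <- character(0)
  flag <- function(bad, msg) {
    if (any(bad)) {
      problems <<- c(problems, sprintf("line %d (%s): %s",
                                       line[bad], x$SNP[bad], msg))
    }
  }
  flag(is.na(x$SNP) | !nzchar(x$SNP), "missing SNP identifier")
  flag(!x$EA %in% c("A", "C", "G", "T"), "effect allele not one of A/C/G/T")
  flag(!x$OA %in% c("A", "C", "G", "T"), "other allele not one of A/C/G/T")
  flag(!is.na(x$EA) & !is.na(x$OA) & x$EA == x$OA,
       "effect allele equals other allele")
  flag(is.na(x$BETA), "missing beta")
  flag(is.na(x$SE) | x$SE <= 0, "standard error not positive")
  flag(is.na(x$P) | x$P <= 0 | x$P > 1, "p-value outside (0, 1]")
  flag(!is.na(x$EAF) & (x$EAF <= 0 | x$EAF >= 1),
       "effect-allele frequency outside (0, 1)")
  flag(!is.na(x$N) & x$N < 1, "sample size below 1")
  if (length(problems)) {
    stop("invalid rows in ", source, ":\n  ",
         paste(problems, collapse = "\n  "))
  }

  # beta/p consistency: |z| from beta/se vs |z| implied by the p-value;
  # 10% relative tolerance, with a small absolute floor so near-zero
  # z-scores rounded to few digits do not trip the check
  z_beta <- abs(x$BETA / x$SE)
  z_p <- stats::qnorm(x$P / 2, lower.tail = FALSE)
  ok <- is.na(z_p) | !is.finite(z_p) | z_beta > 37 |  # p underflows past |z|~37
    abs(z_beta - z_p) <= pmax(0.1 * pmax(z_beta, z_p), 0.05)
  if (any(!ok)) {
    warning("beta/SE and p disagree beyond 10% relative tolerance in ",
            source, " for: ", paste(x$SNP[!ok], collapse = ", "),
            call. = FALSE)
  }
  x
}

# shortest decimal string that round-trips to the same double ("NA" for NA)
.num_to_chr <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    for (d in 1:17) {
      s <- trimws(formatC(v, digits = d, format = "G"))
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

#' Write a summary-statistics table
#'
#' Writes the native tab-separated dialect (`SNP CHR EA OA EAF BETA SE P N`,
#' plus `POS` when any row carries a position). Numbers are written with the
#' fewest digits that reproduce the stored double exactly, so
#' `read_sumstats(write_sumstats(x))` is the identity field-for-field.
#'
#' @param x Association `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  x <- validate_sumstats(x)
  cols <- .sumstats_cols
  if (nrow(x) == 0L || all(is.na(x$POS))) cols <- setdiff(cols, "POS")
  out <- x[cols]
  for (col in intersect(cols, c("EAF", "BETA", "SE", "P", "N", "POS"))) {
    out[[col]] <- .num_to_chr(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Study metadata
#'
#' Sample-size and ancestry metadata for one GWAS, used by Steiger filtering
#' (which needs per-trait sample sizes) and by the power calculation (which
#' needs the outcome's size and, for binary traits, its case fraction).
#'
#' @param trait Trait label, e.g. `"CP"`, `"eGFR"`, `"BUN"`.
#' @param n_total Total sample size (>= 1).
#' @param n_cases,n_controls Optional case/control counts; when both are given
#'   their sum must equal `n_total` and the trait is treated as binary.
#' @param ancestry Free-text ancestry description.
#' @return An object of class `study_meta`.
#' @export
study_meta <- function(trait, n_total, n_cases = NULL, n_controls = NULL,
                       ancestry = "European") {
  stopifnot(is.character(trait), length(trait) == 1L, nzchar(trait))
  n_total <- as.numeric(n_total)
  if (!is.finite(n_total) || n_total < 1) stop("n_total must be >= 1")
  if (!is.null(n_cases) && !is.null(n_controls) &&
      n_cases + n_controls != n_total) {
    stop("n_cases + n_controls must equal n_total for trait ", trait)
  }
  structure(list(trait = trait, n_total = n_total,
                 n_cases = n_cases, n_controls = n_controls,
                 ancestry = ancestry),
            class = "study_meta")
}

#' @export
print.study_meta <- function(x, ...) {
  cc <- if (!is.null(x$n_cases)) {
    sprintf(" (%s cases / %s controls)",
            format(x$n_cases, big.mark = ","),
            format(x$n_controls, big.mark = ","))
  } else ""
  cat(sprintf("<study_meta> %s: n = %s%s, %s\n", x$trait,
              format(x$n_total, big.mark = ","), cc, x$ancestry))
  invisible(x)
}

.is_palindromic <- function(ea, oa) {
  paste(ea, oa) %in% c("A T", "T A", "C G", "G C")
}

#' Harmonize one exposure/outcome association pair onto a common effect allele
#'
#' Expresses the outcome association on the exposure's effect allele. If the
#' outcome row reports the swapped allele pair (EA and OA exchanged) the
#' outcome beta is negated and its frequency replaced by `1 - EAF`
#' (`flipped = TRUE`). If the allele sets disagree even after the swap the
#' pair is dropped (`"allele mismatch"`). Palindromic variants (A/T or C/G)
#' are flagged and dropped when any available allele frequency lies within
#' `palindromic_eaf_window` of 0.5, because the strand -- and hence the
#' effect sign -- cannot be resolved (`"ambiguous palindrome"`). No strand
#' inference is attempted: with frequencies missing, alignment is by allele
#' labels alone.
#'
#' @param exposure_rec,outcome_rec One-row association `data.frame`s for the
#'   same SNP.
#' @param palindromic_eaf_window Half-width of the frequency window around 0.5
#'   inside which palindromic variants are dropped (default 0.08).
#' @return A list with `status` (`"ok"` or `"drop"`), `reason` (`NA` when ok)
#'   and `instrument` (one-row harmonized `data.frame`, or `NULL` on drop).
#' @examples
#' e <- data.frame(SNP = "rs1", CHR = "2", EA = "C", OA = "T",
#'                 EAF = 0.14, BETA = 0.1432, SE = 0.031, P = 3.76e-6)
#' o <- data.frame(SNP = "rs1", CHR = "2", EA = "T", OA = "C",
#'                 EAF = 0.86, BETA = -0.0009, SE = 6e-4, P = 0.103)
#' harmonize(e, o)$instrument$beta_outcome  # +0.0009, flipped
#' @export
harmonize <- function(exposure_rec, outcome_rec, palindromic_eaf_window = 0.08) {
  exposure_rec <- validate_sumstats(as.data.frame(exposure_rec), "exposure record")
  outcome_rec <- validate_sumstats(as.data.frame(outcome_rec), "outcome record")
  stopifnot(nrow(exposure_rec) == 1L, nrow(outcome_rec) == 1L)
  if (exposure_rec$SNP != outcome_rec$SNP) {
    stop("harmonize() requires matching SNP identifiers (got ",
         exposure_rec$SNP, " and ", outcome_rec$SNP, ")")
  }
  stopifnot(palindromic_eaf_window >= 0, palindromic_eaf_window < 0.5)

  drop <- function(reason) list(status = "drop", reason = reason,
                                instrument = NULL)
  same <- outcome_rec$EA == exposure_rec$EA & outcome_rec$OA == exposure_rec$OA
  swapped <- outcome_rec$EA == exposure_rec$OA & outcome_rec$OA == exposure_rec$EA
  if (!same && !swapped) return(drop("allele mismatch"))

  beta_y <- if (swapped) -outcome_rec$BETA else outcome_rec$BETA
  eaf_y <- if (swapped) 1 - outcome_rec$EAF else outcome_rec$EAF
  palindromic <- .is_palindromic(exposure_rec$EA, exposure_rec$OA)
  if (palindromic) {
    eafs <- c(exposure_rec$EAF, eaf_y)
    eafs <- eafs[!is.na(eafs)]
    # inclusive boundary, robust to representation error in the difference
    if (any(abs(eafs - 0.5) <= palindromic_eaf_window + 1e-12)) {
      return(drop("ambiguous palindrome"))
    }
  }
  instrument <- data.frame(
    SNP = exposure_rec$SNP, CHR = exposure_rec$CHR, POS = exposure_rec$POS,
    effect_allele = exposure_rec$EA, other_allele = exposure_rec$OA,
    beta_exposure = exposure_rec$BETA, se_exposure = exposure_rec$SE,
    p_exposure = exposure_rec$P, eaf_exposure = exposure_rec$EAF,
    beta_outcome = beta_y, se_outcome = outcome_rec$SE,
    p_outcome = outcome_rec$P, eaf_outcome = eaf_y,
    palindromic = palindromic, flipped = swapped,
    stringsAsFactors = FALSE
  )
  list(status = "ok", reason = NA_character_, instrument = instrument)
}

#' Build a harmonized instrument set from paired exposure/outcome tables
#'
#' Inner-joins the two tables on SNP identifier (in exposure-table order) and
#' harmonizes each pair with [harmonize()]. Pairs that cannot be harmonized
#' are recorded in the drop log rather than silently discarded.
#'
#' @param exposure_table,outcome_table Association `data.frame`s.
#' @param exposure_meta,outcome_meta [study_meta()] for the two GWAS.
#' @param palindromic_eaf_window Passed to [harmonize()].
#' @return An object of class `instrument_set`: a list with `exposure` and
#'   `outcome` metadata, `instruments` (harmonized `data.frame`, one row per
#'   retained SNP) and `drop_log` (`data.frame` with columns `SNP, stage,
#'   reason`).
#' @export
build_instrument_set <- function(exposure_table, outcome_table,
                                 exposure_meta, outcome_meta,
                                 palindromic_eaf_window = 0.08) {
  exposure_table <- validate_sumstats(exposure_table, "exposure table")
  outcome_table <- validate_sumstats(outcome_table, "outcome table")
  stopifnot(inherits(exposure_meta, "study_meta"),
            inherits(outcome_meta, "study_meta"))
  if (anyDuplicated(exposure_table$SNP)) stop("duplicated SNP in exposure table")
  shared <- exposure_table$SNP[exposure_table$SNP %in% outcome_table$SNP]
  if (length(shared) == 0L) {
    stop("no overlapping SNPs between exposure (", exposure_meta$trait,
         ") and outcome (", outcome_meta$trait, ") tables")
  }
  dropped_overlap <- setdiff(exposure_table$SNP, shared)

  rows <- vector("list", length(shared))
  drop_log <- data.frame(SNP = character(0), stage = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  if (length(dropped_overlap)) {
    drop_log <- rbind(drop_log, data.frame(
      SNP = dropped_overlap, stage = "harmonize",
      reason = "absent from outcome table", stringsAsFactors = FALSE))
  }
  for (i in seq_along(shared)) {
    snp <- shared[i]
    h <- harmonize(exposure_table[exposure_table$SNP == snp, ],
                   outcome_table[outcome_table$SNP == snp, ][1, ],
                   palindromic_eaf_window)
    if (h$status == "ok") {
      rows[[i]] <- h$instrument
    } else {
      drop_log <- rbind(drop_log, data.frame(
        SNP = snp, stage = "harmonize", reason = h$reason,
        stringsAsFactors = FALSE))
    }
  }
  instruments <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(instruments)) {
    stop("all overlapping SNPs were dropped during harmonization")
  }
  new_instrument_set(exposure_meta, outcome_meta, instruments, drop_log)
}

new_instrument_set <- function(exposure, outcome, instruments, drop_log) {
  rownames(instruments) <- NULL
  structure(list(exposure = exposure, outcome = outcome,
                 instruments = instruments, drop_log = drop_log),
            class = "instrument_set")
}

#' Restrict an instrument set to a subset of SNPs
#'
#' @param iset An `instrument_set`.
#' @param snps Character vector of SNP identifiers to keep.
#' @return The restricted `instrument_set` (order preserved).
#' @export
subset_instruments <- function(iset, snps) {
  stopifnot(inherits(iset, "instrument_set"))
  keep <- iset$instruments$SNP %in% snps
  new_instrument_set(iset$exposure, iset$outcome,
                     iset$instruments[keep, , drop = FALSE], iset$drop_log)
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s -> %s: %d instrument(s), %d dropped\n",
              x$exposure$trait, x$outcome$trait,
              nrow(x$instruments), nrow(x$drop_log)))
  invisible(x)
}
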