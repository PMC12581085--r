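VALID_ALLELES <- c("A", "C", "G", "T")

#' Default column-name mapping for summary-statistics files
#'
#' Maps internal field names to the column headers found in a file. Override
#' individual entries to read files with other header conventions.
#'
#' @param ... named overrides, e.g. `variant_id = "rsid"`.
#' @return Named character vector mapping internal names to file columns.
#' @export
default_dialect <- function(...) {
  d <- c(
    variant_id = "SNP", chrom = "CHR", pos = "POS",
    effect_allele = "EA", other_allele = "OA", eaf = "EAF",
    beta = "BETA", se = "SE", pvalue = "P", n = "N",
    n_case = "N_CASE", n_control = "N_CONTROL"
  )
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(d))
    if (length(bad)) stop("unknown dialect fields: ", paste(bad, collapse = ", "))
    d[names(ov)] <- ov
  }
  d
}

#' Construct a validated summary-statistics object
#'
#' A `summary_stats` object is a data frame of per-variant association
#' records (one GWAS trait) carrying trait metadata as attributes. Rows
#' violating the record invariants (positive SE, distinct A/C/G/T alleles,
#' frequency strictly inside (0,1) when present, p in (0,1], position >= 1)
#' are dropped and counted in the attached load report.
#'
#' @param records data frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`
#'   (optionally `n_case`, `n_control` for binary traits).
#' @param trait_name trait label.
#' @param unit one of `"SD"`, `"mmol/L"`, `"mg/dL"`, `"mmHg"`, `"logOR"`.
#' @param ancestry ancestry label (default `"European"`).
#' @return A `summary_stats` data frame; `attr(, "load_report")` records the
#'   number of rows rejected per rule.
#' @export
summary_stats <- function(records, trait_name, unit = "SD",
                          ancestry = "European") {
  unit <- match.arg(unit, c("SD", "mmol/L", "mg/dL", "mmHg", "logOR"))
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pvalue", "n")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("summary statistics missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(records) == 0L) stop("empty summary-statistics table")

  rec <- records
  rec$variant_id <- as.character(rec$variant_id)
  rec$chrom <- as.character(rec$chrom)
  rec$effect_allele <- toupper(as.character(rec$effect_allele))
  rec$other_allele <- toupper(as.character(rec$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    rec[[col]] <- as.numeric(rec[[col]])
  }

  bad_se <- !is.finite(rec$se) | rec$se <= 0
  bad_allele <- !(rec$effect_allele %in% VALID_ALLELES) |
    !(rec$other_allele %in% VALID_ALLELES) |
    rec$effect_allele == rec$other_allele
  bad_eaf <- !is.na(rec$eaf) & (rec$eaf <= 0 | rec$eaf >= 1)
  bad_p <- !is.finite(rec$pvalue) | rec$pvalue <= 0 | rec$pvalue > 1
  bad_pos <- !is.finite(rec$pos) | rec$pos < 1
  bad_beta <- !is.finite(rec$beta)
  drop <- bad_se | bad_allele | bad_eaf | bad_p | bad_pos | bad_beta

  report <- c(
    n_input = nrow(rec), n_rejected = sum(drop),
    bad_se = sum(bad_se), bad_allele = sum(bad_allele),
    bad_eaf = sum(bad_eaf), bad_pvalue = sum(bad_p),
    bad_pos = sum(bad_pos), bad_beta = sum(bad_beta)
  )
  rec <- rec[!drop, , drop = FALSE]
  if (anyDuplicated(rec$variant_id)) {
    stop("duplicate variant_id in trait '", trait_name, "'")
  }
  rownames(rec) <- NULL
  structure(rec,
    class = c("summary_stats", "data.frame"),
    trait_name = trait_name, unit = unit, ancestry = ancestry,
    load_report = report
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s, %s), %d variants\n",
              attr(x, "trait_name"), attr(x, "unit"), attr(x, "ancestry"),
              nrow(x)))
  rep <- attr(x, "load_report")
  if (!is.null(rep) && rep[["n_rejected"]] > 0) {
    cat(sprintf("  %d of %d input rows rejected at load\n",
                rep[["n_rejected"]], rep[["n_input"]]))
  }
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' @param path file path to a header-ed TSV.
#' @param trait_name trait label; defaults to the file stem.
#' @param unit,ancestry trait metadata, see [summary_stats()].
#' @param dialect column mapping from [default_dialect()].
#' @return A `summary_stats` object.
#' @export
read_summary_stats <- function(path, trait_name = NULL, unit = "SD",
                               ancestry = "European",
                               dialect = default_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path)
  mandatory <- c("variant_id", "chrom", "pos", "effect_allele",
                 "other_allele", "beta", "se", "pvalue")
  for (field in mandatory) {
    if (!dialect[[field]] %in% names(raw)) {
      stop("missing mandatory column '", dialect[[field]],
           "' (field ", field, ") in ", path)
    }
  }
  rec <- data.frame(
    variant_id = raw[[dialect[["variant_id"]]]],
    chrom = raw[[dialect[["chrom"]]]],
    pos = raw[[dialect[["pos"]]]],
    effect_allele = raw[[dialect[["effect_allele"]]]],
    other_allele = raw[[dialect[["other_allele"]]]],
    eaf = if (dialect[["eaf"]] %in% names(raw)) raw[[dialect[["eaf"]]]] else NA_real_,
    beta = raw[[dialect[["beta"]]]],
    se = raw[[dialect[["se"]]]],
    pvalue = raw[[dialect[["pvalue"]]]],
    n = if (dialect[["n"]] %in% names(raw)) raw[[dialect[["n"]]]] else NA_real_,
    stringsAsFactors = FALSE
  )
  for (opt in c("n_case", "n_control")) {
    if (dialect[[opt]] %in% names(raw)) rec[[opt]] <- raw[[dialect[[opt]]]]
  }
  if (is.null(trait_name)) {
    trait_name <- sub("\\.[^.]*$", "", basename(path))
  }
  summary_stats(rec, trait_name = trait_name, unit = unit, ancestry = ancestry)
}

#' Write summary statistics as a tab-separated file
#'
#' Uses the same dialect defaults that [read_summary_stats()] accepts, so a
#' round trip preserves the table.
#'
#' @param ss a `summary_stats` object.
#' @param path output file.
#' @param dialect column mapping, see [default_dialect()].
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(ss, path, dialect = default_dialect()) {
  stopifnot(inherits(ss, "summary_stats"))
  out <- as.data.frame(ss)
  keep <- intersect(names(dialect), names(out))
  out <- out[keep]
  names(out) <- dialect[keep]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct an LD matrix of squared correlations
#'
#' @param variant_ids ordered variant identifiers.
#' @param r2 square symmetric matrix of squared correlations in \[0,1\] with
#'   unit diagonal.
#' @return An `ld_matrix` object (the matrix with a `variant_ids` dimnames).
#' @export
ld_matrix <- function(variant_ids, r2) {
  r2 <- as.matrix(r2)
  stopifnot(nrow(r2) == length(variant_ids), ncol(r2) == length(variant_ids))
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0,1]")
  if (max(abs(r2 - t(r2))) > 1e-12) stop("r2 matrix must be symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-12) stop("r2 diagonal must be 1")
  dimnames(r2) <- list(variant_ids, variant_ids)
  class(r2) <- c("ld_matrix", class(r2))
  r2
}

#' Read an LD matrix from TSV (variant IDs as header row and first column)
#' @param path file path.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  m <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                         check.names = FALSE)
  ld_matrix(rownames(m), as.matrix(m))
}

#' Select independent genome-wide-significant instruments
#'
#' Greedy clumping: variants passing `p < p_threshold` are visited in order
#' of ascending p-value (ties broken by variant ID); a variant is retained
#' iff its squared correlation with every already-retained variant within
#' `window_kb` of it is below `r2_max`. When no LD matrix is supplied the
#' fallback is distance-only pruning: retained variants on the same
#' chromosome must be more than `window_kb` apart (windows are centre
#' +/- `window_kb`, inclusive at the boundary).
#'
#' @param ss a `summary_stats` object.
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param r2_max clumping threshold on squared correlation (default 0.001).
#' @param window_kb clumping window half-width in kilobases (default 10000).
#' @param ld optional [ld_matrix()] covering every significant variant.
#' @return A `summary_stats` subset, ordered by chromosome and position.
#' @export
select_instruments <- function(ss, p_threshold = 5e-8, r2_max = 0.001,
                               window_kb = 10000, ld = NULL) {
  stopifnot(inherits(ss, "summary_stats"))
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0,1)")
  if (r2_max < 0 || r2_max > 1) stop("r2_max must be in [0,1]")

  sig <- as.data.frame(ss)[ss$pvalue < p_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) {
    out <- ss[0L, , drop = FALSE]
    return(restore_ss(out, ss))
  }
  if (!is.null(ld)) {
    missing <- setdiff(sig$variant_id, rownames(ld))
    if (length(missing)) {
      stop("LD matrix missing significant variant(s): ",
           paste(missing, collapse = ", "))
    }
  }
  ord <- order(sig$pvalue, sig$variant_id)
  sig <- sig[ord, , drop = FALSE]
  window_bp <- window_kb * 1000

  kept <- integer(0)
  for (i in seq_len(nrow(sig))) {
    ok <- TRUE
    for (k in kept) {
      same_chr <- sig$chrom[i] == sig$chrom[k]
      in_window <- same_chr && abs(sig$pos[i] - sig$pos[k]) <= window_bp
      if (!in_window) next
      if (is.null(ld)) {
        ok <- FALSE  # distance-only: anything within the window conflicts
      } else if (ld[sig$variant_id[i], sig$variant_id[k]] >= r2_max) {
        ok <- FALSE
      }
      if (!ok) break
    }
    if (ok) kept <- c(kept, i)
  }
  out <- sig[kept, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  restore_ss(out, ss)
}

# Re-attach summary_stats class/metadata after a data-frame subset.
restore_ss <- function(df, template) {
  structure(as.data.frame(df),
    class = c("summary_stats", "data.frame"),
    trait_name = attr(template, "trait_name"),
    unit = attr(template, "unit"),
    ancestry = attr(template, "ancestry"),
    load_report = attr(template, "load_report")
  )
}

complement_allele <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic <- function(ea, oa) oa == complement_allele(ea)

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns the two traits' per-variant effects to the exposure's effect
#' allele. Outcome records whose alleles are swapped relative to the
#' exposure have their beta sign flipped and frequency complemented; records
#' coded on the opposite strand are complemented first. Strand-ambiguous
#' (A/T, C/G) variants are aligned by allele frequency when both
#' frequencies lie outside `palindrome_eaf_band`, and dropped otherwise
#' (including when either frequency is missing). Variants absent from
#' either trait, or with irreconcilable alleles, are dropped. Every decision
#' is recorded in the provenance table attached as `attr(, "provenance")`.
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param palindrome_eaf_band frequency interval within which palindromic
#'   variants cannot be safely aligned (default `c(0.40, 0.60)`).
#' @return A `harmonised_set`: data frame with columns `variant_id`,
#'   `chrom`, `pos`, `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf`,
#'   `flag`; exposure/outcome names and provenance as attributes.
#' @export
harmonise <- function(exposure, outcome,
                      palindrome_eaf_band = c(0.40, 0.60)) {
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"))
  ex <- as.data.frame(exposure)
  ot <- as.data.frame(outcome)
  idx <- match(ex$variant_id, ot$variant_id)

  n <- nrow(ex)
  flag <- character(n)
  beta_out <- se_out <- rep(NA_real_, n)
  lo <- palindrome_eaf_band[1]; hi <- palindrome_eaf_band[2]

  for (i in seq_len(n)) {
    j <- idx[i]
    if (is.na(j)) { flag[i] <- "dropped_missing"; next }
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ot$effect_allele[j]; oa_y <- ot$other_allele[j]
    pal <- is_palindromic(ea_x, oa_x)
    if (pal) {
      same_set <- (ea_y == ea_x && oa_y == oa_x) ||
        (ea_y == oa_x && oa_y == ea_x)
      if (!same_set) { flag[i] <- "dropped_mismatch"; next }
      fx <- ex$eaf[i]; fy <- ot$eaf[j]
      inband <- function(f) is.na(f) || (f > lo && f < hi)
      if (inband(fx) || inband(fy)) { flag[i] <- "dropped_palindromic"; next }
      aligned <- (fx < 0.5) == (fy < 0.5)
      if (aligned) {
        flag[i] <- "unchanged"
        beta_out[i] <- ot$beta[j]; se_out[i] <- ot$se[j]
      } else {
        flag[i] <- "allele_flipped"
        beta_out[i] <- -ot$beta[j]; se_out[i] <- ot$se[j]
      }
      next
    }
    # try direct match, then strand-complemented match
    match_type <- NA_character_
    if (ea_y == ea_x && oa_y == oa_x) match_type <- "same"
    else if (ea_y == oa_x && oa_y == ea_x) match_type <- "swap"
    else {
      ea_c <- complement_allele(ea_y); oa_c <- complement_allele(oa_y)
      if (ea_c == ea_x && oa_c == oa_x) match_type <- "same"
      else if (ea_c == oa_x && oa_c == ea_x) match_type <- "swap"
    }
    if (is.na(match_type)) {
      flag[i] <- "dropped_mismatch"
      warning("irreconcilable alleles at ", ex$variant_id[i],
              " (", ea_x, "/", oa_x, " vs ", ea_y, "/", oa_y, "); dropped",
              call. = FALSE)
      next
    }
    if (match_type == "same") {
      flag[i] <- "unchanged"
      beta_out[i] <- ot$beta[j]; se_out[i] <- ot$se[j]
    } else {
      flag[i] <- "allele_flipped"
      beta_out[i] <- -ot$beta[j]; se_out[i] <- ot$se[j]
    }
  }

  provenance <- data.frame(variant_id = ex$variant_id, flag = flag,
                           stringsAsFactors = FALSE)
  keep <- flag %in% c("unchanged", "allele_flipped")
  h <- data.frame(
    variant_id = ex$variant_id[keep],
    chrom = ex$chrom[keep], pos = ex$pos[keep],
    effect_allele = ex$effect_allele[keep],
    other_allele = ex$other_allele[keep],
    beta_exp = ex$beta[keep], se_exp = ex$se[keep],
    beta_out = beta_out[keep], se_out = se_out[keep],
    eaf = ex$eaf[keep], flag = flag[keep],
    stringsAsFactors = FALSE
  )
  rownames(h) <- NULL
  structure(h,
    class = c("harmonised_set", "data.frame"),
    exposure_name = attr(exposure, "trait_name"),
    outcome_name = attr(outcome, "trait_name"),
    outcome_unit = attr(outcome, "unit"),
    provenance = provenance
  )
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("Harmonised instrument set: %s -> %s, %d variants\n",
              attr(x, "exposure_name"), attr(x, "outcome_name"), nrow(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov)) print(table(prov$flag))
  invisible(x)
}

#' Instrument strength (per-variant and mean F-statistics)
#'
#' F for one variant is the squared exposure z-score `(beta_exp/se_exp)^2`.
#' Mean F at or below 10 raises the conventional weak-instrument flag.
#'
#' @param h a `harmonised_set`.
#' @return List with `f` (named per-variant values), `mean_f`, and logical
#'   `weak` (`TRUE` iff mean F <= 10).
#' @export
instrument_strength <- function(h) {
  stopifnot(inherits(h, "harmonised_set"))
  if (nrow(h) == 0L) stop("empty instrument set")
  f <- (h$beta_exp / h$se_exp)^2
  names(f) <- h$variant_id
  mean_f <- mean(f)
  list(f = f, mean_f = mean_f, weak = mean_f <= 10)
}
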