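#' Assemble a multivariable MR dataset
#'
#' Takes the union of genome-wide-significant variants across the
#' exposures, prunes it to independent variants with the same greedy rule
#' as [select_instruments()] (each variant prioritised by its minimum
#' p-value across exposures, ties broken by variant ID), harmonises every
#' exposure and the outcome to a common effect allele (that of the first
#' exposure carrying the variant), and keeps variants observed in all
#' traits.
#'
#' @param exposures list of `summary_stats` (>= 2 for a multivariable fit;
#'   a single exposure is permitted for reduction checks).
#' @param outcome a `summary_stats` object.
#' @param p_threshold,r2_max,window_kb,ld clumping controls as in
#'   [select_instruments()].
#' @return An `mvmr_dataset` data frame: `variant_id`, `beta.<trait>` and
#'   `se.<trait>` per exposure, `beta_out`, `se_out`; exposure names in
#'   `attr(, "exposure_names")`.
#' @export
assemble_mvmr <- function(exposures, outcome, p_threshold = 5e-8,
                          r2_max = 0.001, window_kb = 10000, ld = NULL) {
  stopifnot(length(exposures) >= 1L,
            all(vapply(exposures, inherits, TRUE, "summary_stats")),
            inherits(outcome, "summary_stats"))
  enames <- vapply(exposures, function(e) attr(e, "trait_name"), character(1))
  if (anyDuplicated(enames)) stop("duplicate exposure trait names")

  # union of significant variants, keyed by min p across exposures,
  # with chrom/pos/alleles taken from the first exposure carrying each
  union <- NULL
  for (e in exposures) {
    sig <- as.data.frame(e)[e$pvalue < p_threshold, , drop = FALSE]
    if (nrow(sig) == 0L) next
    sig <- sig[c("variant_id", "chrom", "pos", "effect_allele",
                 "other_allele", "eaf", "pvalue")]
    if (is.null(union)) {
      union <- sig
    } else {
      new <- !(sig$variant_id %in% union$variant_id)
      union <- rbind(union, sig[new, , drop = FALSE])
      upd <- match(sig$variant_id[!new], union$variant_id)
      union$pvalue[upd] <- pmin(union$pvalue[upd], sig$pvalue[!new])
    }
  }
  if (is.null(union) || nrow(union) == 0L) {
    stop("no genome-wide-significant variants across exposures")
  }
  union$beta <- 0; union$se <- 1; union$n <- NA_real_  # carriers for clumping
  union_ss <- summary_stats(union, trait_name = "mvmr_union", unit = "SD")
  pruned <- select_instruments(union_ss, p_threshold = 1 - 1e-12,
                               r2_max = r2_max, window_kb = window_kb,
                               ld = ld)
  # select_instruments needs p < threshold; union rows already filtered, so
  # pruning runs on all of them ordered by their recorded min p.

  ref <- summary_stats(
    transform(as.data.frame(pruned), beta = 0, se = 1, pvalue = 0.5),
    trait_name = "mvmr_reference", unit = "SD"
  )

  d <- data.frame(variant_id = ref$variant_id, stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(d))
  for (k in seq_along(exposures)) {
    hk <- harmonise(ref, exposures[[k]])
    idx <- match(d$variant_id, hk$variant_id)
    d[[paste0("beta.", enames[k])]] <- hk$beta_out[idx]
    d[[paste0("se.", enames[k])]] <- hk$se_out[idx]
    keep <- keep & !is.na(idx)
  }
  ho <- harmonise(ref, outcome)
  idx <- match(d$variant_id, ho$variant_id)
  d$beta_out <- ho$beta_out[idx]
  d$se_out <- ho$se_out[idx]
  keep <- keep & !is.na(idx)
  d <- d[keep, , drop = FALSE]
  rownames(d) <- NULL

  m <- length(exposures)
  if (nrow(d) <= m) {
    stop("under-identified multivariable dataset: ", nrow(d),
         " variants for ", m, " exposures")
  }
  structure(d,
    class = c("mvmr_dataset", "data.frame"),
    exposure_names = enames,
    outcome_name = attr(outcome, "trait_name")
  )
}

#' Multivariable IVW estimation
#'
#' No-intercept weighted least-squares regression of outcome effects on the
#' exposure-effect columns with weights `1/se_out^2`. Each coefficient is
#' the corresponding exposure's direct effect conditional on the others.
#' Standard errors use multiplicative overdispersion floored at 1;
#' p-values from the two-sided normal approximation.
#'
#' @param d an `mvmr_dataset` from [assemble_mvmr()].
#' @return Named list of `mr_estimate` objects, one per exposure.
#' @export
mvmr_ivw <- function(d) {
  stopifnot(inherits(d, "mvmr_dataset"))
  enames <- attr(d, "exposure_names")
  m <- length(enames)
  n <- nrow(d)
  if (n <= m) stop("more exposures than informative variants")
  X <- as.matrix(d[paste0("beta.", enames)])
  colnames(X) <- enames
  qr_x <- qr(X)
  if (qr_x$rank < m) {
    dropped <- enames[-qr_x$pivot[seq_len(qr_x$rank)]]
    stop("collinear exposure effects: ", paste(dropped, collapse = ", "))
  }
  w <- 1 / d$se_out^2
  fit <- wls_fit(X, d$beta_out, w)
  phi <- max(1, sqrt(fit$rss_w / (n - m)))
  se <- fit$se_unit * phi
  out <- lapply(enames, function(nm) {
    mr_estimate("mvmr_ivw", fit$coef[[nm]], se[[nm]], n_snp = n)
  })
  names(out) <- enames
  out
}
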