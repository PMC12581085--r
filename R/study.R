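#' Bonferroni flags for a family of tests
#'
#' Threshold is `0.05/n_tests`, applied with strict inequality; the display
#' threshold is the same value rounded to 4 decimals (so 16 outcomes give
#' 0.0031 and 24 mediators give 0.0021).
#'
#' @param pvalues numeric vector of p-values.
#' @param n_tests family size (>= 1).
#' @return List with `threshold`, `display_threshold`, logical `flags`.
#' @export
apply_bonferroni <- function(pvalues, n_tests) {
  stopifnot(n_tests >= 1)
  thr <- 0.05 / n_tests
  list(threshold = thr,
       display_threshold = round(thr, 4),
       flags = pvalues < thr)
}

#' Format an estimate as "x.xx (x.xx to x.xx)"
#'
#' Two-decimal round-half-away-from-zero presentation; `scale = "or"`
#' exponentiates first (for log-OR estimates).
#'
#' @param e an `mr_estimate`.
#' @param scale `"beta"` or `"or"`.
#' @return A display string.
#' @export
format_effect <- function(e, scale = c("beta", "or")) {
  scale <- match.arg(scale)
  v <- c(e$beta, e$ci_low, e$ci_high)
  if (scale == "or") v <- exp(v)
  v <- round_half_away(v)
  sprintf("%.2f (%.2f to %.2f)", v[1], v[2], v[3])
}

format_pct <- function(p) {
  sprintf("%.2f%% (%.2f%% to %.2f%%)",
          round_half_away(p$percentage),
          round_half_away(min(100, p$ci_low)),
          round_half_away(min(100, p$ci_high)))
}

#' Assemble a study configuration
#'
#' @param exposure list with `name`, `file`, and optionally `unit`.
#' @param outcomes list of outcome specs (`name`, `file`, `category`,
#'   optionally `unit`, default `"logOR"`).
#' @param mediators list of mediator specs (`name`, `file`, `category`,
#'   optionally `unit`, default `"SD"`).
#' @param p_threshold,r2_max,window_kb instrument-selection controls.
#' @param sensitivity character vector naming the sensitivity analyses to
#'   run, from `c("egger", "median", "mode", "presso", "loo", "overlap")`.
#' @param seed integer seed (required when any stochastic sensitivity
#'   analysis is enabled).
#' @return A validated `study_config` list.
#' @export
study_config <- function(exposure, outcomes, mediators,
                         p_threshold = 5e-8, r2_max = 0.001,
                         window_kb = 10000,
                         sensitivity = c("egger", "median", "presso",
                                         "loo", "overlap"),
                         seed = NULL) {
  stopifnot(length(outcomes) >= 1)
  sensitivity <- match.arg(sensitivity,
                           c("egger", "median", "mode", "presso", "loo",
                             "overlap"), several.ok = TRUE)
  needs_seed <- any(c("median", "mode", "presso") %in% sensitivity)
  if (needs_seed && is.null(seed)) {
    stop("a seed is required when stochastic sensitivity analyses are enabled")
  }
  fill <- function(spec, default_unit) {
    stopifnot(!is.null(spec$name), !is.null(spec$file))
    if (is.null(spec$unit)) spec$unit <- default_unit
    if (is.null(spec$category)) spec$category <- "unclassified"
    spec
  }
  structure(list(
    exposure = fill(exposure, "SD"),
    outcomes = lapply(outcomes, fill, default_unit = "logOR"),
    mediators = lapply(mediators, fill, default_unit = "SD"),
    p_threshold = p_threshold, r2_max = r2_max, window_kb = window_kb,
    sensitivity = sensitivity, seed = seed
  ), class = "study_config")
}

#' Read a study configuration from YAML
#'
#' The YAML mirrors the [study_config()] arguments: `exposure:` mapping,
#' `outcomes:`/`mediators:` sequences of mappings, scalar thresholds,
#' `sensitivity:` sequence, `seed:`.
#'
#' @param path YAML file.
#' @param base_dir directory file paths are resolved against (defaults to
#'   the YAML's directory).
#' @return A `study_config`.
#' @export
read_study_config <- function(path, base_dir = dirname(path)) {
  y <- yaml::read_yaml(path)
  resolve <- function(spec) {
    if (!is.null(spec$file) && !grepl("^/", spec$file)) {
      spec$file <- file.path(base_dir, spec$file)
    }
    spec
  }
  study_config(
    exposure = resolve(y$exposure),
    outcomes = lapply(y$outcomes, resolve),
    mediators = lapply(y$mediators, resolve),
    p_threshold = y$p_threshold %||% 5e-8,
    r2_max = y$r2_max %||% 0.001,
    window_kb = y$window_kb %||% 10000,
    sensitivity = unlist(y$sensitivity %||%
                           list("egger", "median", "presso", "loo", "overlap")),
    seed = y$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the default study configuration as YAML
#'
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_default_config <- function(path) {
  yaml::write_yaml(list(
    exposure = list(name = "birth_weight", file = "exposure.tsv", unit = "SD"),
    outcomes = list(list(name = "outcome_1", file = "outcome_1.tsv",
                         unit = "logOR", category = "other")),
    mediators = list(list(name = "mediator_1", file = "mediator_1.tsv",
                          unit = "SD", category = "body composition")),
    p_threshold = 5e-8, r2_max = 0.001, window_kb = 10000,
    sensitivity = list("egger", "median", "presso", "loo", "overlap"),
    seed = 1
  ), path)
  invisible(path)
}

est_row <- function(name, e, extra = list()) {
  cbind(data.frame(trait = name, beta = e$beta, se = e$se,
                   ci_low = e$ci_low, ci_high = e$ci_high,
                   pvalue = e$pvalue, n_snp = e$n_snp,
                   stringsAsFactors = FALSE),
        as.data.frame(extra, stringsAsFactors = FALSE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Run the full two-step MR mediation study
#'
#' Executes the study funnel: instrument selection for the exposure; total
#' effects on every outcome (IVW, with the configured sensitivity
#' analyses); step-1 effects on every mediator; for each outcome passing
#' the outcome-layer Bonferroni screen, multivariable step-2 effects and
#' mediation decomposition for each mediator passing the mediator-layer
#' screen; qualification of each pair; optional overlap-variant exclusion
#' sensitivity. Report tables, a Sankey-style edge list, a run log and a
#' JSON-lines event stream are written under `out_dir`.
#'
#' The mediator-outcome Bonferroni denominator is the realised number of
#' step-2 tests, reported in the run log.
#'
#' @param cfg a `study_config`.
#' @param out_dir output directory (created if missing).
#' @return A `study_report` list with the report tables
#'   (`bw_cvd_table`, `bw_mediator_table`, `mediator_cvd_table`,
#'   `mediation_table`, `sensitivity_block`, `sankey_edges`) and `files`,
#'   the paths written.
#' @export
run_study <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  events <- list()
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                                      msg))
    invisible(NULL)
  }
  event <- function(type, ...) {
    events[[length(events) + 1L]] <<- c(list(event = type), list(...))
  }

  note("study start: %d outcomes, %d mediators, seed %s",
       length(cfg$outcomes), length(cfg$mediators),
       ifelse(is.null(cfg$seed), "none", cfg$seed))
  event("config", p_threshold = cfg$p_threshold, r2_max = cfg$r2_max,
        window_kb = cfg$window_kb, seed = cfg$seed %||% NA)

  exposure <- read_summary_stats(cfg$exposure$file,
                                 trait_name = cfg$exposure$name,
                                 unit = cfg$exposure$unit)
  exp_iv <- select_instruments(exposure, cfg$p_threshold, cfg$r2_max,
                               cfg$window_kb)
  note("exposure %s: %d variants, %d instruments", cfg$exposure$name,
       nrow(exposure), nrow(exp_iv))
  event("instruments", trait = cfg$exposure$name, n = nrow(exp_iv))

  layers <- bonferroni_layers(n_outcomes = length(cfg$outcomes),
                              n_mediators = length(cfg$mediators))

  outcome_data <- lapply(cfg$outcomes, function(s) {
    read_summary_stats(s$file, trait_name = s$name, unit = s$unit)
  })
  mediator_data <- lapply(cfg$mediators, function(s) {
    read_summary_stats(s$file, trait_name = s$name, unit = s$unit)
  })

  # --- total effects: exposure -> each outcome -------------------------
  sens_rows <- list()
  bw_cvd <- do.call(rbind, lapply(seq_along(cfg$outcomes), function(i) {
    s <- cfg$outcomes[[i]]
    h <- harmonise(exp_iv, outcome_data[[i]])
    strength <- instrument_strength(h)
    e <- mr_ivw(h)
    if (strength$weak) note("WARNING weak instruments for %s (mean F %.1f)",
                            s$name, strength$mean_f)
    sens_rows[[length(sens_rows) + 1L]] <<-
      sensitivity_block(h, e, cfg, pair = paste0("exposure->", s$name))
    or <- to_odds_ratio(e)
    est_row(s$name, e, list(category = s$category,
                            or = or$or, or_display = format_effect(e, "or"),
                            mean_f = strength$mean_f))
  }))
  bf_out <- apply_bonferroni(bw_cvd$pvalue, length(cfg$outcomes))
  bw_cvd$significant <- bf_out$flags
  note("outcome screen: threshold %.4g (display %.4f), %d/%d significant",
       bf_out$threshold, bf_out$display_threshold, sum(bf_out$flags),
       nrow(bw_cvd))

  # --- step 1: exposure -> each mediator -------------------------------
  bw_med <- do.call(rbind, lapply(seq_along(cfg$mediators), function(i) {
    s <- cfg$mediators[[i]]
    h <- harmonise(exp_iv, mediator_data[[i]])
    e <- mr_ivw(h)
    sens_rows[[length(sens_rows) + 1L]] <<-
      sensitivity_block(h, e, cfg, pair = paste0("exposure->", s$name))
    est_row(s$name, e, list(category = s$category))
  }))
  bf_med <- apply_bonferroni(bw_med$pvalue, length(cfg$mediators))
  bw_med$significant <- bf_med$flags
  note("mediator screen: threshold %.4g (display %.4f), %d/%d significant",
       bf_med$threshold, bf_med$display_threshold, sum(bf_med$flags),
       nrow(bw_med))

  # --- step 2 + mediation for the significant funnel -------------------
  sig_out <- which(bw_cvd$significant)
  sig_med <- which(bw_med$significant)
  n_pair_tests <- length(sig_out) * length(sig_med)
  pair_layers <- bonferroni_layers(
    n_outcomes = length(cfg$outcomes),
    n_mediators = length(cfg$mediators),
    n_pairs = max(1L, n_pair_tests)
  )
  note("mediator-outcome layer: %d realised tests, threshold %.4g",
       n_pair_tests, pair_layers$alpha_mediator_outcome)

  med_cvd <- NULL
  mediation_tab <- NULL
  for (oi in sig_out) {
    os <- cfg$outcomes[[oi]]
    for (mi in sig_med) {
      ms <- cfg$mediators[[mi]]
      res <- tryCatch(
        mediate_pair(exposure, mediator_data[[mi]], outcome_data[[oi]],
                     p_threshold = cfg$p_threshold, r2_max = cfg$r2_max,
                     window_kb = cfg$window_kb, layers = pair_layers),
        error = function(e) {
          note("ERROR mediation %s -> %s: %s", ms$name, os$name,
               conditionMessage(e))
          event("mediation_error", mediator = ms$name, outcome = os$name,
                message = conditionMessage(e))
          NULL
        })
      if (is.null(res) || !res$estimable) {
        if (!is.null(res)) {
          note("non-estimable mediation %s -> %s", ms$name, os$name)
          event("non_estimable", mediator = ms$name, outcome = os$name)
        }
        next
      }
      med_cvd <- rbind(med_cvd, est_row(
        ms$name, res$beta2,
        list(outcome = os$name,
             significant = res$beta2$pvalue < pair_layers$alpha_mediator_outcome)
      ))
      mediation_tab <- rbind(mediation_tab, data.frame(
        outcome = os$name, mediator = ms$name,
        total = format_effect(res$total),
        beta1 = format_effect(res$beta1),
        beta2 = format_effect(res$beta2),
        indirect = res$indirect$value,
        proportion = format_pct(res$proportion),
        proportion_pct = res$proportion$percentage,
        qualified = res$qualified,
        stringsAsFactors = FALSE
      ))
      if ("overlap" %in% cfg$sensitivity) {
        ov <- overlap_sensitivity(exposure, mediator_data[[mi]],
                                  outcome_data[[oi]],
                                  p_threshold = cfg$p_threshold,
                                  r2_max = cfg$r2_max,
                                  window_kb = cfg$window_kb,
                                  layers = pair_layers)
        note("overlap exclusion %s -> %s: %d shared variants removed%s",
             ms$name, os$name, ov$n_excluded,
             if (ov$estimable) "" else " (non-estimable)")
        event("overlap_sensitivity", mediator = ms$name, outcome = os$name,
              n_excluded = ov$n_excluded, estimable = ov$estimable)
      }
    }
  }

  # keep only qualified mediators in the mediation table, mirroring the
  # published funnel
  if (!is.null(mediation_tab)) {
    mediation_tab <- mediation_tab[mediation_tab$qualified, , drop = FALSE]
    rownames(mediation_tab) <- NULL
  } else {
    mediation_tab <- data.frame(outcome = character(0), mediator = character(0),
                                total = character(0), beta1 = character(0),
                                beta2 = character(0), indirect = numeric(0),
                                proportion = character(0),
                                proportion_pct = numeric(0),
                                qualified = logical(0))
  }
  if (is.null(med_cvd)) {
    med_cvd <- data.frame(trait = character(0), beta = numeric(0),
                          se = numeric(0), ci_low = numeric(0),
                          ci_high = numeric(0), pvalue = numeric(0),
                          n_snp = integer(0), outcome = character(0),
                          significant = logical(0))
  }

  # --- Sankey-style edge list ------------------------------------------
  sankey <- rbind(
    data.frame(source = cfg$exposure$name, target = bw_cvd$trait,
               effect = bw_cvd$beta, width = abs(bw_cvd$beta),
               stringsAsFactors = FALSE)[bw_cvd$significant, , drop = FALSE],
    if (nrow(mediation_tab)) {
      b1 <- bw_med$beta[match(mediation_tab$mediator, bw_med$trait)]
      rbind(
        unique(data.frame(source = cfg$exposure$name,
                          target = mediation_tab$mediator,
                          effect = b1, width = abs(b1),
                          stringsAsFactors = FALSE)),
        data.frame(source = mediation_tab$mediator,
                   target = mediation_tab$outcome,
                   effect = med_cvd$beta[match(
                     paste(mediation_tab$mediator, mediation_tab$outcome),
                     paste(med_cvd$trait, med_cvd$outcome))],
                   width = NA, stringsAsFactors = FALSE)
      )
    }
  )
  if (!is.null(sankey)) sankey$width <- abs(sankey$effect)
  rownames(sankey) <- NULL

  sens_tab <- do.call(rbind, sens_rows)

  files <- c(
    bw_cvd_table = file.path(out_dir, "bw_cvd_table.tsv"),
    bw_mediator_table = file.path(out_dir, "bw_mediator_table.tsv"),
    mediator_cvd_table = file.path(out_dir, "mediator_cvd_table.tsv"),
    mediation_table = file.path(out_dir, "mediation_table.tsv"),
    sensitivity = file.path(out_dir, "sensitivity.tsv"),
    sankey_edges = file.path(out_dir, "sankey_edges.tsv")
  )
  write_tsv(bw_cvd, files[["bw_cvd_table"]])
  write_tsv(bw_med, files[["bw_mediator_table"]])
  write_tsv(med_cvd, files[["mediator_cvd_table"]])
  write_tsv(mediation_tab, files[["mediation_table"]])
  write_tsv(sens_tab, files[["sensitivity"]])
  write_tsv(sankey, files[["sankey_edges"]])

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  events_path <- file.path(out_dir, "events.jsonl")
  writeLines(vapply(events, function(e) {
    jsonlite::toJSON(e, auto_unbox = TRUE, null = "null", na = "null")
  }, character(1)), events_path)

  structure(list(
    bw_cvd_table = bw_cvd, bw_mediator_table = bw_med,
    mediator_cvd_table = med_cvd, mediation_table = mediation_tab,
    sensitivity_block = sens_tab, sankey_edges = sankey,
    files = c(files, run_log = log_path, events = events_path)
  ), class = "study_report")
}

# One tidy block of sensitivity estimates for a harmonised pair.
sensitivity_block <- function(h, ivw_est, cfg, pair) {
  rows <- list(est_row(pair, ivw_est, list(method = "ivw_random")))
  add <- function(e, method) {
    rows[[length(rows) + 1L]] <<- est_row(pair, e, list(method = method))
  }
  add(mr_ivw(h, model = "fixed"), "ivw_fixed")
  n <- nrow(h)
  if ("egger" %in% cfg$sensitivity && n >= 3) {
    eg <- mr_egger(h)
    add(eg$slope, "egger_slope")
    rows[[length(rows) + 1L]] <- data.frame(
      trait = pair, beta = eg$intercept$value, se = eg$intercept$se,
      ci_low = eg$intercept$value - Z95 * eg$intercept$se,
      ci_high = eg$intercept$value + Z95 * eg$intercept$se,
      pvalue = eg$intercept$pvalue, n_snp = n, method = "egger_intercept",
      stringsAsFactors = FALSE)
  }
  if ("median" %in% cfg$sensitivity && n >= 3) {
    add(mr_weighted_median(h, n_boot = 500, seed = cfg$seed), "weighted_median")
  }
  if ("mode" %in% cfg$sensitivity && n >= 3) {
    add(mr_weighted_mode(h, n_boot = 500, seed = cfg$seed), "weighted_mode")
  }
  if ("presso" %in% cfg$sensitivity && n >= 4) {
    pr <- mr_presso(h, n_sim = 500, seed = cfg$seed)
    rows[[length(rows) + 1L]] <- data.frame(
      trait = pair, beta = pr$corrected$beta, se = pr$corrected$se,
      ci_low = pr$corrected$ci_low, ci_high = pr$corrected$ci_high,
      pvalue = pr$global_p, n_snp = pr$corrected$n_snp,
      method = "presso_corrected", stringsAsFactors = FALSE)
  }
  if (n >= 2) {
    q <- cochrans_q(h, mr_ivw(h, model = "fixed"))
    rows[[length(rows) + 1L]] <- data.frame(
      trait = pair, beta = q$Q, se = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, pvalue = q$pvalue, n_snp = n,
      method = "cochran_q", stringsAsFactors = FALSE)
  }
  if ("loo" %in% cfg$sensitivity && n >= 3) {
    loo <- leave_one_out(h)
    spread <- max(loo$beta) - min(loo$beta)
    rows[[length(rows) + 1L]] <- data.frame(
      trait = pair, beta = spread, se = NA_real_, ci_low = min(loo$beta),
      ci_high = max(loo$beta), pvalue = NA_real_, n_snp = n,
      method = "loo_beta_range", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Two-step MR mediation study report\n")
  cat(sprintf("  %d outcomes (%d significant), %d mediators (%d significant)\n",
              nrow(x$bw_cvd_table), sum(x$bw_cvd_table$significant),
              nrow(x$bw_mediator_table), sum(x$bw_mediator_table$significant)))
  cat(sprintf("  %d qualified mediation rows\n", nrow(x$mediation_table)))
  invisible(x)
}
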