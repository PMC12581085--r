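#' Published mediation coefficients for the birth-weight study
#'
#' The printed step-1 (`beta1`), step-2 (`beta2`) and total-effect
#' coefficients, with the printed mediated percentage, for every
#' mediator-outcome pair in the study's mediation table whose coefficients
#' are printed at usable precision. The four systolic-blood-pressure rows
#' are omitted: their step-2 coefficients are printed too coarsely
#' (two decimals on values of magnitude 0.01-0.04) to recompute the
#' percentage. These are transcribed published estimates, used as inputs
#' for arithmetic-reproduction checks, not outputs of this package.
#'
#' @return Data frame with columns `outcome`, `mediator`, `beta1`, `beta2`,
#'   `total`, `percent`.
#' @export
published_mediation_cells <- function() {
  rows <- list(
    c("aortic aneurysm", "appendicular lean mass", 0.47, 0.22, 0.38, 26.32),
    c("aortic aneurysm", "body mass index", 0.11, 0.40, 0.38, 10.53),
    c("venous thromboembolism", "height", 0.60, 0.22, 0.19, 68.42),
    c("venous thromboembolism", "appendicular lean mass", 0.47, 0.18, 0.19, 42.11),
    c("venous thromboembolism", "body mass index", 0.11, 0.36, 0.19, 21.05),
    c("atrial fibrillation", "height", 0.60, 0.29, 0.29, 58.62),
    c("atrial fibrillation", "appendicular lean mass", 0.47, 0.29, 0.29, 48.28),
    c("atrial fibrillation", "body mass index", 0.11, 0.30, 0.29, 10.34),
    c("coronary heart disease", "type 2 diabetes", -0.56, 0.15, -0.32, 25.00),
    c("coronary heart disease", "height", 0.60, -0.11, -0.32, 21.88),
    c("coronary heart disease", "triglycerides", -0.14, 0.36, -0.32, 15.62),
    c("coronary heart disease", "total cholesterol", -0.09, 0.47, -0.32, 12.50),
    c("myocardial infarction", "type 2 diabetes", -0.56, 0.14, -0.34, 23.53),
    c("myocardial infarction", "triglycerides", -0.14, 0.35, -0.34, 14.71),
    c("myocardial infarction", "total cholesterol", -0.09, 0.43, -0.34, 11.76),
    c("angina pectoris", "type 2 diabetes", -0.56, 0.12, -0.21, 33.33),
    c("angina pectoris", "triglycerides", -0.14, 0.41, -0.21, 28.57),
    c("angina pectoris", "total cholesterol", -0.09, 0.34, -0.21, 14.29),
    c("angina pectoris", "alanine", -0.11, 0.26, -0.21, 14.29)
  )
  df <- data.frame(
    outcome = vapply(rows, `[`, character(1), 1),
    mediator = vapply(rows, `[`, character(1), 2),
    beta1 = as.numeric(vapply(rows, `[`, character(1), 3)),
    beta2 = as.numeric(vapply(rows, `[`, character(1), 4)),
    total = as.numeric(vapply(rows, `[`, character(1), 5)),
    percent = as.numeric(vapply(rows, `[`, character(1), 6)),
    stringsAsFactors = FALSE
  )
  df
}

#' Published total effects on the log-OR scale with their 95% CIs
#'
#' Used to reproduce the study's odds-ratio presentation for the outcomes
#' it reports in the abstract.
#'
#' @return Data frame with `outcome`, `beta`, `ci_low`, `ci_high`, `or`,
#'   `or_low`, `or_high` (the printed odds ratios).
#' @export
published_total_effects <- function() {
  data.frame(
    outcome = c("atrial fibrillation", "aortic aneurysm",
                "myocardial infarction"),
    beta = c(0.29, 0.38, -0.34),
    ci_low = c(0.19, 0.19, -0.46),
    ci_high = c(0.39, 0.56, -0.22),
    or = c(1.34, 1.46, 0.71),
    or_low = c(1.21, 1.21, 0.63),
    or_high = c(1.48, 1.75, 0.80),
    stringsAsFactors = FALSE
  )
}
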