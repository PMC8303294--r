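#' @name qpcr_quant
#' @title Comparative-CT qPCR quantification
#'
#' @description
#' Relative quantification of qPCR data against a reference gene using the
#' comparative-CT method with PCR efficiency fixed at 2 (100%): relative
#' expression is `2^-(Ct_target - Ct_ref)` and the fold change between two
#' arms is `2^-(mean dCt_treated - mean dCt_control)`.
NULL

#' Relative expression by the comparative-CT method
#'
#' @param ct_target target-gene Ct value(s), cycles.
#' @param ct_ref reference-gene Ct value(s), cycles.
#' @param calibrator optional relative-expression value of a calibrator
#'   sample; when given, results are scaled by it.
#' @return `2^-(ct_target - ct_ref)`, optionally divided by `calibrator`.
#' @examples
#' relative_expression(25, 20)  # 2^-5
#' @export
relative_expression <- function(ct_target, ct_ref, calibrator = NULL) {
  if (!all(is.finite(ct_target)) || !all(is.finite(ct_ref))) {
    stopf("Ct values must be finite")
  }
  out <- 2^(-(ct_target - ct_ref))
  if (!is.null(calibrator)) {
    check_number(calibrator, "calibrator", lower = 0, strict = TRUE)
    out <- out / calibrator
  }
  out
}

#' Fold change between two arms by the delta-delta-Ct method
#'
#' The delta-delta-Ct is computed on the mean delta-Ct of each arm (the
#' standard comparative-CT convention); per-replicate relative expressions
#' and their mean and standard error are reported alongside.
#'
#' @param treated,control data frames with columns `ct_target` and `ct_ref`
#'   (one row per replicate).
#' @return list with `fold_change` (`2^-ddCt`, treated vs control),
#'   `treated_rel` and `control_rel` (per-replicate relative expressions)
#'   and `summary` (per-arm mean and SEM of relative expression).
#' @export
ddct_fold_change <- function(treated, control) {
  for (arm in list(treated, control)) {
    if (!is.data.frame(arm) || nrow(arm) == 0) {
      stopf("both arms must be non-empty data frames")
    }
    if (!all(c("ct_target", "ct_ref") %in% names(arm))) {
      stopf("arms need columns 'ct_target' and 'ct_ref'")
    }
    if (!all(is.finite(arm$ct_target)) || !all(is.finite(arm$ct_ref))) {
      stopf("Ct values must be finite")
    }
  }
  dct_t <- treated$ct_target - treated$ct_ref
  dct_c <- control$ct_target - control$ct_ref
  rel_t <- 2^(-dct_t)
  rel_c <- 2^(-dct_c)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  list(
    fold_change = 2^(-(mean(dct_t) - mean(dct_c))),
    treated_rel = rel_t,
    control_rel = rel_c,
    summary = data.frame(
      arm = c("control", "treated"),
      n = c(length(rel_c), length(rel_t)),
      mean_rel = c(mean(rel_c), mean(rel_t)),
      sem_rel = c(sem(rel_c), sem(rel_t)),
      stringsAsFactors = FALSE
    )
  )
}
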