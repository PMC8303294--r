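#' @name fibrosis_scoring
#' @title Composite fibrotic score, stratification and signature selection
#'
#' @description
#' The fibrotic score aggregates the relative expression of the three
#' fibrotic marker genes COL1A1, FN1 and ACTA2 into a single number per
#' sample:
#' \deqn{FS_s = \frac{1}{3}\left[\frac{Exp_s(COL1A1)}{ExpMax(COL1A1)} +
#'   \frac{Exp_s(FN1)}{ExpMax(FN1)} +
#'   \frac{Exp_s(ACTA2)}{ExpMax(ACTA2)}\right]}
#' where each `ExpMax` is the highest expression of that marker in the
#' cohort. The score lies in (0, 1]; a sample attaining the cohort maximum
#' for all three markers scores exactly 1. Samples with a score above a
#' threshold (default 0.25) are stratified as "High", the rest as "Low".
#' miRNAs are then ranked by the Pearson correlation of their log2
#' normalized expression with the score, and the signature is the top `k`
#' among those exceeding a minimum correlation (defaults: k = 25, r > 0.5).
NULL

check_marker_panel <- function(markers) {
  if (!is.data.frame(markers)) stopf("'markers' must be a data frame")
  miss <- setdiff(c("sample_id", MARKER_GENES), names(markers))
  if (length(miss) > 0) {
    stopf("marker panel is missing column(s): %s", paste(miss, collapse = ", "))
  }
  vals <- as.matrix(markers[, MARKER_GENES])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stopf("marker expression must be finite and numeric")
  }
  if (any(vals <= 0)) stopf("marker expression must be strictly positive")
  invisible(markers)
}

#' Compute the fibrotic score from a three-marker panel
#'
#' @param markers data frame with columns `sample_id`, `COL1A1`, `FN1`,
#'   `ACTA2` (relative expression, strictly positive), one row per sample.
#' @param max_samples optional character vector of sample ids over which the
#'   per-marker maxima (`ExpMax`) are taken; defaults to the whole cohort.
#' @return data frame with columns `sample_id` and `score`.
#' @examples
#' panel <- data.frame(sample_id = c("S1", "S2", "S3"),
#'                     COL1A1 = c(10, 5, 1), FN1 = c(20, 10, 2),
#'                     ACTA2 = c(30, 15, 3))
#' fibrotic_score(panel)  # scores 1.0, 0.5, 0.1
#' @export
fibrotic_score <- function(markers, max_samples = NULL) {
  check_marker_panel(markers)
  if (nrow(markers) < 2) stopf("need at least 2 samples")
  ref <- markers
  if (!is.null(max_samples)) {
    ref <- markers[markers$sample_id %in% max_samples, , drop = FALSE]
    if (nrow(ref) == 0) stopf("'max_samples' matches no samples")
  }
  vals <- as.matrix(markers[, MARKER_GENES])
  maxima <- apply(as.matrix(ref[, MARKER_GENES]), 2, max)
  ratios <- sweep(vals, 2, maxima, "/")
  data.frame(
    sample_id = markers$sample_id,
    score = rowMeans(ratios),
    stringsAsFactors = FALSE
  )
}

#' Stratify fibrotic scores into Low and High
#'
#' Scores strictly above the threshold are "High"; scores at or below it
#' (including the boundary) are "Low".
#'
#' @param scores numeric vector of fibrotic scores.
#' @param threshold stratification cutoff in (0, 1); default 0.25.
#' @return factor with levels `Low`, `High`.
#' @export
stratify_scores <- function(scores, threshold = 0.25) {
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    stopf("'scores' must be finite numeric")
  }
  if (threshold <= 0 || threshold >= 1) stopf("'threshold' must be in (0, 1)")
  factor(ifelse(scores > threshold, "High", "Low"), levels = c("Low", "High"))
}

#' Score and stratify a cohort in one step
#'
#' @inheritParams fibrotic_score
#' @inheritParams stratify_scores
#' @param groups optional per-sample group labels carried into the output.
#' @return data frame with `sample_id`, `score`, `stratum` (and `group`).
#' @export
annotate_fibrosis <- function(markers, threshold = 0.25, groups = NULL,
                              max_samples = NULL) {
  ann <- fibrotic_score(markers, max_samples = max_samples)
  ann$stratum <- stratify_scores(ann$score, threshold)
  if (!is.null(groups)) ann$group <- groups
  ann
}

#' Correlate miRNA expression with the fibrotic score
#'
#' Computes the Pearson correlation between each miRNA's log2 normalized
#' expression and the fibrotic score across all cohort samples. miRNAs with
#' zero variance across samples have no defined correlation; they are
#' flagged `excluded` and take no rank.
#'
#' @param log_expr numeric matrix of log2 normalized expression (miRNA x
#'   sample) with sample ids as column names.
#' @param scores data frame from [fibrotic_score()] or a named numeric
#'   vector of scores.
#' @return data frame with `mirna_id`, `r`, `rank` (by decreasing `r`, ties
#'   broken by miRNA id), `excluded` and `selected` (all `FALSE`; see
#'   [select_signature()]).
#' @export
correlate_with_score <- function(log_expr, scores) {
  if (is.data.frame(scores)) {
    s <- scores$score
    names(s) <- scores$sample_id
    scores <- s
  }
  if (is.null(colnames(log_expr)) || is.null(names(scores))) {
    stopf("sample ids required on both expression matrix and scores")
  }
  if (!setequal(colnames(log_expr), names(scores))) {
    stopf("sample ids of expression matrix and scores do not match")
  }
  if (ncol(log_expr) < 3) stopf("need at least 3 samples")
  scores <- scores[colnames(log_expr)]
  sds <- apply(log_expr, 1, stats::sd)
  r <- rep(NA_real_, nrow(log_expr))
  ok <- sds > 0
  if (any(ok)) {
    r[ok] <- as.vector(stats::cor(t(log_expr[ok, , drop = FALSE]), scores))
  }
  ids <- rownames(log_expr)
  if (is.null(ids)) ids <- sprintf("row%d", seq_len(nrow(log_expr)))
  out <- data.frame(
    mirna_id = ids, r = r, rank = NA_integer_, excluded = !ok,
    selected = FALSE, stringsAsFactors = FALSE
  )
  ranked <- order(-out$r[ok], out$mirna_id[ok])
  out$rank[which(ok)[ranked]] <- seq_len(sum(ok))
  out
}

#' Select the fibrosis-correlated miRNA signature
#'
#' Marks as selected the `k` highest-correlation miRNAs among those with
#' `r > r_min`; when fewer than `k` qualify, all qualifying miRNAs are
#' selected. Ties at the k-th rank are broken by lexicographic miRNA id
#' (already encoded in the table's ranks).
#'
#' @param table correlation table from [correlate_with_score()].
#' @param r_min minimum Pearson correlation (default 0.5).
#' @param k maximum signature size (default 25).
#' @return the table with its `selected` column filled in.
#' @export
select_signature <- function(table, r_min = 0.5, k = 25) {
  k <- check_count(k, "k", 1L)
  if (!all(c("mirna_id", "r", "rank") %in% names(table))) {
    stopf("'table' must come from correlate_with_score()")
  }
  qual <- !is.na(table$r) & table$r > r_min
  if (sum(qual) == 0) {
    table$selected <- rep(FALSE, nrow(table))
  } else {
    cutoff <- sort(table$rank[qual])[min(k, sum(qual))]
    table$selected <- qual & !is.na(table$rank) & table$rank <= cutoff
  }
  table
}
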