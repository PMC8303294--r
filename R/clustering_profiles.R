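#' @name clustering_profiles
#' @title Pearson-distance clustering and progenitor profile archetypes
#'
#' @description
#' Row Z-scoring of log2 normalized expression, hierarchical clustering
#' with `1 - Pearson correlation` as the distance and complete linkage
#' (the convention of heatmap packages), a rule-based classification of
#' FAP/MP +/- TGFbeta1 expression profiles into four archetypes, and set
#' intersection of miRNA lists.
NULL

#' Z-score the rows of a matrix
#'
#' Each row is centred and scaled to unit sample standard deviation.
#' Constant rows have no Z-score; they are dropped with a warning and
#' listed in the `dropped` attribute of the result.
#'
#' @param x numeric matrix with at least two columns.
#' @return the row-standardized matrix, with attribute `dropped` naming any
#'   removed constant rows.
#' @export
zscore_rows <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stopf("need at least two columns to Z-score")
  sds <- apply(x, 1, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning(sprintf("dropping %d constant row(s)", sum(const)),
            call. = FALSE)
  }
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("row%d", seq_len(nrow(x)))
  out <- (x[!const, , drop = FALSE] -
            rowMeans(x[!const, , drop = FALSE])) / sds[!const]
  attr(out, "dropped") <- ids[const]
  out
}

#' Pearson correlation distance between two vectors
#'
#' @param x,y non-constant numeric vectors of equal length >= 3.
#' @return `1 - cor(x, y)`, in `[0, 2]`.
#' @export
pearson_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stopf("vectors must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("Pearson distance undefined for constant vectors")
  }
  1 - stats::cor(x, y)
}

#' Pairwise Pearson distance matrix over matrix rows
#'
#' @param x numeric matrix; rows are the items.
#' @return `dist` object of `1 - cor` between rows.
#' @export
pearson_dist_matrix <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    stopf("constant rows have undefined Pearson distance; drop them first")
  }
  stats::as.dist(1 - stats::cor(t(x)))
}

#' Complete-linkage hierarchical clustering with Pearson distance
#'
#' @param x numeric matrix of items to cluster.
#' @param axis cluster the `"rows"` (e.g. miRNAs) or the `"cols"`
#'   (samples) of `x`.
#' @return an [stats::hclust] object; cut it with [stats::cutree].
#' @export
hac_complete <- function(x, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  x <- as.matrix(x)
  if (axis == "cols") x <- t(x)
  if (nrow(x) < 2) stopf("need at least two items to cluster")
  stats::hclust(pearson_dist_matrix(x), method = "complete")
}

#' Mean normalized expression per condition
#'
#' @param counts count matrix (miRNA x sample).
#' @param condition character/factor of per-sample condition labels.
#' @param sf size factors; computed with [size_factors()] when `NULL`.
#' @return matrix of normalized condition means (miRNA x condition).
#' @export
condition_means <- function(counts, condition, sf = NULL) {
  counts <- as.matrix(counts)
  if (length(condition) != ncol(counts)) {
    stopf("'condition' length must match the number of samples")
  }
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  conds <- unique(as.character(condition))
  out <- vapply(conds, function(cc) {
    rowMeans(norm[, condition == cc, drop = FALSE])
  }, numeric(nrow(counts)))
  if (nrow(counts) == 1L) out <- matrix(out, nrow = 1,
                                        dimnames = list(rownames(counts),
                                                        conds))
  out
}

ARCHETYPE_CLASSES <- c("C1", "C2", "C3", "C4", "unclassified")

#' Classify FAP/MP +/- TGFbeta1 profiles into four archetypes
#'
#' Each miRNA is summarized by its cell-type enrichment (log2 ratio of mean
#' FAP over mean MP expression, across both treatments) and its TGFbeta1
#' response (log2 fold change under TGFbeta1, measured in the enriched cell
#' type). The archetype rules are: MP-enriched (enrichment <= -e_min) and
#' repressed (response <= -l_min) -> C1; MP-enriched and unresponsive
#' (|response| < l_min) -> C2; FAP-enriched (>= e_min) and repressed -> C3;
#' FAP-enriched and induced (>= l_min) -> C4; anything else unclassified.
#'
#' @param cond_means matrix of normalized condition means (miRNA x
#'   condition) with columns `FAP_control`, `FAP_TGFB`, `MP_control`,
#'   `MP_TGFB`, e.g. from [condition_means()].
#' @param e_min enrichment threshold, log2 units (default 1).
#' @param l_min response threshold, log2 units (default 1).
#' @param expr_floor pseudo-expression added to means before ratios
#'   (default 0.5).
#' @return data frame with `mirna_id`, `cell_enrichment`, `tgfb_response`,
#'   `class`.
#' @export
classify_archetypes <- function(cond_means, e_min = 1, l_min = 1,
                                expr_floor = 0.5) {
  cond_means <- as.matrix(cond_means)
  miss <- setdiff(DESIGN_CONDITIONS, colnames(cond_means))
  if (length(miss) > 0) {
    stopf("missing condition(s): %s", paste(miss, collapse = ", "))
  }
  fc <- cond_means[, "FAP_control"] + expr_floor
  ft <- cond_means[, "FAP_TGFB"] + expr_floor
  mc <- cond_means[, "MP_control"] + expr_floor
  mt <- cond_means[, "MP_TGFB"] + expr_floor
  enrich <- log2((fc + ft) / (mc + mt))
  resp <- ifelse(enrich >= 0, log2(ft / fc), log2(mt / mc))
  class <- rep("unclassified", nrow(cond_means))
  class[enrich <= -e_min & resp <= -l_min] <- "C1"
  class[enrich <= -e_min & abs(resp) < l_min] <- "C2"
  class[enrich >= e_min & resp <= -l_min] <- "C3"
  class[enrich >= e_min & resp >= l_min] <- "C4"
  ids <- rownames(cond_means)
  if (is.null(ids)) ids <- sprintf("row%d", seq_len(nrow(cond_means)))
  data.frame(
    mirna_id = ids,
    cell_enrichment = enrich,
    tgfb_response = resp,
    class = factor(class, levels = ARCHETYPE_CLASSES),
    stringsAsFactors = FALSE
  )
}

#' Intersect two modulated-miRNA sets
#'
#' Venn-style set algebra between, e.g., the miRNAs modulated in dystrophic
#' biopsies and those modulated during progenitor differentiation.
#'
#' @param set_a,set_b character vectors of miRNA ids.
#' @return list with `n_a_only`, `n_both`, `n_b_only` and a sorted
#'   `membership` data frame (`mirna_id`, `in_a`, `in_b`).
#' @export
intersect_modulated <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  ids <- sort(union(set_a, set_b))
  membership <- data.frame(
    mirna_id = ids,
    in_a = ids %in% set_a,
    in_b = ids %in% set_b,
    stringsAsFactors = FALSE
  )
  list(
    n_a_only = sum(membership$in_a & !membership$in_b),
    n_both = sum(membership$in_a & membership$in_b),
    n_b_only = sum(!membership$in_a & membership$in_b),
    membership = membership
  )
}
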