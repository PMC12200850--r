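#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' For each sample independently, genes are ranked by expression and each
#' gene set is scored by a weighted Kolmogorov-Smirnov-like running sum:
#' walking down the ranking from the most highly expressed gene, the
#' cumulative in-set distribution `P_in` (in-set genes weighted by
#' `rank^alpha`, normalized to total in-set weight) is compared with the
#' cumulative out-of-set distribution `P_out` (uniform steps over
#' out-of-set genes), and the score is the sum of `P_in - P_out` over all
#' positions. Because only within-sample ranks enter, scores are invariant
#' to any strictly monotone per-sample transformation.
#'
#' Rank ties within a sample are resolved by average rank for the
#' weighting, with the walking order fixed by gene ID among tied genes, so
#' results are deterministic. Genes missing (`NA`) in a sample are
#' excluded from that sample's ranking.
#'
#' @param mat Gene-by-sample numeric matrix.
#' @param sets Named list of gene-ID vectors (e.g. from [read_gmt()]).
#'   Sets with no gene in the matrix score `NA` with a warning.
#' @param alpha Rank-weighting exponent; 0.25 is the community default.
#' @param normalization `"raw"`; `"range"` (divide all scores by the
#'   global max - min, the customary cross-sample normalization); or
#'   `"zscore"` (per-set z-score across samples, the form used for
#'   relative-infiltration heat maps).
#' @return A set-by-sample numeric matrix with attributes `alpha` and
#'   `normalization`.
#' @export
ssgsea_scores <- function(mat, sets, alpha = 0.25,
                          normalization = c("raw", "range", "zscore")) {
  check_expression_matrix(mat)
  normalization <- match.arg(normalization)
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene sets must have unique names")
  }
  present <- lapply(sets, intersect, x = rownames(mat))
  empty <- lengths(present) == 0L
  if (any(empty)) {
    warning("set(s) with no gene in the matrix scored as NA: ",
            paste(names(sets)[empty], collapse = ", "))
  }
  in_set <- vapply(sets, function(s) rownames(mat) %in% s,
                   logical(nrow(mat)))  # genes x sets

  scores <- vapply(seq_len(ncol(mat)), function(s) {
    x <- mat[, s]
    obs <- !is.na(x)
    r <- rank(x[obs], ties.method = "average")
    # walk from highest expression down; ties ordered by gene ID
    ord <- order(-r, names(x)[obs])
    w <- r[ord] ^ alpha
    ins <- in_set[obs, , drop = FALSE][ord, , drop = FALSE]
    vapply(seq_along(sets), function(k) {
      if (empty[k]) return(NA_real_)
      flag <- ins[, k]
      n_in <- sum(flag)
      n_out <- length(flag) - n_in
      if (n_in == 0L) return(NA_real_)
      p_in <- cumsum(w * flag) / sum(w[flag])
      p_out <- if (n_out > 0L) cumsum(!flag) / n_out else rep(0, length(flag))
      sum(p_in - p_out)
    }, numeric(1))
  }, numeric(length(sets)))
  scores <- matrix(scores, nrow = length(sets),
                   dimnames = list(names(sets), colnames(mat)))

  if (normalization == "range") {
    rng <- range(scores, na.rm = TRUE)
    scores <- scores / (rng[2] - rng[1])
  } else if (normalization == "zscore") {
    scores <- zscore_rows(scores)
  }
  structure(scores, alpha = alpha, normalization = normalization)
}

#' Row-wise z-score (mean 0, sd 1 across samples)
#' @param mat Numeric matrix.
#' @return Matrix of the same shape; constant rows become all-zero.
#' @export
zscore_rows <- function(mat) {
  mu <- rowMeans(mat, na.rm = TRUE)
  sd <- apply(mat, 1L, stats::sd, na.rm = TRUE)
  sd[sd == 0 | is.na(sd)] <- 1
  (mat - mu) / sd
}

#' One-sided rank-sum comparison of a feature between classes
#'
#' Wilcoxon rank-sum (Mann-Whitney) test of a per-sample feature (an
#' ssGSEA score, an immune score, a gene's expression) between case and
#' control samples, in a stated direction. Exact enumeration is used for
#' small tie-free groups, the tie-corrected normal approximation with
#' continuity correction otherwise.
#'
#' @param feature Numeric vector, one value per sample.
#' @param labels Class labels, same length (or named like `feature`).
#' @param direction `"case_gt_control"` or `"control_gt_case"` — the
#'   alternative hypothesis.
#' @param case_label,control_label Class labels.
#' @return List with `statistic` (Mann-Whitney W for case vs control) and
#'   `p_value`.
#' @export
compare_feature_by_class <- function(feature, labels,
                                     direction = c("case_gt_control",
                                                   "control_gt_case"),
                                     case_label = "case",
                                     control_label = "control") {
  direction <- match.arg(direction)
  x <- feature[labels == case_label]
  y <- feature[labels == control_label]
  if (length(x) == 0L || length(y) == 0L) stop("both classes must be non-empty")
  if (length(unique(stats::na.omit(c(x, y)))) <= 1L) {
    warning("constant feature: reporting p = 1")
    return(list(statistic = NA_real_, p_value = 1))
  }
  alt <- if (direction == "case_gt_control") "greater" else "less"
  exact <- length(x) <= 25 && length(y) <= 25
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = exact,
                       correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Spearman correlations between genes and per-set scores
#'
#' Correlates the expression of each requested gene with each row of a
#' set-by-sample score matrix (e.g. ssGSEA immune-cell scores) across the
#' shared samples, with Benjamini-Hochberg adjustment over the whole
#' gene-by-set table.
#'
#' @param mat Gene-by-sample numeric matrix.
#' @param genes Gene IDs to correlate.
#' @param score_matrix Set-by-sample numeric matrix (samples must match
#'   columns of `mat` by name).
#' @param rank_within_sample Convert samples to within-sample ranks over
#'   all genes before correlating. The default (`FALSE`) correlates the
#'   genes' measured values, as is customary for expression-vs-infiltration
#'   heat maps; set `TRUE` for a batch-invariant variant (see
#'   [coexpression_network()]).
#' @return Data frame with columns `gene`, `set`, `rho`, `p_value`, `fdr`.
#' @export
gene_cell_correlations <- function(mat, genes, score_matrix,
                                   rank_within_sample = FALSE) {
  check_expression_matrix(mat)
  unknown <- setdiff(genes, rownames(mat))
  if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  if (rank_within_sample) mat <- rank_transform_samples(mat)
  shared <- intersect(colnames(mat), colnames(score_matrix))
  if (length(shared) < 3L) stop("need at least 3 aligned samples")
  grid <- expand.grid(gene = genes, set = rownames(score_matrix),
                      stringsAsFactors = FALSE)
  res <- t(mapply(function(g, s) {
    spearman_test(mat[g, shared], score_matrix[s, shared])
  }, grid$gene, grid$set))
  out <- data.frame(gene = grid$gene, set = grid$set,
                    rho = res[, 1L], p_value = res[, 2L],
                    stringsAsFactors = FALSE)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

# Spearman rho as Pearson on average ranks (tie-correct), p-value from the
# asymptotic t approximation t = rho * sqrt((n-2) / (1-rho^2)), two-sided.
spearman_test <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) return(c(rho = NA_real_, p_value = NA_real_))
  rho <- suppressWarnings(stats::cor(rank(x), rank(y)))
  if (is.na(rho)) return(c(rho = NA_real_, p_value = NA_real_))
  if (abs(rho) >= 1) return(c(rho = rho, p_value = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p_value = 2 * stats::pt(-abs(tstat), df = n - 2))
}
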