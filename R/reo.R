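#' Encode within-sample relative expression orderings
#'
#' For every pair of genes and every sample, the relative expression
#' ordering (REO) is the binary relation `E_i > E_j` or `E_i < E_j`
#' between the two genes' expression values within that sample. The
#' encoding depends only on within-sample comparisons, so it is invariant
#' to any strictly monotone per-sample transformation of the data.
#'
#' @param mat Gene-by-sample numeric matrix.
#' @param genes Optional subset of gene IDs to encode (default: all).
#' @return An object of class `reo_encoding`; query it with [reo_state()].
#' @export
encode_reo <- function(mat, genes = NULL) {
  check_expression_matrix(mat)
  if (!is.null(genes)) {
    unknown <- setdiff(genes, rownames(mat))
    if (length(unknown)) {
      stop("unknown gene(s): ", paste(unknown, collapse = ", "))
    }
    mat <- mat[genes, , drop = FALSE]
  }
  structure(list(values = mat), class = "reo_encoding")
}

#' Query the REO state of one gene pair in one sample
#'
#' @param encoding A `reo_encoding` from [encode_reo()].
#' @param gene_i,gene_j Gene IDs.
#' @param sample Sample ID or column index.
#' @return One of `"i_gt_j"`, `"i_lt_j"`, `"tie"`, `"missing"`.
#' @export
reo_state <- function(encoding, gene_i, gene_j, sample) {
  stopifnot(inherits(encoding, "reo_encoding"))
  mat <- encoding$values
  for (g in c(gene_i, gene_j)) {
    if (!g %in% rownames(mat)) stop("unknown gene: ", g)
  }
  ei <- mat[gene_i, sample]
  ej <- mat[gene_j, sample]
  if (is.na(ei) || is.na(ej)) return("missing")
  if (ei > ej) return("i_gt_j")
  if (ei < ej) return("i_lt_j")
  "tie"
}

#' @export
print.reo_encoding <- function(x, ...) {
  cat("REO encoding:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  invisible(x)
}

# Pairwise ordering counts over a set of samples. Returns, for the full
# gene x gene grid, the number of samples in which the row gene strictly
# exceeds the column gene (n_gt) and the number in which both genes are
# observed (n_obs). Missing values never contribute to n_gt: a missing
# entry is replaced by -Inf on the left of the comparison and +Inf on the
# right, so any comparison involving it is FALSE.
pairwise_order_counts <- function(mat) {
  n_genes <- nrow(mat)
  n_gt <- matrix(0, n_genes, n_genes)
  obs <- !is.na(mat)
  lo <- mat
  lo[!obs] <- -Inf
  hi <- mat
  hi[!obs] <- Inf
  for (s in seq_len(ncol(mat))) {
    n_gt <- n_gt + outer(lo[, s], hi[, s], ">")
  }
  n_obs <- tcrossprod(obs * 1)
  dimnames(n_gt) <- dimnames(n_obs) <- list(rownames(mat), rownames(mat))
  list(n_gt = n_gt, n_obs = n_obs)
}

#' Mine highly stable gene pairs within one class
#'
#' A gene pair is highly stable in a class when its REO direction is
#' consistent in at least a threshold fraction (default 85%) of the
#' class's samples. All canonical pairs (gene IDs in lexicographic order)
#' of the requested gene subset are examined exhaustively.
#'
#' Ties (`E_i == E_j`) count toward neither direction but remain in the
#' evaluable denominator, so they erode stability rather than inflate it.
#' Samples missing either gene are excluded from the denominator, and a
#' pair must be evaluable in at least `min_evaluable` samples (default:
#' half the class size, rounded up) to be reported.
#'
#' @param mat Gene-by-sample numeric matrix.
#' @param samples Sample IDs (or logical/integer index) of the class.
#' @param threshold Minimum consistency fraction, in (0.5, 1]. The
#'   comparison is inclusive (`>= threshold`).
#' @param genes Optional gene subset to mine (default: all genes).
#' @param min_evaluable Minimum evaluable samples per pair; default
#'   `ceiling(length(samples) / 2)`.
#' @param class_label Optional label recorded on the result.
#' @return A data frame of class `stable_pair_set` with columns `gene_i`,
#'   `gene_j` (canonical order), `direction` (`"i_gt_j"` / `"i_lt_j"`),
#'   `support`, `evaluable`, `frequency`, plus attributes `class_label`,
#'   `threshold`, `n_samples`.
#' @export
mine_stable_pairs <- function(mat, samples = colnames(mat), threshold = 0.85,
                              genes = NULL, min_evaluable = NULL,
                              class_label = NA_character_) {
  check_expression_matrix(mat)
  if (threshold <= 0.5 || threshold > 1) {
    stop("threshold must be in (0.5, 1]: below 0.5 the majority direction is ambiguous")
  }
  sub <- mat[, samples, drop = FALSE]
  if (ncol(sub) == 0L) stop("no samples selected")
  if (!is.null(genes)) {
    unknown <- setdiff(genes, rownames(sub))
    if (length(unknown)) {
      stop("unknown gene(s): ", paste(unknown, collapse = ", "))
    }
    sub <- sub[genes, , drop = FALSE]
  }
  sub <- sub[order(rownames(sub)), , drop = FALSE]
  if (is.null(min_evaluable)) min_evaluable <- ceiling(ncol(sub) / 2)

  counts <- pairwise_order_counts(sub)
  n <- nrow(sub)
  upper <- upper.tri(matrix(0, n, n))
  n_gt <- counts$n_gt[upper]      # samples with gene_i > gene_j (i < j canonical)
  n_lt <- t(counts$n_gt)[upper]   # samples with gene_i < gene_j
  n_obs <- counts$n_obs[upper]
  idx <- which(upper, arr.ind = TRUE)

  freq_gt <- ifelse(n_obs > 0, n_gt / n_obs, 0)
  freq_lt <- ifelse(n_obs > 0, n_lt / n_obs, 0)
  ok <- n_obs >= min_evaluable & (freq_gt >= threshold | freq_lt >= threshold)

  gt_wins <- freq_gt[ok] >= threshold
  out <- data.frame(
    gene_i = rownames(sub)[idx[ok, 1L]],
    gene_j = rownames(sub)[idx[ok, 2L]],
    direction = as.character(ifelse(gt_wins, "i_gt_j", "i_lt_j")),
    support = as.integer(ifelse(gt_wins, n_gt[ok], n_lt[ok])),
    evaluable = as.integer(n_obs[ok]),
    stringsAsFactors = FALSE
  )
  out$frequency <- as.numeric(ifelse(out$evaluable > 0,
                                     out$support / out$evaluable, 0))
  out <- out[order(out$gene_i, out$gene_j), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("stable_pair_set", "data.frame"),
            class_label = class_label,
            threshold = threshold,
            n_samples = ncol(sub),
            min_evaluable = min_evaluable)
}

#' @export
print.stable_pair_set <- function(x, ...) {
  cat(sprintf("Stable pair set (class %s): %d pairs at threshold %.2f over %d samples\n",
              attr(x, "class_label"), nrow(x), attr(x, "threshold"),
              attr(x, "n_samples")))
  if (nrow(x)) print.data.frame(utils::head(x, 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more pairs\n")
  invisible(x)
}

#' Find pairs reversed between two classes
#'
#' Intersects two stable-pair sets mined from the two phenotype classes.
#' Pairs present in both sets with opposite directions are "reversed" —
#' stable in one class but flipped in the other — and are the raw material
#' of a qualitative signature. Pairs stable in both classes with the same
#' direction are returned separately as `same_direction`.
#'
#' @param set_control,set_case `stable_pair_set` objects for the control
#'   and case class, mined at the same threshold.
#' @return A list with data frames `reversed` and `same_direction`, each
#'   carrying both per-class directions and frequencies, and a
#'   `provenance` list (thresholds, class labels, any threshold-mismatch
#'   warning).
#' @export
find_reversed_pairs <- function(set_control, set_case) {
  stopifnot(inherits(set_control, "stable_pair_set"),
            inherits(set_case, "stable_pair_set"))
  thr <- c(control = attr(set_control, "threshold"),
           case = attr(set_case, "threshold"))
  warning_msg <- NULL
  if (!isTRUE(all.equal(thr[["control"]], thr[["case"]]))) {
    warning_msg <- sprintf("threshold mismatch: control %g vs case %g",
                           thr[["control"]], thr[["case"]])
    warning(warning_msg)
  }
  merged <- merge(as.data.frame(set_control), as.data.frame(set_case),
                  by = c("gene_i", "gene_j"),
                  suffixes = c("_control", "_case"))
  merged <- merged[order(merged$gene_i, merged$gene_j), , drop = FALSE]
  rownames(merged) <- NULL
  flipped <- merged$direction_control != merged$direction_case
  list(
    reversed = merged[flipped, , drop = FALSE],
    same_direction = merged[!flipped, , drop = FALSE],
    provenance = list(
      threshold_control = thr[["control"]],
      threshold_case = thr[["case"]],
      class_control = attr(set_control, "class_label"),
      class_case = attr(set_case, "class_label"),
      warning = warning_msg
    )
  )
}

#' Write / read a stable-pair set as TSV
#'
#' @param pairs A `stable_pair_set`.
#' @param path Output path.
#' @export
write_stable_pairs <- function(pairs, path) {
  stopifnot(inherits(pairs, "stable_pair_set"))
  df <- as.data.frame(pairs)
  df$class <- attr(pairs, "class_label")
  df$threshold <- attr(pairs, "threshold")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
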