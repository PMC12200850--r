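#' Discover a gene-set-restricted qualitative signature
#'
#' Runs stable-pair mining separately in the two phenotype classes,
#' restricted to the genes of a supplied gene set (e.g. T-cell-related
#' genes), intersects the two sets, and keeps pairs whose REO direction is
#' reversed between classes. Each surviving pair is oriented so that the
#' case rule reads `E(low_in_case) < E(high_in_case)`: a sample votes
#' "case" on the pair exactly when the first gene is expressed below the
#' second.
#'
#' An empty signature is a valid outcome (reported with zero pairs), not
#' an error.
#'
#' @param mat Gene-by-sample numeric matrix.
#' @param labels Per-sample class labels (named by sample ID, or in column
#'   order).
#' @param gene_set Character vector of gene IDs to restrict mining to, or
#'   a gene-set collection from [read_gmt()] (the union of all sets is
#'   used). `NULL` mines all genes.
#' @param threshold Stability threshold passed to [mine_stable_pairs()].
#' @param case_label,control_label The two class labels; by default the
#'   labels' sorted unique values with `case_label` taken from
#'   `setdiff(labels, control_label)` — pass them explicitly for clarity.
#' @param min_evaluable Passed to [mine_stable_pairs()].
#' @return An object of class `reo_signature`: list with `pairs` (data
#'   frame: `low_in_case`, `high_in_case`, `freq_control`, `freq_case`),
#'   `case_label`, `control_label`, `threshold`, the two per-class
#'   `stable_sets`, and `provenance` (mining tallies).
#' @export
discover_signature <- function(mat, labels, gene_set = NULL, threshold = 0.85,
                               case_label = "case", control_label = "control",
                               min_evaluable = NULL) {
  check_expression_matrix(mat)
  labels <- match_labels(mat, labels)
  for (lab in c(case_label, control_label)) {
    if (!any(labels == lab)) stop("no samples with class label '", lab, "'")
  }
  if (!is.null(gene_set)) {
    if (is.list(gene_set)) gene_set <- unique(unlist(gene_set, use.names = FALSE))
    genes <- intersect(rownames(mat), gene_set)
    if (length(genes) == 0L) {
      stop("no gene of the supplied gene set is present in the matrix")
    }
  } else {
    genes <- rownames(mat)
  }

  ctrl_samples <- colnames(mat)[labels == control_label]
  case_samples <- colnames(mat)[labels == case_label]
  set_control <- mine_stable_pairs(mat, ctrl_samples, threshold, genes,
                                   min_evaluable, class_label = control_label)
  set_case <- mine_stable_pairs(mat, case_samples, threshold, genes,
                                min_evaluable, class_label = case_label)
  rev <- find_reversed_pairs(set_control, set_case)
  r <- rev$reversed

  # orient: the case-class direction says which gene is low in cases
  low <- ifelse(r$direction_case == "i_lt_j", r$gene_i, r$gene_j)
  high <- ifelse(r$direction_case == "i_lt_j", r$gene_j, r$gene_i)
  pairs <- data.frame(
    low_in_case = low,
    high_in_case = high,
    freq_control = r$frequency_control,
    freq_case = r$frequency_case,
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL

  structure(list(
    pairs = pairs,
    case_label = case_label,
    control_label = control_label,
    threshold = threshold,
    stable_sets = list(control = set_control, case = set_case),
    provenance = list(
      n_genes_mined = length(genes),
      n_control_samples = length(ctrl_samples),
      n_case_samples = length(case_samples),
      n_stable_control = nrow(set_control),
      n_stable_case = nrow(set_case),
      n_reversed = nrow(rev$reversed),
      n_same_direction = nrow(rev$same_direction),
      gene_set_restricted = !is.null(gene_set),
      multi_pair = nrow(pairs) > 1L
    )
  ), class = "reo_signature")
}

#' Construct a signature by hand
#'
#' Builds a `reo_signature` directly from oriented gene pairs, e.g. to
#' apply a published pair such as a sample being called case when the
#' first gene is expressed below the second.
#'
#' @param low_in_case,high_in_case Gene IDs, recycled to equal length.
#' @param case_label,control_label Class labels.
#' @param threshold Stability threshold recorded in provenance.
#' @return An object of class `reo_signature`.
#' @export
reo_signature <- function(low_in_case, high_in_case,
                          case_label = "case", control_label = "control",
                          threshold = NA_real_) {
  if (length(low_in_case) == 0L) stop("signature needs at least one pair")
  if (any(low_in_case == high_in_case)) {
    stop("genes within a signature pair must be distinct")
  }
  structure(list(
    pairs = data.frame(low_in_case = low_in_case, high_in_case = high_in_case,
                       freq_control = NA_real_, freq_case = NA_real_,
                       stringsAsFactors = FALSE),
    case_label = case_label,
    control_label = control_label,
    threshold = threshold,
    provenance = list(created_from = "manual")
  ), class = "reo_signature")
}

#' @export
print.reo_signature <- function(x, ...) {
  cat(sprintf("REO qualitative signature: %d pair(s), case = '%s', control = '%s'\n",
              nrow(x$pairs), x$case_label, x$control_label))
  if (nrow(x$pairs)) {
    for (k in seq_len(nrow(x$pairs))) {
      cat(sprintf("  %s rule: E[%s] < E[%s]\n", x$case_label,
                  x$pairs$low_in_case[k], x$pairs$high_in_case[k]))
    }
  } else {
    cat("  (empty signature: no reversed pair survived)\n")
  }
  invisible(x)
}

#' Classify samples by winner-takes-all vote
#'
#' For each signature pair, a sample votes for the case class when the
#' pair's low gene is strictly below its high gene
#' (`E(low_in_case) < E(high_in_case)`), and for the control class when
#' it is strictly above. Ties and pairs with a missing gene vote for
#' neither class. The sample label is the majority vote; an exact vote tie
#' goes to the control class (the case rule requires strict inequality);
#' a sample in which no pair is evaluable is `"unclassifiable"`.
#'
#' With a single-pair signature this reduces exactly to the rule: call
#' case iff the low gene is expressed below the high gene. The label is
#' invariant to any strictly monotone per-sample transformation.
#'
#' A continuous score accompanies each label for ROC analysis:
#' `log2(E(high_in_case) / E(low_in_case))`, averaged over evaluable
#' pairs; positive scores favour case. If either value is non-positive the
#' difference `E(high) - E(low)` is used for that pair and the row is
#' flagged. The score, unlike the label, is not monotone-invariant.
#'
#' @param mat Gene-by-sample numeric matrix.
#' @param signature A `reo_signature`.
#' @return Data frame with one row per sample: `sample_id`, `votes_case`,
#'   `votes_control`, `ties_or_missing`, `label`, `score`,
#'   `score_fallback`. Vote columns always sum to the number of pairs.
#' @export
classify_samples <- function(mat, signature) {
  check_expression_matrix(mat)
  stopifnot(inherits(signature, "reo_signature"))
  pairs <- signature$pairs
  if (nrow(pairs) == 0L) stop("cannot classify with an empty signature")
  genes <- unique(c(pairs$low_in_case, pairs$high_in_case))
  missing_genes <- setdiff(genes, rownames(mat))
  lowv <- matrix(NA_real_, nrow(pairs), ncol(mat))
  highv <- matrix(NA_real_, nrow(pairs), ncol(mat))
  ok_low <- pairs$low_in_case %in% rownames(mat)
  ok_high <- pairs$high_in_case %in% rownames(mat)
  lowv[ok_low, ] <- mat[pairs$low_in_case[ok_low], , drop = FALSE]
  highv[ok_high, ] <- mat[pairs$high_in_case[ok_high], , drop = FALSE]

  observed <- !is.na(lowv) & !is.na(highv)
  votes_case <- colSums(observed & lowv < highv)
  votes_control <- colSums(observed & lowv > highv)
  ties_or_missing <- nrow(pairs) - votes_case - votes_control

  # a tied pair is still evaluable: the case rule demands strict
  # inequality, so a tie falls to control; only a sample in which no pair
  # has both genes observed is unclassifiable
  label <- ifelse(colSums(observed) == 0L, "unclassifiable",
                  ifelse(votes_case > votes_control,
                         signature$case_label, signature$control_label))

  ratio_ok <- !is.na(lowv) & !is.na(highv) & lowv > 0 & highv > 0
  per_pair <- matrix(NA_real_, nrow(pairs), ncol(mat))
  per_pair[ratio_ok] <- log2(highv[ratio_ok] / lowv[ratio_ok])
  diff_ok <- !is.na(lowv) & !is.na(highv) & !ratio_ok
  per_pair[diff_ok] <- highv[diff_ok] - lowv[diff_ok]
  score <- colMeans(per_pair, na.rm = TRUE)
  score[is.nan(score)] <- NA_real_

  out <- data.frame(
    sample_id = colnames(mat),
    votes_case = as.integer(votes_case),
    votes_control = as.integer(votes_control),
    ties_or_missing = as.integer(ties_or_missing),
    label = label,
    score = score,
    score_fallback = colSums(diff_ok) > 0L,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (length(missing_genes)) {
    attr(out, "missing_genes") <- missing_genes
  }
  out
}

#' Classify a single sample
#'
#' @param sample Named numeric vector of expression values (names = gene
#'   IDs) for one sample.
#' @param signature A `reo_signature`.
#' @return A one-row data frame as in [classify_samples()].
#' @export
classify_sample <- function(sample, signature) {
  if (is.null(names(sample))) stop("sample vector must be named by gene ID")
  mat <- matrix(sample, ncol = 1, dimnames = list(names(sample), "sample"))
  classify_samples(mat, signature)
}

#' Continuous score for one sample on one signature pair
#'
#' `log2` fold change of the case-high gene over the case-low gene:
#' positive values favour the case class, a ratio of 1 scores 0. Used for
#' ROC curves only, never for the label. Falls back to the plain
#' difference when either value is non-positive.
#'
#' @param sample Named numeric vector of expression values.
#' @param low_in_case,high_in_case Gene IDs of the oriented pair.
#' @return A single numeric score (`NA` if either gene is missing).
#' @export
score_sample <- function(sample, low_in_case, high_in_case) {
  lo <- sample[[low_in_case]]
  hi <- sample[[high_in_case]]
  if (is.na(lo) || is.na(hi)) return(NA_real_)
  if (lo > 0 && hi > 0) log2(hi / lo) else hi - lo
}

#' Write / read a signature as JSON
#'
#' @param signature A `reo_signature`.
#' @param path Output path.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "reo_signature"))
  obj <- list(
    case_label = signature$case_label,
    control_label = signature$control_label,
    threshold = signature$threshold,
    pairs = signature$pairs,
    provenance = signature$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- as.data.frame(obj$pairs, stringsAsFactors = FALSE)
  structure(list(
    pairs = pairs,
    case_label = obj$case_label,
    control_label = obj$control_label,
    threshold = if (is.null(obj$threshold)) NA_real_ else obj$threshold,
    provenance = obj$provenance
  ), class = "reo_signature")
}
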