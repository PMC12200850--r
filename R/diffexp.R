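#' Wilcoxon rank-sum differential expression
#'
#' Tests every gene for a two-sided case-vs-control difference with the
#' Wilcoxon rank-sum test and controls the false discovery rate over all
#' tested genes by the Benjamini-Hochberg step-up procedure. Exact
#' p-values are used when both classes have at most 25 tie-free samples,
#' the tie-corrected normal approximation with continuity correction
#' otherwise. The per-gene direction comes from the class medians; genes
#' with equal medians get direction `"none"`. Constant genes are kept with
#' p = 1.
#'
#' @param mat Gene-by-sample numeric matrix.
#' @param labels Per-sample class labels.
#' @param case_label,control_label Class labels.
#' @param fdr_cutoff Significance cutoff on the BH-adjusted p-value
#'   (`fdr < cutoff`), recorded in the `significant` column.
#' @return A data frame of class `deg_table`: `gene`, `statistic` (W),
#'   `p_value`, `fdr`, `direction` (`"up_in_case"` / `"down_in_case"` /
#'   `"none"`), `median_case`, `median_control`, `significant`.
#' @export
wilcoxon_deg <- function(mat, labels, case_label = "case",
                         control_label = "control", fdr_cutoff = 0.01) {
  check_expression_matrix(mat)
  labels <- match_labels(mat, labels)
  case_cols <- labels == case_label
  ctrl_cols <- labels == control_label
  if (sum(case_cols) < 2L || sum(ctrl_cols) < 2L) {
    stop("need at least 2 samples per class")
  }
  exact <- sum(case_cols) <= 25 && sum(ctrl_cols) <= 25
  res <- t(apply(mat, 1L, function(v) {
    x <- v[case_cols]
    y <- v[ctrl_cols]
    if (length(unique(stats::na.omit(c(x, y)))) <= 1L) {
      return(c(NA_real_, 1, stats::median(x, na.rm = TRUE),
               stats::median(y, na.rm = TRUE)))
    }
    w <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
    c(unname(w$statistic), w$p.value,
      stats::median(x, na.rm = TRUE), stats::median(y, na.rm = TRUE))
  }))
  out <- data.frame(
    gene = rownames(mat),
    statistic = res[, 1L],
    p_value = res[, 2L],
    fdr = stats::p.adjust(res[, 2L], method = "BH"),
    direction = ifelse(res[, 3L] > res[, 4L], "up_in_case",
                       ifelse(res[, 3L] < res[, 4L], "down_in_case", "none")),
    median_case = res[, 3L],
    median_control = res[, 4L],
    stringsAsFactors = FALSE
  )
  out$significant <- out$fdr < fdr_cutoff
  rownames(out) <- NULL
  structure(out, class = c("deg_table", "data.frame"),
            fdr_cutoff = fdr_cutoff,
            case_label = case_label, control_label = control_label)
}

#' Genes consistently dysregulated across two cohorts
#'
#' Intersects two differential-expression tables: a gene is a consistent
#' DEG when it is significant in both cohorts with the SAME direction of
#' change (a signless direction never qualifies).
#'
#' @param table_a,table_b `deg_table` objects sharing a gene namespace.
#' @return Data frame: `gene`, `direction`, `fdr_a`, `fdr_b`.
#' @export
consistent_degs <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "deg_table"), inherits(table_b, "deg_table"))
  a <- table_a[table_a$significant & table_a$direction != "none", ]
  b <- table_b[table_b$significant & table_b$direction != "none", ]
  m <- merge(a[, c("gene", "direction", "fdr")],
             b[, c("gene", "direction", "fdr")],
             by = "gene", suffixes = c("_a", "_b"))
  m <- m[m$direction_a == m$direction_b, , drop = FALSE]
  out <- data.frame(gene = m$gene, direction = m$direction_a,
                    fdr_a = m$fdr_a, fdr_b = m$fdr_b,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman co-expression network around seed genes
#'
#' Screens every (seed gene, candidate gene) pair by Spearman rank
#' correlation across samples. The Benjamini-Hochberg adjustment spans
#' all tested pairs in one family, and an edge is kept only when BOTH
#' `|rho| > rho_cutoff` (strict) and `fdr < fdr_cutoff` hold. Pairs where
#' the seed equals the candidate are skipped.
#'
#' By default every sample is first converted to within-sample ranks over
#' all genes of the matrix before the across-sample correlation is taken.
#' This makes the network — like every other statistic in the package —
#' invariant to per-sample monotone distortion, at the price of some
#' attenuation of strong correlations. `rank_within_sample = FALSE` gives
#' the classical Spearman correlation of the genes' measured values, which
#' assumes samples are already on a comparable scale.
#'
#' @param mat Gene-by-sample numeric matrix (>= 4 samples).
#' @param seed_genes,candidate_genes Gene ID vectors present in `mat`.
#' @param rho_cutoff Absolute-correlation threshold (default 0.6).
#' @param fdr_cutoff FDR threshold (default 0.01).
#' @param rank_within_sample Replace each sample by its within-sample
#'   ranks before correlating (default `TRUE`; see Details).
#' @return Data frame of edges: `seed_gene`, `partner_gene`, `rho`,
#'   `p_value`, `fdr`, `sign`. The full screened table (pre-filter) is in
#'   attribute `"tested"`.
#' @export
coexpression_network <- function(mat, seed_genes, candidate_genes,
                                 rho_cutoff = 0.6, fdr_cutoff = 0.01,
                                 rank_within_sample = TRUE) {
  check_expression_matrix(mat)
  if (ncol(mat) < 4L) stop("need at least 4 samples")
  unknown <- setdiff(c(seed_genes, candidate_genes), rownames(mat))
  if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  if (rank_within_sample) mat <- rank_transform_samples(mat)
  ranks <- t(apply(mat[unique(c(seed_genes, candidate_genes)), , drop = FALSE],
                   1L, rank, ties.method = "average", na.last = "keep"))
  grid <- expand.grid(seed_gene = seed_genes, partner_gene = candidate_genes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$seed_gene != grid$partner_gene, , drop = FALSE]
  res <- t(mapply(function(s, p) spearman_test(ranks[s, ], ranks[p, ]),
                  grid$seed_gene, grid$partner_gene))
  tested <- data.frame(seed_gene = grid$seed_gene,
                       partner_gene = grid$partner_gene,
                       rho = res[, 1L], p_value = res[, 2L],
                       stringsAsFactors = FALSE)
  tested$fdr <- stats::p.adjust(tested$p_value, method = "BH")
  keep <- !is.na(tested$rho) & abs(tested$rho) > rho_cutoff &
    tested$fdr < fdr_cutoff
  edges <- tested[keep, , drop = FALSE]
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  edges <- edges[order(edges$seed_gene, edges$partner_gene), , drop = FALSE]
  rownames(edges) <- rownames(tested) <- NULL
  structure(edges, tested = tested,
            rho_cutoff = rho_cutoff, fdr_cutoff = fdr_cutoff)
}

# Replace each sample (column) by its within-sample ranks over all genes;
# invariant to any strictly monotone per-sample transformation.
rank_transform_samples <- function(mat) {
  out <- apply(mat, 2L, rank, ties.method = "average", na.last = "keep")
  dimnames(out) <- dimnames(mat)
  out
}

#' Hypergeometric over-representation of gene sets
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected when drawing `|query|` genes from the universe without
#' replacement: the p-value is the upper tail `P(X >= overlap)` of the
#' hypergeometric distribution. Sets are intersected with the universe
#' first; sets with no universe gene are skipped with a warning. P-values
#' are BH-adjusted across the surviving sets and rows are sorted by
#' p-value.
#'
#' @param query_genes Character vector (must be a subset of `universe`).
#' @param sets Named list of gene-ID vectors.
#' @param universe Character vector of all eligible genes.
#' @return Data frame: `set_name`, `overlap_count`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, `fdr`.
#' @export
hypergeom_enrich <- function(query_genes, sets, universe) {
  query_genes <- unique(query_genes)
  universe <- unique(universe)
  stray <- setdiff(query_genes, universe)
  if (length(stray)) {
    stop("query genes outside the universe: ", paste(stray, collapse = ", "))
  }
  sets_u <- lapply(sets, intersect, x = universe)
  empty <- lengths(sets_u) == 0L
  if (any(empty)) {
    warning("set(s) with no universe gene skipped: ",
            paste(names(sets)[empty], collapse = ", "))
    sets_u <- sets_u[!empty]
  }
  if (length(sets_u) == 0L) stop("no set intersects the universe")
  rows <- lapply(names(sets_u), function(nm) {
    s <- sets_u[[nm]]
    k <- length(intersect(query_genes, s))
    data.frame(
      set_name = nm,
      overlap_count = k,
      set_size = length(s),
      query_size = length(query_genes),
      universe_size = length(universe),
      p_value = stats::phyper(k - 1, length(s),
                              length(universe) - length(s),
                              length(query_genes), lower.tail = FALSE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tag differential genes with inflammation categories
#'
#' Annotates each gene of a DEG list with the inflammation-related
#' categories (e.g. chemokine / cytokine / inflammatory response /
#' interferon response) that contain it. Genes in several categories get
#' one row per category; genes in none are retained untagged (`NA`
#' category).
#'
#' @param deg A data frame with at least a `gene` column (e.g. from
#'   [consistent_degs()] or a filtered [wilcoxon_deg()] table).
#' @param inflammation_sets Named list of gene-ID vectors.
#' @return The input rows replicated per matching category, with an added
#'   `category` column.
#' @export
localize_inflammation_genes <- function(deg, inflammation_sets) {
  stopifnot(is.data.frame(deg), "gene" %in% names(deg))
  rows <- lapply(seq_len(nrow(deg)), function(i) {
    g <- deg$gene[i]
    cats <- names(inflammation_sets)[
      vapply(inflammation_sets, function(s) g %in% s, logical(1))]
    if (length(cats) == 0L) cats <- NA_character_
    cbind(deg[rep(i, length(cats)), , drop = FALSE],
          category = cats, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
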