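# Independent brute-force oracles used to verify the fast implementations.
# These are deliberately naive (triple loops, full enumeration) and share
# no code with the package internals.

# Stable-pair mining by explicit loops over canonical pairs and samples.
# Tie rule: ties stay in the evaluable denominator but support neither
# direction; samples missing either gene are excluded entirely.
oracle_stable_pairs <- function(mat, threshold, min_evaluable) {
  genes <- sort(rownames(mat))
  rows <- list()
  for (a in seq_along(genes)) {
    for (b in seq_along(genes)) {
      if (a >= b) next
      gi <- genes[a]; gj <- genes[b]
      n_gt <- 0L; n_lt <- 0L; n_obs <- 0L
      for (s in seq_len(ncol(mat))) {
        ei <- mat[gi, s]; ej <- mat[gj, s]
        if (is.na(ei) || is.na(ej)) next
        n_obs <- n_obs + 1L
        if (ei > ej) n_gt <- n_gt + 1L
        if (ei < ej) n_lt <- n_lt + 1L
      }
      if (n_obs < min_evaluable || n_obs == 0L) next
      if (n_gt / n_obs >= threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_i = gi, gene_j = gj, direction = "i_gt_j",
          support = n_gt, evaluable = n_obs, frequency = n_gt / n_obs,
          stringsAsFactors = FALSE)
      } else if (n_lt / n_obs >= threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_i = gi, gene_j = gj, direction = "i_lt_j",
          support = n_lt, evaluable = n_obs, frequency = n_lt / n_obs,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_i = character(), gene_j = character(),
                      direction = character(), support = integer(),
                      evaluable = integer(), frequency = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_i, out$gene_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Benjamini-Hochberg step-up by direct definition: adj_i = min over
# j >= i (ordered) of m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    adj[ord[i]] <- min(1, min(vals))
  }
  adj
}

# AUC by enumerating every (positive, negative) pair; ties count 1/2.
oracle_auc <- function(scores, truth, positive) {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exact one-sided Mann-Whitney p-value P(U >= u_obs) for "x tends larger
# than y", by enumerating every assignment of the pooled ranks (tie-free
# data only).
oracle_mw_one_sided <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(u_all >= u_obs)
}

# Small labelled matrix with controllable values; genes g1..gN, samples s1..sM.
make_matrix <- function(values, n_genes, n_samples) {
  matrix(values, n_genes, n_samples,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}

# Random matrix with injected ties and missing values, for oracle checks.
random_reo_matrix <- function(n_genes, n_samples, tie_frac = 0.15,
                              missing_frac = 0.1) {
  vals <- sample(1:5, n_genes * n_samples, replace = TRUE) +
    ifelse(stats::runif(n_genes * n_samples) < tie_frac, 0, stats::runif(n_genes * n_samples))
  vals[stats::runif(n_genes * n_samples) < missing_frac] <- NA
  make_matrix(vals, n_genes, n_samples)
}

expect_same_pairs <- function(a, b) {
  a <- as.data.frame(a)[, c("gene_i", "gene_j", "direction", "support",
                            "evaluable", "frequency")]
  b <- as.data.frame(b)[, c("gene_i", "gene_j", "direction", "support",
                            "evaluable", "frequency")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
}
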