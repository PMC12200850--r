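#' Configuration for a synthetic two-class expression cohort
#'
#' Describes a two-class (case/control) gene-by-sample cohort with the
#' statistical structure the REO pipeline assumes: log-normal baseline
#' intensities, planted reversed gene pairs with controlled per-class
#' ordering stability, planted same-direction stable pairs, class-specific
#' differential expression, equicorrelated gene modules, per-sample
#' monotone distortion (emulating batch / platform / normalization
#' differences, which REO statistics must shrug off), and completely-at-
#' random missingness.
#'
#' Defaults describe the reference validation scenario used throughout
#' the package's tests: 200 genes, 100 + 100 samples, one reversed pair
#' planted at 95% per-class stability, no differential expression, no
#' modules, no missingness.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_class Length-2 vector `c(control, case)`.
#' @param planted_reversed_pairs Data frame with columns `gene_i`,
#'   `gene_j` (1-based gene indices), `stability_control`,
#'   `stability_case` (fractions in `[0, 1]`). In control samples the
#'   pair's intended ordering is `E_i > E_j`; in case samples `E_i < E_j`;
#'   each stability is the intended fraction of samples conforming.
#'   `NULL` plants nothing.
#' @param planted_stable_pairs_per_class Count of extra pairs planted with
#'   the SAME direction in both classes (at stability
#'   `stable_pair_stability`) — decoys that must survive mining but not
#'   reversal.
#' @param stable_pair_stability Stability used for those same-direction
#'   pairs.
#' @param n_de_genes Number of differentially expressed genes (chosen
#'   among genes not used by planted pairs; signs alternate up/down in
#'   case).
#' @param de_log_fold_change Absolute case-vs-control log2 fold change of
#'   DE genes.
#' @param n_correlated_modules,module_size,module_correlation Number,
#'   size and pairwise (log-scale) correlation of equicorrelated gene
#'   modules.
#' @param monotone_distortion List with `scale_range`, `shift_range`,
#'   `power_range` (each length-2): per-sample parameters of the monotone
#'   map `x -> a * x^c + b` drawn uniformly from these ranges. Use
#'   [no_distortion()] for the identity.
#' @param missing_rate Fraction of entries set to `NA`, completely at
#'   random, after everything else.
#' @param noise_sd Log-scale standard deviation of baseline expression.
#' @param rng_seed Integer seed governing all randomness.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 200,
                          n_samples_per_class = c(control = 100, case = 100),
                          planted_reversed_pairs = data.frame(
                            gene_i = 1L, gene_j = 2L,
                            stability_control = 0.95, stability_case = 0.95),
                          planted_stable_pairs_per_class = 0,
                          stable_pair_stability = 0.95,
                          n_de_genes = 0,
                          de_log_fold_change = 1,
                          n_correlated_modules = 0,
                          module_size = 10,
                          module_correlation = 0.8,
                          monotone_distortion = list(
                            scale_range = c(0.5, 2),
                            shift_range = c(0, 5),
                            power_range = c(0.8, 1.25)),
                          missing_rate = 0,
                          noise_sd = 0.5,
                          rng_seed = 1L) {
  cfg <- structure(list(
    n_genes = as.integer(n_genes),
    n_samples_per_class = stats::setNames(as.integer(n_samples_per_class),
                                          c("control", "case")),
    planted_reversed_pairs = planted_reversed_pairs,
    planted_stable_pairs_per_class = as.integer(planted_stable_pairs_per_class),
    stable_pair_stability = stable_pair_stability,
    n_de_genes = as.integer(n_de_genes),
    de_log_fold_change = de_log_fold_change,
    n_correlated_modules = as.integer(n_correlated_modules),
    module_size = as.integer(module_size),
    module_correlation = module_correlation,
    monotone_distortion = monotone_distortion,
    missing_rate = missing_rate,
    noise_sd = noise_sd,
    rng_seed = as.integer(rng_seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' Identity monotone distortion (a = 1, b = 0, c = 1 for every sample)
#' @return A distortion list usable in [cohort_config()].
#' @export
no_distortion <- function() {
  list(scale_range = c(1, 1), shift_range = c(0, 0), power_range = c(1, 1))
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 2, all(cfg$n_samples_per_class >= 1),
            cfg$noise_sd > 0,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            cfg$module_correlation > 0, cfg$module_correlation < 1,
            cfg$stable_pair_stability >= 0, cfg$stable_pair_stability <= 1)
  d <- cfg$monotone_distortion
  stopifnot(length(d$scale_range) == 2, length(d$shift_range) == 2,
            length(d$power_range) == 2,
            all(d$scale_range > 0), all(d$power_range > 0))
  pp <- cfg$planted_reversed_pairs
  if (!is.null(pp) && nrow(pp)) {
    stopifnot(all(c("gene_i", "gene_j", "stability_control", "stability_case")
                  %in% names(pp)))
    if (any(pp$gene_i == pp$gene_j)) {
      stop("planted pair genes must be distinct")
    }
    if (any(c(pp$gene_i, pp$gene_j) < 1) ||
        any(c(pp$gene_i, pp$gene_j) > cfg$n_genes)) {
      stop("planted pair gene index outside 1..n_genes")
    }
    if (anyDuplicated(c(pp$gene_i, pp$gene_j))) {
      stop("a gene may participate in at most one planted pair")
    }
    s <- c(pp$stability_control, pp$stability_case)
    if (any(s < 0 | s > 1)) stop("stabilities must lie in [0, 1]")
  }
  reserved <- if (is.null(pp)) 0L else 2L * nrow(pp)
  needed <- reserved + 2L * cfg$planted_stable_pairs_per_class +
    cfg$n_de_genes + cfg$n_correlated_modules * cfg$module_size
  if (needed > cfg$n_genes) {
    stop("planted structure needs ", needed, " distinct genes but n_genes = ",
         cfg$n_genes, "; planted pairs, DE genes and modules may not share genes ",
         "(a DE effect on a planted-pair gene could contradict its direction)")
  }
  invisible(cfg)
}

#' Generate a synthetic two-class cohort
#'
#' Baseline expression is log-normal per gene (gene means drawn uniformly
#' on the log scale, common log-sd `noise_sd`). Correlated modules share a
#' per-sample latent factor on the log scale. DE genes get a
#' `de_log_fold_change` shift (in log2 units, alternating sign) in case
#' samples. Reversed and same-direction stable pairs are then planted by
#' drawing, per sample, a Bernoulli "conforming" flag at the pair's
#' stability and swapping the two genes' values whenever the realised
#' ordering disagrees with the intended one — giving exact control of the
#' ordering frequency independent of the genes' marginals. The per-sample
#' monotone distortion `x -> a x^c + b` is applied after planting (it
#' preserves within-sample orderings by construction), and missingness is
#' applied last, completely at random.
#'
#' The same seed always yields a bit-identical cohort; the caller's RNG
#' state is untouched.
#'
#' @param config A [cohort_config()].
#' @return An object of class `reo_cohort`: list with `matrix`
#'   (gene-by-sample), `labels` (named character, `"control"`/`"case"`),
#'   `truth` (planted pairs with gene IDs, intended directions and
#'   stabilities), `truth_de` (gene, sign) and `truth_modules` (module,
#'   gene), plus the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  withr::with_seed(config$rng_seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n_ctrl <- cfg$n_samples_per_class[["control"]]
  n_case <- cfg$n_samples_per_class[["case"]]
  n <- n_ctrl + n_case
  width <- max(4L, nchar(cfg$n_genes))
  gene_ids <- sprintf(paste0("g%0", width, "d"), seq_len(cfg$n_genes))
  sample_ids <- c(sprintf("ctrl_%03d", seq_len(n_ctrl)),
                  sprintf("case_%03d", seq_len(n_case)))
  labels <- stats::setNames(rep(c("control", "case"), c(n_ctrl, n_case)),
                            sample_ids)
  is_case <- labels == "case"

  # assign gene roles: planted pairs first (fixed by config), then stable
  # decoy pairs, DE genes and modules from the remaining pool
  pp <- cfg$planted_reversed_pairs
  pair_idx <- if (is.null(pp)) integer(0) else c(rbind(pp$gene_i, pp$gene_j))
  pool <- setdiff(seq_len(cfg$n_genes), pair_idx)
  take <- function(k) {
    if (k == 0L) return(integer(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  stable_idx <- take(2L * cfg$planted_stable_pairs_per_class)
  de_idx <- take(cfg$n_de_genes)
  module_idx <- take(cfg$n_correlated_modules * cfg$module_size)

  meanlog <- stats::runif(cfg$n_genes, log(50), log(5000))
  # pair genes share a baseline mean: the ordering-enforcing swap then leaves
  # both marginals near-identical (no collateral stable pairs against genes of
  # intermediate abundance) and keeps the pair's fold change near 1, the
  # regime where qualitative reversal carries signal a quantitative cutoff
  # would miss
  if (!is.null(pp) && nrow(pp)) meanlog[pp$gene_j] <- meanlog[pp$gene_i]
  if (cfg$planted_stable_pairs_per_class > 0) {
    even <- seq_len(cfg$planted_stable_pairs_per_class) * 2L
    meanlog[stable_idx[even]] <- meanlog[stable_idx[even - 1L]]
  }
  logx <- matrix(stats::rnorm(cfg$n_genes * n, sd = cfg$noise_sd),
                 cfg$n_genes, n) + meanlog

  truth_modules <- NULL
  if (cfg$n_correlated_modules > 0) {
    rho <- cfg$module_correlation
    for (m in seq_len(cfg$n_correlated_modules)) {
      idx <- module_idx[(m - 1L) * cfg$module_size + seq_len(cfg$module_size)]
      latent <- stats::rnorm(n)
      eps <- matrix(stats::rnorm(length(idx) * n), length(idx), n)
      logx[idx, ] <- meanlog[idx] + cfg$noise_sd *
        (sqrt(rho) * matrix(latent, length(idx), n, byrow = TRUE) +
           sqrt(1 - rho) * eps)
    }
    truth_modules <- data.frame(
      module = rep(seq_len(cfg$n_correlated_modules), each = cfg$module_size),
      gene = gene_ids[module_idx], stringsAsFactors = FALSE)
  }

  truth_de <- NULL
  if (cfg$n_de_genes > 0) {
    signs <- rep_len(c(1, -1), cfg$n_de_genes)
    logx[de_idx, is_case] <- logx[de_idx, is_case] +
      signs * cfg$de_log_fold_change * log(2)
    truth_de <- data.frame(gene = gene_ids[de_idx], sign = signs,
                           stringsAsFactors = FALSE)
  }

  x <- exp(logx)
  dimnames(x) <- list(gene_ids, sample_ids)

  # plant orderings by conditional swapping: intended control direction is
  # E_i > E_j, intended case direction E_i < E_j (reversed pairs); decoy
  # stable pairs keep E_a > E_b in both classes
  plant <- function(x, i, j, stab_ctrl, stab_case, reverse_in_case) {
    conform <- stats::rbinom(n, 1L, ifelse(is_case, stab_case, stab_ctrl)) == 1L
    want_i_gt_j <- if (reverse_in_case) conform != is_case else conform
    # non-conforming samples get the opposite ordering enforced
    swap <- (x[i, ] > x[j, ]) != want_i_gt_j
    tmp <- x[i, swap]
    x[i, swap] <- x[j, swap]
    x[j, swap] <- tmp
    x
  }

  truth_pairs <- NULL
  if (!is.null(pp) && nrow(pp)) {
    for (k in seq_len(nrow(pp))) {
      x <- plant(x, pp$gene_i[k], pp$gene_j[k],
                 pp$stability_control[k], pp$stability_case[k],
                 reverse_in_case = TRUE)
    }
    truth_pairs <- data.frame(
      gene_i = gene_ids[pp$gene_i], gene_j = gene_ids[pp$gene_j],
      type = "reversed",
      stability_control = pp$stability_control,
      stability_case = pp$stability_case,
      direction_control = "i_gt_j", direction_case = "i_lt_j",
      stringsAsFactors = FALSE)
  }
  if (cfg$planted_stable_pairs_per_class > 0) {
    for (k in seq_len(cfg$planted_stable_pairs_per_class)) {
      i <- stable_idx[2L * k - 1L]
      j <- stable_idx[2L * k]
      x <- plant(x, i, j, cfg$stable_pair_stability, cfg$stable_pair_stability,
                 reverse_in_case = FALSE)
      truth_pairs <- rbind(truth_pairs, data.frame(
        gene_i = gene_ids[i], gene_j = gene_ids[j], type = "stable",
        stability_control = cfg$stable_pair_stability,
        stability_case = cfg$stable_pair_stability,
        direction_control = "i_gt_j", direction_case = "i_gt_j",
        stringsAsFactors = FALSE))
    }
  }

  x <- apply_monotone_distortion(x, cfg$monotone_distortion)

  if (cfg$missing_rate > 0) {
    x[stats::runif(length(x)) < cfg$missing_rate] <- NA_real_
  }

  structure(list(
    matrix = x,
    labels = labels,
    truth = truth_pairs,
    truth_de = truth_de,
    truth_modules = truth_modules,
    config = cfg
  ), class = "reo_cohort")
}

#' @export
print.reo_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d genes x %d samples (%d control, %d case)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$labels == "control"), sum(x$labels == "case")))
  cat(sprintf("  planted pairs: %d reversed, %d stable; DE genes: %d; modules: %d\n",
              sum(x$truth$type == "reversed"), sum(x$truth$type == "stable"),
              NROW(x$truth_de), length(unique(x$truth_modules$module))))
  invisible(x)
}

#' Apply a random per-sample monotone distortion
#'
#' Transforms each sample (column) by `x -> a * x^c + b` with per-sample
#' `a`, `b`, `c` drawn uniformly from the configured ranges (`a, c > 0`;
#' `b` is raised if necessary so all outputs stay strictly positive). The
#' map is strictly increasing on positive values, so within-sample ranks
#' — and hence every REO statistic — are unchanged. Draws come from the
#' caller's RNG stream.
#'
#' @param mat Strictly positive gene-by-sample matrix (`NA` allowed).
#' @param distortion List with `scale_range`, `shift_range`,
#'   `power_range` (see [cohort_config()]), or a full `cohort_config`.
#' @return Distorted matrix, same dimensions and dimnames.
#' @export
apply_monotone_distortion <- function(mat, distortion = cohort_config()$monotone_distortion) {
  if (inherits(distortion, "cohort_config")) {
    distortion <- distortion$monotone_distortion
  }
  if (any(mat <= 0, na.rm = TRUE)) {
    stop("monotone distortion x -> a*x^c + b requires strictly positive values")
  }
  ns <- ncol(mat)
  a <- stats::runif(ns, distortion$scale_range[1], distortion$scale_range[2])
  b <- stats::runif(ns, distortion$shift_range[1], distortion$shift_range[2])
  c_ <- stats::runif(ns, distortion$power_range[1], distortion$power_range[2])
  out <- mat
  for (s in seq_len(ns)) {
    v <- a[s] * mat[, s] ^ c_[s] + b[s]
    lo <- suppressWarnings(min(v, na.rm = TRUE))
    if (is.finite(lo) && lo <= 0) v <- v - lo + .Machine$double.eps
    out[, s] <- v
  }
  out
}

#' Write a cohort to disk
#'
#' Emits `matrix.tsv` (genes x samples), `labels.tsv` (sample_id, class)
#' and `truth.json` (planted pairs, DE genes, modules) under `dir`.
#'
#' @param cohort A `reo_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "reo_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(cohort$matrix, file.path(dir, "matrix.tsv"))
  write_labels(cohort$labels, file.path(dir, "labels.tsv"))
  jsonlite::write_json(
    list(pairs = cohort$truth, de = cohort$truth_de,
         modules = cohort$truth_modules),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null")
  invisible(dir)
}

#' Read / write a cohort configuration as YAML
#'
#' Flat key/value file with a nested `monotone_distortion` block and a
#' `planted_reversed_pairs` list.
#'
#' @param path Path to the YAML file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$planted_reversed_pairs)) {
    y$planted_reversed_pairs <-
      do.call(rbind, lapply(y$planted_reversed_pairs, as.data.frame))
  }
  do.call(cohort_config, y)
}

#' @rdname read_cohort_config
#' @param config A `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  y <- unclass(config)
  y$n_samples_per_class <- as.list(y$n_samples_per_class)
  if (!is.null(y$planted_reversed_pairs)) {
    y$planted_reversed_pairs <- lapply(
      seq_len(nrow(y$planted_reversed_pairs)),
      function(k) as.list(y$planted_reversed_pairs[k, ]))
  }
  yaml::write_yaml(y, path)
  invisible(path)
}
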