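#' Run the signature-discovery stage
#'
#' Orchestrates the discovery flow on a training cohort: optional probe
#' collapsing, stable-pair mining per class, reversal intersection,
#' gene-set restriction and orientation. Writes the signature JSON, the
#' two per-class stable-pair TSVs and a run manifest into `out_dir`.
#'
#' @param mat Gene-by-sample matrix, or a path to a matrix TSV.
#' @param labels Named label vector, or a path to a labels TSV.
#' @param gene_set Gene-ID vector, gene-set collection, or path to a GMT
#'   file (union of sets used). `NULL` mines all genes.
#' @param out_dir Output directory (created if needed).
#' @param threshold Stability threshold.
#' @param case_label,control_label Class labels.
#' @param probe_annotation Optional probe-to-gene data frame (or path to
#'   a two-column TSV); when given, the matrix is collapsed first.
#' @return The discovered `reo_signature`, invisibly; output paths in
#'   attribute `"paths"`.
#' @export
run_discovery <- function(mat, labels, gene_set = NULL, out_dir,
                          threshold = 0.85, case_label = "case",
                          control_label = "control",
                          probe_annotation = NULL) {
  inputs <- list()
  if (is.character(mat) && length(mat) == 1L) {
    inputs$matrix <- mat
    mat <- read_matrix(mat)
  }
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    inputs$labels <- labels
    labels <- read_labels(labels)
  }
  if (is.character(gene_set) && length(gene_set) == 1L && file.exists(gene_set)) {
    inputs$gene_set <- gene_set
    gene_set <- read_gmt(gene_set)
  }
  if (!is.null(probe_annotation)) {
    if (is.character(probe_annotation)) {
      inputs$probe_annotation <- probe_annotation
      probe_annotation <- utils::read.delim(probe_annotation,
                                            colClasses = "character")
    }
    mat <- collapse_probes(mat, probe_annotation)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sig <- discover_signature(mat, labels, gene_set, threshold,
                            case_label, control_label)
  sets <- sig$stable_sets
  paths <- c(signature = file.path(out_dir, "signature.json"),
             stable_control = file.path(out_dir, "stable_pairs_control.tsv"),
             stable_case = file.path(out_dir, "stable_pairs_case.tsv"))
  write_signature(sig, paths[["signature"]])
  write_stable_pairs(sets$control, paths[["stable_control"]])
  write_stable_pairs(sets$case, paths[["stable_case"]])
  write_manifest(out_dir, "discovery", inputs,
                 params = list(threshold = threshold,
                               case_label = case_label,
                               control_label = control_label,
                               n_pairs = nrow(sig$pairs)),
                 outputs = paths)
  message(sprintf(
    "discovery: %d genes mined, %d/%d stable pairs (control/case), %d reversed, %d in signature",
    sig$provenance$n_genes_mined, sig$provenance$n_stable_control,
    sig$provenance$n_stable_case, sig$provenance$n_reversed, nrow(sig$pairs)))
  if (nrow(sig$pairs) == 0L) message("discovery: no signature found")
  attr(sig, "paths") <- paths
  invisible(sig)
}

#' Run the validation stage
#'
#' Classifies every sample of a cohort with a discovered (or manually
#' built) signature and writes predictions, evaluation metrics (binary
#' and score-based AUC side by side) and a manifest.
#'
#' @param signature A `reo_signature` or path to a signature JSON.
#' @param mat Gene-by-sample matrix, or a path to a matrix TSV.
#' @param labels Named label vector, or path to a labels TSV.
#' @param out_dir Output directory.
#' @return List with `predictions` (data frame) and `metrics` (list),
#'   invisibly.
#' @export
run_validate <- function(signature, mat, labels, out_dir) {
  inputs <- list()
  if (is.character(signature) && length(signature) == 1L) {
    inputs$signature <- signature
    signature <- read_signature(signature)
  }
  if (is.character(mat) && length(mat) == 1L) {
    inputs$matrix <- mat
    mat <- read_matrix(mat)
  }
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    inputs$labels <- labels
    labels <- read_labels(labels)
  }
  if (ncol(mat) == 0L) stop("empty cohort: no samples to validate")
  labels <- match_labels(mat, labels)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pred <- classify_samples(mat, signature)
  cm <- confusion_metrics(pred$label, labels,
                          positive_label = signature$case_label,
                          negative_label = signature$control_label)
  score_roc <- roc_auc(pred$score, labels, signature$case_label)
  binary_roc <- roc_auc(as.numeric(pred$label == signature$case_label),
                        labels, signature$case_label)
  fc <- fold_change_summary(mat, signature$pairs$low_in_case[1L],
                            signature$pairs$high_in_case[1L], labels)
  metrics <- list(
    confusion = unclass(cm),
    auc_binary = binary_roc$auc,
    auc_binary_ci95 = binary_roc$ci95,
    auc_score = score_roc$auc,
    auc_score_ci95 = score_roc$ci95,
    fold_change_first_pair = fc
  )
  paths <- c(predictions = file.path(out_dir, "predictions.tsv"),
             metrics = file.path(out_dir, "metrics.json"))
  utils::write.table(pred, paths[["predictions"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(metrics, paths[["metrics"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_manifest(out_dir, "validate", inputs,
                 params = list(case_label = signature$case_label,
                               control_label = signature$control_label,
                               n_pairs = nrow(signature$pairs)),
                 outputs = paths)
  message(sprintf(
    "validate: n = %d, sensitivity %.2f%%, specificity %.2f%%, accuracy %.2f%%, AUC (score) %.4f",
    cm$n, 100 * cm$sensitivity, 100 * cm$specificity, 100 * cm$accuracy,
    score_roc$auc))
  invisible(list(predictions = pred, metrics = metrics))
}

#' Run the characterization stage
#'
#' Downstream biology on a labelled cohort: ssGSEA immune scores with
#' one-sided class comparisons, Wilcoxon/BH differential expression,
#' gene-vs-cell Spearman correlations, a seed-gene co-expression network
#' and hypergeometric over-representation of the significant genes.
#'
#' @param mat Gene-by-sample matrix, or a path to a matrix TSV.
#' @param labels Named label vector, or path to a labels TSV.
#' @param immune_sets Gene-set collection (or GMT path) for ssGSEA.
#' @param out_dir Output directory.
#' @param signature Optional `reo_signature` (or JSON path); its genes
#'   become correlation/network seeds.
#' @param seed_genes Network seed genes (default: the signature's genes,
#'   if any).
#' @param inflammation_sets Optional gene-set collection (or GMT path)
#'   used to tag significant genes with inflammation categories.
#' @param enrichment_sets Gene sets for over-representation of the
#'   significant DEGs (default: `immune_sets`).
#' @param case_label,control_label Class labels.
#' @param fdr_cutoff DEG significance cutoff.
#' @param rho_cutoff,network_fdr_cutoff Network thresholds.
#' @return List with the computed tables, invisibly.
#' @export
run_characterize <- function(mat, labels, immune_sets, out_dir,
                             signature = NULL, seed_genes = NULL,
                             inflammation_sets = NULL,
                             enrichment_sets = NULL,
                             case_label = "case", control_label = "control",
                             fdr_cutoff = 0.01, rho_cutoff = 0.6,
                             network_fdr_cutoff = 0.01) {
  inputs <- list()
  if (is.character(mat) && length(mat) == 1L) {
    inputs$matrix <- mat
    mat <- read_matrix(mat)
  }
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    inputs$labels <- labels
    labels <- read_labels(labels)
  }
  if (is.character(immune_sets)) {
    inputs$immune_sets <- immune_sets
    immune_sets <- read_gmt(immune_sets)
  }
  if (is.character(signature) && length(signature) == 1L) {
    inputs$signature <- signature
    signature <- read_signature(signature)
  }
  if (is.character(inflammation_sets)) {
    inputs$inflammation_sets <- inflammation_sets
    inflammation_sets <- read_gmt(inflammation_sets)
  }
  if (is.null(enrichment_sets)) enrichment_sets <- immune_sets
  labels <- match_labels(mat, labels)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  scores <- ssgsea_scores(mat, immune_sets)
  comparisons <- do.call(rbind, lapply(rownames(scores), function(nm) {
    r <- compare_feature_by_class(scores[nm, ], labels,
                                  direction = "case_gt_control",
                                  case_label, control_label)
    data.frame(set = nm, statistic = r$statistic, p_value = r$p_value,
               direction = "case_gt_control", stringsAsFactors = FALSE)
  }))
  comparisons$fdr <- stats::p.adjust(comparisons$p_value, method = "BH")

  deg <- wilcoxon_deg(mat, labels, case_label, control_label, fdr_cutoff)
  sig_genes <- deg$gene[deg$significant]

  if (is.null(seed_genes) && !is.null(signature)) {
    seed_genes <- unique(c(signature$pairs$low_in_case,
                           signature$pairs$high_in_case))
  }
  network <- NULL
  correlations <- NULL
  if (!is.null(seed_genes) && length(seed_genes)) {
    candidates <- setdiff(rownames(mat), seed_genes)
    network <- coexpression_network(mat, seed_genes, candidates,
                                    rho_cutoff, network_fdr_cutoff)
    correlations <- gene_cell_correlations(mat, seed_genes, scores)
  }

  enrichment <- NULL
  if (length(sig_genes)) {
    enrichment <- tryCatch(
      hypergeom_enrich(sig_genes, enrichment_sets, rownames(mat)),
      error = function(e) NULL)
  }
  localized <- NULL
  if (!is.null(inflammation_sets) && length(sig_genes)) {
    localized <- localize_inflammation_genes(
      deg[deg$significant, , drop = FALSE], inflammation_sets)
  }

  paths <- c(ssgsea = file.path(out_dir, "ssgsea_scores.tsv"),
             comparisons = file.path(out_dir, "class_comparisons.tsv"),
             deg = file.path(out_dir, "deg.tsv"))
  utils::write.table(data.frame(set = rownames(scores), scores,
                                check.names = FALSE),
                     paths[["ssgsea"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(comparisons, paths[["comparisons"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(deg), paths[["deg"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(network)) {
    paths[["network"]] <- file.path(out_dir, "network_edges.tsv")
    utils::write.table(as.data.frame(network), paths[["network"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths[["correlations"]] <- file.path(out_dir, "gene_cell_correlations.tsv")
    utils::write.table(correlations, paths[["correlations"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(enrichment)) {
    paths[["enrichment"]] <- file.path(out_dir, "enrichment.tsv")
    utils::write.table(enrichment, paths[["enrichment"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(localized)) {
    paths[["inflammation"]] <- file.path(out_dir, "inflammation_genes.tsv")
    utils::write.table(localized, paths[["inflammation"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(out_dir, "characterize", inputs,
                 params = list(fdr_cutoff = fdr_cutoff,
                               rho_cutoff = rho_cutoff,
                               network_fdr_cutoff = network_fdr_cutoff,
                               n_deg = sum(deg$significant),
                               n_edges = NROW(network)),
                 outputs = paths)
  message(sprintf("characterize: %d significant DEGs, %d network edges, %d immune sets scored",
                  sum(deg$significant), NROW(network), nrow(scores)))
  invisible(list(ssgsea = scores, comparisons = comparisons, deg = deg,
                 network = network, correlations = correlations,
                 enrichment = enrichment, inflammation = localized))
}

# Run manifest: config snapshot, input/output digests, timestamps. The
# manifest itself is the only stage output containing a timestamp, so all
# analytic outputs of a rerun are byte-identical.
write_manifest <- function(out_dir, stage, inputs, params, outputs) {
  digest <- function(paths) {
    paths <- unlist(paths)
    if (length(paths) == 0L) return(NULL)
    as.list(tools::md5sum(paths))
  }
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("reosig")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    inputs = digest(inputs),
    outputs = digest(outputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
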