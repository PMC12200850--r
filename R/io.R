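#' Read a gene-by-sample expression matrix
#'
#' Reads a tab-delimited expression matrix with genes in rows (column 1 =
#' gene or probe identifier, row 1 = sample identifiers). Two dialects are
#' supported: plain TSV, and the GEO series-matrix dialect in which the
#' numeric table is wrapped in a `!series_matrix_table_begin` /
#' `!series_matrix_table_end` envelope, identifiers may be double-quoted,
#' and all other `!`-prefixed metadata lines are ignored.
#'
#' Empty cells, `NA` and `null` are read as missing values. No
#' normalization or log transform is ever applied: downstream
#' relative-ordering statistics are invariant to monotone per-sample
#' transforms, so values are used exactly as stored.
#'
#' @param path Path to the file.
#' @param dialect `"plain_tsv"` or `"geo_series_matrix"`.
#' @return A numeric matrix with gene IDs as rownames and sample IDs as
#'   colnames. Missing values are `NA`.
#' @seealso [write_matrix()], [collapse_probes()]
#' @export
read_matrix <- function(path, dialect = c("plain_tsv", "geo_series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  offset <- 0L
  if (dialect == "geo_series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
      stop("malformed series-matrix envelope in ", path)
    }
    offset <- begin
    lines <- lines[(begin + 1L):(end - 1L)]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("matrix file has no data rows: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "geo_series_matrix") {
    cells <- lapply(cells, function(x) gsub('^"|"$', "", x))
  }
  ncol_expected <- length(cells[[1L]])
  widths <- lengths(cells)
  if (any(widths != ncol_expected)) {
    bad <- which(widths != ncol_expected)[1L]
    stop("ragged row at line ", bad + offset, " of ", path,
         " (expected ", ncol_expected, " fields, found ", widths[bad], ")")
  }
  sample_ids <- cells[[1L]][-1L]
  gene_ids <- vapply(cells[-1L], `[[`, character(1), 1L)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene IDs in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  body <- vapply(cells[-1L], function(x) x[-1L], character(length(sample_ids)))
  body <- if (is.matrix(body)) t(body) else matrix(body, ncol = length(sample_ids))
  body[body %in% c("", "NA", "null")] <- NA_character_
  suppressWarnings(values <- as.numeric(body))
  bad <- !is.na(body) & is.na(values)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at data row ", idx[1L], " (gene ", gene_ids[idx[1L]],
         "), column ", idx[2L], " of ", path, ": '", body[bad][1L], "'")
  }
  mat <- matrix(values, nrow = length(gene_ids),
                dimnames = list(gene_ids, sample_ids))
  mat
}

#' Write an expression matrix as plain TSV
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param id_header Label for the top-left header cell.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, id_header = "gene_id") {
  check_expression_matrix(mat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_header, colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 2L, format_number)
  if (!is.matrix(body)) body <- matrix(body, nrow = nrow(mat))
  writeLines(paste(rownames(mat), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

format_number <- function(x) {
  out <- formatC(x, format = "g", digits = 15)
  out[is.na(x)] <- "NA"
  out
}

#' Read / write per-sample class labels
#'
#' Labels are stored as a two-column TSV (`sample_id`, `class`) with a
#' header line.
#'
#' @param path Path to the labels file.
#' @return A named character vector: values are class labels, names are
#'   sample IDs.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L) stop("labels file needs columns sample_id, class: ", path)
  if (anyDuplicated(df[[1L]])) stop("duplicate sample IDs in ", path)
  stats::setNames(df[[2L]], df[[1L]])
}

#' @rdname read_labels
#' @param labels Named character vector of class labels (names = sample IDs).
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), class = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse a probe-level matrix to gene level
#'
#' Probes mapping to zero genes or to two or more genes are eliminated.
#' For each gene, the expression value per sample is the arithmetic mean
#' over its surviving probes; missing probe values are excluded from the
#' mean (a gene value is `NA` only when every probe is missing in that
#' sample). Output genes are sorted by gene ID so the result is
#' deterministic; sample order is preserved.
#'
#' @param mat Probe-by-sample numeric matrix (probe IDs as rownames).
#' @param annotation A data frame with columns `probe_id` and `gene_id`;
#'   one row per (probe, gene) mapping, so multi-mapping probes occupy
#'   several rows. Probes absent from the annotation are treated as
#'   unmapped and dropped.
#' @return Gene-by-sample numeric matrix.
#' @export
collapse_probes <- function(mat, annotation) {
  check_expression_matrix(mat)
  if (!all(c("probe_id", "gene_id") %in% names(annotation))) {
    stop("annotation must have columns probe_id and gene_id")
  }
  annotation <- unique(annotation[, c("probe_id", "gene_id")])
  n_genes <- table(annotation$probe_id)
  single <- names(n_genes)[n_genes == 1L]
  keep <- annotation[annotation$probe_id %in% single &
                       annotation$probe_id %in% rownames(mat), , drop = FALSE]
  if (nrow(keep) == 0L) {
    stop("no probe maps to exactly one gene; nothing survives collapsing")
  }
  sub <- mat[keep$probe_id, , drop = FALSE]
  gene <- factor(keep$gene_id, levels = sort(unique(keep$gene_id)))
  out <- apply(sub, 2L, function(col) {
    tapply(col, gene, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else mean(v)
    })
  })
  if (!is.matrix(out)) out <- matrix(out, nrow = nlevels(gene))
  dimnames(out) <- list(levels(gene), colnames(mat))
  out
}

#' Read a GMT gene-set file
#'
#' Each line is `set_name <TAB> description <TAB> member1 <TAB> member2 ...`.
#' Member order is preserved; duplicate members within a set are removed.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (gene IDs), with the per-set
#'   descriptions in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) stop("GMT line ", which(short)[1L], " has fewer than 3 fields")
  set_names <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(set_names)) {
    stop("duplicate gene-set names: ",
         paste(unique(set_names[duplicated(set_names)]), collapse = ", "))
  }
  sets <- lapply(fields, function(x) unique(x[-(1:2)]))
  names(sets) <- set_names
  attr(sets, "description") <- stats::setNames(
    vapply(fields, `[[`, character(1), 2L), set_names)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set must be named")
  }
  if (is.null(description)) {
    description <- attr(sets, "description")
    if (is.null(description)) description <- rep("na", length(sets))
  }
  writeLines(mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), description, sets), path)
  invisible(path)
}

check_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("expression matrix must be a numeric matrix")
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate gene IDs")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample IDs")
  invisible(mat)
}

match_labels <- function(mat, labels) {
  if (is.null(names(labels))) {
    if (length(labels) != ncol(mat)) {
      stop("unnamed labels must have one entry per sample")
    }
    names(labels) <- colnames(mat)
  }
  missing <- setdiff(colnames(mat), names(labels))
  if (length(missing)) {
    stop("no class label for samples: ", paste(missing, collapse = ", "))
  }
  labels[colnames(mat)]
}
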