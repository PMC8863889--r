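# Readers/writers for the tabular artifacts (gene x cell-line matrices,
# annotations, pair lists, gene sets) and dataset alignment.

#' Read a gene-by-cell-line matrix from CSV
#'
#' Parses a numeric panel such as a CERES-style dependency matrix or a
#' log2(TPM+1) expression matrix.  The first column holds row identifiers and
#' the header holds column identifiers.  Whether rows are genes or cell lines
#' is auto-detected from the header corner token (`gene`/`symbol` versus
#' `cell_line`/`depmap_id`/`cell`) and can be forced with `orientation`;
#' matrices are always returned with genes in rows.
#'
#' @param path CSV file (optionally gzip-compressed).
#' @param kind `"dependency"` or `"expression"`.  Expression values are
#'   validated to be non-negative after missing-value handling.
#' @param orientation `"auto"`, `"genes_in_rows"` or `"cells_in_rows"`.
#' @return A numeric matrix, genes in rows, cell lines in columns, with a
#'   `kind` attribute.  Cells that failed numeric parsing become `NA` and are
#'   reported via warning.
#' @export
read_matrix <- function(path, kind = c("dependency", "expression"),
                        orientation = c("auto", "genes_in_rows", "cells_in_rows")) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  raw <- read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("empty matrix in ", path)
  }
  ids <- as.character(raw[[1L]])
  corner <- tolower(names(raw)[1L])
  body <- raw[, -1L, drop = FALSE]
  n_bad <- 0L
  vals <- vapply(body, function(col) {
    if (is.numeric(col)) return(as.numeric(col))
    suppressWarnings(as.numeric(col))
  }, numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, names(body)))
  introduced <- is.na(vals) & !vapply(body, function(col) is.na(col),
                                      logical(nrow(raw)))
  if (any(introduced)) {
    bad_rows <- unique(ids[which(introduced, arr.ind = TRUE)[, 1L]])
    warning(sum(introduced), " unparseable numeric cell(s) set to NA in rows: ",
            paste(head(bad_rows, 5L), collapse = ", "),
            if (length(bad_rows) > 5L) ", ...")
  }
  if (orientation == "auto") {
    orientation <- if (corner %in% c("cell_line", "cellline", "cell", "depmap_id",
                                     "line", "cell_lines"))
      "cells_in_rows" else "genes_in_rows"
  }
  if (orientation == "cells_in_rows") vals <- t(vals)
  .check_unique_ids(rownames(vals), "gene")
  .check_unique_ids(colnames(vals), "cell line")
  attr(vals, "kind") <- kind
  vals
}

.check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicated ", what, " identifier(s): ",
         paste(head(dup, 5L), collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a gene-by-cell-line matrix to CSV
#'
#' Inverse of [read_matrix()]; round-trips values exactly (full double
#' precision).
#'
#' @param x numeric matrix with gene rownames and cell-line colnames.
#' @param path output CSV path (".gz" suffix writes gzip).
#' @export
write_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell-line annotation table
#'
#' @param path CSV/TSV with columns `cell_line` and `tissue_type`
#'   (separator sniffed from the header line).
#' @return data.frame with `cell_line` and `tissue_type` character columns.
#' @export
read_cell_annotation <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  ann <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  need <- c("cell_line", "tissue_type")
  if (!all(need %in% names(ann))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  .check_unique_ids(ann$cell_line, "cell line")
  ann[need]
}

#' Align dependency, expression and annotation on shared cell lines
#'
#' Restricts all three inputs to the intersection of their cell lines, in
#' lexicographic order (a deterministic order keeps permutation seeds and
#' golden files stable).  Dependency genes with a missing score in any
#' retained cell line are dropped and reported; missing expression values are
#' floored to 0 (the log2(TPM+1) floor) with a warning.
#'
#' @param dependency,expression numeric gene x cell-line matrices.
#' @param annotation data.frame with `cell_line`, `tissue_type`.
#' @return An object of class `cebu_data`: list with `dependency`,
#'   `expression`, `annotation` (cell-line order identical across all three)
#'   and `dropped_genes`.
#' @export
align_datasets <- function(dependency, expression, annotation) {
  stopifnot(is.matrix(dependency), is.matrix(expression))
  cells <- sort(intersect(intersect(colnames(dependency), colnames(expression)),
                          annotation$cell_line))
  if (length(cells) == 0L) {
    stop("no cell lines shared by dependency, expression and annotation")
  }
  dep <- dependency[, cells, drop = FALSE]
  expr <- expression[, cells, drop = FALSE]
  keep <- complete.cases(dep)
  dropped <- rownames(dep)[!keep]
  dep <- dep[keep, , drop = FALSE]
  if (anyNA(expr)) {
    warning(sum(is.na(expr)), " missing expression value(s) floored to 0")
    expr[is.na(expr)] <- 0
  }
  if (any(expr < 0)) {
    stop("expression matrix contains negative values; expected log2(TPM+1)")
  }
  ann <- annotation[match(cells, annotation$cell_line), , drop = FALSE]
  rownames(ann) <- NULL
  structure(list(dependency = dep, expression = expr, annotation = ann,
                 dropped_genes = dropped),
            class = "cebu_data")
}

#' @export
print.cebu_data <- function(x, ...) {
  cat("Aligned dependency/expression panel\n")
  cat(sprintf("  dependency: %d genes, expression: %d genes, %d cell lines\n",
              nrow(x$dependency), nrow(x$expression), ncol(x$dependency)))
  cat(sprintf("  tissues: %d; dropped dependency genes: %d\n",
              length(unique(x$annotation$tissue_type)),
              length(x$dropped_genes)))
  invisible(x)
}

#' Read a gene-pair table
#'
#' @param path TSV file.  Required columns: `gene_a`, `gene_b`; kind `"gi"`
#'   additionally requires `cell_line` and `score`.
#' @param kind `"duplicated"`, `"annotation"`, `"ppi"` (all treated as
#'   unordered pairs) or `"gi"` (ordered rows with a per-cell-line score).
#' @return data.frame of pairs with a `kind` attribute.  For unordered kinds
#'   a `key` column holds the symmetric pair key used by [pairs_contain()].
#' @export
read_pair_table <- function(path, kind = c("duplicated", "annotation", "ppi", "gi")) {
  kind <- match.arg(kind)
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", if (kind == "gi") c("cell_line", "score"))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("pair table missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (kind == "gi") df$score <- as.numeric(df$score)
  if (kind != "gi") df$key <- pair_key(df$gene_a, df$gene_b)
  attr(df, "kind") <- kind
  df
}

#' Symmetric pair key
#'
#' `pair_key(a, b) == pair_key(b, a)`; used for unordered membership queries
#' on annotation-style pair lists.
#' @param a,b character vectors of gene symbols.
#' @export
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Unordered pair membership
#' @param pairs data.frame from [read_pair_table()] (non-`gi` kind) or any
#'   data.frame with `gene_a`/`gene_b`.
#' @param a,b gene symbols (vectorized).
#' @return logical vector.
#' @export
pairs_contain <- function(pairs, a, b) {
  keys <- if (!is.null(pairs$key)) pairs$key else pair_key(pairs$gene_a, pairs$gene_b)
  pair_key(a, b) %in% keys
}

#' Write a gene-pair table to TSV
#' @param pairs data.frame.
#' @param path output path.
#' @export
write_pair_table <- function(pairs, path) {
  pairs$key <- NULL
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(pairs, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, `name<TAB>description<TAB>gene...`.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) character(0) else unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  sets
}
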