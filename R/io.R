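# Readers and writers for the plain-text interchange formats: counts as
# TSV (genes in rows) or MatrixMarket, sample metadata CSV, GMT gene
# sets, ground-truth JSON.

#' Write / read a count matrix as TSV
#'
#' Genes in rows (first column `gene`), one column per sample.
#'
#' @param counts integer matrix or `count_matrix`.
#' @param path file path.
#' @return `read_counts_tsv()` returns an integer matrix with gene
#'   rownames and sample colnames.
#' @export
write_counts_tsv <- function(counts, path) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  df <- tibble::as_tibble(counts, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(df)[1] != "gene") {
    abort_sc("first column of a counts TSV must be 'gene'", "sc_parse_error")
  }
  m <- as.matrix(df[-1])
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene
  m
}

#' Write / read a count matrix as MatrixMarket
#'
#' Writes `<stem>.mtx` plus `<stem>.rows.txt` / `<stem>.cols.txt` index
#' files with the gene and sample identifiers.
#'
#' @param counts integer matrix or `count_matrix`.
#' @param stem path stem (without extension).
#' @return `read_counts_mtx()` returns a dense integer matrix.
#' @export
write_counts_mtx <- function(counts, stem) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  paste0(stem, ".mtx"))
  writeLines(rownames(counts), paste0(stem, ".rows.txt"))
  writeLines(colnames(counts), paste0(stem, ".cols.txt"))
  invisible(stem)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(stem) {
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  storage.mode(m) <- "integer"
  rownames(m) <- readLines(paste0(stem, ".rows.txt"))
  colnames(m) <- readLines(paste0(stem, ".cols.txt"))
  m
}

#' Read GMT gene-set files
#'
#' Thin wrapper over `fgsea::gmtPathways()` (set name, description,
#' tab-separated genes per line).
#'
#' @param path GMT file path.
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    abort_sc("reading GMT requires the fgsea package", "sc_missing_dep")
  }
  fgsea::gmtPathways(path)
}

#' Write GMT gene-set files
#'
#' @param sets named list of character gene vectors.
#' @param path output path.
#' @param description per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- mapply(function(nm, genes, desc) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), sets, rep_len(description, length(sets)))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Serialize ground truth to JSON
#'
#' @param truth a `ground_truth` from [simulate_counts()].
#' @param path output path.
#' @return `read_ground_truth()` rebuilds the `ground_truth` object.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(list(
    module_of_gene = as.list(truth$module_of_gene),
    de_genes_per_contrast = lapply(truth$de_genes_per_contrast, function(d)
      list(gene = d$gene, sign = d$sign)),
    susceptibility_module = truth$susceptibility_module,
    resilience_module = truth$resilience_module
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    module_of_gene = unlist(x$module_of_gene),
    de_genes_per_contrast = lapply(x$de_genes_per_contrast, function(d)
      tibble::tibble(gene = as.character(d$gene), sign = as.numeric(d$sign))),
    susceptibility_module = x$susceptibility_module,
    resilience_module = x$resilience_module
  ), class = "ground_truth")
}
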