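#' Load a domain from disk
#'
#' Reads a cells x genes matrix in Matrix Market (`mtx`, with `genes.tsv` /
#' `barcodes.tsv` sidecars in the same directory) or dense delimited
#' (`csv`/`tsv`) format and returns a validated [DomainDataset-class].
#' The on-disk orientation is normalized: MTX files written genes x cells
#' (the common CellRanger layout, detected from the sidecar lengths) are
#' transposed to cells x genes.
#'
#' The dense dialect is: first row gene ids, first column cell ids. A label
#' file, when given, is a two-column table (cell id, label) with or without a
#' header, and must cover every cell in the matrix.
#'
#' @param path path to the `.mtx` or delimited matrix file.
#' @param format one of `"mtx"`, `"csv"`, `"tsv"`. `"h5ad"` is recognised but
#'   not supported by this implementation.
#' @param labels_path optional path to a two-column cell id / label table.
#' @param role `"source"` (labels mandatory) or `"target"`.
#' @param modality `"rna"` or `"atac_gene_activity"`.
#' @return a [DomainDataset-class].
#' @seealso [writeDomain()] for the inverse operation.
#' @export
loadDomain <- function(path, format = c("mtx", "csv", "tsv", "h5ad"),
                       labels_path = NULL,
                       role = c("source", "target"),
                       modality = c("rna", "atac_gene_activity")) {
  format <- match.arg(format)
  role <- match.arg(role)
  modality <- match.arg(modality)
  if (format == "h5ad")
    stop("format 'h5ad' is not supported by this implementation; ",
         "export the matrix as mtx or csv", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    genes <- readSidecar(file.path(dir, "genes.tsv"))
    barcodes <- readSidecar(file.path(dir, "barcodes.tsv"))
    if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
      m <- t(m)                       # genes x cells on disk
    } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(genes))) {
      stop(sprintf(
        "MTX dimensions %dx%d match neither genes.tsv (%d) x barcodes.tsv (%d) nor its transpose",
        nrow(m), ncol(m), length(genes), length(barcodes)), call. = FALSE)
    }
    dimnames(m) <- list(barcodes, genes)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                            check.names = FALSE)
    m <- as.matrix(df)
  }
  storage.mode(m) <- "double"
  if (!all(is.finite(m)))
    stop("matrix contains NaN/Inf entries", call. = FALSE)

  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- readLabelFile(labels_path, rownames(m))
  } else if (role == "source") {
    stop("source domain requires labels", call. = FALSE)
  }
  DomainDataset(m, labels = labels, modality = modality, role = role)
}

readSidecar <- function(path) {
  if (!file.exists(path))
    stop("missing MTX sidecar file: ", path, call. = FALSE)
  as.character(utils::read.table(path, sep = "\t", header = FALSE,
                                 stringsAsFactors = FALSE)[[1]])
}

readLabelFile <- function(path, cell_ids) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = guessSep(path), header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("label file must have two columns: cell id, label", call. = FALSE)
  # tolerate a header row
  if (!tab[1, 1] %in% cell_ids && nrow(tab) == length(cell_ids) + 1L)
    tab <- tab[-1, , drop = FALSE]
  ids <- as.character(tab[[1]])
  missing <- setdiff(cell_ids, ids)
  extra <- setdiff(ids, cell_ids)
  if (length(missing) || length(extra)) {
    stop("cell id mismatch between matrix and label file; missing: [",
         paste(utils::head(missing, 5), collapse = ", "), "], unknown: [",
         paste(utils::head(extra, 5), collapse = ", "), "]", call. = FALSE)
  }
  as.character(tab[[2]])[match(cell_ids, ids)]
}

guessSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else " "
}

#' Write a domain to disk
#'
#' Inverse of [loadDomain()]. For `mtx` the matrix is written genes x cells
#' (CellRanger layout) together with `genes.tsv` and `barcodes.tsv` sidecars;
#' for `csv`/`tsv` a dense table with gene ids as header and cell ids as the
#' first column. Labels, when present, go to `labels.tsv` next to the matrix.
#'
#' @param ds a [DomainDataset-class].
#' @param path output matrix path.
#' @param format `"mtx"`, `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeDomain <- function(ds, path, format = c("mtx", "csv", "tsv")) {
  format <- match.arg(format)
  m <- exprMatrix(ds)
  if (format == "mtx") {
    dir <- dirname(path)
    Matrix::writeMM(Matrix::Matrix(t(m), sparse = TRUE), path)
    writeLines(geneIds(ds), file.path(dir, "genes.tsv"))
    writeLines(cellIds(ds), file.path(dir, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(cell_id = cellIds(ds), m, check.names = FALSE)
    colnames(df) <- c("cell_id", geneIds(ds))
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(cellLabels(ds))) {
    utils::write.table(
      data.frame(cellIds(ds), cellLabels(ds)),
      file.path(dirname(path), "labels.tsv"),
      sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
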