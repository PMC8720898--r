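#' Read a UMI count matrix
#'
#' Reads genes x cells nonnegative integer counts from Matrix Market
#' (`.mtx`, with gene/cell id sidecar files) or dense CSV/TSV (first column
#' gene ids, header row cell ids). The in-memory orientation is always
#' genes-as-rows; for Matrix Market input the orientation is auto-detected
#' from the sidecar lengths, with an explicit override.
#'
#' @param path Input file.
#' @param format One of `"auto"` (by extension), `"mtx"`, `"csv"`, `"tsv"`.
#' @param genes,cells Sidecar files with one id per line (Matrix Market
#'   only); default `<path>.genes.txt` and `<path>.cells.txt`.
#' @param orientation `"auto"`, `"genes_rows"` or `"cells_rows"` (Matrix
#'   Market only).
#' @return Sparse `dgCMatrix` (mtx) or dense integer matrix (csv/tsv) with
#'   gene/cell dimnames.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                        genes = NULL, cells = NULL,
                        orientation = c("auto", "genes_rows", "cells_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "mtx") {
    if (is.null(genes)) genes <- paste0(path, ".genes.txt")
    if (is.null(cells)) cells <- paste0(path, ".cells.txt")
    for (f in c(genes, cells)) {
      if (!file.exists(f)) stop("sidecar file not found: ", f)
    }
    m <- Matrix::readMM(path)
    gid <- readLines(genes)
    cid <- readLines(cells)
    if (orientation == "auto") {
      orientation <- if (nrow(m) == length(gid) && ncol(m) == length(cid)) {
        "genes_rows"
      } else if (nrow(m) == length(cid) && ncol(m) == length(gid)) {
        "cells_rows"
      } else {
        stop("matrix is ", nrow(m), " x ", ncol(m), " but sidecars list ",
             length(gid), " genes and ", length(cid), " cells")
      }
    }
    if (orientation == "cells_rows") m <- Matrix::t(m)
    if (nrow(m) != length(gid) || ncol(m) != length(cid)) {
      stop("dimension mismatch between matrix and sidecar ids")
    }
    m <- as(as(m, "CsparseMatrix"), "generalMatrix")
    dimnames(m) <- list(gid, cid)
    .validate_count_matrix(m)
    m
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- read.delim(path, sep = sep, header = TRUE, row.names = 1,
                      check.names = FALSE)
    m <- as.matrix(tab)
    storage.mode(m) <- "double"
    .validate_count_matrix(m)
    storage.mode(m) <- "integer"
    m
  }
}

.validate_count_matrix <- function(m) {
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(m))) stop("duplicate cell ids")
  x <- if (is(m, "sparseMatrix")) m@x else as.vector(m)
  if (any(!is.finite(x))) stop("non-finite count entries")
  bad <- which(x < 0 | x != floor(x))
  if (length(bad)) {
    idx <- if (is(m, "sparseMatrix")) {
      which(as.matrix(m) < 0 | as.matrix(m) != floor(as.matrix(m)),
            arr.ind = TRUE)[1, ]
    } else {
      which(m < 0 | m != floor(m), arr.ind = TRUE)[1, ]
    }
    stop("invalid count (negative or fractional) at gene '",
         rownames(m)[idx[1]], "', cell '", colnames(m)[idx[2]], "'")
  }
  invisible(m)
}

#' Write a UMI count matrix
#'
#' Inverse of [read_counts()]: Matrix Market plus `<path>.genes.txt` /
#' `<path>.cells.txt` sidecars, or dense CSV/TSV with gene ids in the first
#' column.
#'
#' @param m Genes x cells count matrix with dimnames.
#' @param path Output file; format inferred from the extension unless given.
#' @param format `"auto"`, `"mtx"`, `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, format = c("auto", "mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv",
                     stop("cannot infer format from extension of ", path))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("`m` must carry gene and cell ids as dimnames")
  }
  if (format == "mtx") {
    Matrix::writeMM(as(as(as.matrix(m), "sparseMatrix"), "generalMatrix"),
                    path)
    writeLines(rownames(m), paste0(path, ".genes.txt"))
    writeLines(colnames(m), paste0(path, ".cells.txt"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene_id = rownames(m), as.matrix(m),
                     check.names = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Filter genes by non-zero cell support
#'
#' Keeps genes with non-zero expression in at least `min_cells` cells
#' (default 5), preserving gene order; the removed gene ids are attached as
#' attribute `"removed"`.
#'
#' @param counts Genes x cells count matrix.
#' @param min_cells Minimum number of cells with a non-zero count.
#' @return The filtered matrix.
#' @export
filter_genes <- function(counts, min_cells = 5L) {
  nz <- Matrix::rowSums(counts > 0)
  keep <- nz >= min_cells
  out <- counts[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(counts)[!keep]
  out
}

#' Read a cell metadata table
#'
#' TSV with one row per cell; must contain a `cell_id` column. Rows are
#' reordered to match `cell_ids` when supplied.
#'
#' @param path Metadata TSV.
#' @param cell_ids Optional cell ordering to enforce.
#' @return `data.frame` of cell metadata.
#' @export
read_cell_metadata <- function(path, cell_ids = NULL) {
  md <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!"cell_id" %in% names(md)) stop("metadata must have a `cell_id` column")
  if (anyDuplicated(md$cell_id)) stop("duplicate cell ids in metadata")
  if (!is.null(cell_ids)) {
    miss <- setdiff(cell_ids, md$cell_id)
    if (length(miss)) {
      stop("metadata missing cells: ", paste(head(miss, 5), collapse = ", "))
    }
    md <- md[match(cell_ids, md$cell_id), , drop = FALSE]
  }
  md
}

# shared TSV writer: header, tabs, 6 significant digits
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
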