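#' Read a sparse UMI count matrix (Matrix Market + side files)
#'
#' 10x-style triplet layout: an MTX file plus one-column gene and barcode
#' TSVs. Dimensions are validated against the side files; duplicate gene
#' symbols are disambiguated by suffixing.
#'
#' @param mtx_path Matrix Market file (genes x cells triplets, 1-based).
#' @param genes_path,barcodes_path one-column TSVs of labels.
#' @return sparse genes x cells dgCMatrix with dimnames.
#' @export
read_counts <- function(mtx_path, genes_path, barcodes_path) {
  # readMM only warns on truncated input; the entry-count check below
  # turns that into a hard error
  m <- tryCatch(suppressWarnings(Matrix::readMM(mtx_path)),
                error = function(e)
    stop("malformed MTX file '", mtx_path, "': ", conditionMessage(e),
         call. = FALSE))
  # guard against silent partial loads: the header's entry count must
  # match the number of triplets actually present
  hdr <- readLines(mtx_path, n = 50L)
  hdr <- hdr[!startsWith(hdr, "%")][1L]
  nnz_declared <- as.numeric(strsplit(trimws(hdr), "\\s+")[[1L]][3L])
  if (is.finite(nnz_declared) && Matrix::nnzero(m) < nnz_declared)
    stop("truncated MTX file '", mtx_path, "': header declares ",
         nnz_declared, " entries but ", Matrix::nnzero(m), " were read",
         call. = FALSE)
  genes <- readLines(genes_path)
  barcodes <- readLines(barcodes_path)
  if (nrow(m) != length(genes))
    stop("gene file '", genes_path, "' has ", length(genes),
         " entries but matrix has ", nrow(m), " rows", call. = FALSE)
  if (ncol(m) != length(barcodes))
    stop("barcode file '", barcodes_path, "' has ", length(barcodes),
         " entries but matrix has ", ncol(m), " columns", call. = FALSE)
  if (anyDuplicated(genes)) genes <- make.unique(genes, sep = ".")
  dimnames(m) <- list(genes, barcodes)
  methods::as(m, "CsparseMatrix")
}

#' Write a sparse count matrix with side files
#'
#' @param counts genes x cells matrix with dimnames.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return invisibly, the written file paths.
#' @export
write_counts <- function(counts, dir, prefix = "counts") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                   "CsparseMatrix")
  paths <- file.path(dir, paste0(prefix, c(".mtx", "_genes.tsv",
                                           "_barcodes.tsv")))
  Matrix::writeMM(m, paths[1])
  writeLines(rownames(counts), paths[2])
  writeLines(colnames(counts), paths[3])
  invisible(paths)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated: set name, description, members. Duplicate members are
#' deduplicated with a warning; empty sets are dropped with a warning;
#' duplicate set names are an error.
#'
#' @param path GMT file.
#' @return named list of member vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) {
    warning(sum(bad), " GMT line(s) with no members dropped")
    parts <- parts[!bad]
  }
  nms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) stop("duplicate set names in GMT", call. = FALSE)
  sets <- lapply(parts, function(p) {
    mem <- p[-(1:2)]
    mem <- mem[nzchar(mem)]
    if (anyDuplicated(mem)) {
      warning("duplicate members deduplicated in set ", p[1])
      mem <- unique(mem)
    }
    mem
  })
  setNames(sets, nms)
}

#' Write a GMT gene-set collection
#'
#' @param gene_sets named list of member vectors.
#' @param path output file.
#' @param descriptions optional per-set description column.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i)
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path) {
  d <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
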