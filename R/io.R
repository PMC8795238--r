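# Containers and standard-format I/O (10x-style Matrix Market triplets,
# TSV tables, GMT gene sets).

#' Construct a UMI count-matrix object
#'
#' @param values sparse non-negative integer matrix, cells x genes.
#' @param features data.frame with columns `id`, `symbol`, `chromosome`,
#'   `start` and logical flags `mito`, `hemoglobin` (flags are derived from
#'   symbols if absent).
#' @return object of class `count_matrix` with fields `values`, `cell_ids`,
#'   `features`.
#' @export
count_matrix <- function(values, features) {
  values <- methods::as(values, "CsparseMatrix")
  if (any(values@x < 0)) stop_cfg("counts must be non-negative")
  if (any(values@x != round(values@x))) stop_cfg("counts must be integral")
  if (ncol(values) != nrow(features))
    stop_cfg("feature table must have one row per gene column")
  need <- c("id", "symbol", "chromosome", "start")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop_cfg("features lack column(s): %s",
                             paste(miss, collapse = ", "))
  if (is.null(features$mito))
    features$mito <- grepl("^MT-", features$symbol)
  if (is.null(features$hemoglobin))
    features$hemoglobin <- grepl("^HB[ABDG]", features$symbol)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("cell_%05d", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values))) stop_cfg("duplicate cell barcodes")
  colnames(values) <- features$symbol
  structure(list(values = values, cell_ids = rownames(values),
                 features = features),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes, %d nonzero\n",
              nrow(x$values), ncol(x$values), length(x$values@x)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Construct a per-cell allele-count object
#'
#' Paired sparse ref/alt matrices over a hotspot catalog; a (cell, variant)
#' pair with zero total depth is "not covered".
#'
#' @param ref,alt sparse non-negative integer matrices, cells x variants,
#'   identical dimnames.
#' @param catalog data.frame with at least `variant_id`, `gene`, `position`,
#'   `protein_change`; one row per column of `alt`.
#' @return object of class `allele_counts`.
#' @export
allele_counts <- function(ref, alt, catalog) {
  ref <- methods::as(ref, "CsparseMatrix")
  alt <- methods::as(alt, "CsparseMatrix")
  if (!identical(dim(ref), dim(alt)))
    stop_cfg("ref and alt must have identical dimensions")
  if (any(ref@x < 0) || any(alt@x < 0))
    stop_cfg("allele counts must be non-negative")
  if (nrow(catalog) != ncol(alt))
    stop_cfg("catalog must have one row per variant column")
  if (anyDuplicated(catalog$variant_id)) stop_cfg("duplicate variant ids")
  if (any(catalog$position <= 0)) stop_cfg("positions must be positive")
  colnames(ref) <- colnames(alt) <- catalog$variant_id
  structure(list(ref = ref, alt = alt, catalog = catalog),
            class = "allele_counts")
}

#' Write a count matrix as 10x-style Matrix Market triplet files
#'
#' Writes `matrix.mtx` (genes x cells, the 10x orientation), `barcodes.tsv`
#' and `features.tsv` (id, symbol, chromosome, start) under `dir`.
#'
#' @param cm a [count_matrix()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(cm$values), file.path(dir, "matrix.mtx"))
  writeLines(cm$cell_ids, file.path(dir, "barcodes.tsv"))
  write.table(cm$features[, c("id", "symbol", "chromosome", "start")],
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a 10x-style Matrix Market triplet directory
#'
#' Expects `matrix.mtx` (genes x cells), `barcodes.tsv` and `features.tsv`
#' (id, symbol, chromosome, start).
#'
#' @param dir directory written by [write_count_matrix()] or an equivalent
#'   10x-dialect export.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  feats <- read.delim(file.path(dir, "features.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)
  names(feats)[1:4] <- c("id", "symbol", "chromosome", "start")
  vals <- methods::as(Matrix::t(m), "CsparseMatrix")
  rownames(vals) <- barcodes
  count_matrix(vals, feats)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, name TAB description TAB genes...
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(out) <- vapply(strsplit(lines, "\t"), `[`, "", 1L)
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read allele counts from a triplet TSV
#'
#' Dialect: columns `cell`, `variant_id`, `ref`, `alt`; variants must exist
#' in the catalog.
#'
#' @param path TSV path.
#' @param catalog variant catalog data.frame (`variant_id`, `gene`,
#'   `position`, `protein_change`).
#' @return an [allele_counts()].
#' @export
read_allele_counts <- function(path, catalog) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  bad <- setdiff(df$variant_id, catalog$variant_id)
  if (length(bad)) stop_cfg("variant id(s) absent from catalog: %s",
                            paste(unique(bad), collapse = ", "))
  cells <- unique(df$cell)
  ci <- match(df$cell, cells)
  vi <- match(df$variant_id, catalog$variant_id)
  dims <- c(length(cells), nrow(catalog))
  dn <- list(cells, catalog$variant_id)
  ref <- Matrix::sparseMatrix(i = ci, j = vi, x = df$ref, dims = dims, dimnames = dn)
  alt <- Matrix::sparseMatrix(i = ci, j = vi, x = df$alt, dims = dims, dimnames = dn)
  allele_counts(ref, alt, catalog)
}
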