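# Cell quality control, depth normalization, and the immune split.

#' Quality-control configuration
#'
#' The four low-quality-cell rules: (1) standard deviation of raw counts
#' across all genes below `stddev_floor`; (2) fraction of genes at zero at
#' or above `zero_fraction_ceiling`; (3) mitochondrial-plus-hemoglobin UMI
#' fraction at or above `mito_hb_fraction_ceiling`; (4) total UMI strictly
#' below `umi_floor` or strictly above `umi_ceiling`.
#'
#' @param stddev_floor rule-1 floor on per-cell raw-count sd.
#' @param zero_fraction_ceiling rule-2 ceiling (inclusive) on the zero-gene
#'   fraction.
#' @param mito_hb_fraction_ceiling rule-3 ceiling (inclusive) on the
#'   mito+hemoglobin UMI fraction.
#' @param umi_floor,umi_ceiling rule-4 bounds (exclusive) on total UMI.
#' @return object of class `qc_config`.
#' @export
qc_config <- function(stddev_floor = 1.0, zero_fraction_ceiling = 0.90,
                      mito_hb_fraction_ceiling = 0.10,
                      umi_floor = 100, umi_ceiling = 20000) {
  if (umi_floor >= umi_ceiling) stop_cfg("umi_floor must be < umi_ceiling")
  if (zero_fraction_ceiling < 0 || zero_fraction_ceiling > 1 ||
      mito_hb_fraction_ceiling < 0 || mito_hb_fraction_ceiling > 1)
    stop_cfg("fraction ceilings must lie in [0, 1]")
  structure(list(stddev_floor = stddev_floor,
                 zero_fraction_ceiling = zero_fraction_ceiling,
                 mito_hb_fraction_ceiling = mito_hb_fraction_ceiling,
                 umi_floor = umi_floor, umi_ceiling = umi_ceiling),
            class = "qc_config")
}

#' Apply the four low-quality-cell filters
#'
#' A cell is removed iff it violates at least one rule (see [qc_config()]).
#' Rule 1 is evaluated on raw counts, before any normalization.
#'
#' @param counts a [count_matrix()].
#' @param cfg a [qc_config()].
#' @return list with `kept` (filtered [count_matrix()]) and `report`
#'   (data.frame: `cell`, `total_umi`, `sd_counts`, `zero_fraction`,
#'   `mito_hb_fraction`, `rules_violated` (comma-separated ids among
#'   low_sd, high_zero, high_mito, umi_range; "" if kept), `kept`).
#' @export
filter_cells <- function(counts, cfg = qc_config()) {
  stopifnot(inherits(counts, "count_matrix"))
  v <- counts$values
  if (nrow(v) == 0L) stop_cfg("empty count matrix")
  n_genes <- ncol(v)
  total <- Matrix::rowSums(v)
  sq <- Matrix::rowSums(v^2)
  mean_c <- total / n_genes
  # per-cell sd of raw counts across all genes (sample sd, as var() would give)
  sd_c <- sqrt(pmax(sq - n_genes * mean_c^2, 0) / (n_genes - 1))
  nnz <- Matrix::rowSums(v > 0)
  zero_frac <- 1 - nnz / n_genes
  mh <- counts$features$mito | counts$features$hemoglobin
  mh_frac <- Matrix::rowSums(v[, mh, drop = FALSE]) / pmax(total, 1)
  mh_frac[total == 0] <- 0

  viol <- cbind(low_sd = sd_c < cfg$stddev_floor,
                high_zero = zero_frac >= cfg$zero_fraction_ceiling,
                high_mito = mh_frac >= cfg$mito_hb_fraction_ceiling,
                umi_range = total < cfg$umi_floor | total > cfg$umi_ceiling)
  rules <- apply(viol, 1, function(r) paste(colnames(viol)[r], collapse = ","))
  keep <- !apply(viol, 1, any)
  if (!any(keep)) stop_cfg("empty after QC: every cell violates a rule")
  report <- data.frame(cell = counts$cell_ids, total_umi = total,
                       sd_counts = sd_c, zero_fraction = zero_frac,
                       mito_hb_fraction = mh_frac, rules_violated = rules,
                       kept = keep, row.names = NULL,
                       stringsAsFactors = FALSE)
  kept_cm <- count_matrix(v[keep, , drop = FALSE], counts$features)
  list(kept = kept_cm, report = report)
}

#' Depth-normalize and log-transform a count matrix
#'
#' value(c, g) = log(1 + count(c, g) / total(c) * scale_factor). The
#' per-cell vector is invariant to multiplying that cell's counts by a
#' constant, so sequencing depth drops out.
#'
#' @param counts a [count_matrix()]; every cell must have total UMI > 0.
#' @param scale_factor pseudo-library size; 10,000 is the conventional
#'   default for this normalization family.
#' @return object of class `normalized_matrix`: fields `values` (sparse
#'   cells x genes, natural-log scale), `scale_factor`, `features`.
#' @export
normalize_log <- function(counts, scale_factor = 1e4) {
  stopifnot(inherits(counts, "count_matrix"))
  total <- Matrix::rowSums(counts$values)
  if (any(total == 0))
    stop_cfg("cell(s) with zero total UMI; run filter_cells first")
  scaled <- Matrix::Diagonal(x = scale_factor / total) %*% counts$values
  vals <- methods::as(scaled, "CsparseMatrix")
  vals@x <- log1p(vals@x)
  dimnames(vals) <- dimnames(counts$values)
  structure(list(values = vals, scale_factor = scale_factor,
                 features = counts$features),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d cells x %d genes (log scale, scale factor %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' Split clusters into immune and non-immune by PTPRC (CD45)
#'
#' A cluster is called immune iff its mean PTPRC expression exceeds the
#' threshold; the default threshold is the global mean PTPRC across cells,
#' a cluster-level call that is robust to dropout.
#'
#' @param norm a [normalize_log()] matrix containing PTPRC.
#' @param clusters per-cell cluster labels (length = cells).
#' @param threshold numeric cutoff on cluster-mean PTPRC, or `NULL` for the
#'   global mean.
#' @return list with `cell_class` (per-cell "immune"/"non_immune"),
#'   `cluster_class` (named per-cluster), `threshold`.
#' @export
split_immune <- function(norm, clusters, threshold = NULL) {
  sym <- norm$features$symbol
  if (!"PTPRC" %in% sym)
    stop_cfg("feature PTPRC (CD45) absent; cannot split immune cells")
  x <- norm$values[, match("PTPRC", sym)]
  if (is.null(threshold)) threshold <- mean(x)
  cl_mean <- tapply(x, clusters, mean)
  cluster_class <- ifelse(cl_mean > threshold, "immune", "non_immune")
  cell_class <- unname(cluster_class[as.character(clusters)])
  list(cell_class = cell_class, cluster_class = cluster_class,
       threshold = threshold)
}
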