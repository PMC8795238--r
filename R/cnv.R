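# Expression-inferred copy-number scoring along genomic position.

#' Infer per-cell copy-number scores from expression
#'
#' Standard moving-window expression-CNV construction: genes ordered by
#' (chromosome, start, id); expression centered by reference-cell gene
#' means; centered values clipped to +/- `clip`; centered moving average of
#' `window` genes within each chromosome; per-cell median re-centering.
#' Per-cell burden is the mean squared score, which separates malignant
#' cells (genome-wide dosage deviation) from the diploid reference.
#'
#' @param norm a [normalize_log()] matrix; features must carry `chromosome`
#'   and `start`.
#' @param reference_cells barcodes of non-malignant reference cells
#'   (epithelial / stromal types).
#' @param window odd moving-average width in genes.
#' @param clip symmetric clip on centered expression.
#' @return object of class `cnv_matrix`: `values` (cells x genes scores in
#'   genome order), `gene_order` (feature rows in genome order), `window`,
#'   `reference_cells`, `burden` (named per-cell mean squared score).
#' @export
infer_cnv_scores <- function(norm, reference_cells, window = 101L, clip = 3) {
  v <- norm$values
  feats <- norm$features
  ok <- !is.na(feats$chromosome) & !is.na(feats$start)
  if (mean(ok) < 0.5) stop_cfg("missing genomic coordinates for > 50% of genes")
  ref_ix <- match(reference_cells, rownames(v))
  if (!length(ref_ix) || anyNA(ref_ix))
    stop_cfg("reference cells empty or absent from the matrix")
  ord <- order(feats$chromosome[ok], feats$start[ok], feats$id[ok])
  gene_rows <- which(ok)[ord]
  x <- as.matrix(v[, gene_rows, drop = FALSE])
  ref_mean <- colMeans(x[ref_ix, , drop = FALSE])
  x <- sweep(x, 2, ref_mean, "-")
  x <- pmin(pmax(x, -clip), clip)

  chrom <- feats$chromosome[gene_rows]
  sm <- smooth_genome(x, chrom, window)
  med <- apply(sm, 1, median)
  sm <- sweep(sm, 1, med, "-")
  # re-center so reference cells average ~0 per gene
  sm <- sweep(sm, 2, colMeans(sm[ref_ix, , drop = FALSE]), "-")
  burden <- rowMeans(sm^2)
  structure(list(values = sm, gene_order = gene_rows, window = window,
                 clip = clip, reference_cells = reference_cells,
                 burden = burden),
            class = "cnv_matrix")
}

# per-chromosome centered moving average; edge windows shrink, so each
# cell's chromosome mean is restored exactly afterwards
smooth_genome <- function(x, chrom, window) {
  sm <- x
  for (ch in unique(chrom)) {
    cix <- which(chrom == ch)
    w <- min(window, length(cix))
    blk <- t(apply(x[, cix, drop = FALSE], 1, running_mean, w = w))
    blk <- blk + (rowMeans(x[, cix, drop = FALSE]) - rowMeans(blk))
    sm[, cix] <- blk
  }
  sm
}

# centered moving average with shrinking windows at chromosome edges
running_mean <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half <- (w - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Call gene-level amplification / deletion per cluster
#'
#' A gene is called amplified in a cluster if its mean CNV score there
#' exceeds `threshold`, deleted if below `-threshold`.
#'
#' @param cnv a [infer_cnv_scores()] result.
#' @param genes gene symbols to interrogate (e.g. CD44, CDK6, GATA4, GATA6,
#'   KLF5, KRAS for amplifications; ARID1A, SMAD4 for deletions).
#' @param clusters per-cell cluster (or cell-type) labels aligned with the
#'   CNV matrix rows.
#' @param features the feature table the CNV matrix was built from.
#' @param threshold call threshold on the mean score (default 0.15, above
#'   the between-type baseline wobble of expression-only scores).
#' @return data.frame: `gene`, `cluster`, `mean_score`, `call` in
#'   {amplified, deleted, neutral}; genes absent from the matrix appear
#'   with call "absent" rather than being dropped.
#' @export
call_gene_cnv <- function(cnv, genes, clusters, features, threshold = 0.15) {
  stopifnot(inherits(cnv, "cnv_matrix"))
  sym_in_order <- features$symbol[cnv$gene_order]
  cl <- as.character(clusters)
  out <- list()
  for (g in genes) {
    j <- match(g, sym_in_order)
    if (is.na(j)) {
      out[[g]] <- data.frame(gene = g, cluster = NA_character_,
                             mean_score = NA_real_, call = "absent")
      next
    }
    for (k in sort(unique(cl))) {
      m <- mean(cnv$values[cl == k, j])
      call <- if (is.infinite(threshold)) "neutral"
      else if (m > threshold) "amplified"
      else if (m < -threshold) "deleted" else "neutral"
      out[[paste(g, k)]] <- data.frame(gene = g, cluster = k,
                                       mean_score = m, call = call)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
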