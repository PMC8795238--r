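# Variable-gene selection, SNN/Louvain clustering, one-vs-rest marker
# testing, marker-table cell typing, and per-sample frequency tests.

#' Highly-variable-gene selection configuration
#'
#' Mean-binned dispersion selection: dispersion = log(variance/mean) of the
#' de-logged normalized expression, z-scored within equal-width mean bins.
#'
#' @param mean_low,mean_high open interval of acceptable mean expression
#'   (de-logged scale).
#' @param dispersion_cutoff floor on the binned-standardized dispersion.
#' @param n_bins number of equal-width mean bins.
#' @return object of class `hvg_config`.
#' @export
hvg_config <- function(mean_low = 0.0125, mean_high = 6,
                       dispersion_cutoff = 0.5, n_bins = 20L) {
  if (mean_low >= mean_high) stop_cfg("mean_low must be < mean_high")
  structure(list(mean_low = mean_low, mean_high = mean_high,
                 dispersion_cutoff = dispersion_cutoff,
                 n_bins = as.integer(n_bins)), class = "hvg_config")
}

#' Select highly variable genes
#'
#' @param norm a [normalize_log()] matrix with at least two cells.
#' @param cfg an [hvg_config()].
#' @return character vector of selected gene symbols (possibly empty, with
#'   a warning if every gene is constant).
#' @export
select_hvg <- function(norm, cfg = hvg_config()) {
  v <- norm$values
  if (nrow(v) < 2L) stop_cfg("need at least two cells")
  # mean / dispersion on the de-logged (relative count) scale
  ex <- v
  ex@x <- expm1(ex@x)
  mu <- Matrix::colMeans(ex)
  ex2 <- ex
  ex2@x <- ex2@x^2
  varg <- (Matrix::colSums(ex2) - nrow(ex) * mu^2) / (nrow(ex) - 1)
  if (all(varg == 0)) {
    warning("all genes constant; no variable genes")
    return(character(0))
  }
  disp <- ifelse(mu > 0 & varg > 0, log(varg / mu), NA_real_)
  logmu <- log1p(mu)
  bins <- cut(logmu, breaks = cfg$n_bins)
  zdisp <- rep(NA_real_, length(disp))
  for (b in levels(bins)) {
    ix <- which(bins == b & !is.na(disp))
    if (length(ix) >= 2L) {
      s <- sd(disp[ix])
      zdisp[ix] <- if (s > 0) (disp[ix] - mean(disp[ix])) / s else 0
    } else if (length(ix) == 1L) zdisp[ix] <- 0
  }
  sel <- !is.na(zdisp) & mu > cfg$mean_low & mu < cfg$mean_high &
    zdisp > cfg$dispersion_cutoff
  norm$features$symbol[sel]
}

#' Clustering configuration
#'
#' @param n_pcs_compute principal components computed.
#' @param n_pcs_use leading components used for the SNN graph.
#' @param resolution Louvain modularity resolution.
#' @param knn_k neighbors for the SNN graph (Jaccard weights).
#' @param seed seed for community detection.
#' @return object of class `cluster_config`.
#' @export
cluster_config <- function(n_pcs_compute = 30L, n_pcs_use = 20L,
                           resolution = 0.8, knn_k = 20L, seed = 12345L) {
  if (n_pcs_use > n_pcs_compute) stop_cfg("n_pcs_use must be <= n_pcs_compute")
  if (resolution <= 0) stop_cfg("resolution must be > 0")
  structure(list(n_pcs_compute = as.integer(n_pcs_compute),
                 n_pcs_use = as.integer(n_pcs_use), resolution = resolution,
                 knn_k = as.integer(knn_k), seed = as.integer(seed)),
            class = "cluster_config")
}

#' PCA embedding and SNN/Louvain clustering
#'
#' PCA on the centered and scaled HVG submatrix; shared-nearest-neighbor
#' graph (k nearest neighbors, Jaccard edge weights) on the leading
#' components; Louvain community detection at the configured resolution.
#' Labels are dense integers 0..K-1 ordered by decreasing cluster size.
#'
#' @param norm a [normalize_log()] matrix.
#' @param hvg character vector of variable-gene symbols.
#' @param cfg a [cluster_config()].
#' @return list with `embedding` (cells x n_pcs_compute PC scores) and
#'   `clusters` (integer labels).
#' @export
embed_and_cluster <- function(norm, hvg, cfg = cluster_config()) {
  ix <- match(intersect(hvg, norm$features$symbol), norm$features$symbol)
  if (length(ix) < 2L) stop_cfg("need at least two variable genes present")
  if (nrow(norm$values) <= cfg$knn_k)
    stop_cfg("fewer cells than knn_k; reduce knn_k")
  x <- as.matrix(norm$values[, ix, drop = FALSE])
  sdv <- apply(x, 2, sd)
  x <- x[, sdv > 0, drop = FALSE]
  x <- scale(x)
  npc <- min(cfg$n_pcs_compute, ncol(x), nrow(x) - 1L)
  pcs <- prcomp(x, rank. = npc, center = FALSE, scale. = FALSE)$x
  emb <- pcs[, seq_len(min(cfg$n_pcs_use, ncol(pcs))), drop = FALSE]

  g <- snn_graph(emb, k = cfg$knn_k)
  set.seed(cfg$seed)
  comm <- igraph::cluster_louvain(g, resolution = cfg$resolution)
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  clusters <- unname(relabel[as.character(memb)])
  list(embedding = pcs, clusters = as.integer(clusters))
}

# kNN -> shared-nearest-neighbor graph with Jaccard weights.
snn_graph <- function(emb, k) {
  n <- nrow(emb)
  d <- as.matrix(dist(emb))
  nbr <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    nbr[i, ] <- order(d[i, ])[2:(k + 1)]  # self excluded
  }
  nbr_sets <- lapply(seq_len(n), function(i) c(i, nbr[i, ]))
  edges <- integer(0); wts <- numeric(0)
  ei <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- unique(unlist(nbr_sets[nbr_sets[[i]]]))
    cand <- cand[cand > i]
    for (j in cand) {
      shared <- length(intersect(nbr_sets[[i]], nbr_sets[[j]]))
      jac <- shared / (2 * (k + 1) - shared)
      if (jac > 1 / 15) ei[[i]] <- c(ei[[i]], j, jac)
    }
  }
  mat <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (is.null(ei[[i]])) return(NULL)
    m <- matrix(ei[[i]], ncol = 2, byrow = TRUE)
    cbind(i, m)
  }))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(mat) && nrow(mat)) {
    g <- igraph::add_edges(g, t(mat[, 1:2]))
    igraph::E(g)$weight <- mat[, 3]
  }
  g
}

#' One-vs-rest Wilcoxon marker test per cluster
#'
#' For each cluster, genes detected in at least `min_pct` of in-cluster
#' cells and with natural-log fold change at least `lfc_floor` are tested
#' one-vs-rest by Wilcoxon rank-sum. Both Bonferroni-adjusted p and BH FDR
#' are reported; the final marker flag requires at least 2-fold
#' up-regulation and FDR < 0.01.
#'
#' @param norm a [normalize_log()] matrix.
#' @param clusters per-cell cluster labels.
#' @param min_pct detection floor within the cluster.
#' @param lfc_floor pre-test log-fold-change floor (natural log).
#' @return data.frame with `gene`, `cluster`, `log_fold_change`,
#'   `fraction_in`, `fraction_out`, `p_raw`, `p_bonferroni`, `fdr`,
#'   `is_marker`; clusters of size 1 are skipped and listed in the
#'   `skipped_clusters` attribute.
#' @export
find_markers <- function(norm, clusters, min_pct = 0.25, lfc_floor = 0.25) {
  cl <- as.character(clusters)
  if (length(unique(cl)) < 2L) stop_cfg("need at least two clusters")
  v <- norm$values
  ex <- v
  ex@x <- expm1(ex@x)
  skipped <- character(0)
  res <- list()
  for (g in sort(unique(cl))) {
    inn <- cl == g
    if (sum(inn) < 2L) { skipped <- c(skipped, g); next }
    pct_in <- Matrix::colMeans(v[inn, , drop = FALSE] > 0)
    pct_out <- Matrix::colMeans(v[!inn, , drop = FALSE] > 0)
    mu_in <- Matrix::colMeans(ex[inn, , drop = FALSE])
    mu_out <- Matrix::colMeans(ex[!inn, , drop = FALSE])
    lfc <- log(mu_in + 1) - log(mu_out + 1)
    test_ix <- which(pct_in >= min_pct & lfc >= lfc_floor)
    if (!length(test_ix)) next
    p <- vapply(test_ix, function(j) {
      xin <- v[inn, j]; xout <- v[!inn, j]
      if (max(xin, xout) == min(xin, xout)) return(1)
      suppressWarnings(wilcox.test(xin, xout)$p.value)
    }, 0)
    res[[g]] <- data.frame(
      gene = norm$features$symbol[test_ix], cluster = g,
      log_fold_change = lfc[test_ix], fraction_in = pct_in[test_ix],
      fraction_out = pct_out[test_ix], p_raw = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene = character(), cluster = character(),
                      log_fold_change = numeric(), fraction_in = numeric(),
                      fraction_out = numeric(), p_raw = numeric())
  }
  m <- ncol(v)  # tests corrected over the gene universe
  out$p_bonferroni <- pmin(1, out$p_raw * m)
  out$fdr <- p.adjust(out$p_raw, "BH")
  out$is_marker <- out$log_fold_change >= log(2) & out$fdr < 0.01
  rownames(out) <- NULL
  attr(out, "skipped_clusters") <- skipped
  out
}

#' Assign cell types to clusters from a marker table
#'
#' Each cluster gets the type maximizing the mean z-scored expression of
#' that type's markers within the cluster; ties are broken by detected
#' marker overlap then lexicographic type name. Clusters where no marker of
#' any type is detected are labeled "unassigned".
#'
#' @param norm a [normalize_log()] matrix.
#' @param clusters per-cell cluster labels.
#' @param markers named list, cell type -> marker symbols (e.g.
#'   [default_marker_table()]).
#' @param degs optional [find_markers()] table used for the tie-break
#'   overlap count.
#' @return list with `cluster_type` (named per-cluster), `cell_type`
#'   (per-cell) and `scores` (clusters x types mean marker z-score).
#' @export
assign_cell_types <- function(norm, clusters, markers = default_marker_table(),
                              degs = NULL) {
  if (!length(markers)) stop_cfg("marker table is empty")
  cl <- as.character(clusters)
  z <- zscore_cols(as.matrix(norm$values))
  sym <- norm$features$symbol
  cls <- sort(unique(cl))
  scores <- matrix(NA_real_, length(cls), length(markers),
                   dimnames = list(cls, names(markers)))
  detected <- scores
  for (ty in names(markers)) {
    mk <- intersect(markers[[ty]], sym)
    if (!length(mk)) next
    zi <- z[, match(mk, sym), drop = FALSE]
    expressed <- Matrix::colSums(norm$values[, match(mk, sym), drop = FALSE] > 0) > 0
    for (g in cls) {
      inn <- cl == g
      scores[g, ty] <- mean(zi[inn, , drop = FALSE])
      detected[g, ty] <- sum(Matrix::colSums(norm$values[inn, match(mk, sym), drop = FALSE] > 0) > 0)
    }
  }
  cluster_type <- setNames(character(length(cls)), cls)
  for (g in cls) {
    s <- scores[g, ]
    if (all(is.na(s)) || all(detected[g, ] == 0, na.rm = TRUE)) {
      cluster_type[g] <- "unassigned"
      next
    }
    best <- which(s == max(s, na.rm = TRUE))
    if (length(best) > 1L) {
      ov <- detected[g, best]
      best <- best[ov == max(ov)]
      best <- best[order(names(s)[best])][1]
    }
    cluster_type[g] <- names(s)[best]
  }
  list(cluster_type = cluster_type,
       cell_type = unname(cluster_type[cl]),
       scores = scores)
}

#' Per-sample cell-type frequency tests between groups
#'
#' Computes per-sample cell-type frequencies (each sample's frequencies sum
#' to 1), runs a two-sample t-test per cell type between the two groups,
#' and a per-cluster two-proportion z-test of patient composition.
#'
#' @param cell_type per-cell type labels.
#' @param sample per-cell sample ids.
#' @param group per-cell group labels with exactly two levels (e.g.
#'   adjacent vs cancer, IGC vs DGC); each sample must map to one group.
#' @return list with `frequencies` (samples x types), `t_tests` (per-type
#'   data.frame: type, mean difference, t, p) and `proportion_tests`
#'   (per-type two-proportion z-test of samples contributing to the type).
#'   Comparisons with fewer than two samples per group are skipped with a
#'   notice in the `skipped` field.
#' @export
celltype_frequency_test <- function(cell_type, sample, group) {
  smp <- unique(sample)
  smp_group <- vapply(smp, function(s) unique(group[sample == s])[1], "")
  tab <- table(sample, cell_type)
  freq <- sweep(as.matrix(tab), 1, rowSums(tab), "/")
  freq <- freq[smp, , drop = FALSE]
  gl <- unique(smp_group)
  if (length(gl) != 2L) stop_cfg("need exactly two groups")
  skipped <- character(0)
  if (min(table(smp_group)) < 2L) {
    return(list(frequencies = freq, t_tests = NULL, proportion_tests = NULL,
                skipped = sprintf("group with < 2 samples: %s",
                                  gl[which.min(table(smp_group)[gl])])))
  }
  tt <- do.call(rbind, lapply(colnames(freq), function(ty) {
    a <- freq[smp_group == gl[1], ty]
    b <- freq[smp_group == gl[2], ty]
    if (sd(c(a, b)) == 0) {
      data.frame(type = ty, diff = 0, t = 0, p = 1)
    } else {
      ht <- t.test(a, b)
      data.frame(type = ty, diff = mean(a) - mean(b),
                 t = unname(ht$statistic), p = ht$p.value)
    }
  }))
  pt <- do.call(rbind, lapply(colnames(freq), function(ty) {
    pres <- freq[, ty] > 0
    n1 <- sum(smp_group == gl[1]); n2 <- sum(smp_group == gl[2])
    x1 <- sum(pres[smp_group == gl[1]]); x2 <- sum(pres[smp_group == gl[2]])
    pv <- tryCatch(suppressWarnings(prop.test(c(x1, x2), c(n1, n2))$p.value),
                   error = function(e) NA_real_)
    data.frame(type = ty, prop1 = x1 / n1, prop2 = x2 / n2, p = pv)
  }))
  list(frequencies = freq, t_tests = tt, proportion_tests = pt,
       skipped = skipped)
}
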