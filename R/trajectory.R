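# Pseudotime trajectory over an MST of k-medoid centroids, progression
# states, pseudotime-dependent gene tests, cross-lineage DEG overlap.

#' Build a pseudotime trajectory
#'
#' Reduces the HVG submatrix by PCA to `n_pcs` components, fits k-medoids
#' over cells in that space, connects medoid centroids by a Euclidean
#' minimum spanning tree, roots the tree at the centroid richest in the
#' configured benign cell types (or an explicit node), and assigns each
#' cell a pseudotime equal to the tree geodesic distance from the root to
#' its centroid plus a local offset (projection of the cell onto the
#' incoming tree edge direction). Branch states are the tree segments
#' between branch points. A 2-D view (symmetric fixed-point ICA rotation
#' of the PCs; plain PCA selectable) is returned for plotting; the tree
#' itself lives in the full PC space so lineage geometry is not crowded
#' out by unrelated cell-type contrasts.
#'
#' @param norm a [normalize_log()] matrix with at least three cells.
#' @param hvg variable-gene symbols used for the reduction.
#' @param root_types benign cell types whose centroid share picks the root
#'   (requires `annotations`); ignored when `root_id` is given.
#' @param annotations per-cell type labels, needed for `root_types`.
#' @param root_id explicit root centroid index.
#' @param k_medoids number of medoid centroids (capped at n/3).
#' @param reduction "ica" (default) or "pca" for the 2-D view.
#' @param n_pcs PCs kept for the tree space.
#' @param smooth_k kNN-denoising neighborhood applied to the PC
#'   coordinates before tree construction (`NULL` = 5% of cells, floor
#'   10); 0 disables.
#' @param smooth_passes denoising iterations.
#' @param seed seed for the reduction and medoid fit.
#' @return object of class `trajectory`: `embedding` (cells x 2), `centroids`
#'   (k x 2), `assignment` (cell -> centroid), `tree` (igraph MST), `root`
#'   (centroid index), `pseudotime` (per-cell, root cell at 0),
#'   `branch_state` (per-cell integer segment id), `centroid_pseudotime`.
#' @export
build_trajectory <- function(norm, hvg, root_types = NULL, annotations = NULL,
                             root_id = NULL, k_medoids = 10L,
                             reduction = c("ica", "pca"), n_pcs = 5L,
                             smooth_k = NULL, smooth_passes = 2L,
                             seed = 12345L) {
  reduction <- match.arg(reduction)
  v <- norm$values
  n <- nrow(v)
  if (n < 3L) stop_cfg("need at least three cells")
  ix <- match(intersect(hvg, norm$features$symbol), norm$features$symbol)
  if (length(ix) < 2L) stop_cfg("need at least two variable genes present")
  x <- as.matrix(v[, ix, drop = FALSE])
  sdv <- apply(x, 2, sd)
  x <- scale(x[, sdv > 0, drop = FALSE])
  npc <- min(n_pcs, ncol(x), n - 1L)
  pcs <- prcomp(x, rank. = npc, center = FALSE)$x
  emb <- if (reduction == "ica" && npc > 2L) {
    fast_ica(pcs, n_comp = 2L, seed = seed)
  } else pcs[, seq_len(min(2L, ncol(pcs))), drop = FALSE]
  if (ncol(emb) < 2L) emb <- cbind(emb, 0)
  rownames(emb) <- rownames(pcs) <- rownames(v)

  if (is.null(smooth_k)) smooth_k <- max(10L, ceiling(0.05 * n))
  smooth_k <- min(smooth_k, n - 1L)
  if (smooth_k > 0 && smooth_passes > 0) {
    for (it in seq_len(smooth_passes)) {
      dmat <- as.matrix(dist(pcs))
      pcs <- t(vapply(seq_len(n), function(i) {
        colMeans(pcs[order(dmat[i, ])[seq_len(smooth_k + 1L)], , drop = FALSE])
      }, numeric(ncol(pcs))))
      rownames(pcs) <- rownames(v)
    }
  }

  k <- max(2L, min(k_medoids, n %/% 3L))
  set.seed(seed)
  pm <- cluster::pam(pcs, k = k, pamonce = 5)
  centroids <- pm$medoids
  assignment <- pm$clustering

  dmat <- as.matrix(dist(centroids))
  g <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)

  if (is.null(root_id)) {
    if (is.null(root_types) || is.null(annotations))
      stop_cfg("provide root_id, or root_types with annotations")
    share <- vapply(seq_len(k), function(ci) {
      mean(annotations[assignment == ci] %in% root_types)
    }, 0)
    if (all(share == 0))
      stop_cfg("root rule matches no centroid (types: %s)",
               paste(root_types, collapse = ", "))
    root_id <- which.max(share)
  }
  if (root_id < 1L || root_id > k) stop_cfg("root_id outside centroid range")

  geo <- igraph::distances(tree, v = root_id)[1, ]
  # parent of each centroid on its path to root, for the local offset
  paths <- igraph::shortest_paths(tree, from = root_id,
                                  to = igraph::V(tree))$vpath
  parent <- vapply(seq_len(k), function(ci) {
    p <- as.integer(paths[[ci]])
    if (length(p) < 2L) NA_integer_ else p[length(p) - 1L]
  }, 0L)

  # local offset: project the cell onto the nearest incident tree edge of
  # its centroid; walking toward the parent subtracts, away adds
  pt <- numeric(n)
  for (i in seq_len(n)) {
    ci <- assignment[i]
    nbs <- as.integer(igraph::neighbors(tree, ci))
    best_d <- Inf
    best_pt <- geo[ci]
    for (nb in nbs) {
      e <- centroids[nb, ] - centroids[ci, ]
      len <- sqrt(sum(e^2))
      if (len == 0) next
      u <- e / len
      a <- min(max(sum((pcs[i, ] - centroids[ci, ]) * u), 0), len)
      dd <- sum((pcs[i, ] - (centroids[ci, ] + a * u))^2)
      if (dd < best_d) {
        best_d <- dd
        best_pt <- if (!is.na(parent[ci]) && nb == parent[ci]) geo[ci] - a
        else geo[ci] + a
      }
    }
    pt[i] <- max(best_pt, 0)
  }
  names(pt) <- rownames(v)

  seg <- tree_segments(tree)
  branch_state <- seg[assignment]

  structure(list(embedding = emb, centroids = centroids,
                 assignment = assignment, tree = tree, root = root_id,
                 pseudotime = pt, branch_state = branch_state,
                 centroid_pseudotime = geo),
            class = "trajectory")
}

# segment id per tree node: components after detaching branch points
# (degree >= 3); each branch point forms its own singleton segment.
tree_segments <- function(tree) {
  k <- igraph::vcount(tree)
  deg <- igraph::degree(tree)
  branch_pts <- which(deg >= 3)
  g2 <- igraph::delete_vertices(tree, branch_pts)
  comp <- igraph::components(g2)$membership
  seg <- integer(k)
  seg[setdiff(seq_len(k), branch_pts)] <- comp
  nseg <- max(comp, 0)
  for (b in branch_pts) {
    nseg <- nseg + 1L
    seg[b] <- nseg
  }
  seg
}

#' Assign progression states along the trajectory
#'
#' Cells of excluded types (fibroblasts, endothelial cells in the atlas)
#' keep their own terminal labels ("excluded_<type>"); remaining cells are
#' divided into `n_states` equal-count pseudotime quantile bins, labeled
#' `prefix`1..`prefix`n in order of mean pseudotime.
#'
#' @param traj a [build_trajectory()] object.
#' @param annotations per-cell type labels.
#' @param n_states number of progression states (3 for the intestinal
#'   lineage I1-I3, 4 for the diffuse lineage D1-D4).
#' @param exclude_types types excluded from progression states.
#' @param prefix state-label prefix ("I" or "D").
#' @return list with `state` (per-cell labels), `boundaries` (pseudotime
#'   quantile cut points) and `state_order` (labels by mean pseudotime).
#' @export
assign_progression_states <- function(traj, annotations, n_states = 3L,
                                      exclude_types = c("fibroblast", "EC"),
                                      prefix = "S") {
  stopifnot(inherits(traj, "trajectory"))
  pt <- traj$pseudotime
  excl <- annotations %in% exclude_types
  state <- character(length(pt))
  state[excl] <- paste0("excluded_", annotations[excl])
  inc <- which(!excl)
  if (length(inc)) {
    qs <- quantile(pt[inc], probs = seq(0, 1, length.out = n_states + 1))
    if (length(unique(qs)) < n_states + 1L)
      stop_cfg("too few distinct pseudotime values for %d states", n_states)
    bin <- cut(pt[inc], breaks = qs, include.lowest = TRUE, labels = FALSE)
    state[inc] <- paste0(prefix, bin)
  } else qs <- numeric(0)
  lbl <- unique(state[!excl])
  ord <- lbl[order(vapply(lbl, function(l) mean(pt[state == l]), 0))]
  list(state = state, boundaries = qs, state_order = ord)
}

#' Pseudotime-dependence likelihood-ratio test per gene
#'
#' Compares a smooth pseudotime model (natural cubic spline basis, 3 df,
#' Gaussian working model on the log-normalized scale) against an
#' intercept-only model; p-values from chi-square with 3 df on the
#' likelihood-ratio statistic n*log(RSS0/RSS1). Constant genes get p = 1
#' by convention.
#'
#' @param norm a [normalize_log()] matrix.
#' @param pseudotime per-cell pseudotime covering every cell.
#' @param genes optional symbols to test (default all).
#' @return data.frame: `gene`, `lrt_stat`, `df`, `p`.
#' @export
pseudotime_deg_lrt <- function(norm, pseudotime, genes = NULL) {
  if (anyNA(pseudotime)) stop_cfg("pseudotime undefined for some cells")
  v <- norm$values
  gene_names <- norm$features$symbol
  if (!is.null(genes)) {
    ix <- match(intersect(genes, norm$features$symbol), norm$features$symbol)
    v <- v[, ix, drop = FALSE]
    gene_names <- gene_names[ix]
  }
  y <- as.matrix(v)
  colnames(y) <- gene_names
  n <- nrow(y)
  basis <- splines::ns(pseudotime, df = 3)
  X <- cbind(1, basis)
  qx <- qr(X)
  res1 <- qr.resid(qx, y)
  rss1 <- colSums(res1^2)
  rss0 <- colSums(sweep(y, 2, colMeans(y), "-")^2)
  stat <- ifelse(rss0 > 0 & rss1 > 0, n * log(rss0 / rss1), 0)
  df <- ncol(basis)
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  p[rss0 == 0] <- 1  # constant gene
  data.frame(gene = colnames(y), lrt_stat = stat, df = df, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlap of two DEG sets
#'
#' Returns |A intersect B| / |A| as a percentage, mirroring cross-lineage
#' comparisons such as diffuse-state DEGs overlapping intestinal-state
#' DEGs.
#'
#' @param degs_a,degs_b character vectors; `degs_a` must be nonempty.
#' @return list with `percent` and `intersection`.
#' @export
state_overlap <- function(degs_a, degs_b) {
  a <- unique(degs_a)
  if (!length(a)) stop_cfg("first DEG set is empty; overlap undefined")
  inter <- intersect(a, unique(degs_b))
  list(percent = 100 * length(inter) / length(a), intersection = inter)
}
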