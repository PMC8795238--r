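# Gene-set scoring, signature deconvolution into molecular subtypes, the
# intestinal / EMT / EmyoT tumor grouping, enrichment and ANOVA tests.

#' Default synthetic gene sets
#'
#' Editable stand-ins for the signature lists the analysis consumes: EMT,
#' EmyoT (epithelial-myofibroblast transition: TAGLN, EGR1, MRTFA, SRF,
#' IGFBP5), stemness (embryonic-stem-cell factor targets), intestinal,
#' G1/S, and the CAF subtype signatures (iCAF / myCAF / inCAF). Symbols
#' are chosen from the simulated gene universe; real supplementary-table
#' lists can be dropped in via [read_gmt()].
#'
#' @return named list of gene symbol vectors.
#' @export
default_gene_sets <- function() {
  list(
    EMT = c("VIM", "ZEB1", "SNAI2", "TWIST1", "FOXC2", "FN1"),
    EmyoT = c("TAGLN", "EGR1", "MRTFA", "SRF", "IGFBP5"),
    stemness = c("SOX2", "NANOG", "POU5F1", "MYC", "LGR5", "PROM1"),
    intestinal = c("CDH17", "CDX1", "CDX2", "TFF3", "EPCAM"),
    G1S = c("CCND1", "CDK4", "CDK6", "RB1"),
    iCAF = c("IL6", "IL11", "CXCL1", "CXCL2"),
    myCAF = c("TPM1", "TPM2", "MYL9", "TAGLN", "POSTN"),
    inCAF = c("PDGFRA", "POSTN", "ID1", "ID3")
  )
}

#' Score a gene set per cell
#'
#' Score = mean, over the set's genes, of each gene's z-scored expression;
#' by construction invariant to genes outside the set. Missing genes are
#' reported via an attribute.
#'
#' @param norm a [normalize_log()] matrix (or plain samples x genes matrix
#'   with gene-symbol column names for bulk data).
#' @param set character vector of gene symbols.
#' @param name set name for error messages.
#' @return named numeric per-cell score with attribute `missing_genes`.
#' @export
score_gene_set <- function(norm, set, name = "gene set") {
  if (inherits(norm, "normalized_matrix")) {
    x <- as.matrix(norm$values)
    colnames(x) <- norm$features$symbol
  } else x <- as.matrix(norm)
  present <- intersect(set, colnames(x))
  if (!length(present))
    stop_cfg("no gene of set '%s' present in the matrix", name)
  z <- zscore_cols(x[, present, drop = FALSE])
  out <- rowMeans(z)
  names(out) <- rownames(x)
  attr(out, "missing_genes") <- setdiff(set, present)
  out
}

#' Variance-weighted non-negative deconvolution onto a signature matrix
#'
#' Fits each cell/sample profile onto the signature columns by non-negative
#' least squares, with genes down-weighted by their variance across the
#' reference columns (inverse variance, floor-clamped) so unstable genes
#' contribute less. Weights are normalized to sum to 1; the label is the
#' argmax weight, "ambiguous" on a tie.
#'
#' @param expr samples/cells x genes matrix with symbol column names, or a
#'   [normalize_log()] matrix.
#' @param sig genes x subtypes signature matrix (rownames = symbols,
#'   >= 2 columns, non-negative).
#' @param var_floor clamp on the cross-reference gene variance.
#' @return list with `weights` (samples x subtypes, rows sum to 1 where
#'   defined), `label` (argmax subtype per sample; "ambiguous" on ties, NA
#'   with a flag for all-zero inputs) and `flagged` (all-zero inputs).
#' @export
deconvolve_subtypes <- function(expr, sig, var_floor = 1e-6) {
  if (inherits(expr, "normalized_matrix")) {
    x <- as.matrix(expr$values)
    colnames(x) <- expr$features$symbol
  } else x <- as.matrix(expr)
  sig <- as.matrix(sig)
  if (ncol(sig) < 2L) stop_cfg("signature matrix needs >= 2 subtypes")
  if (any(sig < 0)) stop_cfg("signature entries must be non-negative")
  shared <- intersect(colnames(x), rownames(sig))
  if (length(shared) < 2L) stop_cfg("fewer than 2 shared genes with signature")
  S <- sig[shared, , drop = FALSE]
  Y <- x[, shared, drop = FALSE]
  w <- 1 / pmax(apply(S, 1, var), var_floor)
  sw <- sqrt(w)
  Sw <- S * sw
  n <- nrow(Y)
  W <- matrix(0, n, ncol(S), dimnames = list(rownames(x), colnames(S)))
  flagged <- logical(n)
  label <- character(n)
  for (i in seq_len(n)) {
    y <- Y[i, ]
    if (all(y == 0)) {
      flagged[i] <- TRUE
      label[i] <- NA_character_
      next
    }
    fit <- pracma::lsqnonneg(Sw, y * sw)
    b <- fit$x
    if (sum(b) > 0) b <- b / sum(b)
    W[i, ] <- b
    mx <- which(b == max(b))
    label[i] <- if (length(mx) > 1L) "ambiguous" else colnames(S)[mx]
  }
  list(weights = W, label = label, flagged = flagged)
}

#' Classify tumor cells into intestinal / EMT / EmyoT groups
#'
#' Standardizes the three signature scores across cells and labels each
#' cell by the argmax, with the EmyoT call additionally requiring the
#' EmyoT score to exceed the EMT score (EmyoT cells are myofibroblast-high
#' but EMT-low). Exact ties resolve by priority EmyoT > EMT > intestinal
#' and are flagged.
#'
#' @param scores data.frame or matrix with columns `intestinal`, `EMT`,
#'   `EmyoT` (per-cell signature scores).
#' @return list with `label` (per cell) and `tie` (logical flag).
#' @export
classify_tumor_groups <- function(scores) {
  sc <- as.matrix(scores)
  need <- c("intestinal", "EMT", "EmyoT")
  if (!all(need %in% colnames(sc)))
    stop_cfg("scores must contain columns: %s", paste(need, collapse = ", "))
  z <- zscore_cols(sc[, need, drop = FALSE])
  priority <- c(EmyoT = 3, EMT = 2, intestinal = 1)
  n <- nrow(z)
  label <- character(n)
  tie <- logical(n)
  for (i in seq_len(n)) {
    s <- z[i, ]
    mx <- names(s)[s == max(s)]
    if (length(mx) > 1L) {
      tie[i] <- TRUE
      mx <- mx[which.max(priority[mx])]
    }
    if (mx == "EmyoT" && !(s["EmyoT"] > s["EMT"]) && !tie[i]) mx <- "EMT"
    label[i] <- mx
  }
  list(label = label, tie = tie)
}

#' One-sided hypergeometric enrichment of a DEG set in pathways
#'
#' For each pathway, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap when sampling |deg| genes from the
#' universe. Pathways disjoint from the universe are skipped with a
#' notice; a BH-adjusted column is included.
#'
#' @param deg character vector, subset of `universe`.
#' @param pathways named list of gene sets.
#' @param universe background gene symbols.
#' @return data.frame: `pathway`, `overlap`, `pathway_size`, `p`, `fdr`;
#'   skipped pathways in attribute `skipped`.
#' @export
hypergeometric_enrichment <- function(deg, pathways, universe) {
  deg <- unique(deg)
  universe <- unique(universe)
  if (!all(deg %in% universe)) stop_cfg("deg set must be a subset of the universe")
  skipped <- character(0)
  rows <- list()
  for (nm in names(pathways)) {
    pw <- intersect(pathways[[nm]], universe)
    if (!length(pw)) { skipped <- c(skipped, nm); next }
    k <- length(intersect(deg, pw))
    p <- phyper(k - 1, length(pw), length(universe) - length(pw),
                length(deg), lower.tail = FALSE)
    rows[[nm]] <- data.frame(pathway = nm, overlap = k,
                             pathway_size = length(pw), p = p,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pathway = character(), overlap = integer(),
                      pathway_size = integer(), p = numeric())
  out$fdr <- p.adjust(out$p, "BH")
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' One-way ANOVA of scores across groups
#'
#' @param scores numeric vector.
#' @param groups group labels; >= 2 groups, each with >= 2 members.
#' @return list with `F` and `p`.
#' @export
compare_scores_anova <- function(scores, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop_cfg("need >= 2 groups")
  sizes <- table(g)
  if (any(sizes < 2L))
    stop_cfg("singleton group(s): %s",
             paste(names(sizes)[sizes < 2], collapse = ", "))
  fit <- aov(scores ~ g)
  s <- summary(fit)[[1]]
  Fv <- s[["F value"]][1]
  p <- s[["Pr(>F)"]][1]
  if (!is.finite(Fv)) { Fv <- 0; p <- 1 }  # identical group means, zero residual
  list(F = Fv, p = p)
}
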