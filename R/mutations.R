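# Per-cell hotspot VAF, variant filtering, mutation tabulation, Fisher
# enrichment.

#' Per-cell variant allele frequencies
#'
#' VAF = alt / (alt + ref) wherever total depth is positive; (cell,
#' variant) pairs with zero depth are not covered and reported as NA. A
#' cell is flagged mutated at a variant when it has at least `min_alt`
#' alt reads.
#'
#' @param ac an [allele_counts()] object.
#' @param min_alt alt-read floor for the mutated flag.
#' @return list with `vaf` (dense cells x variants matrix, NA where not
#'   covered) and `mutated` (logical matrix).
#' @export
tabulate_vaf <- function(ac, min_alt = 1L) {
  stopifnot(inherits(ac, "allele_counts"))
  ref <- as.matrix(ac$ref)
  alt <- as.matrix(ac$alt)
  if (any(ref < 0) || any(alt < 0)) stop_cfg("negative allele counts")
  depth <- ref + alt
  vaf <- ifelse(depth > 0, alt / depth, NA_real_)
  dimnames(vaf) <- dimnames(alt)
  list(vaf = vaf, mutated = alt >= min_alt & depth > 0)
}

#' Filter allele counts to informative catalog hotspots
#'
#' Keeps only catalog variants, drops variants with zero alt reads across
#' all cells, and removes immune cells from downstream tabulation.
#'
#' @param ac an [allele_counts()] object.
#' @param catalog variant catalog (nonempty; defaults to the one carried by
#'   `ac`).
#' @param annotations per-cell type labels aligned with `ac` rows.
#' @param immune_types labels treated as immune and excluded.
#' @return filtered [allele_counts()].
#' @export
filter_hotspot_variants <- function(ac, catalog = ac$catalog, annotations,
                                    immune_types = "immune") {
  stopifnot(inherits(ac, "allele_counts"))
  if (is.null(catalog) || nrow(catalog) == 0L) stop_cfg("empty variant catalog")
  keep_v <- colnames(ac$alt) %in% catalog$variant_id
  keep_v <- keep_v & Matrix::colSums(ac$alt) > 0
  keep_c <- !(annotations %in% immune_types)
  if (!any(keep_v)) {
    empty <- ac$alt[keep_c, 0, drop = FALSE]
    return(allele_counts(empty, empty, catalog[0, , drop = FALSE]))
  }
  allele_counts(ac$ref[keep_c, keep_v, drop = FALSE],
                ac$alt[keep_c, keep_v, drop = FALSE],
                catalog[match(colnames(ac$alt)[keep_v], catalog$variant_id), ,
                        drop = FALSE])
}

#' Mutated-cell counts by gene and cell type
#'
#' Counts cells with at least one alt read per gene per cell type;
#' unannotated cells are counted under "unassigned". When `lesion` is
#' given, a per-gene adjacent-vs-cancer breakdown is added.
#'
#' @param ac a (filtered) [allele_counts()] object.
#' @param annotations per-cell type labels (NA allowed).
#' @param lesion optional per-cell lesion labels (e.g. adjacent / cancer).
#' @return list with `by_celltype` (genes x types count matrix) and
#'   `by_lesion` (genes x lesions, or NULL).
#' @export
mutation_by_celltype <- function(ac, annotations, lesion = NULL) {
  stopifnot(inherits(ac, "allele_counts"))
  ann <- as.character(annotations)
  ann[is.na(ann) | ann == ""] <- "unassigned"
  genes <- unique(ac$catalog$gene)
  types <- sort(unique(ann))
  mut <- as.matrix(ac$alt) >= 1
  out <- matrix(0L, length(genes), length(types),
                dimnames = list(genes, types))
  for (g in genes) {
    vix <- which(ac$catalog$gene == g)
    cell_mut <- rowSums(mut[, vix, drop = FALSE]) > 0
    out[g, ] <- as.integer(tapply(cell_mut, factor(ann, types), sum))
  }
  out[is.na(out)] <- 0L
  by_lesion <- NULL
  if (!is.null(lesion)) {
    les <- sort(unique(as.character(lesion)))
    by_lesion <- matrix(0L, length(genes), length(les),
                        dimnames = list(genes, les))
    for (g in genes) {
      vix <- which(ac$catalog$gene == g)
      cell_mut <- rowSums(mut[, vix, drop = FALSE]) > 0
      by_lesion[g, ] <- as.integer(tapply(cell_mut, factor(lesion, les), sum))
    }
    by_lesion[is.na(by_lesion)] <- 0L
  }
  list(by_celltype = out, by_lesion = by_lesion)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric two-sided p (probability-mass criterion); the odds
#' ratio is the sample OR with a Haldane 0.5 correction applied when any
#' cell is zero. A zero margin makes the test degenerate: p = 1 with a
#' flag.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with `odds_ratio`, `p`, `degenerate`.
#' @export
enrichment_fisher <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L))) stop_cfg("need a 2x2 table")
  if (any(tb < 0) || any(tb != round(tb))) stop_cfg("counts must be non-negative integers")
  degen <- any(rowSums(tb) == 0) || any(colSums(tb) == 0)
  if (degen) {
    or <- (tb[1, 1] + 0.5) * (tb[2, 2] + 0.5) /
      ((tb[1, 2] + 0.5) * (tb[2, 1] + 0.5))
    return(list(odds_ratio = or, p = 1, degenerate = TRUE))
  }
  p <- fisher.test(tb)$p.value
  if (any(tb == 0)) {
    or <- (tb[1, 1] + 0.5) * (tb[2, 2] + 0.5) /
      ((tb[1, 2] + 0.5) * (tb[2, 1] + 0.5))
  } else {
    or <- tb[1, 1] * tb[2, 2] / (tb[1, 2] * tb[2, 1])
  }
  list(odds_ratio = or, p = p, degenerate = FALSE)
}
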