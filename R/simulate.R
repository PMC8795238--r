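# Synthetic-data generator: every downstream stage is exercised against
# data with planted, recoverable ground truth.

# Mitochondrial / hemoglobin symbols used for the QC fraction rule.
MITO_SYMBOLS <- paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "ATP6", "ATP8",
                                "CO3", "ND3", "ND4L", "ND4", "ND5", "ND6",
                                "CYB", "RNR1", "RNR2"))
HB_SYMBOLS <- c("HBA1", "HBA2", "HBB", "HBD", "HBG1")

#' Default marker table for the gastric atlas cell types
#'
#' Literature-based lineage markers: endothelial (PLVAP/KDR/PTPRB),
#' enteroendocrine (CHGA/GAST/PROX1), fibroblast (MMP2/PDGFRA/MYL9/FN1/CAV1),
#' gland mucous (MUC6/TFF2), intestinal metaplasia (TFF3/CDX1/CDX2),
#' metaplastic stem-like (OLFM4/REG1A/CLDN3), pit mucous (GKN1/GKN2/MUC5AC),
#' tumor (EPCAM/CDH17/COL3A1/PDGFRB) and immune (PTPRC plus pan-leukocyte
#' genes).
#'
#' @return named list mapping cell type to marker gene symbols.
#' @export
default_marker_table <- function() {
  list(
    EC          = c("PLVAP", "KDR", "PTPRB"),
    enteroendocrine = c("CHGA", "GAST", "PROX1"),
    fibroblast  = c("MMP2", "PDGFRA", "MYL9", "FN1", "CAV1"),
    GMC         = c("MUC6", "TFF2"),
    IM          = c("TFF3", "CDX1", "CDX2"),
    MSC         = c("OLFM4", "REG1A", "CLDN3"),
    PMC         = c("GKN1", "GKN2", "MUC5AC"),
    tumor       = c("EPCAM", "CDH17", "COL3A1", "PDGFRB"),
    immune      = c("PTPRC", "CD3D", "CD52")
  )
}

# Extra symbols planted in the universe so CNV / mutation / signature stages
# can address real gene names (positions are synthetic).
EXTRA_SYMBOLS <- c("CCND1", "CDK4", "CDK6", "CDKN2A", "RB1", "CD44", "GATA4",
                   "GATA6", "KLF5", "KRAS", "ARID1A", "SMAD4", "RAC1",
                   "TAGLN", "EGR1", "MRTFA", "SRF", "IGFBP5", "TPM1", "TPM2",
                   "POSTN", "IL6", "IL11", "CXCL1", "CXCL2", "ID1", "ID3",
                   "VIM", "ZEB1", "SNAI2", "TWIST1", "FOXC2",
                   "SOX2", "NANOG", "POU5F1", "MYC", "LGR5", "PROM1")

#' Simulation configuration
#'
#' Bundles everything [simulate_cells()] and its companions need: per-type
#' cell counts, per-type mean-expression programs with marker elevation, an
#' optional differentiation lineage (piecewise-linear interpolation between
#' consecutive type programs at a latent time in [0, 1]), planted QC-rule
#' violations, copy-number blocks, and hotspot-mutation carriers.
#'
#' Counts are negative binomial with a shared overdispersion and log-normal
#' per-cell library size; these are the study conditions every acceptance
#' check runs under.
#'
#' @param n_genes size of the gene universe.
#' @param n_cells_per_type named integer vector, cells per type; names must
#'   appear in `marker_assignments`.
#' @param marker_assignments named list, cell type -> marker symbols placed
#'   in the universe and elevated `marker_fold`-fold in that type's program.
#' @param marker_fold fold elevation of a type's markers over base.
#' @param lineage_spec `NULL` or a list with `types` (ordered program names,
#'   benign first) and `n_cells`; lineage cells get latent times uniform in
#'   [0, 1] and convexly interpolated programs.
#' @param qc_violation_counts named counts of planted low-quality cells, any
#'   of `low_sd`, `high_zero`, `high_mito`, `low_umi`, `high_umi`.
#' @param cnv_blocks list of blocks from [cnv_block()].
#' @param mutation_spec `NULL` or data.frame with columns `variant_id`,
#'   `gene`, `position`, `protein_change`, `carrier_types`
#'   (comma-separated), `carrier_prob` (fraction of carrier-type cells that
#'   carry), `vaf` (expected alt-read fraction in carriers), `mean_depth`.
#' @param cell_type_programs optional genes x types matrix of relative mean
#'   expression overriding the generated programs (columns must cover
#'   every configured type); lets two simulations share one biology while
#'   drawing independent noise.
#' @param dispersion negative-binomial overdispersion (NB size = 1/dispersion),
#'   shared across genes.
#' @param mean_umi,libsize_sdlog log-normal library-size model: median total
#'   UMI and sdlog.
#' @param seed integer; the single seed behind all generator randomness.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1200L,
                       n_cells_per_type = c(GMC = 120L, PMC = 80L, MSC = 100L,
                                            tumor = 100L, fibroblast = 60L,
                                            EC = 50L, immune = 90L),
                       marker_assignments = default_marker_table(),
                       marker_fold = 8,
                       lineage_spec = NULL,
                       qc_violation_counts = c(low_sd = 0L, high_zero = 0L,
                                               high_mito = 0L, low_umi = 0L,
                                               high_umi = 0L),
                       cnv_blocks = list(),
                       mutation_spec = NULL,
                       cell_type_programs = NULL,
                       dispersion = 0.4,
                       mean_umi = 3000,
                       libsize_sdlog = 0.25,
                       seed = 1L) {
  if (n_genes < 100L) stop_cfg("gene universe too small (need >= 100 genes)")
  if (length(n_cells_per_type) < 1L || is.null(names(n_cells_per_type)))
    stop_cfg("n_cells_per_type must be a named vector with at least one type")
  if (any(n_cells_per_type < 0)) stop_cfg("cell counts must be >= 0")
  if (dispersion <= 0) stop_cfg("dispersion must be > 0")
  types <- names(n_cells_per_type)
  missing_types <- setdiff(types, names(marker_assignments))
  if (length(missing_types))
    stop_cfg("no marker assignment for type(s): %s",
             paste(missing_types, collapse = ", "))
  if (!is.null(lineage_spec)) {
    if (!all(lineage_spec$types %in% names(marker_assignments)))
      stop_cfg("lineage types must have marker assignments")
    if (length(lineage_spec$types) < 2L)
      stop_cfg("a lineage needs at least two endpoint programs")
  }
  qdef <- c(low_sd = 0L, high_zero = 0L, high_mito = 0L,
            low_umi = 0L, high_umi = 0L)
  bad <- setdiff(names(qc_violation_counts), names(qdef))
  if (length(bad)) stop_cfg("unknown QC violation rule(s): %s",
                            paste(bad, collapse = ", "))
  qdef[names(qc_violation_counts)] <- as.integer(qc_violation_counts)
  if (any(qdef < 0)) stop_cfg("violation counts must be >= 0")
  for (b in cnv_blocks) {
    if (b$multiplier <= 0) stop_cfg("CNV multiplier must be > 0")
    if (min(b$genes) < 1L || max(b$genes) > n_genes)
      stop_cfg("CNV block gene range outside universe")
  }
  if (!is.null(mutation_spec)) {
    need <- c("variant_id", "gene", "position", "protein_change",
              "carrier_types", "carrier_prob", "vaf", "mean_depth")
    miss <- setdiff(need, names(mutation_spec))
    if (length(miss)) stop_cfg("mutation_spec lacks column(s): %s",
                               paste(miss, collapse = ", "))
    if (anyDuplicated(mutation_spec$variant_id))
      stop_cfg("variant ids must be unique")
    if (any(mutation_spec$carrier_prob < 0 | mutation_spec$carrier_prob > 1) ||
        any(mutation_spec$vaf < 0 | mutation_spec$vaf > 1))
      stop_cfg("carrier_prob and vaf must lie in [0, 1]")
  }

  cfg <- structure(list(
    n_genes = as.integer(n_genes),
    n_cells_per_type = n_cells_per_type,
    marker_assignments = marker_assignments,
    marker_fold = marker_fold,
    lineage_spec = lineage_spec,
    qc_violation_counts = qdef,
    cnv_blocks = cnv_blocks,
    mutation_spec = mutation_spec,
    dispersion = dispersion,
    mean_umi = mean_umi,
    libsize_sdlog = libsize_sdlog,
    seed = as.integer(seed)
  ), class = "sim_config")
  cfg$features <- build_features(cfg)
  if (is.null(cell_type_programs)) {
    cfg$programs <- build_programs(cfg)
  } else {
    if (nrow(cell_type_programs) != cfg$n_genes ||
        !all(types %in% colnames(cell_type_programs)))
      stop_cfg("cell_type_programs must be genes x types covering every type")
    if (any(cell_type_programs < 0)) stop_cfg("program means must be >= 0")
    cfg$programs <- sweep(cell_type_programs, 2,
                          colSums(cell_type_programs), "/")
  }
  cfg
}

#' Describe a planted copy-number block
#'
#' @param genes integer vector of feature-row indices covered by the event
#'   (contiguous in genome order for a realistic block).
#' @param multiplier mean-expression multiplier (> 1 amplification,
#'   < 1 deletion); must be positive.
#' @param carriers character vector of carrier cell types.
#' @return list consumed by [sim_config()].
#' @export
cnv_block <- function(genes, multiplier, carriers) {
  if (multiplier <= 0) stop_cfg("CNV multiplier must be > 0")
  list(genes = as.integer(genes), multiplier = multiplier,
       carriers = as.character(carriers))
}

#' Default hotspot variant catalog for simulations
#'
#' A small synthetic stand-in for a pan-cancer hotspot catalog, centred on
#' the CCND1 T286/P287 gain-of-function sites carried by the metaplastic
#' stem-like (MSC) -> tumor lineage, plus cell-cycle and MAPK entries and
#' deliberately uncarried decoys.
#'
#' @param carrier_types cell types carrying the CCND1 hotspots.
#' @param carrier_prob fraction of carrier-type cells that carry.
#' @param vaf expected alt-read fraction in carrier cells.
#' @param mean_depth mean Poisson read depth per (cell, variant).
#' @return data.frame usable as `mutation_spec` in [sim_config()].
#' @export
default_mutation_spec <- function(carrier_types = c("MSC", "tumor"),
                                  carrier_prob = 0.4, vaf = 0.5,
                                  mean_depth = 8) {
  carriers <- paste(carrier_types, collapse = ",")
  data.frame(
    variant_id = c("CCND1_T286", "CCND1_P287", "CDK4_R24", "KRAS_G12",
                   "RAC1_P29", "CDKN2A_R80", "RB1_R455", "SMAD4_R361"),
    gene = c("CCND1", "CCND1", "CDK4", "KRAS", "RAC1", "CDKN2A", "RB1",
             "SMAD4"),
    position = c(69641000, 69641003, 58145430, 25398284, 57421235, 21971120,
                 48941648, 48604676),
    protein_change = c("T286", "P287", "R24", "G12", "P29", "R80", "R455",
                       "R361"),
    carrier_types = c(carriers, carriers, carriers, "tumor", "tumor",
                      "tumor", "", ""),
    carrier_prob = c(carrier_prob, carrier_prob, carrier_prob / 2, 0.3, 0.2,
                     0.2, 0, 0),
    vaf = vaf,
    mean_depth = mean_depth,
    pathway = c("cell_cycle", "cell_cycle", "cell_cycle", "MAPK", "MAPK",
                "cell_cycle", "cell_cycle", "TGFB"),
    stringsAsFactors = FALSE
  )
}

# Gene universe: 10 synthetic chromosomes of contiguous gene runs, 1-based
# start coordinates, marker/extra/mito/hemoglobin symbols spread evenly.
build_features <- function(cfg) {
  n <- cfg$n_genes
  sym <- sprintf("GENE%05d", seq_len(n))
  special <- unique(c(unlist(cfg$marker_assignments), EXTRA_SYMBOLS,
                      MITO_SYMBOLS, HB_SYMBOLS))
  if (length(special) > n - 10L) stop_cfg("gene universe too small for markers")
  idx <- round(seq(3L, n - 2L, length.out = length(special)))
  idx <- unique(idx)
  # even spacing can collide only if n is barely large enough; validated above
  stopifnot(length(idx) == length(special))
  sym[idx] <- special
  n_chrom <- 10L
  chrom <- paste0("chr", rep(seq_len(n_chrom), each = ceiling(n / n_chrom)))[seq_len(n)]
  start <- unlist(lapply(split(seq_len(n), factor(chrom, unique(chrom))),
                         function(ix) seq_along(ix) * 10000L),
                  use.names = FALSE)
  data.frame(
    id = sprintf("ENSG%08d", seq_len(n)),
    symbol = sym,
    chromosome = chrom,
    start = start,
    mito = sym %in% MITO_SYMBOLS,
    hemoglobin = sym %in% HB_SYMBOLS,
    stringsAsFactors = FALSE
  )
}

# Per-type relative mean-expression programs (columns sum to 1), reproducible
# from the config seed alone. Each type elevates its markers marker_fold-fold
# and a random 8% of genes 2-6-fold to give clusters real structure.
build_programs <- function(cfg) {
  set.seed(cfg$seed + 77L)
  n <- cfg$n_genes
  types <- names(cfg$marker_assignments)
  base <- rgamma(n, shape = 1.2, rate = 1.2)
  base[cfg$features$mito] <- base[cfg$features$mito] * 2  # modest mito content
  progs <- matrix(base, n, length(types), dimnames = list(cfg$features$symbol, types))
  for (ty in types) {
    specific <- sample.int(n, size = max(10L, round(0.08 * n)))
    progs[specific, ty] <- progs[specific, ty] * runif(length(specific), 2, 6)
    mk <- cfg$marker_assignments[[ty]]
    hit <- match(mk, cfg$features$symbol)
    if (anyNA(hit)) stop_cfg("marker symbol(s) absent from gene universe: %s",
                             paste(mk[is.na(hit)], collapse = ", "))
    progs[hit, ty] <- pmax(progs[hit, ty], mean(base)) * cfg$marker_fold
  }
  sweep(progs, 2, colSums(progs), "/")
}

#' Simulate a UMI count matrix with known ground truth
#'
#' Draws negative-binomial counts per cell from its type program (lineage
#' cells from the convex interpolation of consecutive endpoint programs at
#' their latent time), applies planted copy-number multipliers for carrier
#' types, appends planted low-quality cells violating each configured QC
#' rule, and records everything in a truth object.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a count-matrix object, see
#'   [count_matrix()]) and `truth` (data.frame: `cell`, `true_type`,
#'   `true_latent_time` (NA off-lineage), `true_stage`, `true_qc_fail`
#'   (comma-separated rule ids, "" if clean), plus attribute matrices
#'   `true_cnv` (cells x blocks logical) and `true_carrier`
#'   (cells x variants logical)).
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  feats <- config$features
  progs <- config$programs
  n_genes <- config$n_genes
  size <- 1 / config$dispersion

  types <- rep(names(config$n_cells_per_type), config$n_cells_per_type)
  latent <- rep(NA_real_, length(types))
  stage <- rep(NA_integer_, length(types))
  lin <- config$lineage_spec
  if (!is.null(lin)) {
    t_lat <- sort(runif(lin$n_cells))
    m <- length(lin$types)
    seg <- pmin(floor(t_lat * (m - 1)), m - 2)
    w <- t_lat * (m - 1) - seg
    lin_types <- lin$types[round(t_lat * (m - 1)) + 1]
    types <- c(types, lin_types)
    latent <- c(latent, t_lat)
    stage <- c(stage, pmin(ceiling(t_lat * m + 1e-12), m))
    stage[is.na(latent)] <- NA_integer_
  }
  n_cells <- length(types)
  if (n_cells == 0L) stop_cfg("configuration yields zero cells")

  # per-cell mean program
  mu_rel <- progs[, types, drop = FALSE]
  if (!is.null(lin)) {
    lin_ix <- which(!is.na(latent))
    P <- progs[, lin$types, drop = FALSE]
    m <- length(lin$types)
    for (k in seq_along(lin_ix)) {
      t0 <- latent[lin_ix[k]]
      s <- min(floor(t0 * (m - 1)), m - 2)
      w <- t0 * (m - 1) - s
      mu_rel[, lin_ix[k]] <- (1 - w) * P[, s + 1] + w * P[, s + 2]
    }
  }

  # planted CNV multipliers
  true_cnv <- matrix(FALSE, n_cells, length(config$cnv_blocks))
  for (bi in seq_along(config$cnv_blocks)) {
    b <- config$cnv_blocks[[bi]]
    carrier <- types %in% b$carriers
    true_cnv[, bi] <- carrier
    if (any(carrier))
      mu_rel[b$genes, carrier] <- mu_rel[b$genes, carrier] * b$multiplier
  }

  libsize <- rlnorm(n_cells, log(config$mean_umi), config$libsize_sdlog)
  counts <- matrix(0L, n_cells, n_genes)
  for (c_i in seq_len(n_cells)) {
    mu <- mu_rel[, c_i] / sum(mu_rel[, c_i]) * libsize[c_i]
    counts[c_i, ] <- rnbinom(n_genes, size = size, mu = mu)
  }

  qc_fail <- character(n_cells)

  # planted QC violations appended as extra cells of the first type's program
  qv <- config$qc_violation_counts
  base_type <- names(config$n_cells_per_type)[1]
  prob <- progs[, base_type]
  add_cells <- function(counts, n_new) rbind(counts, matrix(0L, n_new, n_genes))
  mito_ix <- which(feats$mito)
  nonmito_top <- order(prob, decreasing = TRUE)
  nonmito_top <- setdiff(nonmito_top, c(mito_ix, which(feats$hemoglobin)))
  for (rule in names(qv)) {
    for (k in seq_len(qv[[rule]])) {
      counts <- add_cells(counts, 1L)
      i <- nrow(counts)
      row <- switch(rule,
        low_umi = as.integer(rmultinom(1, 50, prob)),
        high_umi = as.integer(rmultinom(1, 30000, prob)),
        low_sd = rep(1L, n_genes),
        high_zero = {
          r <- integer(n_genes)
          keep <- nonmito_top[seq_len(floor(0.05 * n_genes))]
          r[keep] <- as.integer(rmultinom(1, 2000, prob[keep] + 1e-9))
          r
        },
        high_mito = {
          r <- as.integer(rmultinom(1, 1500, prob))
          r[mito_ix] <- r[mito_ix] + as.integer(rmultinom(1, 1500, rep(1, length(mito_ix))))
          r
        })
      counts[i, ] <- row
      types <- c(types, base_type)
      latent <- c(latent, NA_real_)
      stage <- c(stage, NA_integer_)
      qc_fail <- c(qc_fail, rule)
      true_cnv <- rbind(true_cnv, rep(FALSE, ncol(true_cnv)))
    }
  }
  n_cells <- nrow(counts)
  barcodes <- sprintf("cell_%05d", seq_len(n_cells))
  dimnames(counts) <- list(barcodes, feats$symbol)

  # carrier draw recorded here so allele-count simulation is consistent
  ms <- config$mutation_spec
  true_carrier <- matrix(FALSE, n_cells, if (is.null(ms)) 0L else nrow(ms),
                         dimnames = list(barcodes,
                                         if (is.null(ms)) NULL else ms$variant_id))
  if (!is.null(ms)) {
    for (vi in seq_len(nrow(ms))) {
      ctypes <- strsplit(ms$carrier_types[vi], ",")[[1]]
      eligible <- types %in% ctypes & qc_fail == ""
      true_carrier[, vi] <- eligible & rbinom(n_cells, 1, ms$carrier_prob[vi]) == 1
    }
  }

  truth <- data.frame(cell = barcodes, true_type = types,
                      true_latent_time = latent, true_stage = stage,
                      true_qc_fail = qc_fail, stringsAsFactors = FALSE)
  attr(truth, "true_cnv") <- true_cnv
  attr(truth, "true_carrier") <- true_carrier

  cm <- count_matrix(methods::as(counts, "CsparseMatrix"), feats)
  list(counts = cm, truth = truth)
}

#' Simulate per-cell allele counts at hotspot variants
#'
#' Every cell is covered at each catalog variant with Poisson depth; carrier
#' cells (recorded in the truth from [simulate_cells()]) draw alt reads
#' binomially at the configured expected VAF, non-carriers get reference
#' reads only. Zero-depth (cell, variant) pairs are absent, i.e. not
#' covered.
#'
#' @param truth truth object from [simulate_cells()] run with `config`.
#' @param config the same [sim_config()]; must have a `mutation_spec`.
#' @return [allele_counts()] object (paired sparse ref/alt matrices plus the
#'   variant catalog).
#' @export
simulate_allele_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  ms <- config$mutation_spec
  if (is.null(ms)) stop_cfg("config has no mutation_spec")
  carrier <- attr(truth, "true_carrier")
  if (is.null(carrier) || !identical(colnames(carrier), ms$variant_id))
    stop_cfg("truth does not match this config's mutation_spec")
  set.seed(config$seed + 1L)
  n_cells <- nrow(truth)
  n_var <- nrow(ms)
  ref <- matrix(0L, n_cells, n_var,
                dimnames = list(truth$cell, ms$variant_id))
  alt <- ref
  for (vi in seq_len(n_var)) {
    depth <- rpois(n_cells, ms$mean_depth[vi])
    a <- integer(n_cells)
    is_c <- carrier[, vi]
    a[is_c] <- rbinom(sum(is_c), depth[is_c], ms$vaf[vi])
    alt[, vi] <- a
    ref[, vi] <- depth - a
  }
  allele_counts(methods::as(ref, "CsparseMatrix"),
                methods::as(alt, "CsparseMatrix"),
                catalog = ms)
}

#' Simulate a bulk expression cohort with group-dependent survival
#'
#' Sample expression is a convex mixture of cell-type programs (library-
#' scaled, log1p), plus a per-batch location/scale shift and Gaussian noise.
#' Survival times are exponential with a per-group hazard under independent
#' exponential censoring.
#'
#' @param config a [sim_config()] (supplies the type programs and seed).
#' @param groups named list: group -> named mixture weights over cell types
#'   (normalized internally).
#' @param n_per_group named integer vector of samples per group.
#' @param hazards named positive per-group event hazards (events/month).
#' @param censor_hazard independent censoring hazard; 0 disables censoring.
#' @param batches number of batches (assigned round-robin).
#' @param batch_shift,batch_scale_sd per-batch location shift magnitude and
#'   log-scale sd; 0 disables batch effects.
#' @param noise_sd Gaussian noise on the log scale.
#' @return list with `expr` (samples x genes matrix, log scale), `samples`
#'   (data.frame: sample, group, batch, time, event) and `truth` (the
#'   mixture weights used).
#' @export
simulate_bulk_cohort <- function(config, groups, n_per_group, hazards,
                                 censor_hazard = 0.005, batches = 2L,
                                 batch_shift = 1, batch_scale_sd = 0.1,
                                 noise_sd = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  if (length(groups) < 1L) stop_cfg("need at least one group")
  if (!all(names(groups) %in% names(hazards)) ||
      !all(names(groups) %in% names(n_per_group)))
    stop_cfg("groups, hazards and n_per_group must share names")
  if (any(unlist(hazards) <= 0)) stop_cfg("hazards must be > 0")
  set.seed(config$seed + 2L)
  progs <- config$programs
  grp <- rep(names(groups), n_per_group[names(groups)])
  n <- length(grp)
  batch <- paste0("batch", (seq_len(n) - 1L) %% batches + 1L)
  shift <- setNames(rnorm(batches, 0, batch_shift), unique(batch))
  scl <- setNames(exp(rnorm(batches, 0, batch_scale_sd)), unique(batch))
  expr <- matrix(0, n, nrow(progs),
                 dimnames = list(sprintf("sample_%04d", seq_len(n)),
                                 rownames(progs)))
  for (i in seq_len(n)) {
    w <- unlist(groups[[grp[i]]])
    w <- w / sum(w)
    mix <- as.numeric(progs[, names(w), drop = FALSE] %*% w)
    base <- log1p(mix * 1e4)
    expr[i, ] <- base * scl[batch[i]] + shift[batch[i]] + rnorm(nrow(progs), 0, noise_sd)
  }
  ev_time <- rexp(n, rate = unlist(hazards)[grp])
  if (censor_hazard > 0) {
    cens <- rexp(n, censor_hazard)
  } else cens <- rep(Inf, n)
  time <- pmin(ev_time, cens)
  event <- as.integer(ev_time <= cens)
  samples <- data.frame(sample = rownames(expr), group = grp, batch = batch,
                        time = time, event = event, stringsAsFactors = FALSE)
  list(expr = expr, samples = samples, truth = groups)
}

#' Simulate aligned stain channels with planted co-positive regions
#'
#' Channels are background noise with rectangular high-intensity regions
#' planted on a tile grid, so per-tile positivity and per-pair
#' co-positivity are known exactly.
#'
#' @param width,height image size in pixels.
#' @param n_cols,n_rows tile grid (defaults mirror the 45 x 34 = 1530-tile
#'   layout sized to a tumor cell).
#' @param channels channel names.
#' @param regions list of lists with `channels`, `cols` (tile column range),
#'   `rows` (tile row range), and optional `intensity` (default 0.9).
#' @param background,noise_sd background intensity model.
#' @param seed integer seed.
#' @return list with `images` (named list of height x width matrices in
#'   [0,1]), `grid` (the [grid_tiles()] object) and `truth` (tiles x
#'   channels logical positivity matrix).
#' @export
simulate_ihc <- function(width = 450L, height = 340L, n_cols = 45L,
                         n_rows = 34L,
                         channels = c("MRTFA", "SRF", "IGFBP5"),
                         regions = list(), background = 0.05,
                         noise_sd = 0.02, seed = 1L) {
  grid <- grid_tiles(width, height, n_cols, n_rows)
  set.seed(seed)
  truth <- matrix(FALSE, nrow(grid$tiles), length(channels),
                  dimnames = list(NULL, channels))
  images <- lapply(channels, function(ch) {
    pmin(pmax(matrix(rnorm(width * height, background, noise_sd),
                     height, width), 0), 1)
  })
  names(images) <- channels
  for (rg in regions) {
    if (min(rg$cols) < 1L || max(rg$cols) > n_cols ||
        min(rg$rows) < 1L || max(rg$rows) > n_rows)
      stop_cfg("planted region outside the tile grid")
    if (!all(rg$channels %in% channels))
      stop_cfg("region names unknown channel(s)")
    tiles <- which(grid$tiles$col %in% rg$cols & grid$tiles$row %in% rg$rows)
    intensity <- rg$intensity %||% 0.9
    for (ch in rg$channels) {
      truth[tiles, ch] <- TRUE
      for (ti in tiles) {
        b <- grid$tiles[ti, ]
        images[[ch]][b$y0:b$y1, b$x0:b$x1] <-
          pmin(intensity + rnorm((b$y1 - b$y0 + 1) * (b$x1 - b$x0 + 1),
                                 0, noise_sd), 1)
      }
    }
  }
  list(images = images, grid = grid, truth = truth)
}
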