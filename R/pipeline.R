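# Configuration-driven orchestration of all stages on synthetic data.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] for the synthetic input.
#' @param stages character subset of
#'   c("qc", "annotate", "cnv", "trajectory", "mutations", "signatures",
#'     "cohort", "ihc"); simulation always runs first when any stage needs
#'   it. Order of execution follows stage dependencies, not this vector.
#' @param qc a [qc_config()].
#' @param cluster a [cluster_config()].
#' @param hvg an [hvg_config()].
#' @param n_states progression states for the trajectory stage.
#' @param seed global seed; stage seeds derive from it.
#' @param out_dir optional directory; when given, stage tables are written
#'   as TSV under it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("qc", "annotate", "cnv", "trajectory",
                                       "mutations", "signatures", "cohort",
                                       "ihc"),
                            qc = qc_config(), cluster = cluster_config(),
                            hvg = hvg_config(), n_states = 3L,
                            seed = sim$seed, out_dir = NULL) {
  known <- c("qc", "annotate", "cnv", "trajectory", "mutations",
             "signatures", "cohort", "ihc")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_cfg("unknown stage(s): %s", paste(bad, collapse = ", "))
  structure(list(sim = sim, stages = stages, qc = qc, cluster = cluster,
                 hvg = hvg, n_states = as.integer(n_states),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the synthetic atlas pipeline end to end
#'
#' Executes the enabled stages in dependency order (simulate -> qc ->
#' annotate -> {cnv, trajectory, mutations, signatures} -> cohort -> ihc)
#' and returns every stage result plus a manifest of per-stage row counts
#' and seeds. A failed stage halts with the stage name in the error;
#' rerunning with the same config reproduces identical manifest counts.
#'
#' @param config a [pipeline_config()].
#' @return list with one entry per executed stage and a `manifest`
#'   data.frame (stage, rows, seed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  res <- list()
  manifest <- list()
  note <- function(stage, rows) {
    manifest[[stage]] <<- data.frame(stage = stage, rows = rows,
                                     seed = config$seed)
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  if (length(st)) {
    res$sim <- run_stage("simulate", function() simulate_cells(config$sim))
    note("simulate", nrow(res$sim$truth))
  }
  if ("qc" %in% st) {
    res$qc <- run_stage("qc", function() filter_cells(res$sim$counts, config$qc))
    res$norm <- normalize_log(res$qc$kept)
    note("qc", nrow(res$qc$kept$values))
  }
  needs_clusters <- any(c("annotate", "cnv", "trajectory", "signatures") %in% st)
  if (needs_clusters) {
    res$hvg <- run_stage("annotate", function() select_hvg(res$norm, config$hvg))
    res$clust <- run_stage("annotate", function()
      embed_and_cluster(res$norm, res$hvg, config$cluster))
    res$types <- run_stage("annotate", function()
      assign_cell_types(res$norm, res$clust$clusters,
                        config$sim$marker_assignments))
    note("annotate", length(unique(res$clust$clusters)))
  }
  if ("cnv" %in% st) {
    ref_cells <- rownames(res$norm$values)[res$types$cell_type %in%
                                             c("GMC", "PMC", "EC", "fibroblast")]
    res$cnv <- run_stage("cnv", function()
      infer_cnv_scores(res$norm, ref_cells))
    note("cnv", length(res$cnv$burden))
  }
  if ("trajectory" %in% st) {
    res$traj <- run_stage("trajectory", function()
      build_trajectory(res$norm, res$hvg, root_types = c("GMC", "enteroendocrine"),
                       annotations = res$types$cell_type, seed = config$seed))
    res$states <- run_stage("trajectory", function()
      assign_progression_states(res$traj, res$types$cell_type,
                                n_states = config$n_states))
    note("trajectory", length(res$traj$pseudotime))
  }
  if ("mutations" %in% st && !is.null(config$sim$mutation_spec)) {
    ac <- run_stage("mutations", function()
      simulate_allele_counts(res$sim$truth, config$sim))
    kept <- res$qc$report$kept
    ac_kept <- allele_counts(ac$ref[kept, , drop = FALSE],
                             ac$alt[kept, , drop = FALSE], ac$catalog)
    res$ac <- run_stage("mutations", function()
      filter_hotspot_variants(ac_kept, annotations = res$types$cell_type))
    res$vaf <- tabulate_vaf(res$ac)
    note("mutations", ncol(res$ac$alt))
  }
  if ("signatures" %in% st) {
    sets <- default_gene_sets()
    res$scores <- run_stage("signatures", function()
      sapply(c("intestinal", "EMT", "EmyoT", "stemness"), function(nm)
        score_gene_set(res$norm, sets[[nm]], nm)))
    res$groups <- run_stage("signatures", function()
      classify_tumor_groups(res$scores[, c("intestinal", "EMT", "EmyoT")]))
    note("signatures", nrow(res$scores))
  }
  if ("cohort" %in% st) {
    res$bulk <- run_stage("cohort", function()
      simulate_bulk_cohort(config$sim,
        groups = list(intestinal = c(MSC = 0.5, tumor = 0.5),
                      EmyoT = c(fibroblast = 0.4, tumor = 0.6)),
        n_per_group = c(intestinal = 150L, EmyoT = 150L),
        hazards = c(intestinal = 0.01, EmyoT = 0.0172)))
    res$surv <- run_stage("cohort", function()
      fit_cox_km(res$bulk$samples$time, res$bulk$samples$event,
                 res$bulk$samples$group, reference = "intestinal"))
    note("cohort", nrow(res$bulk$samples))
  }
  if ("ihc" %in% st) {
    res$ihc <- run_stage("ihc", function()
      simulate_ihc(seed = config$seed,
                   regions = list(list(channels = c("MRTFA", "SRF"),
                                       cols = 10:13, rows = 8:9))))
    pos <- lapply(res$ihc$images, annotate_tiles, grid = res$ihc$grid)
    res$ihc_overlap <- overlap_tiles(pos$MRTFA, pos$SRF, res$ihc$grid)
    note("ihc", nrow(res$ihc$grid$tiles))
  }
  res$manifest <- do.call(rbind, manifest)
  rownames(res$manifest) <- NULL
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

# TSV exports for the stage tables; seed recorded in a manifest file.
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  if (!is.null(res$manifest)) wt(res$manifest, "manifest.tsv")
  if (!is.null(res$qc)) wt(res$qc$report, "qc_report.tsv")
  if (!is.null(res$clust))
    wt(data.frame(cell = rownames(res$norm$values),
                  cluster = res$clust$clusters,
                  cell_type = res$types$cell_type), "annotation.tsv")
  if (!is.null(res$traj))
    wt(data.frame(cell = names(res$traj$pseudotime),
                  pseudotime = res$traj$pseudotime,
                  branch = res$traj$branch_state,
                  state = res$states$state), "trajectory.tsv")
  if (!is.null(res$surv)) wt(res$surv$hr, "cox_hr.tsv")
  invisible(dir)
}
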