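#' Assemble a pipeline run configuration
#'
#' Collects all stage parameters (defaults follow the established
#' practice for each stage: QC bounds 5/100 transcripts and 90/2000 px,
#' malignancy purity 0.95, DE limits 0.5 / 0.05, CNV window 101) plus
#' stage toggles, input paths and the global seed. Every stochastic stage
#' receives a sub-seed derived deterministically from the global seed and
#' the stage name, so toggling one stage never changes another's draws.
#'
#' @param out_dir Output directory.
#' @param seed Global integer seed.
#' @param n_patients Patients to simulate.
#' @param stages Named logical list of stage toggles.
#' @param tissue,cells,expression,cluster,malignancy,spatial,deconvolve
#'   Stage parameter lists; see the stage functions for meanings.
#'   `expression$malignant_patient_sd` controls how strongly each
#'   patient's malignant cells carry a private expression program; it is
#'   what lets the patient-composition rule find malignant clusters in
#'   simulated cohorts, mirroring the patient-specific clustering of
#'   malignant cells in real tumors. `expression$batch_sd` is the global
#'   technical batch effect; the pipeline keeps it modest so normal cell
#'   types co-cluster across patients, the other half of the structure
#'   the composition rule relies on.
#' @param inputs Input paths (per-patient named lists `spots`, `mask`)
#'   used when the simulate stage is off.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("nodular_run_"), seed = 1L,
                       n_patients = 3,
                       stages = list(simulate = TRUE, cells = TRUE,
                                     cluster = TRUE, malignancy = TRUE,
                                     trajectory = TRUE, spatial = TRUE,
                                     deconvolve = TRUE),
                       tissue = list(n_cells = 2000, n_nodules = 3,
                                     field_width = 2000, field_height = 2000),
                       cells = list(min_transcripts = 5,
                                    max_transcripts = 100,
                                    min_area = 90, max_area = 2000,
                                    nucleus_radius = 7,
                                    background_rate = 1e-5),
                       expression = list(malignant_patient_sd = 0.5,
                                         batch_sd = 0.05),
                       cluster = list(n_pcs = 30, k = 20, resolution = 1.0,
                                      merge_r_min = 0.95),
                       malignancy = list(purity = 0.95, window = 101,
                                         clip = 1.0),
                       spatial = list(method = "knn", k = 6, B = 500,
                                      bandwidth = 75, grid_step = 2),
                       deconvolve = list(n_bulk_patients = 6,
                                         noise_sd = 0.1, batch_sd = 0.2),
                       inputs = list()) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_patients = n_patients, stages = stages, tissue = tissue,
              cells = cells, expression = expression, cluster = cluster,
              malignancy = malignancy, spatial = spatial,
              deconvolve = deconvolve, inputs = inputs)
  # partial section lists overlay the defaults element-wise
  defaults <- formals(run_config)
  for (sec in c("stages", "tissue", "cells", "expression", "cluster",
                "malignancy", "spatial", "deconvolve")) {
    def <- eval(defaults[[sec]])
    for (nm in names(cfg[[sec]])) def[[nm]] <- cfg[[sec]][[nm]]
    cfg[[sec]] <- def
  }
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  defaults <- formals(run_config)
  allowed <- names(defaults)
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    rlang::abort(paste0("unknown config key(s): ",
                        paste(unknown, collapse = ", ")))
  for (sec in c("stages", "tissue", "cells", "expression", "cluster",
                "malignancy", "spatial", "deconvolve")) {
    def <- eval(defaults[[sec]])
    bad <- setdiff(names(cfg[[sec]]), names(def))
    if (length(bad) > 0)
      rlang::abort(paste0("unknown config key(s) in ", sec, ": ",
                          paste(bad, collapse = ", ")))
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are
#' rejected. Sections present in the file override the defaults
#' element-wise.
#'
#' @param path YAML path.
#' @param out_dir,seed Optional overrides.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL, seed = NULL) {
  assert_that(file.exists(path), paste0("config not found: ", path))
  y <- yaml::read_yaml(path)
  base <- run_config()
  unknown <- setdiff(names(y), names(base))
  if (length(unknown) > 0)
    rlang::abort(paste0("unknown config key(s): ",
                        paste(unknown, collapse = ", ")))
  for (nm in names(y)) {
    if (is.list(base[[nm]]) && is.list(y[[nm]])) {
      for (sub in names(y[[nm]])) base[[nm]][[sub]] <- y[[nm]][[sub]]
    } else base[[nm]] <- y[[nm]]
  }
  if (!is.null(out_dir)) base$out_dir <- out_dir
  if (!is.null(seed)) base$seed <- as.integer(seed)
  validate_run_config(base)
  structure(base, class = "run_config")
}

stage_seed <- function(cfg, stage) derive_seed(cfg$seed, stage)

#' Run the full pipeline
#'
#' Executes `simulate -> cells -> cluster -> malignancy -> trajectory ->
#' spatial -> deconvolve` as toggled in the config, writing stage outputs
#' and a JSON run report (seeds, parameters, counts in and out per stage)
#' under `out_dir`. Identical config and seed give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return The run report, invisibly (list; also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed, stages = list())
  state <- new.env(parent = emptyenv())

  if (isTRUE(cfg$stages$simulate)) report$stages$simulate <-
    stage_simulate(cfg, state)
  if (isTRUE(cfg$stages$cells)) report$stages$cells <-
    stage_cells(cfg, state)
  if (isTRUE(cfg$stages$cluster)) report$stages$cluster <-
    stage_cluster(cfg, state)
  if (isTRUE(cfg$stages$malignancy)) report$stages$malignancy <-
    stage_malignancy(cfg, state)
  if (isTRUE(cfg$stages$trajectory)) report$stages$trajectory <-
    stage_trajectory(cfg, state)
  if (isTRUE(cfg$stages$spatial)) report$stages$spatial <-
    stage_spatial(cfg, state)
  if (isTRUE(cfg$stages$deconvolve)) report$stages$deconvolve <-
    stage_deconvolve(cfg, state)

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}

stage_simulate <- function(cfg, state) {
  tcfg <- do.call(tissue_config,
                  c(cfg$tissue, list(seed = stage_seed(cfg, "tissue"))))
  cohort <- simulate_cohort(tcfg, n_patients = cfg$n_patients)
  ecfg_sn <- expression_config(
    "snrna", malignant_patient_sd = cfg$expression$malignant_patient_sd,
    batch_sd = cfg$expression$batch_sd)
  expr_sn <- simulate_expression(cohort$cells, ecfg_sn,
                                 seed = stage_seed(cfg, "expression_snrna"))
  expr_sp <- simulate_expression(cohort$cells, expression_config("spatial"),
                                 seed = stage_seed(cfg, "expression_spatial"))
  sim_dir <- file.path(cfg$out_dir, "simulate")
  dir.create(file.path(sim_dir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  write_tsv_plain(cohort$cells, file.path(sim_dir, "truth", "cells.tsv"))
  write_tsv_plain(expr_sn$truth$latent_time,
                  file.path(sim_dir, "truth", "latent_time.tsv"))
  if (!is.null(expr_sn$truth$cnv))
    write_tsv_plain(expr_sn$truth$cnv,
                    file.path(sim_dir, "truth", "cnv_blocks.tsv"))
  write_counts(expr_sn$counts, file.path(sim_dir, "snrna"),
               metadata = dplyr::select(cohort$cells, "cell_id", "patient"),
               genes = expr_sn$genes)
  spots_masks <- list()
  for (p in names(cohort$tissues)) {
    tis <- cohort$tissues[[p]]
    sm <- simulate_spots_and_masks(
      tis, expr_sp$counts[tis$cells$cell_id, , drop = FALSE],
      nucleus_radius = cfg$cells$nucleus_radius,
      background_rate = cfg$cells$background_rate,
      seed = stage_seed(cfg, paste0("spots_", p)))
    write_spots(sm$spots, file.path(sim_dir, paste0("spots_", p, ".csv")))
    write_label_mask(sm$mask, file.path(sim_dir, paste0("mask_", p, ".tif")))
    spots_masks[[p]] <- sm
  }
  state$cohort <- cohort
  state$expr_sn <- expr_sn
  state$expr_sp <- expr_sp
  state$spots_masks <- spots_masks
  list(seed = stage_seed(cfg, "tissue"), n_cells = nrow(cohort$cells),
       n_patients = cfg$n_patients,
       n_genes_snrna = ncol(expr_sn$counts),
       n_genes_spatial = ncol(expr_sp$counts))
}

stage_cells <- function(cfg, state) {
  per_patient <- list()
  if (!is.null(state$spots_masks)) {
    for (p in names(state$spots_masks))
      per_patient[[p]] <- list(spots = state$spots_masks[[p]]$spots,
                               mask = state$spots_masks[[p]]$mask)
  } else {
    assert_that(length(cfg$inputs) > 0,
                "cells stage needs simulated data or inputs$<patient> paths")
    for (p in names(cfg$inputs)) {
      ip <- cfg$inputs[[p]]
      for (f in c("spots", "mask"))
        if (!file.exists(ip[[f]] %||% ""))
          rlang::abort(paste0("missing ", f, " file for ", p, ": ",
                              ip[[f]] %||% "<unset>"))
      per_patient[[p]] <- list(spots = read_spots(ip$spots),
                               mask = read_label_mask(ip$mask))
    }
  }
  out <- list(); removed <- 0L; unassigned <- 0L
  for (p in names(per_patient)) {
    sc <- assign_spots_to_cells(per_patient[[p]]$spots[c("x", "y", "gene")],
                                per_patient[[p]]$mask)
    before <- nrow(sc$counts)
    scf <- qc_filter_cells(sc, cfg$cells$min_transcripts,
                           cfg$cells$max_transcripts,
                           cfg$cells$min_area, cfg$cells$max_area)
    removed <- removed + before - nrow(scf$counts)
    unassigned <- unassigned + sc$unassigned
    scf$metadata$patient <- p
    scf$metadata$cell_id <- paste0(p, "_", scf$metadata$cell_id)
    rownames(scf$counts) <- scf$metadata$cell_id
    out[[p]] <- scf
    write_counts(scf$counts,
                 file.path(cfg$out_dir, "cells", p),
                 metadata = scf$metadata)
  }
  state$spatial_cells <- out
  list(n_cells = sum(vapply(out, function(x) nrow(x$counts), numeric(1))),
       removed_by_qc = removed, unassigned_spots = unassigned)
}

stage_cluster <- function(cfg, state) {
  assert_that(!is.null(state$expr_sn), "cluster stage needs expression data")
  # cluster on uncorrected data: malignant cells then separate by patient
  # (private tumor programs) while normal cells mix, which is what the
  # downstream patient-composition rule relies on
  norm <- normalize_counts(state$expr_sn$counts)
  cl <- embed_and_cluster(norm, n_pcs = cfg$cluster$n_pcs,
                          k = cfg$cluster$k,
                          resolution = cfg$cluster$resolution,
                          seed = stage_seed(cfg, "cluster"))
  cl <- merge_similar_clusters(cl, norm, r_min = cfg$cluster$merge_r_min)
  state$norm_sn <- norm
  state$clusters <- cl
  write_tsv_plain(cl$assignments,
                  file.path(cfg$out_dir, "clusters.tsv"))
  list(seed = stage_seed(cfg, "cluster"),
       n_clusters = nrow(cl$centroids),
       modularity = cl$params$modularity)
}

stage_malignancy <- function(cfg, state) {
  assert_that(!is.null(state$clusters), "malignancy stage needs clusters")
  cl <- state$clusters$assignments
  tab <- table(cl$cluster, state$cohort$cells$patient[
    match(cl$cell_id, state$cohort$cells$cell_id)])
  calls <- call_malignant_clusters(as.matrix(unclass(tab)),
                                   purity = cfg$malignancy$purity)
  normal_clusters <- calls$cluster[calls$call == "normal"]
  ref_ids <- cl$cell_id[as.character(cl$cluster) %in% normal_clusters]
  cnv <- NULL
  if (length(ref_ids) >= 20) {
    cnv <- infer_cnv_profiles(state$norm_sn, state$expr_sn$genes,
                              ref_ids, window = cfg$malignancy$window,
                              clip = cfg$malignancy$clip)
    state$cnv <- cnv
  } else rlang::warn("fewer than 20 reference cells; CNV profiling skipped")
  state$malignant_calls <- calls
  write_tsv_plain(calls, file.path(cfg$out_dir, "malignant_calls.tsv"))
  list(n_malignant_clusters = sum(calls$call == "malignant"),
       n_reference_cells = length(ref_ids))
}

stage_trajectory <- function(cfg, state) {
  assert_that(!is.null(state$malignant_calls), "trajectory needs calls")
  cl <- state$clusters$assignments
  mal_clusters <- state$malignant_calls$cluster[
    state$malignant_calls$call == "malignant"]
  in_mal <- as.character(cl$cluster) %in% mal_clusters
  assert_that(sum(in_mal) > 10, "too few malignant cells for a trajectory")
  # patient programs dominate the raw malignant clusters; integrate the
  # malignant cells (per-patient centering) and re-embed so the shared
  # differentiation axis drives the trajectory clusters
  ids <- cl$cell_id[in_mal]
  patients <- state$cohort$cells$patient[
    match(ids, state$cohort$cells$cell_id)]
  adj <- batch_adjust(state$norm_sn[ids, , drop = FALSE], patients)
  sub <- embed_and_cluster(adj, n_pcs = cfg$cluster$n_pcs,
                           k = min(cfg$cluster$k, length(ids) - 1),
                           resolution = cfg$cluster$resolution,
                           seed = stage_seed(cfg, "trajectory_cluster"))
  sub <- merge_similar_clusters(sub, adj, r_min = cfg$cluster$merge_r_min)
  pcs <- sub$pcs
  rownames(pcs) <- ids
  labs <- sub$assignments$cluster
  cent <- t(vapply(sort(unique(labs)), function(c1)
    colMeans(pcs[labs == c1, , drop = FALSE]), numeric(ncol(pcs))))
  rownames(cent) <- sort(unique(labs))
  genes <- state$expr_sn$genes
  prolif <- genes$gene[genes$marker_of == "prolif_early_cgnp"]
  phases <- cell_cycle_phase(adj,
                             s_set = prolif[seq_len(ceiling(length(prolif) / 2))],
                             g2m_set = prolif[-seq_len(ceiling(length(prolif) / 2))],
                             seed = stage_seed(cfg, "cc_score"))
  root <- pick_root_cluster(phases, labs)
  lin <- lineage_graph(cent, root)
  pt <- pseudotime(pcs, lin)
  state$lineages <- lin
  state$pseudotime <- pt
  write_tsv_plain(pt, file.path(cfg$out_dir, "pseudotime.tsv"))
  jsonlite::write_json(lin$lineages,
                       file.path(cfg$out_dir, "lineages.json"),
                       pretty = TRUE)
  list(root = lin$root, n_lineages = length(lin$lineages),
       n_cells = nrow(pt))
}

stage_spatial <- function(cfg, state) {
  assert_that(!is.null(state$spatial_cells), "spatial stage needs cells")
  ref <- t(normalize_counts(state$expr_sp$truth$state_means * 100))
  out <- list()
  for (p in names(state$spatial_cells)) {
    sc <- state$spatial_cells[[p]]
    norm_sp <- normalize_counts(sc$counts, scale_factor = 100)
    ann <- annotate_by_reference(norm_sp, ref)
    g <- build_spatial_graph(sc$metadata, method = cfg$spatial$method,
                             k = cfg$spatial$k)
    enr <- colocalization_enrichment(
      g, setNames(ann$label, ann$cell_id), B = cfg$spatial$B,
      seed = stage_seed(cfg, paste0("coloc_", p)))
    cmap <- compartment_map(sc$metadata, ann$label,
                            nodular_anchor_types = "differentiated",
                            bandwidth = cfg$spatial$bandwidth,
                            grid_step = cfg$spatial$grid_step,
                            field = c(cfg$tissue$field_width,
                                      cfg$tissue$field_height))
    comp <- compartment_composition(ann$label, cmap$cells$compartment)
    utils::write.table(round(enr$score, 4),
                       file.path(cfg$out_dir, paste0("enrichment_", p, ".tsv")),
                       sep = "\t", quote = FALSE)
    write_tsv_plain(cmap$cells,
                    file.path(cfg$out_dir, paste0("compartments_", p, ".tsv")))
    out[[p]] <- list(annotation = ann, graph = g, enrichment = enr,
                     compartment_map = cmap, composition = comp)
  }
  state$spatial_results <- out
  list(patients = names(out),
       n_edges = vapply(out, function(o) nrow(o$graph$edges), numeric(1)))
}

stage_deconvolve <- function(cfg, state) {
  assert_that(!is.null(state$expr_sn), "deconvolve stage needs signatures")
  S <- t(state$expr_sn$truth$state_means)
  design <- default_bulk_design(cfg$deconvolve$n_bulk_patients)
  sim <- simulate_bulk_compartments(S, design,
                                    noise_sd = cfg$deconvolve$noise_sd,
                                    batch_sd = cfg$deconvolve$batch_sd,
                                    seed = stage_seed(cfg, "bulk"))
  dec <- deconvolve_bulk(sim$bulk, S)
  props <- tibble::as_tibble(dec$proportions) |>
    dplyr::mutate(sample = rownames(dec$proportions),
                  compartment = design$compartment[
                    match(.data$sample, design$sample)])
  stats_tab <- composition_statistics(props, colnames(dec$proportions),
                                      by = "compartment")
  write_bulk(sim$bulk, file.path(cfg$out_dir, "bulk.tsv"))
  write_tsv_plain(stats_tab,
                  file.path(cfg$out_dir, "deconvolution_tests.tsv"))
  state$deconvolution <- dec
  state$bulk_truth <- sim$true_proportions
  state$deconv_tests <- stats_tab
  list(n_samples = nrow(dec$proportions),
       mean_abs_error = mean(abs(dec$proportions -
                                   sim$true_proportions[rownames(dec$proportions), ])),
       n_significant = sum(stats_tab$p_value < 0.05, na.rm = TRUE))
}
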