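#' Configuration for synthetic expression counts
#'
#' Defines a gene panel (state markers plus background genes laid out along
#' simulated chromosomes), negative-binomial noise, per-patient batch
#' factors, and optional planted copy-number blocks.
#'
#' Two stock panels are provided. `"spatial"` mimics a targeted in-situ
#' panel: 120 genes (15 markers per state plus 30 housekeeping genes) at a
#' low baseline so per-cell totals land in the range a 12- to 100-plex
#' experiment produces. `"snrna"` mimics a transcriptome-scale panel: 2000
#' genes with the same marker scheme plus a dense background, the substrate
#' for expression-based CNV inference (a 300-gene contiguous block can carry
#' a planted fold-change).
#'
#' @param panel `"spatial"` or `"snrna"`.
#' @param markers_per_state Markers per state.
#' @param baseline_mean Baseline NB mean per gene per cell.
#' @param marker_fold Fold-change of a state's markers in that state.
#' @param size Negative-binomial size (inverse dispersion); large values
#'   approach Poisson noise.
#' @param batch_sd Standard deviation of per-patient, per-gene log-normal
#'   batch factors.
#' @param malignant_patient_sd Standard deviation of per-patient log-normal
#'   factors applied only to malignant cells (the CGNP lineage plus
#'   astrocytic-like cells): patient-private tumor programs. At the
#'   default 0 malignant cells of different patients are biologically
#'   identical; positive values make them cluster apart by patient, the
#'   behavior observed in real tumor cohorts.
#' @param cnv Either `NULL` or a list
#'   `list(patient=, chrom=, genes=, fold=)` planting a multiplicative
#'   fold-change on a contiguous gene block in the malignant cells of one
#'   patient. The default for the snrna panel plants a 1.5x gain over 300
#'   genes on chr2 of patient P1.
#' @return An `expression_config` list (includes the gene annotation tibble
#'   `genes` with columns gene/chrom/pos/marker_of).
#' @export
expression_config <- function(panel = c("snrna", "spatial"),
                              markers_per_state = 15,
                              baseline_mean = NULL,
                              marker_fold = NULL,
                              size = 4,
                              batch_sd = 0.2,
                              malignant_patient_sd = 0,
                              cnv = NULL) {
  panel <- match.arg(panel)
  if (panel == "spatial") {
    n_genes <- 120
    baseline_mean <- baseline_mean %||% 0.15
    marker_fold <- marker_fold %||% 8
  } else {
    n_genes <- 2000
    baseline_mean <- baseline_mean %||% 0.5
    marker_fold <- marker_fold %||% 6
    if (is.null(cnv)) cnv <- list(patient = "P1", chrom = "chr2",
                                  fold = 1.5, n_block = 300)
  }
  assert_that(baseline_mean > 0, "baseline_mean must be positive")
  if (!is.null(cnv)) assert_that(cnv$fold > 0, "CNV fold-change must be > 0")
  genes <- build_gene_panel(panel, n_genes, markers_per_state)
  cnv_tbl <- NULL
  if (!is.null(cnv)) {
    block <- genes$gene[genes$chrom == cnv$chrom & genes$marker_of == "none"]
    block <- head(block, cnv$n_block %||% length(block))
    assert_that(length(block) > 0, "no background genes on the CNV chromosome")
    cnv_tbl <- tibble::tibble(patient = cnv$patient, chrom = cnv$chrom,
                              gene = block, fold = cnv$fold)
  }
  structure(list(panel = panel, genes = genes,
                 markers_per_state = markers_per_state,
                 baseline_mean = baseline_mean, marker_fold = marker_fold,
                 size = size, batch_sd = batch_sd,
                 malignant_patient_sd = malignant_patient_sd,
                 cnv = cnv_tbl),
            class = "expression_config")
}

# genes tiled over chromosomes chr1..chr10 in annotation order; markers
# interleaved across chromosomes except chr2, reserved for the CNV block
build_gene_panel <- function(panel, n_genes, markers_per_state) {
  n_states <- length(tissue_states)
  n_markers <- n_states * markers_per_state
  assert_that(n_genes > n_markers, "panel too small for the marker scheme")
  gene <- sprintf("G%04d", seq_len(n_genes))
  n_chrom <- if (panel == "spatial") 4L else 6L
  chrom <- paste0("chr", rep_len(seq_len(n_chrom), n_genes))
  chrom <- sort(chrom)  # contiguous blocks per chromosome
  marker_of <- rep("none", n_genes)
  # background-only chromosome for the CNV block on the snrna panel
  eligible <- if (panel == "snrna") which(chrom != "chr2") else seq_len(n_genes)
  marker_idx <- eligible[seq_len(n_markers)]
  marker_of[marker_idx] <- rep(tissue_states, each = markers_per_state)
  tibble::tibble(gene = gene, chrom = chrom,
                 pos = stats::ave(seq_len(n_genes), chrom, FUN = seq_along) * 1e5,
                 marker_of = marker_of) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

# smooth differentiation programs: early/mid/late marker sets peak in
# their latent-time window so both discrete states and the continuous
# axis are recoverable; proliferation (cell-cycle-like) markers are
# on/off with the proliferating state rather than time-graded
lineage_multiplier <- function(state_of_marker, t, fold) {
  a <- fold - 1
  switch(state_of_marker,
    early_cgnp        = 1 + a * (1 - stats::plogis((t - 0.40) / 0.07)),
    migrating         = 1 + a * exp(-((t - 0.55) / 0.12)^2),
    differentiated    = 1 + a * stats::plogis((t - 0.70) / 0.07),
    stop("not a lineage state"))
}

latent_time_for_state <- function(state, n) {
  switch(state,
    prolif_early_cgnp = stats::rbeta(n, 2, 6) * 0.35,
    early_cgnp        = 0.15 + 0.30 * stats::rbeta(n, 2, 2),
    migrating         = 0.40 + 0.30 * stats::rbeta(n, 2, 2),
    differentiated    = 0.65 + 0.35 * stats::rbeta(n, 2, 2),
    rep(NA_real_, n))
}

#' Simulate expression counts for a tissue cohort
#'
#' Draws negative-binomial counts with mean
#' `baseline x state/time effect x patient batch factor x CNV fold-change`.
#' Cells of the four CGNP lineage states carry a latent differentiation
#' time `t` in `[0, 1]`; marker programs rise and fall smoothly with `t`
#' (early programs high at small `t`, migrating programs peaking mid-way,
#' differentiated programs high late) so pseudotime is recoverable from the
#' counts. Astrocytic-like and stromal markers are constant within their
#' state. Planted CNV blocks multiply the means of block genes in the
#' malignant cells of the configured patient.
#'
#' @param cells Cell tibble from [simulate_tissue()] or [simulate_cohort()]
#'   (columns `cell_id`, `state`, `patient`).
#' @param config An [expression_config()].
#' @param seed Integer seed.
#' @return List with `counts` (cells x genes integer matrix), `genes`
#'   (annotation tibble), and `truth` (list: `latent_time` tibble,
#'   `batch_factors` patients x genes matrix, `cnv` tibble or NULL,
#'   `state_means` states x genes matrix of noise-free mean profiles).
#' @export
simulate_expression <- function(cells, config = expression_config(),
                                seed = 1L) {
  with_seed(seed, {
    genes <- config$genes
    n_c <- nrow(cells); n_g <- nrow(genes)
    patients <- unique(cells$patient)
    batch <- matrix(exp(rnorm(length(patients) * n_g, 0, config$batch_sd)),
                    nrow = length(patients),
                    dimnames = list(patients, genes$gene))

    t <- rep(NA_real_, n_c)
    for (s in lineage_states) {
      idx <- which(cells$state == s)
      t[idx] <- latent_time_for_state(s, length(idx))
    }

    mu <- matrix(config$baseline_mean, n_c, n_g,
                 dimnames = list(cells$cell_id, genes$gene))
    graded_states <- setdiff(lineage_states, "prolif_early_cgnp")
    for (s in tissue_states) {
      gi <- which(genes$marker_of == s)
      if (length(gi) == 0) next
      if (s %in% graded_states) {
        on_lineage <- which(!is.na(t))
        mult <- lineage_multiplier(s, t[on_lineage], config$marker_fold)
        mu[on_lineage, gi] <- mu[on_lineage, gi] * mult
      } else {
        ci <- which(cells$state == s)
        mu[ci, gi] <- mu[ci, gi] * config$marker_fold
      }
    }

    mu <- mu * batch[cells$patient, , drop = FALSE]

    mal_sd <- config$malignant_patient_sd %||% 0
    if (mal_sd > 0) {
      mal_factors <- matrix(
        exp(rnorm(length(patients) * n_g, 0, mal_sd)),
        nrow = length(patients), dimnames = list(patients, genes$gene))
      mal <- cells$state %in% c(lineage_states, "astrocytic_like")
      mu[mal, ] <- mu[mal, ] * mal_factors[cells$patient[mal], , drop = FALSE]
    }

    if (!is.null(config$cnv)) {
      for (p in unique(config$cnv$patient)) {
        gset <- config$cnv$gene[config$cnv$patient == p]
        fold <- config$cnv$fold[config$cnv$patient == p][1]
        ci <- which(cells$patient == p &
                      cells$state %in% c(lineage_states, "astrocytic_like"))
        gi <- match(gset, genes$gene)
        mu[ci, gi] <- mu[ci, gi] * fold
      }
    }

    assert_that(all(mu > 0), "non-positive expression means")
    counts <- matrix(rnbinom(n_c * n_g, mu = mu, size = config$size),
                     n_c, n_g, dimnames = dimnames(mu))

    state_means <- noise_free_state_means(config)
    list(counts = counts, genes = genes,
         truth = list(
           latent_time = tibble::tibble(cell_id = cells$cell_id, t = t),
           batch_factors = batch, cnv = config$cnv,
           state_means = state_means))
  })
}

# expected profile of each state at its typical latent time, no batch/CNV;
# the signature matrix used for bulk simulation and deconvolution truth
noise_free_state_means <- function(config) {
  genes <- config$genes
  t_typ <- c(prolif_early_cgnp = 0.10, early_cgnp = 0.30, migrating = 0.55,
             differentiated = 0.85)
  m <- matrix(config$baseline_mean, length(tissue_states), nrow(genes),
              dimnames = list(tissue_states, genes$gene))
  graded_states <- setdiff(lineage_states, "prolif_early_cgnp")
  for (s in tissue_states) {
    gi <- which(genes$marker_of == s)
    if (length(gi) == 0) next
    if (s %in% graded_states) {
      for (s2 in lineage_states)
        m[s2, gi] <- config$baseline_mean *
          lineage_multiplier(s, t_typ[[s2]], config$marker_fold)
    } else {
      m[s, gi] <- config$baseline_mean * config$marker_fold
    }
  }
  m
}
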