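#' Call clusters malignant by patient composition
#'
#' Tumor cells cluster by patient while normal cells mix across patients,
#' so a cluster is called malignant when at least `purity` of its cells
#' come from a single patient (boundary inclusive).
#'
#' @param cluster_patient_table Clusters x patients matrix (or data frame)
#'   of cell counts.
#' @param purity Minimum single-patient fraction for a malignant call.
#' @return Tibble: `cluster`, `n_cells`, `max_patient`, `max_fraction`,
#'   `call` in malignant/normal.
#' @export
call_malignant_clusters <- function(cluster_patient_table, purity = 0.95) {
  tab <- as.matrix(cluster_patient_table)
  assert_that(all(tab >= 0), "cell counts must be non-negative")
  n <- rowSums(tab)
  assert_that(all(n > 0), "empty cluster row")
  frac <- tab / n
  j <- max.col(frac, ties.method = "first")
  mx <- frac[cbind(seq_len(nrow(tab)), j)]
  tibble::tibble(
    cluster = rownames(tab) %||% as.character(seq_len(nrow(tab))),
    n_cells = as.integer(n),
    max_patient = colnames(tab)[j] %||% as.character(j),
    max_fraction = mx,
    call = ifelse(mx >= purity, "malignant", "normal"))
}

#' Infer copy-number profiles from expression
#'
#' Expression-based CNV proxy against a non-malignant reference: per gene,
#' the reference mean log-expression is subtracted; residuals are clipped
#' to `+/- clip`, smoothed by a moving average over `window` consecutive
#' genes in genomic order within each chromosome (never across
#' chromosomes), and each cell's median is subtracted to remove per-cell
#' depth offsets.
#'
#' @param norm Cells x genes normalized (log-scale) matrix.
#' @param gene_annotation Tibble with `gene`, `chrom`, `pos`; only
#'   annotated genes are used, in (chrom, pos) order.
#' @param reference_cell_ids Ids of >= 20 non-malignant reference cells.
#' @param window Moving-average width in genes (shrunk with a warning on
#'   chromosomes with fewer genes).
#' @param clip Residual clip bound (log2-scale units).
#' @return A `cnv_profile`: list with `profile` (cells x genes smoothed
#'   matrix, columns in genomic order) and `genes` (annotation used).
#' @export
infer_cnv_profiles <- function(norm, gene_annotation, reference_cell_ids,
                               window = 101, clip = 1.0) {
  assert_that(length(reference_cell_ids) >= 20,
              "need >= 20 reference cells")
  assert_that(all(reference_cell_ids %in% rownames(norm)),
              "unknown reference cell ids")
  ann <- dplyr::filter(gene_annotation, .data$gene %in% colnames(norm)) |>
    dplyr::arrange(.data$chrom, .data$pos)
  assert_that(nrow(ann) > 0, "no annotated genes in the matrix")
  m <- norm[, ann$gene, drop = FALSE]
  ref_mu <- colMeans(m[reference_cell_ids, , drop = FALSE])
  resid <- sweep(m, 2, ref_mu, "-")
  resid[resid > clip] <- clip
  resid[resid < -clip] <- -clip

  sm <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (ch in unique(ann$chrom)) {
    ci <- which(ann$chrom == ch)
    w <- window
    if (length(ci) < w) {
      w <- length(ci)
      rlang::warn(paste0(ch, " has ", length(ci),
                         " genes; window shrunk to chromosome size"))
    }
    if (w %% 2 == 0) w <- max(1, w - 1)  # keep the window centered
    block <- resid[, ci, drop = FALSE]
    sm[, ci] <- t(apply(block, 1, function(r)
      zoo::rollmean(r, w, fill = NA)))
    # shrink the window toward the chromosome ends instead of dropping genes
    half <- (w - 1) / 2
    if (half > 0) {
      cs <- cbind(0, t(apply(block, 1, cumsum)))
      n_g <- length(ci)
      for (j in c(seq_len(half), (n_g - half + 1):n_g)) {
        lo <- max(1, j - half); hi <- min(n_g, j + half)
        sm[, ci[j]] <- (cs[, hi + 1] - cs[, lo]) / (hi - lo + 1)
      }
    }
  }
  med <- apply(sm, 1, median)
  sm <- sweep(sm, 1, med, "-")
  structure(list(profile = sm, genes = ann, cell_medians = med),
            class = "cnv_profile")
}

#' @exportS3Method base::print
print.cnv_profile <- function(x, ...) {
  cat("<cnv_profile> ", nrow(x$profile), " cells x ", ncol(x$profile),
      " genes over ", length(unique(x$genes$chrom)), " chromosomes\n",
      sep = "")
  invisible(x)
}

#' Per-cell copy-number burden
#'
#' Mean squared smoothed ratio per cell — a scalar flag for cells or
#' clusters carrying genome-scale imbalances.
#'
#' @param profile A `cnv_profile`.
#' @param clusters Optional cluster labels aligned with profile rows; adds
#'   a per-cluster summary.
#' @return Tibble `cell_id`, `burden`; when `clusters` is given, attribute
#'   `cluster_summary` holds the per-cluster mean burden and rank.
#' @export
cnv_burden <- function(profile, clusters = NULL) {
  p <- profile$profile
  burden <- rowMeans(p^2)
  out <- tibble::tibble(cell_id = rownames(p), burden = burden)
  if (!is.null(clusters)) {
    summ <- tibble::tibble(cluster = clusters, burden = burden) |>
      dplyr::summarise(mean_burden = mean(.data$burden),
                       .by = "cluster") |>
      dplyr::arrange(dplyr::desc(.data$mean_burden)) |>
      dplyr::mutate(rank = dplyr::row_number())
    attr(out, "cluster_summary") <- summ
  }
  out
}

#' Mean CNV score over a genomic block
#'
#' @param profile A `cnv_profile`.
#' @param genes Genes defining the block.
#' @return Named per-cell numeric vector.
#' @export
cnv_block_score <- function(profile, genes) {
  genes <- intersect(genes, colnames(profile$profile))
  assert_that(length(genes) > 0, "no block genes in the profile")
  rowMeans(profile$profile[, genes, drop = FALSE])
}
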