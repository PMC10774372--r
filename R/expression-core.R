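#' Library-size normalize and log-transform a count matrix
#'
#' Per-cell counts are scaled to a common total and log1p-transformed, the
#' conventional normalization for panel-scale and droplet data. Zero counts
#' map to zero; an all-zero cell stays all-zero.
#'
#' @param counts Cells x genes count matrix.
#' @param scale_factor Common per-cell total after scaling.
#' @return Cells x genes numeric matrix (log1p scale), with the scale
#'   factor stored in attribute `scale_factor`.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  assert_counts(counts)
  tot <- rowSums(counts)
  sf <- ifelse(tot > 0, scale_factor / tot, 0)
  out <- log1p(as.matrix(counts) * sf)
  attr(out, "scale_factor") <- scale_factor
  out
}

# top-k nearest neighbours in PC space, computed blockwise to bound memory
knn_indices <- function(pcs, k, block = 512L) {
  n <- nrow(pcs)
  idx <- matrix(0L, n, k)
  sq <- rowSums(pcs^2)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(n, start + block - 1L)
    d2 <- outer(sq[rows], sq, "+") - 2 * pcs[rows, , drop = FALSE] %*% t(pcs)
    d2[cbind(seq_along(rows), rows)] <- Inf
    idx[rows, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  idx
}

#' Embed cells by PCA and cluster with Louvain community detection
#'
#' Centers genes, projects cells onto the top principal components, builds
#' a k-nearest-neighbour graph (Euclidean in PC space) and partitions it by
#' modularity optimization. Cells are ordered canonically by id before
#' graph construction, so the partition is invariant to input row order.
#'
#' @param norm Cells x genes normalized matrix.
#' @param n_pcs Number of principal components (reduced with a warning when
#'   fewer genes are available).
#' @param k Neighbours per cell.
#' @param resolution Louvain resolution.
#' @param seed Integer seed controlling the community-detection order.
#' @return A `cluster_result`: list with `assignments` (tibble `cell_id`,
#'   `cluster`), `centroids` (clusters x genes means of `norm`), `pcs`
#'   (cells x n_pcs scores), `params`.
#' @export
embed_and_cluster <- function(norm, n_pcs = 30, k = 20, resolution = 1.0,
                              seed = 1L) {
  assert_that(nrow(norm) >= k + 1, "need at least k + 1 cells")
  if (ncol(norm) < n_pcs) {
    rlang::warn(paste0("only ", ncol(norm), " genes; reducing n_pcs"))
    n_pcs <- ncol(norm)
  }
  ord <- order(rownames(norm))
  m <- norm[ord, , drop = FALSE]
  pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = n_pcs)
  pcs <- pc$x
  nn <- knn_indices(pcs, k)
  edges <- cbind(rep(seq_len(nrow(m)), k), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  labels <- igraph::membership(comm)
  assignments <- tibble::tibble(cell_id = rownames(m),
                                cluster = as.integer(labels))
  # report in the caller's row order
  assignments <- assignments[match(rownames(norm), assignments$cell_id), ]
  res <- structure(list(
    assignments = assignments,
    centroids = cluster_centroids(norm, assignments),
    pcs = pcs[match(rownames(norm), rownames(m)), , drop = FALSE],
    params = list(n_pcs = n_pcs, k = k, resolution = resolution, seed = seed,
                  modularity = igraph::modularity(comm))),
    class = "cluster_result")
  res
}

cluster_centroids <- function(norm, assignments) {
  cl <- assignments$cluster[match(rownames(norm), assignments$cell_id)]
  u <- sort(unique(cl))
  cent <- t(vapply(u, function(c1) colMeans(norm[cl == c1, , drop = FALSE]),
                   numeric(ncol(norm))))
  rownames(cent) <- u
  cent
}

#' @exportS3Method base::print
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$assignments), " cells in ",
      nrow(x$centroids), " clusters (modularity ",
      round(x$params$modularity, 3), ")\n", sep = "")
  invisible(x)
}

#' Merge clusters with near-identical mean expression profiles
#'
#' Computes Pearson correlations between cluster mean profiles and merges
#' the connected components of the pairs correlated at or above `r_min`
#' (transitive
#' closure), the usual post-hoc cleanup when community detection over-splits
#' a homogeneous population.
#'
#' @param clusters A `cluster_result`.
#' @param norm The normalized matrix the clustering was computed on.
#' @param r_min Minimum Pearson correlation for a merge.
#' @return A `cluster_result` with merged, re-numbered labels.
#' @export
merge_similar_clusters <- function(clusters, norm, r_min = 0.95) {
  cent <- clusters$centroids
  if (nrow(cent) <= 1) return(clusters)
  r <- suppressWarnings(cor(t(cent)))
  r[is.na(r)] <- 0
  adj <- (r >= r_min) & (r < 1 + 1e-12)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  map <- setNames(comp, rownames(cent))
  out <- clusters
  out$assignments <- dplyr::mutate(
    clusters$assignments,
    cluster = as.integer(map[as.character(.data$cluster)]))
  out$centroids <- cluster_centroids(norm, out$assignments)
  out$params$merged_from <- nrow(cent)
  out
}

#' One-vs-rest marker genes per cluster
#'
#' Wilcoxon rank-sum test of each gene in a cluster against all other
#' cells, log2 fold-change of means with pseudocount 1, and
#' Benjamini-Hochberg adjustment within each cluster. Zero-variance genes
#' are reported with `p = 1` rather than dropped, keeping the output shape
#' stable. Clusters with fewer than 3 cells are skipped with a warning.
#'
#' @param norm Cells x genes normalized matrix.
#' @param clusters A `cluster_result` or an integer vector of labels
#'   aligned with `rownames(norm)`.
#' @return Tibble: `cluster`, `gene`, `log2_fc`, `p_value`, `q_value`,
#'   sorted by cluster then p.
#' @export
find_markers <- function(norm, clusters) {
  cl <- cluster_labels(clusters, norm)
  out <- purrr::map_dfr(sort(unique(cl)), function(c1) {
    in_c <- cl == c1
    if (sum(in_c) < 3) {
      rlang::warn(paste0("cluster ", c1, " has < 3 cells; skipped"))
      return(NULL)
    }
    a <- norm[in_c, , drop = FALSE]
    b <- norm[!in_c, , drop = FALSE]
    stats_g <- purrr::map_dfr(seq_len(ncol(norm)), function(j) {
      x <- a[, j]; y <- b[, j]
      p <- if (var(c(x, y)) == 0) 1
           else suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
      tibble::tibble(gene = colnames(norm)[j],
                     log2_fc = log2((mean(x) + 1) / (mean(y) + 1)),
                     p_value = p)
    })
    stats_g$q_value <- p.adjust(stats_g$p_value, "BH")
    dplyr::mutate(stats_g, cluster = c1, .before = 1)
  })
  dplyr::arrange(out, .data$cluster, .data$p_value)
}

cluster_labels <- function(clusters, norm) {
  if (inherits(clusters, "cluster_result"))
    clusters$assignments$cluster[
      match(rownames(norm), clusters$assignments$cell_id)]
  else clusters
}

#' Expression-bin-matched module score
#'
#' The control-matched signature score of Tirosh and colleagues: genes are
#' binned by mean expression, each set gene draws `n_ctrl` control genes
#' from its own bin, and the score is the per-cell mean over set genes
#' minus the mean over controls. A random gene set therefore scores ~0
#' regardless of cell depth.
#'
#' @param norm Cells x genes normalized matrix.
#' @param gene_set Character vector of gene names (order-irrelevant).
#' @param n_bins Expression bins.
#' @param n_ctrl Control genes drawn per set gene.
#' @param seed Integer seed for the control draw.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(norm, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1L) {
  gene_set <- sort(unique(intersect(gene_set, colnames(norm))))
  assert_that(length(gene_set) > 0, "no gene_set genes in the matrix")
  avg <- colMeans(norm)
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  names(bins) <- colnames(norm)
  ctrl <- with_seed(seed, unlist(lapply(gene_set, function(g) {
    pool <- names(bins)[bins == bins[[g]]]
    pool[sample.int(length(pool), min(n_ctrl, length(pool)))]
  })))
  rowMeans(norm[, gene_set, drop = FALSE]) -
    rowMeans(norm[, ctrl, drop = FALSE])
}

#' Call cell-cycle phase from S and G2M signature scores
#'
#' @param norm Cells x genes normalized matrix.
#' @param s_set,g2m_set Gene sets for the S and G2M programs.
#' @param ... Passed to [module_score()].
#' @return Tibble: `cell_id`, `s_score`, `g2m_score`,
#'   `phase` in G1/S/G2M (G1 when both scores are <= 0).
#' @export
cell_cycle_phase <- function(norm, s_set, g2m_set, ...) {
  s <- module_score(norm, s_set, ...)
  g <- module_score(norm, g2m_set, ...)
  phase <- ifelse(s <= 0 & g <= 0, "G1", ifelse(s > g, "S", "G2M"))
  tibble::tibble(cell_id = rownames(norm), s_score = s, g2m_score = g,
                 phase = phase)
}

#' Annotate cells by correlation to reference centroids
#'
#' Spearman correlation of every cell to each reference mean profile over
#' the shared genes; a cell takes the best-correlated label, or
#' `"unassigned"` when the best correlation falls below `min_rho`.
#'
#' @param norm Cells x genes normalized matrix.
#' @param reference_centroids Genes x types (or types x genes) matrix of
#'   reference mean profiles.
#' @param min_rho Minimum correlation to accept a label.
#' @return Tibble: `cell_id`, `label`, `rho`.
#' @export
annotate_by_reference <- function(norm, reference_centroids, min_rho = 0.2) {
  ref <- as.matrix(reference_centroids)
  if (!is.null(rownames(ref)) && any(rownames(ref) %in% colnames(norm)) == FALSE
      && any(colnames(ref) %in% colnames(norm)))
    ref <- t(ref)  # accept types x genes orientation
  shared <- intersect(rownames(ref), colnames(norm))
  assert_that(length(shared) >= 3, "too few shared genes with the reference")
  ref <- ref[shared, , drop = FALSE]
  rho <- suppressWarnings(
    cor(t(norm[, shared, drop = FALSE]), ref, method = "spearman"))
  rho[is.na(rho)] <- -Inf
  best <- max.col(rho, ties.method = "first")
  best_rho <- rho[cbind(seq_len(nrow(rho)), best)]
  tibble::tibble(
    cell_id = rownames(norm),
    label = ifelse(is.finite(best_rho) & best_rho >= min_rho,
                   colnames(ref)[best], "unassigned"),
    rho = ifelse(is.finite(best_rho), best_rho, NA_real_))
}

#' Remove additive batch effects by per-batch gene centering
#'
#' Subtracts each batch's per-gene mean, leaving every batch centered at
#' zero for every gene. A simple, transparent adjustment for location
#' shifts between samples or protocols.
#'
#' @param norm Cells x genes normalized matrix.
#' @param batch Batch label per cell (aligned with rows).
#' @param scale Also divide by the per-batch gene standard deviation
#'   (where positive).
#' @return Adjusted matrix of the same shape.
#' @export
batch_adjust <- function(norm, batch, scale = FALSE) {
  assert_that(length(batch) == nrow(norm), "one batch label per cell")
  out <- norm
  for (b in unique(batch)) {
    rows <- batch == b
    mu <- colMeans(out[rows, , drop = FALSE])
    out[rows, ] <- sweep(out[rows, , drop = FALSE], 2, mu, "-")
    if (scale) {
      sdv <- apply(out[rows, , drop = FALSE], 2, sd)
      sdv[sdv == 0 | is.na(sdv)] <- 1
      out[rows, ] <- sweep(out[rows, , drop = FALSE], 2, sdv, "/")
    }
  }
  out
}

#' Transcription-factor activity by per-cell multivariate regression
#'
#' Regresses each cell's log-expression vector on the TF-by-gene weight
#' matrix of a regulon network (one slope per TF, plus intercept); the
#' t-values of the slopes are the activity scores. Positive scores mean the
#' TF's weighted targets are up in that cell relative to the cell's
#' baseline.
#'
#' @param norm Cells x genes normalized matrix.
#' @param regulons Tibble with `tf`, `target`, `weight` (the regulon
#'   network); needs >= 2 TFs with >= 3 targets each in the matrix.
#' @return Cells x TFs matrix of t-values. Collinear TFs are dropped with
#'   a warning; an all-zero weight column is an error.
#' @export
tf_activity <- function(norm, regulons) {
  assert_that(all(c("tf", "target", "weight") %in% names(regulons)),
              "regulons needs tf/target/weight columns")
  assert_that(all(is.finite(regulons$weight)), "non-finite regulon weights")
  regulons <- dplyr::filter(regulons, .data$target %in% colnames(norm))
  sizes <- dplyr::count(regulons, .data$tf)
  keep_tf <- sizes$tf[sizes$n >= 3]
  assert_that(length(keep_tf) >= 2, "need >= 2 TFs with >= 3 targets")
  regulons <- dplyr::filter(regulons, .data$tf %in% keep_tf)
  tfs <- sort(unique(regulons$tf))
  X <- matrix(0, ncol(norm), length(tfs),
              dimnames = list(colnames(norm), tfs))
  X[cbind(match(regulons$target, colnames(norm)),
          match(regulons$tf, tfs))] <- regulons$weight
  if (any(colSums(X != 0) == 0))
    rlang::abort("regulon with all-zero weights: rank-deficient design")
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop_cols <- setdiff(colnames(D)[qrD$pivot[-seq_len(qrD$rank)]],
                         "(Intercept)")
    rlang::warn(paste0("dropping collinear TFs: ",
                       paste(drop_cols, collapse = ", ")))
    tfs <- setdiff(tfs, drop_cols)
    D <- cbind(`(Intercept)` = 1, X[, tfs, drop = FALSE])
    qrD <- qr(D)
  }
  Y <- t(norm)                        # genes x cells
  xtx_inv <- solve(crossprod(D))
  beta <- xtx_inv %*% crossprod(D, Y) # (1 + nTF) x cells
  res <- Y - D %*% beta
  df <- nrow(D) - ncol(D)
  assert_that(df > 0, "more TFs than genes")
  sigma2 <- colSums(res^2) / df
  se <- sqrt(outer(diag(xtx_inv), sigma2))
  tval <- t(beta / se)[, -1, drop = FALSE]
  colnames(tval) <- tfs
  rownames(tval) <- rownames(norm)
  tval
}

#' Chi-squared overlap test between a query gene set and references
#'
#' Builds the 2x2 membership table of each reference set against the query
#' within a gene universe and applies the chi-squared test with continuity
#' correction, switching to Fisher's exact test when any expected cell is
#' below 5 — the standard marker-set enrichment check used to transfer
#' annotations between panels.
#'
#' @param query_set Character vector of genes.
#' @param reference_sets Named list of character vectors.
#' @param universe_size Number of genes in the universe.
#' @return Tibble: `set`, `overlap`, `statistic` (NA for Fisher),
#'   `odds_ratio`, `p_value`, `method`.
#' @export
gene_set_overlap_test <- function(query_set, reference_sets, universe_size) {
  query_set <- unique(query_set)
  purrr::imap_dfr(reference_sets, function(ref, nm) {
    ref <- unique(ref)
    a <- length(intersect(query_set, ref))
    b <- length(query_set) - a
    c_ <- length(ref) - a
    d <- universe_size - a - b - c_
    assert_that(d >= 0, "universe_size smaller than the union of sets")
    tab <- matrix(c(a, b, c_, d), 2, 2)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- fisher.test(tab)
      tibble::tibble(set = nm, overlap = a, statistic = NA_real_,
                     odds_ratio = unname(ft$estimate), p_value = ft$p.value,
                     method = "fisher")
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
      or <- (a * d) / max(1e-12, (b * c_))
      tibble::tibble(set = nm, overlap = a,
                     statistic = unname(ct$statistic),
                     odds_ratio = or, p_value = ct$p.value,
                     method = "chi-squared")
    }
  })
}
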