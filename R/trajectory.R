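#' Cluster-level lineage topology from a minimum spanning tree
#'
#' Connects cluster centroids in PC space by a minimum spanning tree and
#' reads lineages as root-to-leaf paths, the cluster-scale skeleton of a
#' Slingshot-style trajectory. Tied edge weights are broken
#' lexicographically by cluster id so the tree is deterministic.
#'
#' @param centroids Clusters x dimensions matrix of centroid coordinates
#'   (rownames are cluster ids).
#' @param root_cluster Id of the root cluster (for differentiation
#'   trajectories, typically the cluster with the highest proliferation
#'   score; see [pick_root_cluster()]).
#' @return A `lineage_set`: list with `lineages` (list of ordered cluster
#'   id vectors, all starting at the root), `centroids`, `root`,
#'   `mst_edges` (tibble `from`, `to`, `length`).
#' @export
lineage_graph <- function(centroids, root_cluster) {
  centroids <- as.matrix(centroids)
  ids <- rownames(centroids) %||% as.character(seq_len(nrow(centroids)))
  rownames(centroids) <- ids
  assert_that(nrow(centroids) >= 2, "need >= 2 clusters")
  assert_that(as.character(root_cluster) %in% ids, "root cluster not found")
  d <- as.matrix(dist(centroids))
  # deterministic tie-break: nudge each unordered pair by a distinct
  # epsilon that increases lexicographically in cluster id
  r <- rank(ids)
  n_id <- length(ids)
  eps <- outer(r, r, function(a, b) pmin(a, b) * n_id + pmax(a, b)) *
    1e-12 * max(d, 1)
  g <- igraph::graph_from_adjacency_matrix(d + eps,
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g)
  deg <- igraph::degree(mst)
  root <- as.character(root_cluster)
  leaves <- setdiff(ids[deg == 1], root)
  if (length(leaves) == 0) leaves <- ids[ids != root]
  lineages <- lapply(leaves, function(leaf) {
    p <- igraph::shortest_paths(mst, from = root, to = leaf)$vpath[[1]]
    ids[as.integer(p)]
  })
  names(lineages) <- paste0("lineage_", seq_along(lineages))
  el <- igraph::as_edgelist(mst)
  structure(list(
    lineages = lineages, centroids = centroids, root = root,
    mst_edges = tibble::tibble(from = el[, 1], to = el[, 2],
                               length = d[el])),
    class = "lineage_set")
}

#' @exportS3Method base::print
print.lineage_set <- function(x, ...) {
  cat("<lineage_set> root ", x$root, "; ", length(x$lineages),
      " lineage(s):\n", sep = "")
  for (nm in names(x$lineages))
    cat("  ", nm, ": ", paste(x$lineages[[nm]], collapse = " -> "), "\n",
        sep = "")
  invisible(x)
}

#' Pick the trajectory root as the most proliferative cluster
#'
#' @param phase_scores Tibble from [cell_cycle_phase()].
#' @param clusters Cluster label per cell (aligned with `phase_scores`).
#' @return The cluster id with the highest mean S + G2M score.
#' @export
pick_root_cluster <- function(phase_scores, clusters) {
  agg <- tibble::tibble(cluster = clusters,
                        act = phase_scores$s_score + phase_scores$g2m_score) |>
    dplyr::summarise(act = mean(.data$act), .by = "cluster")
  as.character(agg$cluster[which.max(agg$act)])
}

# orthogonal projection of points onto one piecewise-linear path; returns
# per-point arc length and squared distance to the path
project_on_path <- function(points, path_coords) {
  n_seg <- nrow(path_coords) - 1
  seg_len <- sqrt(rowSums((path_coords[-1, , drop = FALSE] -
                             path_coords[-nrow(path_coords), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg_len))
  best_d2 <- rep(Inf, nrow(points))
  best_t <- rep(0, nrow(points))
  for (s in seq_len(n_seg)) {
    a <- path_coords[s, ]; b <- path_coords[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    rel <- sweep(points, 2, a, "-")
    tt <- if (len2 > 0) pmin(1, pmax(0, (rel %*% ab) / len2)) else
      matrix(0, nrow(points))
    proj <- outer(as.vector(tt), ab)
    d2 <- rowSums((rel - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_t[upd] <- cum[s] + as.vector(tt)[upd] * seg_len[s]
  }
  list(t = best_t, d2 = best_d2, total_length = cum[n_seg + 1])
}

#' Per-cell pseudotime along piecewise-linear lineage paths
#'
#' Projects each cell orthogonally onto the piecewise-linear path through
#' the centroids of its nearest lineage; pseudotime is the arc length from
#' the root to the projection. Cells equidistant to two lineages take the
#' lower-index lineage.
#'
#' @param cells_pc Cells x dimensions matrix in the same space as the
#'   lineage centroids.
#' @param lineages A `lineage_set`.
#' @return Tibble: `cell_id`, `lineage`, `pseudotime`, `dist_to_path`.
#' @export
pseudotime <- function(cells_pc, lineages) {
  cells_pc <- as.matrix(cells_pc)
  dims <- seq_len(ncol(lineages$centroids))
  pts <- cells_pc[, dims, drop = FALSE]
  proj <- lapply(lineages$lineages, function(lin)
    project_on_path(pts, lineages$centroids[lin, , drop = FALSE]))
  d2 <- vapply(proj, function(p) p$d2, numeric(nrow(pts)))
  d2 <- matrix(d2, nrow = nrow(pts))
  pick <- apply(d2, 1, which.min)   # ties -> lowest index
  tibble::tibble(
    cell_id = rownames(cells_pc) %||% as.character(seq_len(nrow(pts))),
    lineage = names(lineages$lineages)[pick],
    pseudotime = vapply(seq_len(nrow(pts)),
                        function(i) proj[[pick[i]]]$t[i], numeric(1)),
    dist_to_path = sqrt(d2[cbind(seq_len(nrow(pts)), pick)]))
}
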