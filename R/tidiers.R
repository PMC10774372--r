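#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a clustering result into a per-cell tibble
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return Tibble: `cell_id`, `cluster`.
#' @export
tidy.cluster_result <- function(x, ...) x$assignments

#' @rdname tidy.cluster_result
#' @return `glance()`: one-row tibble with `n_cells`, `n_clusters`,
#'   `modularity`, `n_pcs`, `k`, `resolution`.
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$assignments),
                 n_clusters = nrow(x$centroids),
                 modularity = x$params$modularity,
                 n_pcs = x$params$n_pcs, k = x$params$k,
                 resolution = x$params$resolution)
}

#' Tidy a lineage set into per-lineage cluster orderings
#'
#' @param x A `lineage_set`.
#' @param ... Unused.
#' @return Tibble: `lineage`, `position`, `cluster`.
#' @export
tidy.lineage_set <- function(x, ...) {
  purrr::imap_dfr(x$lineages, function(lin, nm)
    tibble::tibble(lineage = nm, position = seq_along(lin), cluster = lin))
}

#' @rdname tidy.lineage_set
#' @export
glance.lineage_set <- function(x, ...) {
  tibble::tibble(n_lineages = length(x$lineages), root = x$root,
                 n_clusters = nrow(x$centroids),
                 total_edge_length = sum(x$mst_edges$length))
}

#' Tidy a co-localization enrichment matrix into type pairs
#'
#' @param x An `enrichment_matrix`.
#' @param ... Unused.
#' @return Tibble: `type_a`, `type_b` (a <= b), `score`, `p_value`,
#'   `observed`, `expected`.
#' @export
tidy.enrichment_matrix <- function(x, ...) {
  lev <- rownames(x$score)
  purrr::map_dfr(seq_along(lev), function(i)
    purrr::map_dfr(i:length(lev), function(j)
      tibble::tibble(type_a = lev[i], type_b = lev[j],
                     score = x$score[i, j], p_value = x$p_value[i, j],
                     observed = x$observed[i, j],
                     expected = x$expected[i, j])))
}

#' @rdname tidy.enrichment_matrix
#' @export
glance.enrichment_matrix <- function(x, ...) {
  tibble::tibble(n_types = nrow(x$score), B = x$B, seed = x$seed,
                 n_enriched = sum(x$score > 0 & x$p_value < 0.05,
                                  na.rm = TRUE) / 2)
}

#' Tidy deconvolved proportions into long format
#'
#' @param x A `deconvolution_result`.
#' @param ... Unused.
#' @return Tibble: `sample`, `state`, `proportion`.
#' @export
tidy.deconvolution_result <- function(x, ...) {
  tibble::as_tibble(x$proportions, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "state",
                        values_to = "proportion")
}

#' @rdname tidy.deconvolution_result
#' @export
glance.deconvolution_result <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$proportions),
                 n_states = ncol(x$proportions),
                 mean_residual = mean(x$residual_norm),
                 condition_number = x$condition_number)
}

#' Tidy a compartment differential-expression result
#'
#' @param x A `compartment_de`.
#' @param ... Unused.
#' @return The per-gene DE tibble.
#' @export
tidy.compartment_de <- function(x, ...) x$table

#' @rdname tidy.compartment_de
#' @export
glance.compartment_de <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$table),
                 n_significant = sum(x$table$significant),
                 n_nodular = length(x$gene_sets$nodular),
                 n_internodular = length(x$gene_sets$internodular),
                 lfc_min = x$params$lfc_min, alpha = x$params$alpha)
}
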