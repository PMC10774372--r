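#' Differential expression between nodular and internodular compartments
#'
#' Per-gene linear model `expression ~ compartment + patient` on log2-scale
#' bulk profiles: patient enters as a fixed effect so the paired
#' microdissection design is batch-adjusted. Genes pass at
#' `|log2FC| >= lfc_min` and BH-adjusted `p <= alpha` (defaults 0.5 and
#' 0.05), and the significant genes are split into nodular-up and
#' internodular-up sets.
#'
#' @param bulk Genes x samples matrix (log2 scale).
#' @param metadata Tibble with `sample`, `patient`,
#'   `compartment` (nodular/internodular), rows matching `colnames(bulk)`.
#' @param lfc_min Minimum absolute log2 fold-change (nodular vs
#'   internodular).
#' @param alpha Maximum BH-adjusted p-value.
#' @return A `compartment_de` list: `table` (tibble `gene`, `log2_fc`,
#'   `t`, `p_value`, `q_value`, `significant`), `gene_sets` (list
#'   `nodular`, `internodular`), `params`.
#' @export
de_between_compartments <- function(bulk, metadata, lfc_min = 0.5,
                                    alpha = 0.05) {
  assert_that(all(colnames(bulk) == metadata$sample),
              "metadata rows must match bulk columns")
  assert_that(all(metadata$compartment %in% c("nodular", "internodular")),
              "compartment must be nodular/internodular")
  both <- dplyr::summarise(metadata,
                           n_comp = dplyr::n_distinct(.data$compartment),
                           .by = "patient")
  assert_that(sum(both$n_comp == 2) >= 2,
              "need >= 2 patients with both compartments")
  comp <- factor(metadata$compartment, c("internodular", "nodular"))
  pat <- factor(metadata$patient)
  D <- stats::model.matrix(~ comp + pat)
  if (qr(D)$rank < ncol(D))
    rlang::abort("confounded design: compartment aliases patient")
  Y <- t(as.matrix(bulk))               # samples x genes
  xtx_inv <- solve(crossprod(D))
  beta <- xtx_inv %*% crossprod(D, Y)
  res <- Y - D %*% beta
  df <- nrow(D) - ncol(D)
  assert_that(df > 0, "not enough residual degrees of freedom")
  sigma2 <- colSums(res^2) / df
  se <- sqrt(xtx_inv[2, 2] * sigma2)
  lfc <- beta[2, ]
  tval <- lfc / se
  p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  q <- p.adjust(p, "BH")
  tab <- tibble::tibble(gene = rownames(bulk), log2_fc = lfc, t = tval,
                        p_value = p, q_value = q,
                        significant = abs(lfc) >= lfc_min & q <= alpha) |>
    dplyr::arrange(.data$q_value)
  structure(list(
    table = tab,
    gene_sets = list(
      nodular = tab$gene[tab$significant & tab$log2_fc > 0],
      internodular = tab$gene[tab$significant & tab$log2_fc < 0]),
    params = list(lfc_min = lfc_min, alpha = alpha, df = df)),
    class = "compartment_de")
}

#' @exportS3Method base::print
print.compartment_de <- function(x, ...) {
  cat("<compartment_de> ", sum(x$table$significant), " of ",
      nrow(x$table), " genes pass |log2FC| >= ", x$params$lfc_min,
      ", q <= ", x$params$alpha, " (nodular-up ",
      length(x$gene_sets$nodular), ", internodular-up ",
      length(x$gene_sets$internodular), ")\n", sep = "")
  invisible(x)
}

#' Single-sample rank-weighted enrichment scores
#'
#' For each sample, genes are ranked by expression in decreasing order and
#' a weighted Kolmogorov-Smirnov running sum is walked down the list
#' (in-set steps weighted by `(N - position + 1)^tau`); the score is the
#' signed maximum deviation, positive when the set concentrates at the top
#' of the ranking. This is the single-sample (ssGSEA-style) statistic used
#' to map compartment signature sets onto cluster pseudobulks.
#'
#' @param profiles Genes x samples matrix.
#' @param gene_sets Named list of gene sets.
#' @param tau Rank weighting exponent (`0` = unweighted KS).
#' @return Sets x samples matrix of scores.
#' @export
signature_enrichment <- function(profiles, gene_sets, tau = 0.25) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  out <- matrix(NA_real_, length(gene_sets), ncol(profiles),
                dimnames = list(names(gene_sets), colnames(profiles)))
  for (j in seq_len(ncol(profiles))) {
    ord <- order(profiles[, j], decreasing = TRUE)
    ranked <- rownames(profiles)[ord]
    w <- (n - seq_len(n) + 1)^tau
    for (s in seq_along(gene_sets)) {
      hit <- ranked %in% gene_sets[[s]]
      m <- sum(hit)
      if (m == 0 || m == n) { out[s, j] <- NA_real_; next }
      p_hit <- cumsum(w * hit) / sum(w[hit])
      p_miss <- cumsum(!hit) / (n - m)
      dev <- p_hit - p_miss
      out[s, j] <- dev[which.max(abs(dev))]
    }
  }
  out
}

#' Deconvolve bulk profiles into cell-state proportions
#'
#' Non-negative least squares of each bulk sample against the state
#' signature matrix over the shared genes. Signature columns and bulk
#' samples are normalized to unit sum, making the fit invariant to a
#' common rescaling of a sample, and the NNLS coefficients are renormalized
#' to the proportion simplex.
#'
#' @param bulk Genes x samples non-negative matrix.
#' @param state_signatures Genes x states non-negative matrix.
#' @return A `deconvolution_result`: `proportions` (samples x states, rows
#'   sum to 1), `residual_norm` per sample, `condition_number` of the
#'   signature matrix on shared genes.
#' @export
deconvolve_bulk <- function(bulk, state_signatures) {
  S <- as.matrix(state_signatures)
  assert_that(ncol(S) >= 2, "need >= 2 states")
  shared <- intersect(rownames(bulk), rownames(S))
  assert_that(length(shared) >= ncol(S), "fewer shared genes than states")
  S <- S[shared, , drop = FALSE]
  S <- sweep(S, 2, colSums(S), "/")
  kappa_s <- kappa(S, exact = TRUE)
  if (qr(S)$rank < ncol(S))
    rlang::warn(paste0("rank-deficient signatures (condition number ",
                       format(kappa_s), ")"))
  B <- as.matrix(bulk)[shared, , drop = FALSE]
  B <- sweep(B, 2, colSums(B), "/")
  fits <- apply(B, 2, function(b) pracma::lsqnonneg(S, b))
  P <- t(vapply(fits, function(f) f$x, numeric(ncol(S))))
  resid <- vapply(fits, function(f) sqrt(f$resid.norm), numeric(1))
  P <- P / pmax(rowSums(P), .Machine$double.eps)
  dimnames(P) <- list(colnames(bulk), colnames(S))
  structure(list(proportions = P, residual_norm = resid,
                 condition_number = kappa_s),
            class = "deconvolution_result")
}

#' @exportS3Method base::print
print.deconvolution_result <- function(x, ...) {
  cat("<deconvolution_result> ", nrow(x$proportions), " samples x ",
      ncol(x$proportions), " states; mean residual ",
      signif(mean(x$residual_norm), 3), "\n", sep = "")
  invisible(x)
}

#' Group statistics on per-sample compositions
#'
#' Two-sided t-tests for two-group contrasts and Spearman correlation for
#' continuous covariates, applied to each value column (e.g. deconvolved
#' proportions per compartment, or state percentages per patient against
#' age of onset). Degenerate inputs (zero variance in both groups, or a
#' constant covariate) are reported as NA rather than an error.
#'
#' @param data Tibble with the value columns and the grouping column.
#' @param value_cols Character vector of value column names.
#' @param by Name of the grouping (2 levels -> t-test) or covariate
#'   (numeric -> Spearman) column.
#' @return Tibble: `variable`, `method`, `estimate` (mean difference or
#'   rho), `statistic`, `p_value`.
#' @export
composition_statistics <- function(data, value_cols, by) {
  g <- data[[by]]
  is_group <- is.character(g) || is.factor(g) || is.logical(g)
  purrr::map_dfr(value_cols, function(v) {
    x <- data[[v]]
    if (is_group) {
      lv <- unique(as.character(g))
      assert_that(length(lv) == 2, "grouping column must have 2 levels")
      a <- x[g == lv[1]]; b <- x[g == lv[2]]
      if (sd(a) == 0 && sd(b) == 0)
        return(tibble::tibble(variable = v, method = "t-test",
                              estimate = mean(a) - mean(b),
                              statistic = NA_real_, p_value = NA_real_))
      tt <- t.test(a, b, alternative = "two.sided")
      tibble::tibble(variable = v, method = "t-test",
                     estimate = unname(diff(rev(tt$estimate))),
                     statistic = unname(tt$statistic), p_value = tt$p.value)
    } else {
      if (sd(x) == 0 || sd(g) == 0)
        return(tibble::tibble(variable = v, method = "spearman",
                              estimate = NA_real_, statistic = NA_real_,
                              p_value = NA_real_))
      ct <- suppressWarnings(cor.test(x, g, method = "spearman"))
      tibble::tibble(variable = v, method = "spearman",
                     estimate = unname(ct$estimate),
                     statistic = unname(ct$statistic), p_value = ct$p.value)
    }
  })
}
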