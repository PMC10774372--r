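#' Default compartment composition for simulated microdissected bulks
#'
#' Mean cell-state proportions of the two histological compartments: the
#' internodular compartment is rich in proliferating/early CGNP-like and
#' stromal cells, the nodular compartment in migrating, neuronally
#' differentiated and astrocytic-like cells. Every state's mean differs
#' between compartments with a definite sign, so deconvolution benchmarks
#' have an unambiguous planted direction.
#'
#' @return Tibble: `compartment`, one column per state; rows sum to 1.
#' @export
default_compartment_proportions <- function() {
  tibble::tribble(
    ~compartment,   ~prolif_early_cgnp, ~early_cgnp, ~migrating,
                    ~differentiated, ~astrocytic_like, ~stromal_immune,
    "internodular", 0.25, 0.28, 0.17, 0.05, 0.05, 0.20,
    "nodular",      0.05, 0.07, 0.23, 0.45, 0.08, 0.12
  )
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' Simulate microdissected compartment bulk profiles
#'
#' Each bulk sample is a mixture of the state signature columns at
#' sample-specific proportions drawn around the compartment means, scaled
#' by multiplicative log-normal measurement noise and (optionally) a
#' per-patient batch factor. True proportions are emitted.
#'
#' @param state_signatures Genes x states non-negative matrix; columns are
#'   normalized to sum to 1 internally.
#' @param design Tibble with columns `sample`, `patient`, `compartment`
#'   (values `nodular` / `internodular`).
#' @param proportions Compartment mean proportions as returned by
#'   [default_compartment_proportions()].
#' @param concentration Dirichlet concentration controlling sample-to-sample
#'   proportion spread around the compartment mean.
#' @param noise_sd Log-normal measurement noise sd (0 = noiseless).
#' @param batch_sd Log-normal per-patient, per-gene batch factor sd
#'   (0 = off).
#' @param seed Integer seed.
#' @return List with `bulk` (genes x samples matrix), `metadata` (the
#'   design tibble), and `true_proportions` (samples x states matrix).
#' @export
simulate_bulk_compartments <- function(state_signatures,
                                       design = default_bulk_design(),
                                       proportions = default_compartment_proportions(),
                                       concentration = 100,
                                       noise_sd = 0.1, batch_sd = 0.2,
                                       seed = 1L) {
  S <- as.matrix(state_signatures)
  S <- sweep(S, 2, colSums(S), "/")
  states <- colnames(S)
  assert_that(all(states %in% names(proportions)),
              "proportions must cover every signature column")
  with_seed(seed, {
    n_s <- nrow(design)
    P <- matrix(NA_real_, n_s, length(states),
                dimnames = list(design$sample, states))
    for (i in seq_len(n_s)) {
      mu <- unlist(proportions[proportions$compartment == design$compartment[i],
                               states])
      P[i, ] <- if (concentration > 0)
        rdirichlet(1, mu * concentration) else mu
    }
    bulk <- S %*% t(P)
    colnames(bulk) <- design$sample
    if (batch_sd > 0) {
      pats <- unique(design$patient)
      bf <- matrix(exp(rnorm(nrow(S) * length(pats), 0, batch_sd)),
                   nrow(S), length(pats), dimnames = list(rownames(S), pats))
      bulk <- bulk * bf[, design$patient, drop = FALSE]
    }
    if (noise_sd > 0)
      bulk <- bulk * matrix(exp(rnorm(length(bulk), 0, noise_sd)),
                            nrow(bulk), ncol(bulk))
    list(bulk = bulk, metadata = design, true_proportions = P)
  })
}

#' Paired bulk design: both compartments microdissected from each patient
#'
#' @param n_patients Number of patients.
#' @return Tibble with `sample`, `patient`, `compartment`.
#' @export
default_bulk_design <- function(n_patients = 6) {
  tidyr::crossing(patient = paste0("P", seq_len(n_patients)),
                  compartment = c("internodular", "nodular")) |>
    dplyr::mutate(sample = paste0(.data$patient, "_", .data$compartment),
                  .before = 1)
}
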