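# paired bulk design: n_pat patients x 2 compartments, patient offsets,
# a block of genes shifted in nodular samples by `lfc`
paired_bulk <- function(n_genes = 400, n_pat = 6, n_de = 40, lfc = 1,
                        sd = 0.2, seed = 1) {
  set.seed(seed)
  meta <- tibble::tibble(
    sample = paste0("s", seq_len(2 * n_pat)),
    patient = rep(paste0("P", seq_len(n_pat)), each = 2),
    compartment = rep(c("internodular", "nodular"), n_pat))
  base <- runif(n_genes, 4, 10)
  pat_shift <- rnorm(n_pat, sd = 1)
  bulk <- sapply(seq_len(2 * n_pat), function(j) {
    mu <- base + pat_shift[(j + 1) %/% 2]
    if (meta$compartment[j] == "nodular")
      mu[seq_len(n_de)] <- mu[seq_len(n_de)] + lfc
    mu + rnorm(n_genes, sd = sd)
  })
  dimnames(bulk) <- list(paste0("g", seq_len(n_genes)), meta$sample)
  list(bulk = bulk, meta = meta, de_genes = paste0("g", seq_len(n_de)))
}

test_that("planted compartment DE is recovered with controlled FDR", {
  fx <- paired_bulk()
  de <- de_between_compartments(fx$bulk, fx$meta)
  called <- de$table$gene[de$table$significant]
  sens <- length(intersect(called, fx$de_genes)) / length(fx$de_genes)
  fdr <- if (length(called) == 0) 0 else
    length(setdiff(called, fx$de_genes)) / length(called)
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
  # planted genes are up in nodular
  expect_true(all(intersect(called, fx$de_genes) %in% de$gene_sets$nodular))
})

test_that("effects below the fold-change limit are excluded however significant", {
  fx <- paired_bulk(lfc = 0.4, sd = 0.05, seed = 2)
  de <- de_between_compartments(fx$bulk, fx$meta)
  tab <- dplyr::filter(de$table, gene %in% fx$de_genes)
  expect_true(all(tab$q_value < 0.05))     # strongly significant...
  expect_false(any(tab$significant))       # ...but under the 0.5 limit
})

test_that("the patient covariate absorbs paired batch shifts", {
  # null data with big patient offsets: the model must not call anything
  fx <- paired_bulk(n_de = 0, lfc = 0, seed = 3)
  de <- de_between_compartments(fx$bulk, fx$meta)
  expect_equal(sum(de$table$significant), 0)
  # p-values approximately uniform under the null
  expect_gt(ks.test(de$table$p_value, "punif")$p.value, 0.01)
})

test_that("log2 fold-change estimates match a per-gene lm oracle", {
  fx <- paired_bulk(n_genes = 20, n_de = 5, seed = 4)
  de <- de_between_compartments(fx$bulk, fx$meta)
  g <- "g1"
  fit <- lm(fx$bulk[g, ] ~ factor(fx$meta$compartment,
                                  c("internodular", "nodular")) +
              factor(fx$meta$patient))
  co <- summary(fit)$coefficients[2, ]
  row <- dplyr::filter(de$table, gene == g)
  expect_equal(unname(row$log2_fc), unname(co["Estimate"]), tolerance = 1e-10)
  expect_equal(unname(row$t), unname(co["t value"]), tolerance = 1e-10)
  expect_equal(unname(row$p_value), unname(co["Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("a fully confounded design is refused", {
  meta <- tibble::tibble(sample = paste0("s", 1:4),
                         patient = c("P1", "P1", "P2", "P2"),
                         compartment = c("nodular", "nodular",
                                         "internodular", "internodular"))
  bulk <- matrix(rnorm(40), 10, 4,
                 dimnames = list(paste0("g", 1:10), meta$sample))
  expect_error(de_between_compartments(bulk, meta), "confounded|>= 2 patients")
})

test_that("unweighted enrichment of extreme sets matches hand computation", {
  prof <- matrix(c(4, 3, 2, 1), 4, 1,
                 dimnames = list(paste0("g", 1:4), "s1"))
  top <- list(set = c("g1", "g2"))
  bottom <- list(set = c("g3", "g4"))
  expect_equal(signature_enrichment(prof, top, tau = 0)["set", "s1"], 1)
  expect_equal(signature_enrichment(prof, bottom, tau = 0)["set", "s1"], -1)
})

test_that("enrichment is antisymmetric under profile negation", {
  set.seed(8)
  prof <- matrix(rnorm(100), 100, 1,
                 dimnames = list(paste0("g", 1:100), "s1"))
  gs <- list(a = paste0("g", 1:10))
  up <- signature_enrichment(prof, gs, tau = 0)
  dn <- signature_enrichment(-prof, gs, tau = 0)
  expect_equal(unname(up["a", 1]), unname(-dn["a", 1]), tolerance = 1e-12)
})

test_that("random gene sets score near zero on average", {
  set.seed(9)
  prof <- matrix(rnorm(500 * 4), 500, 4,
                 dimnames = list(paste0("g", 1:500), paste0("s", 1:4)))
  scores <- replicate(50, {
    gs <- list(r = sample(rownames(prof), 25))
    mean(signature_enrichment(prof, gs, tau = 0)["r", ])
  })
  expect_lt(abs(mean(scores)), 0.05)
  # rank weighting (tau > 0) adds a positive offset but must preserve order:
  # a set planted at the top outranks every random set
  top_set <- list(t = rownames(prof)[order(prof[, 1],
                                           decreasing = TRUE)][1:25])
  top_score <- signature_enrichment(prof, top_set)["t", 1]
  rand <- replicate(20, {
    gs <- list(r = sample(rownames(prof), 25))
    signature_enrichment(prof, gs)["r", 1]
  })
  expect_gt(top_score, max(rand))
})

test_that("degenerate gene sets yield NA scores", {
  prof <- matrix(1:4, 4, 1, dimnames = list(paste0("g", 1:4), "s1"))
  res <- signature_enrichment(prof, list(none = "absent",
                                         all = paste0("g", 1:4)))
  expect_true(all(is.na(res)))
})

test_that("noiseless deconvolution recovers proportions exactly", {
  set.seed(12)
  S <- matrix(runif(300 * 4, 0.1, 2), 300, 4,
              dimnames = list(paste0("g", 1:300), paste0("st", 1:4)))
  P <- rbind(c(0.4, 0.3, 0.2, 0.1), c(0.25, 0.25, 0.25, 0.25),
             c(0.7, 0.1, 0.1, 0.1))
  Sn <- sweep(S, 2, colSums(S), "/")
  bulk <- Sn %*% t(P)
  colnames(bulk) <- paste0("b", 1:3)
  res <- deconvolve_bulk(bulk, S)
  expect_equal(unname(res$proportions), P, tolerance = 1e-6)
  expect_lt(max(res$residual_norm), 1e-8)
})

test_that("a pure sample deconvolves to a one-hot vector", {
  set.seed(13)
  S <- matrix(runif(200 * 3, 0.1, 2), 200, 3,
              dimnames = list(paste0("g", 1:200), c("a", "b", "c")))
  bulk <- matrix(S[, "b"], 200, 1, dimnames = list(rownames(S), "s1"))
  res <- deconvolve_bulk(bulk, S)
  expect_equal(unname(res$proportions[1, ]), c(0, 1, 0), tolerance = 1e-6)
})

test_that("deconvolution is invariant to rescaling a sample", {
  set.seed(14)
  S <- matrix(runif(200 * 3, 0.1, 2), 200, 3,
              dimnames = list(paste0("g", 1:200), c("a", "b", "c")))
  bulk <- S %*% c(0.5, 0.3, 0.2)
  bulk <- cbind(s1 = bulk[, 1], s2 = 37 * bulk[, 1])
  res <- deconvolve_bulk(bulk, S)
  expect_equal(res$proportions["s1", ], res$proportions["s2", ],
               tolerance = 1e-9)
})

test_that("deconvolution stays accurate under count noise", {
  cfg <- expression_config("spatial")
  S <- t(nodular:::noise_free_state_means(cfg))
  design <- default_bulk_design(6)
  sim <- simulate_bulk_compartments(S, design, noise_sd = 0.1,
                                    batch_sd = 0.1, seed = 15)
  res <- deconvolve_bulk(sim$bulk, S)
  truth <- as.matrix(sim$true_proportions[, colnames(res$proportions)])
  mae <- mean(abs(res$proportions - truth))
  expect_lte(mae, 0.05)
})

test_that("composition t-test matches the base oracle and detects a shift", {
  set.seed(17)
  d <- tibble::tibble(
    group = rep(c("x", "y"), each = 8),
    v1 = c(rnorm(8, 0.6, 0.05), rnorm(8, 0.3, 0.05)),  # shifted
    v2 = rnorm(16, 0.2, 0.05))                          # null
  res <- composition_statistics(d, c("v1", "v2"), "group")
  or1 <- t.test(d$v1[d$group == "x"], d$v1[d$group == "y"])
  expect_equal(res$p_value[res$variable == "v1"], or1$p.value)
  expect_equal(res$estimate[res$variable == "v1"],
               unname(diff(rev(or1$estimate))))
  expect_lt(res$p_value[res$variable == "v1"], 0.01)
  expect_gt(res$p_value[res$variable == "v2"], 0.05)
})

test_that("numeric covariates use Spearman correlation", {
  d <- tibble::tibble(age = c(1, 2, 3, 4, 5, 6),
                      v = c(0.1, 0.15, 0.3, 0.32, 0.5, 0.61))
  res <- composition_statistics(d, "v", "age")
  expect_equal(res$method, "spearman")
  expect_equal(res$estimate, 1)
  d2 <- tibble::tibble(age = rep(3, 5), v = runif(5))
  res2 <- composition_statistics(d2, "v", "age")
  expect_true(is.na(res2$p_value))
})

test_that("degenerate two-group input yields NA rather than an error", {
  d <- tibble::tibble(group = rep(c("x", "y"), each = 3),
                      v = c(1, 1, 1, 2, 2, 2))
  res <- composition_statistics(d, "v", "group")
  expect_equal(res$estimate, -1)
  expect_true(is.na(res$p_value))
  bad <- tibble::tibble(group = c("x", "y", "z"), v = 1:3)
  expect_error(composition_statistics(bad, "v", "group"), "2 levels")
})
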