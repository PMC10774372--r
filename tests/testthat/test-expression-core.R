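# two well-separated Gaussian blobs in gene space
two_blob_matrix <- function(n_per = 60, n_genes = 40, shift = 5, seed = 3) {
  set.seed(seed)
  m <- matrix(rnorm(2 * n_per * n_genes), 2 * n_per, n_genes)
  m[seq_len(n_per), seq_len(10)] <- m[seq_len(n_per), seq_len(10)] + shift
  rownames(m) <- sprintf("c%03d", seq_len(2 * n_per))
  colnames(m) <- paste0("g", seq_len(n_genes))
  m
}

test_that("normalization equalizes library sizes on the count scale", {
  counts <- matrix(rpois(200, 5), 20, 10,
                   dimnames = list(paste0("c", 1:20), paste0("g", 1:10)))
  norm <- normalize_counts(counts, scale_factor = 1e3)
  back <- expm1(norm)
  expect_equal(unname(rowSums(back)), rep(1e3, 20))
  zero <- counts; zero[1, ] <- 0L
  expect_silent(nz <- normalize_counts(zero))
  expect_true(all(nz[1, ] == 0))
})

test_that("two separated blobs are clustered perfectly", {
  m <- two_blob_matrix()
  res <- embed_and_cluster(m, n_pcs = 10, k = 10, seed = 1)
  truth <- rep(1:2, each = 60)
  expect_equal(length(unique(res$assignments$cluster)), 2)
  tab <- table(res$assignments$cluster, truth)
  expect_equal(sum(apply(tab, 1, max)), 120)  # pure clusters
})

test_that("clustering is invariant to the input row order", {
  m <- two_blob_matrix()
  res1 <- embed_and_cluster(m, n_pcs = 10, k = 10, seed = 1)
  perm <- sample(nrow(m))
  res2 <- embed_and_cluster(m[perm, ], n_pcs = 10, k = 10, seed = 1)
  a1 <- res1$assignments
  a2 <- res2$assignments[match(a1$cell_id, res2$assignments$cell_id), ]
  # labels may be renamed, but the partition must be identical
  expect_equal(length(unique(paste(a1$cluster, a2$cluster))),
               length(unique(a1$cluster)))
})

test_that("near-identical clusters are merged transitively", {
  # fabricate a cluster_result with 3 clusters: 1 and 2 identical profile,
  # 3 orthogonal
  set.seed(5)
  base <- rnorm(30)
  m <- rbind(matrix(rep(base, 10), 10, byrow = TRUE),
             matrix(rep(base, 10), 10, byrow = TRUE),
             matrix(rep(rev(base), 10), 10, byrow = TRUE)) +
    matrix(rnorm(900, sd = 0.2), 30, 30)
  rownames(m) <- paste0("c", 1:30); colnames(m) <- paste0("g", 1:30)
  cl <- structure(list(
    assignments = tibble::tibble(cell_id = rownames(m),
                                 cluster = rep(1:3, each = 10)),
    centroids = cluster_centroids(m, tibble::tibble(
      cell_id = rownames(m), cluster = rep(1:3, each = 10))),
    pcs = NULL, params = list()), class = "cluster_result")
  merged <- merge_similar_clusters(cl, m, r_min = 0.95)
  lab <- merged$assignments$cluster
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:20])), 1)
  expect_false(lab[1] == lab[30])
  # with r_min above the observed correlation nothing merges
  keep <- merge_similar_clusters(cl, m, r_min = 0.9999)
  expect_equal(length(unique(keep$assignments$cluster)), 3)
})

test_that("markers recover a planted differential gene and not a null one", {
  set.seed(11)
  m <- matrix(rnorm(200 * 20), 200, 20,
              dimnames = list(paste0("c", 1:200), paste0("g", 1:20)))
  cl <- rep(1:2, each = 100)
  m[cl == 1, 1] <- m[cl == 1, 1] + 3   # planted marker of cluster 1
  mk <- find_markers(m, cl)
  g1 <- dplyr::filter(mk, cluster == 1, gene == "g1")
  expect_lt(g1$q_value, 1e-6)
  expect_gt(g1$log2_fc, 0)
  null_q <- dplyr::filter(mk, cluster == 1, gene != "g1")$q_value
  expect_gt(min(null_q), 0.05)
})

test_that("zero-variance genes get p = 1 instead of an error", {
  m <- matrix(rnorm(60), 20, 3,
              dimnames = list(paste0("c", 1:20), paste0("g", 1:3)))
  m[, 2] <- 7
  mk <- find_markers(m, rep(1:2, each = 10))
  expect_equal(dplyr::filter(mk, gene == "g2")$p_value, c(1, 1))
})

test_that("tiny clusters are skipped with a warning", {
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("c", 1:10), paste0("g", 1:4)))
  expect_warning(mk <- find_markers(m, c(rep(1, 8), 2, 2)), "< 3 cells")
  expect_setequal(unique(mk$cluster), 1)
})

test_that("module score is near zero for a random set and shifted for a planted one", {
  set.seed(21)
  base_mu <- runif(300, 0, 4)
  m <- matrix(rnorm(400 * 300), 400, 300,
              dimnames = list(paste0("c", 1:400), paste0("g", 1:300)))
  m <- sweep(m, 2, base_mu, "+")
  rand_set <- sample(colnames(m), 20)
  sc0 <- module_score(m, rand_set)
  expect_lt(abs(mean(sc0)), 0.05)
  # shift a small set by +1 in half the cells; sparse enough that the
  # expression-matched control bins stay dominated by unshifted genes
  planted <- sample(colnames(m), 6)
  m2 <- m
  m2[1:200, planted] <- m2[1:200, planted] + 1
  sc1 <- module_score(m2, planted)
  # bin matching absorbs the population-average part of the shift, so the
  # on/off contrast carries the planted +1
  expect_lt(abs((mean(sc1[1:200]) - mean(sc1[201:400])) - 1), 0.15)
  expect_gt(mean(sc1[1:200]), 0)
  expect_lt(mean(sc1[201:400]), 0)
  # invariance to gene order within the set
  expect_identical(sc1, module_score(m2, rev(planted)))
})

test_that("cell-cycle phase is G1 for flat cells and detects a planted program", {
  set.seed(31)
  m <- matrix(rnorm(300 * 200), 300, 200,
              dimnames = list(paste0("c", 1:300), paste0("g", 1:200)))
  m <- sweep(m, 2, runif(200, 0, 4), "+")
  picks <- sample(colnames(m), 30)
  s_set <- picks[1:15]; g2m_set <- picks[16:30]
  m[1:100, s_set] <- m[1:100, s_set] + 2      # S cells
  m[101:200, g2m_set] <- m[101:200, g2m_set] + 2  # G2M cells
  # non-cycling cells genuinely lack both programs
  m[201:300, c(s_set, g2m_set)] <- m[201:300, c(s_set, g2m_set)] - 1
  ph <- cell_cycle_phase(m, s_set, g2m_set)
  expect_gte(mean(ph$phase[1:100] == "S"), 0.9)
  expect_gte(mean(ph$phase[101:200] == "G2M"), 0.9)
  expect_gte(mean(ph$phase[201:300] == "G1"), 0.9)
})

test_that("reference annotation labels cells correctly and flags noise", {
  fx <- small_cohort()
  cfg <- expression_config("snrna")
  ref <- t(nodular:::noise_free_state_means(cfg))  # genes x states
  ref <- log1p(sweep(ref, 2, colSums(ref), "/") * 1e4)
  # rank correlation over the full panel is diluted by uninformative genes,
  # so annotate over the informative (marker) subset, as done in practice
  mk <- cfg$genes$gene[cfg$genes$marker_of != "none"]
  ann <- annotate_by_reference(fx$norm[, mk], ref[mk, ])
  acc <- mean(ann$label == fx$cohort$cells$state)
  expect_gte(acc, 0.9)
  # pure-noise cells fall below the correlation floor
  set.seed(41)
  noise <- matrix(sample(fx$norm, 50 * length(mk)), 50, length(mk),
                  dimnames = list(paste0("n", 1:50), mk))
  ann0 <- annotate_by_reference(noise, ref[mk, ])
  expect_gte(mean(ann0$label == "unassigned"), 0.8)
})

test_that("batch adjustment zeroes per-batch gene means and preserves structure", {
  fx <- small_cohort()
  adj <- fx$adj
  for (p in unique(fx$cohort$cells$patient)) {
    mu <- colMeans(adj[fx$cohort$cells$patient == p, ])
    expect_lt(max(abs(mu)), 1e-9)
  }
  # a planted additive batch shift is fully removed
  m <- two_blob_matrix()
  batch <- rep(c("a", "b"), 60)
  m2 <- m; m2[batch == "b", ] <- m2[batch == "b", ] + 4
  back <- batch_adjust(m2, batch)
  centered <- batch_adjust(m, batch)
  expect_equal(back, centered, tolerance = 1e-12)
})

test_that("TF activity recovers planted activity with the right sign", {
  set.seed(51)
  n_genes <- 120
  genes <- paste0("g", seq_len(n_genes))
  reg <- tibble::tibble(
    tf = rep(c("tfA", "tfB"), each = 15),
    target = c(genes[1:15], genes[16:30]),
    weight = 1)
  m <- matrix(rnorm(80 * n_genes, sd = 0.5), 80, n_genes,
              dimnames = list(paste0("c", 1:80), genes))
  m[1:40, genes[1:15]] <- m[1:40, genes[1:15]] + 2     # tfA on in cells 1-40
  m[41:80, genes[16:30]] <- m[41:80, genes[16:30]] - 2 # tfB repressed
  act <- tf_activity(m, reg)
  expect_true(all(act[1:40, "tfA"] > 2))
  expect_true(all(act[41:80, "tfB"] < -2))
  expect_lt(mean(abs(act[41:80, "tfA"])), 2)
})

test_that("TF activity t-values match lm() on a single cell", {
  set.seed(52)
  genes <- paste0("g", 1:30)
  reg <- tibble::tibble(tf = rep(c("t1", "t2"), each = 5),
                        target = genes[1:10], weight = runif(10, 0.5, 2))
  y <- rnorm(30)
  m <- rbind(y, rnorm(30), rnorm(30))
  dimnames(m) <- list(c("a", "b", "c"), genes)
  act <- tf_activity(m, reg)
  X <- matrix(0, 30, 2, dimnames = list(genes, c("t1", "t2")))
  X[cbind(match(reg$target, genes), match(reg$tf, c("t1", "t2")))] <- reg$weight
  fit <- summary(lm(y ~ X))
  expect_equal(unname(act["a", ]), unname(fit$coefficients[-1, "t value"]),
               tolerance = 1e-8)
})

test_that("degenerate regulons are rejected or dropped", {
  genes <- paste0("g", 1:20)
  m <- matrix(rnorm(100), 5, 20, dimnames = list(paste0("c", 1:5), genes))
  dup <- tibble::tibble(tf = rep(c("t1", "t2"), each = 4),
                        target = rep(genes[1:4], 2), weight = 1)
  expect_warning(act <- tf_activity(m, dup), "collinear")
  expect_equal(ncol(act), 1)
  none <- tibble::tibble(tf = "t1", target = "absent_gene", weight = 1)
  expect_error(tf_activity(m, none), ">= 2 TFs")
})

test_that("set overlap test matches hand-computed chi-squared and Fisher", {
  # large balanced case: a=40, b=60, c=60, d=840 within universe 1000
  q <- paste0("g", 1:100)
  ref <- list(big = paste0("g", c(1:40, 101:160)),
              tiny = paste0("g", c(1, 2, 990:992)))
  res <- gene_set_overlap_test(q, ref, universe_size = 1000)
  tab <- matrix(c(40, 60, 60, 840), 2, 2)
  expect_equal(res$statistic[res$set == "big"],
               unname(suppressWarnings(chisq.test(tab, correct = TRUE))$statistic))
  expect_equal(res$method[res$set == "big"], "chi-squared")
  tab2 <- matrix(c(2, 98, 3, 897), 2, 2)
  expect_equal(res$p_value[res$set == "tiny"], fisher.test(tab2)$p.value)
  expect_equal(res$method[res$set == "tiny"], "fisher")
  expect_equal(res$overlap, c(40L, 2L))
})
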