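# shared fixtures, built once per test run
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small 3-patient cohort with snRNA-scale expression (CNV block planted
# in patient P1), used across clustering/malignancy/trajectory tests
small_cohort <- function() fixture("small_cohort", function() {
  cohort <- simulate_cohort(tissue_config(n_cells = 700, seed = 42),
                            n_patients = 3)
  expr <- simulate_expression(cohort$cells, expression_config("snrna"),
                              seed = 43)
  norm <- normalize_counts(expr$counts)
  list(cohort = cohort, expr = expr, norm = norm,
       adj = batch_adjust(norm, cohort$cells$patient))
})

small_clusters <- function() fixture("small_clusters", function() {
  fx <- small_cohort()
  merge_similar_clusters(embed_and_cluster(fx$adj, seed = 1), fx$adj)
})

# single small tissue with spatial-panel spots and masks
small_spatial <- function() fixture("small_spatial", function() {
  tis <- simulate_tissue(tissue_config(field_width = 600, field_height = 600,
                                       n_nodules = 1,
                                       nodule_radius_mean = 150,
                                       nodule_radius_sd = 10,
                                       n_cells = 400, seed = 9))
  expr <- simulate_expression(tis$cells, expression_config("spatial"),
                              seed = 10)
  sm <- simulate_spots_and_masks(tis, expr$counts, seed = 11)
  list(tissue = tis, expr = expr, sm = sm)
})

# draw a disc image (matrix [x, y]) for segmentation tests
disc_image <- function(nx, ny, centers, radius, value = 1) {
  img <- matrix(0, nx, ny)
  for (i in seq_len(nrow(centers))) {
    for (x in seq_len(nx)) {
      dy2 <- radius^2 - (x - 0.5 - centers[i, 1])^2
      if (dy2 < 0) next
      yr <- which((seq_len(ny) - 0.5 - centers[i, 2])^2 <= dy2)
      img[x, yr] <- value
    }
  }
  img
}
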