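#' Cell states simulated in a nodular tumor tissue
#'
#' The six states carried by the simulator: four malignant states along the
#' cerebellar granule neuronal precursor (CGNP) differentiation axis
#' (proliferating early CGNP-like, early CGNP-like, migrating, neuronally
#' differentiated), a malignant astrocytic-like state that sits at the nodule
#' rim, and a non-malignant stromal/immune state.
#'
#' @format Character vector of length 6.
#' @export
tissue_states <- c("prolif_early_cgnp", "early_cgnp", "migrating",
                   "differentiated", "astrocytic_like", "stromal_immune")

#' Malignant lineage states, ordered by differentiation
#' @rdname tissue_states
#' @export
lineage_states <- c("prolif_early_cgnp", "early_cgnp", "migrating",
                    "differentiated")

default_state_proportions <- function() {
  c(prolif_early_cgnp = 0.15, early_cgnp = 0.20, migrating = 0.20,
    differentiated = 0.25, astrocytic_like = 0.08, stromal_immune = 0.12)
}

# per-state placement weights for the three geometric zones; nodular
# architecture: early/proliferating/stromal internodular, differentiated
# nodular, migrating in both, astrocytic-like at the nodule rim
default_spatial_propensity <- function() {
  tibble::tribble(
    ~state,               ~internodular, ~nodular, ~rim,
    "prolif_early_cgnp",  1.00,          0.05,     0.10,
    "early_cgnp",         1.00,          0.05,     0.10,
    "migrating",          0.50,          0.50,     0.50,
    "differentiated",     0.05,          1.00,     0.30,
    "astrocytic_like",    0.05,          0.05,     1.00,
    "stromal_immune",     1.00,          0.10,     0.20
  )
}

#' Configuration for the synthetic nodular tissue generator
#'
#' Describes a 2-D tissue field with circular nodules embedded in an
#' internodular background, and how six cell states distribute across the
#' internodular space, the nodules and the nodule rim.
#'
#' @param field_width,field_height Field size in micrometers.
#' @param n_nodules Number of circular nodules; `0` gives a purely
#'   internodular tissue.
#' @param nodule_radius_mean,nodule_radius_sd Nodule radius distribution (um).
#' @param n_cells Cells to place per tissue section.
#' @param state_proportions Named numeric simplex over [tissue_states].
#' @param spatial_propensity Tibble with columns `state`, `internodular`,
#'   `nodular`, `rim`: non-negative placement weights per geometric zone.
#' @param rim_width Width of the rim annulus straddling each nodule
#'   boundary (um); the annulus spans radius +/- `rim_width / 2`.
#' @param min_cell_spacing Hard-core minimum distance between cell
#'   centers (um). Must exceed twice the nucleus radius used when images
#'   are rendered.
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A `tissue_config` list.
#' @export
tissue_config <- function(field_width = 2000, field_height = 2000,
                          n_nodules = 3,
                          nodule_radius_mean = 300, nodule_radius_sd = 30,
                          n_cells = 5000,
                          state_proportions = default_state_proportions(),
                          spatial_propensity = default_spatial_propensity(),
                          rim_width = 60, min_cell_spacing = 16,
                          seed = 1L) {
  assert_that(abs(sum(state_proportions) - 1) <= 1e-9,
              "state_proportions must sum to 1")
  assert_that(setequal(names(state_proportions), tissue_states),
              "state_proportions must be named by the six tissue states")
  assert_that(rim_width > 0, "rim_width must be > 0")
  assert_that(all(c("state", "internodular", "nodular", "rim") %in%
                    names(spatial_propensity)),
              "spatial_propensity needs state/internodular/nodular/rim columns")
  structure(list(
    field_width = field_width, field_height = field_height,
    n_nodules = n_nodules, nodule_radius_mean = nodule_radius_mean,
    nodule_radius_sd = nodule_radius_sd, n_cells = n_cells,
    state_proportions = state_proportions[tissue_states],
    spatial_propensity = spatial_propensity,
    rim_width = rim_width, min_cell_spacing = min_cell_spacing,
    seed = as.integer(seed)
  ), class = "tissue_config")
}

# zone of each point given nodule geometry: rim takes precedence so the
# rim propensity acts on the annulus straddling the boundary
point_zone <- function(x, y, nodules, rim_width) {
  zone <- rep("internodular", length(x))
  inside <- rep(FALSE, length(x))
  in_rim <- rep(FALSE, length(x))
  if (nrow(nodules) > 0) {
    for (i in seq_len(nrow(nodules))) {
      d <- sqrt((x - nodules$cx[i])^2 + (y - nodules$cy[i])^2)
      inside <- inside | d <= nodules$r[i]
      in_rim <- in_rim |
        (d >= nodules$r[i] - rim_width / 2 & d <= nodules$r[i] + rim_width / 2)
    }
  }
  zone[inside] <- "nodular"
  zone[in_rim] <- "rim"
  list(zone = zone, inside = inside)
}

place_nodules <- function(config) {
  n <- config$n_nodules
  if (n == 0)
    return(tibble::tibble(nodule = integer(), cx = numeric(),
                          cy = numeric(), r = numeric()))
  out <- tibble::tibble(nodule = seq_len(n), cx = NA_real_, cy = NA_real_,
                        r = NA_real_)
  placed <- 0L
  for (attempt in seq_len(2000L * n)) {
    r <- abs(rnorm(1, config$nodule_radius_mean, config$nodule_radius_sd))
    if (r <= 0 || 2 * r >= min(config$field_width, config$field_height)) next
    cx <- runif(1, r, config$field_width - r)
    cy <- runif(1, r, config$field_height - r)
    if (placed > 0) {
      d <- sqrt((out$cx[seq_len(placed)] - cx)^2 +
                  (out$cy[seq_len(placed)] - cy)^2)
      if (any(d < out$r[seq_len(placed)] + r + config$rim_width)) next
    }
    placed <- placed + 1L
    out$cx[placed] <- cx; out$cy[placed] <- cy; out$r[placed] <- r
    if (placed == n) return(out)
  }
  rlang::abort("could not place non-overlapping nodules inside the field")
}

#' Simulate a nodular tissue section
#'
#' Places `n_cells` cells by rejection sampling: candidate positions are
#' uniform over the field, accepted with probability proportional to the
#' cell state's propensity for the candidate's geometric zone
#' (internodular, nodular, or the rim annulus), subject to a hard-core
#' minimum spacing. Ground-truth compartment labels (a cell is nodular iff
#' it lies inside a nodule disc) are emitted alongside the geometry.
#'
#' @param config A [tissue_config()].
#' @param patient Patient identifier attached to every cell.
#' @return A `nodular_tissue` object: list with `cells` (tibble: `cell_id`,
#'   `x`, `y`, `state`, `patient`, `compartment`), `nodules` (tibble:
#'   `nodule`, `cx`, `cy`, `r`) and the `config`.
#' @examples
#' tis <- simulate_tissue(tissue_config(n_cells = 200, seed = 7))
#' dplyr::count(tis$cells, compartment)
#' @export
simulate_tissue <- function(config = tissue_config(), patient = "P1") {
  with_seed(config$seed, {
    nodules <- place_nodules(config)
    states <- sample(rep(tissue_states,
                         round_simplex(config$state_proportions, config$n_cells)))
    prop <- config$spatial_propensity
    wmax <- max(prop$internodular, prop$nodular, prop$rim)
    assert_that(wmax > 0, "at least one spatial propensity must be positive")
    wtab <- as.matrix(prop[, c("internodular", "nodular", "rim")]) / wmax
    rownames(wtab) <- prop$state

    spacing2 <- config$min_cell_spacing^2
    cell_w <- config$min_cell_spacing
    ngx <- max(1L, ceiling(config$field_width / cell_w))
    ngy <- max(1L, ceiling(config$field_height / cell_w))
    grid <- vector("list", ngx * ngy)
    xs <- ys <- numeric(config$n_cells)

    n_placed <- 0L
    max_attempts <- 500L * config$n_cells
    attempts <- 0L
    while (n_placed < config$n_cells) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        rlang::abort(paste0("infeasible packing: placed ", n_placed, " of ",
                            config$n_cells, " cells after ", max_attempts,
                            " attempts; reduce n_cells or min_cell_spacing"))
      x <- runif(1, 0, config$field_width)
      y <- runif(1, 0, config$field_height)
      st <- states[n_placed + 1L]
      z <- point_zone(x, y, nodules, config$rim_width)$zone
      if (runif(1) > wtab[st, z]) next
      gx <- min(ngx, 1L + floor(x / cell_w)); gy <- min(ngy, 1L + floor(y / cell_w))
      ok <- TRUE
      for (dx in -1:1) for (dy in -1:1) {
        cx <- gx + dx; cy <- gy + dy
        if (cx < 1 || cx > ngx || cy < 1 || cy > ngy) next
        for (j in grid[[(cy - 1L) * ngx + cx]]) {
          if ((xs[j] - x)^2 + (ys[j] - y)^2 < spacing2) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) next
      n_placed <- n_placed + 1L
      xs[n_placed] <- x; ys[n_placed] <- y
      idx <- (gy - 1L) * ngx + gx
      grid[[idx]] <- c(grid[[idx]], n_placed)
    }

    inside <- point_zone(xs, ys, nodules, config$rim_width)$inside
    cells <- tibble::tibble(
      cell_id = paste0(patient, "_c", seq_len(config$n_cells)),
      x = xs, y = ys, state = states, patient = patient,
      compartment = ifelse(inside, "nodular", "internodular")
    )
    structure(list(cells = cells, nodules = nodules, config = config),
              class = "nodular_tissue")
  })
}

# deterministic integer allocation of n cells to the proportion simplex
round_simplex <- function(p, n) {
  k <- floor(p * n)
  rem <- n - sum(k)
  if (rem > 0) {
    frac <- p * n - k
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    k[add] <- k[add] + 1
  }
  k
}

#' Simulate a multi-patient cohort of tissue sections
#'
#' Generates one tissue per patient with patient-specific sub-seeds derived
#' from the config seed, and returns the concatenated cell table plus the
#' per-patient tissues.
#'
#' @inheritParams simulate_tissue
#' @param n_patients Number of patients.
#' @return List with `cells` (all patients bound), `tissues` (named list of
#'   `nodular_tissue`) and `config`.
#' @export
simulate_cohort <- function(config = tissue_config(), n_patients = 3) {
  patients <- paste0("P", seq_len(n_patients))
  tissues <- purrr::map2(patients, seq_along(patients), function(p, i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("tissue_", p))
    simulate_tissue(cfg, patient = p)
  })
  names(tissues) <- patients
  list(cells = dplyr::bind_rows(purrr::map(tissues, "cells")),
       tissues = tissues, config = config)
}

#' @exportS3Method base::print
print.nodular_tissue <- function(x, ...) {
  cat("<nodular_tissue> ", nrow(x$cells), " cells, ", nrow(x$nodules),
      " nodules, field ", x$config$field_width, "x", x$config$field_height,
      " um\n", sep = "")
  print(dplyr::count(x$cells, .data$state, .data$compartment))
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated tissue section
#'
#' @param object A `nodular_tissue`.
#' @param ... Unused.
#' @return A ggplot: cells colored by state with nodule outlines.
#' @export
autoplot.nodular_tissue <- function(object, ...) {
  circ <- tidyr::crossing(object$nodules, theta = seq(0, 2 * pi, length.out = 90)) |>
    dplyr::mutate(px = .data$cx + .data$r * cos(.data$theta),
                  py = .data$cy + .data$r * sin(.data$theta))
  ggplot2::ggplot(object$cells, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$state), size = 0.4) +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(.data$px, .data$py, group = .data$nodule)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = "state")
}
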