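#' Build a spatial neighbourhood graph over cell positions
#'
#' `"delaunay"` triangulates the positions (Bowyer-Watson) and prunes
#' edges longer than `max_edge_factor` times the median nearest-neighbour
#' distance, removing convex-hull artifacts; `"knn"` connects each cell to
#' its `k` nearest neighbours (symmetrized). Degenerate input (collinear
#' points) falls back to kNN with a warning.
#'
#' @param positions Tibble or matrix with `x`, `y` (and optionally
#'   `cell_id`).
#' @param method `"delaunay"` or `"knn"`.
#' @param k Neighbours for the kNN graph.
#' @param max_edge_factor Delaunay pruning multiple of the median
#'   nearest-neighbour distance.
#' @return A `spatial_graph`: list with `edges` (tibble `from`, `to`,
#'   `length`; `from < to`), `positions`, `params`.
#' @export
build_spatial_graph <- function(positions, method = c("delaunay", "knn"),
                                k = 6, max_edge_factor = 4) {
  method <- match.arg(method)
  pos <- as.data.frame(positions)
  assert_that(all(c("x", "y") %in% names(pos)), "positions need x and y")
  ids <- pos$cell_id %||% as.character(seq_len(nrow(pos)))
  xy <- cbind(pos$x, pos$y)
  n <- nrow(xy)
  assert_that(n >= 2, "need >= 2 positions")

  if (method == "delaunay") {
    degenerate <- n < 3 || {
      ctr <- sweep(xy, 2, colMeans(xy), "-")
      s <- svd(ctr)$d
      s[2] < 1e-9 * max(s[1], 1)
    }
    if (degenerate) {
      rlang::warn("degenerate (collinear) positions: falling back to knn")
      method <- "knn"
    }
  }

  if (method == "delaunay") {
    ed <- delaunay_edges(xy)
    len <- sqrt(rowSums((xy[ed[, 1], , drop = FALSE] -
                           xy[ed[, 2], , drop = FALSE])^2))
    med_nn <- median(nn_distance(xy))
    keep <- len <= max_edge_factor * med_nn
    ed <- ed[keep, , drop = FALSE]; len <- len[keep]
  } else {
    kk <- min(k, n - 1)
    nn <- knn_indices(xy, kk)
    ed <- cbind(rep(seq_len(n), kk), as.vector(nn))
    ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    ed <- unique(ed)
    len <- sqrt(rowSums((xy[ed[, 1], , drop = FALSE] -
                           xy[ed[, 2], , drop = FALSE])^2))
  }
  structure(list(
    edges = tibble::tibble(from = ids[ed[, 1]], to = ids[ed[, 2]],
                           length = len),
    positions = tibble::tibble(cell_id = ids, x = pos$x, y = pos$y),
    params = list(method = method, k = k, max_edge_factor = max_edge_factor)),
    class = "spatial_graph")
}

nn_distance <- function(xy) {
  nn <- knn_indices(xy, 1)
  sqrt(rowSums((xy - xy[nn[, 1], , drop = FALSE])^2))
}

# Bowyer-Watson incremental Delaunay triangulation; returns the unique
# edge index pairs. Pure R: adequate for the tissue scales this package
# simulates (a few thousand cells).
delaunay_edges <- function(xy) {
  n <- nrow(xy)
  rng <- apply(xy, 2, range)
  span <- max(rng[2, ] - rng[1, ], 1)
  cx <- mean(rng[, 1]); cy <- mean(rng[, 2])
  # super-triangle well outside the data
  sv <- rbind(c(cx - 20 * span, cy - 10 * span),
              c(cx + 20 * span, cy - 10 * span),
              c(cx, cy + 20 * span))
  pts <- rbind(xy, sv)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  cap <- 4L * n + 16L
  tri <- matrix(NA_integer_, cap, 3)
  ccx <- ccy <- cr2 <- rep(NA_real_, cap)
  alive <- rep(FALSE, cap)
  ntri <- 0L

  circum <- function(a, b, c) {
    ax <- pts[a, 1]; ay <- pts[a, 2]
    bx <- pts[b, 1]; by <- pts[b, 2]
    cx_ <- pts[c, 1]; cy_ <- pts[c, 2]
    d <- 2 * (ax * (by - cy_) + bx * (cy_ - ay) + cx_ * (ay - by))
    if (abs(d) < 1e-12 * span^2) return(c(NA, NA, Inf))
    ux <- ((ax^2 + ay^2) * (by - cy_) + (bx^2 + by^2) * (cy_ - ay) +
             (cx_^2 + cy_^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx_ - bx) + (bx^2 + by^2) * (ax - cx_) +
             (cx_^2 + cy_^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  add_tri <- function(a, b, c) {
    ntri <<- ntri + 1L
    if (ntri > cap) {
      grow <- ntri + cap
      tri2 <- matrix(NA_integer_, grow, 3); tri2[seq_len(cap), ] <- tri
      tri <<- tri2
      ccx <<- c(ccx, rep(NA_real_, grow - cap))
      ccy <<- c(ccy, rep(NA_real_, grow - cap))
      cr2 <<- c(cr2, rep(NA_real_, grow - cap))
      alive <<- c(alive, rep(FALSE, grow - cap))
      cap <<- grow
    }
    tri[ntri, ] <<- c(a, b, c)
    cc <- circum(a, b, c)
    ccx[ntri] <<- cc[1]; ccy[ntri] <<- cc[2]; cr2[ntri] <<- cc[3]
    alive[ntri] <<- TRUE
  }
  add_tri(s1, s2, s3)

  for (p in seq_len(n)) {
    live <- which(alive[seq_len(ntri)])
    bad <- live[(pts[p, 1] - ccx[live])^2 + (pts[p, 2] - ccy[live])^2 <=
                  cr2[live] * (1 + 1e-12)]
    if (length(bad) == 0) next  # numerically degenerate; skip point
    # boundary polygon = edges of bad triangles that appear exactly once
    e <- rbind(tri[bad, c(1, 2), drop = FALSE],
               tri[bad, c(2, 3), drop = FALSE],
               tri[bad, c(3, 1), drop = FALSE])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    once <- names(which(table(key) == 1))
    alive[bad] <- FALSE
    for (kk in once) {
      ab <- as.integer(strsplit(kk, " ")[[1]])
      add_tri(ab[1], ab[2], p)
    }
  }
  live <- which(alive[seq_len(ntri)])
  tr <- tri[live, , drop = FALSE]
  keep <- rowSums(tr > n) == 0
  tr <- tr[keep, , drop = FALSE]
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  e
}

#' Permutation co-localization enrichment on a spatial graph
#'
#' Counts observed edges between every pair of cell types and compares
#' them with `B` random relabelings of the cells over the fixed graph.
#' The score is `log2((obs + 1) / (mean_perm + 1))`: positive when two
#' types sit next to each other more often than chance. P-values are
#' two-sided permutation tails (smaller tail doubled, +1 corrected,
#' capped at 1).
#'
#' @param graph A `spatial_graph`.
#' @param types Named character vector (names = cell ids) or a vector
#'   aligned with the graph's positions.
#' @param B Number of label permutations.
#' @param seed Integer seed.
#' @return An `enrichment_matrix`: list with `score`, `p_value`,
#'   `observed`, `expected` (types x types symmetric matrices), `B`,
#'   `seed`. Pairs with an absent type are NA.
#' @export
colocalization_enrichment <- function(graph, types, B = 1000, seed = 1L) {
  ids <- graph$positions$cell_id
  ty <- if (!is.null(names(types))) types[ids] else types
  assert_that(length(ty) == length(ids), "one type per graph node")
  lev <- sort(unique(as.character(ty)))
  assert_that(length(lev) >= 2, "need >= 2 cell types")
  ti <- match(ty, lev)
  a <- match(graph$edges$from, ids)
  b <- match(graph$edges$to, ids)
  nl <- length(lev)
  pair_id <- function(t1, t2)
    (pmin(t1, t2) - 1L) * nl + pmax(t1, t2)
  npair <- nl * nl
  obs <- tabulate(pair_id(ti[a], ti[b]), npair)
  perm_counts <- matrix(0L, B, npair)
  with_seed(seed, {
    for (i in seq_len(B)) {
      pp <- ti[sample.int(length(ti))]
      perm_counts[i, ] <- tabulate(pair_id(pp[a], pp[b]), npair)
    }
  })
  expd <- colMeans(perm_counts)
  score_v <- log2((obs + 1) / (expd + 1))
  p_up <- (1 + colSums(perm_counts >= rep(obs, each = B))) / (B + 1)
  p_dn <- (1 + colSums(perm_counts <= rep(obs, each = B))) / (B + 1)
  p_v <- pmin(1, 2 * pmin(p_up, p_dn))

  to_mat <- function(v) {
    m <- matrix(NA_real_, nl, nl, dimnames = list(lev, lev))
    for (i in seq_len(nl)) for (j in i:nl) {
      m[i, j] <- m[j, i] <- v[(i - 1L) * nl + j]
    }
    m
  }
  score <- to_mat(score_v); pmat <- to_mat(p_v)
  omat <- to_mat(as.numeric(obs)); emat <- to_mat(expd)
  present <- table(factor(ty, lev)) > 0
  score[!present, ] <- NA; score[, !present] <- NA
  pmat[!present, ] <- NA; pmat[, !present] <- NA
  structure(list(score = score, p_value = pmat, observed = omat,
                 expected = emat, B = B, seed = seed),
            class = "enrichment_matrix")
}

#' @exportS3Method base::print
print.enrichment_matrix <- function(x, ...) {
  cat("<enrichment_matrix> ", nrow(x$score), " types, B = ", x$B, "\n",
      sep = "")
  print(round(x$score, 2))
  invisible(x)
}

#' Data-driven nodular/internodular compartment map
#'
#' Nodules are identified where the cells anchoring them (by default the
#' neuronally differentiated cells that fill nodules) are dense: a
#' Gaussian kernel density of anchor cells is computed on a grid, Otsu's
#' threshold separates nodule regions from background, and every cell
#' falling inside a region is labeled nodular.
#'
#' @param positions Tibble with `cell_id`, `x`, `y` (um).
#' @param type_labels Cell types aligned with `positions` rows.
#' @param nodular_anchor_types Types whose density defines nodules.
#' @param bandwidth Kernel bandwidth (um).
#' @param grid_step Grid resolution (um).
#' @param field Optional `c(width, height)`; defaults to the position
#'   bounding box.
#' @return A `compartment_map`: list with `cells` (tibble `cell_id`,
#'   `compartment`), `regions` (integer grid matrix of nodule labels),
#'   `grid_step`, `density` (the smoothed anchor density).
#' @export
compartment_map <- function(positions, type_labels,
                            nodular_anchor_types = "differentiated",
                            bandwidth = 75, grid_step = 2, field = NULL) {
  pos <- as.data.frame(positions)
  ids <- pos$cell_id %||% as.character(seq_len(nrow(pos)))
  if (is.null(field)) field <- c(max(pos$x), max(pos$y))
  nx <- max(2L, ceiling(field[1] / grid_step))
  ny <- max(2L, ceiling(field[2] / grid_step))
  gx <- pmin(nx, 1L + floor(pos$x / grid_step))
  gy <- pmin(ny, 1L + floor(pos$y / grid_step))
  anchor <- type_labels %in% nodular_anchor_types
  if (!any(anchor)) {
    rlang::warn("no anchor cells: labeling everything internodular")
    return(structure(list(
      cells = tibble::tibble(cell_id = ids, compartment = "internodular"),
      regions = matrix(0L, nx, ny), grid_step = grid_step,
      density = matrix(0, nx, ny)), class = "compartment_map"))
  }
  dens <- matrix(0, nx, ny)
  cnt <- table(factor((gy[anchor] - 1L) * nx + gx[anchor],
                      levels = seq_len(nx * ny)))
  dens[] <- as.numeric(cnt)
  # gblur's kernel is 2 * ceiling(3 * sigma) + 1 wide and must fit the grid
  sigma <- bandwidth / grid_step
  sigma_max <- (min(nx, ny) - 3) / 6
  if (sigma > sigma_max) {
    rlang::warn("bandwidth large relative to the field; kernel capped")
    sigma <- max(sigma_max, 0.5)
  }
  dens <- EBImage::gblur(dens, sigma = sigma)
  scaled <- (dens - min(dens)) / max(max(dens) - min(dens), 1e-12)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  regions <- EBImage::bwlabel(scaled > thr)
  regions <- matrix(as.integer(EBImage::imageData(regions)), nx, ny)
  comp <- ifelse(regions[cbind(gx, gy)] > 0, "nodular", "internodular")
  structure(list(cells = tibble::tibble(cell_id = ids, compartment = comp),
                 regions = regions, grid_step = grid_step, density = dens),
            class = "compartment_map")
}

#' Intersection-over-union of mapped nodules against known discs
#'
#' Rasterizes each reference disc on the map's grid and reports the best
#' IoU against the mapped regions, one row per disc.
#'
#' @param map A `compartment_map`.
#' @param nodules Tibble with `cx`, `cy`, `r` (um).
#' @return Tibble: `nodule`, `iou`.
#' @export
nodule_iou <- function(map, nodules) {
  nx <- nrow(map$regions); ny <- ncol(map$regions)
  step <- map$grid_step
  cx_g <- (seq_len(nx) - 0.5) * step
  cy_g <- (seq_len(ny) - 0.5) * step
  purrr::map_dfr(seq_len(nrow(nodules)), function(i) {
    disc <- outer(cx_g, cy_g, function(xx, yy)
      (xx - nodules$cx[i])^2 + (yy - nodules$cy[i])^2 <= nodules$r[i]^2)
    labs <- setdiff(unique(map$regions[disc]), 0L)
    iou <- 0
    for (l in labs) {
      reg <- map$regions == l
      iou <- max(iou, sum(reg & disc) / sum(reg | disc))
    }
    tibble::tibble(nodule = i, iou = iou)
  })
}

#' Cell-type composition by compartment
#'
#' @param type_labels Cell types.
#' @param compartments Compartment label per cell.
#' @return List with `composition` (tibble, one row per compartment,
#'   proportions per type summing to 1; an empty compartment gives an NA
#'   row) and `type_fractions` (tibble: `type`, `nodular_fraction`).
#' @export
compartment_composition <- function(type_labels, compartments) {
  lev_c <- unique(compartments)
  lev_t <- sort(unique(type_labels))
  comp <- purrr::map_dfr(lev_c, function(cc) {
    sel <- compartments == cc
    n <- sum(sel)
    props <- if (n == 0) setNames(rep(NA_real_, length(lev_t)), lev_t)
      else table(factor(type_labels[sel], lev_t)) / n
    dplyr::bind_cols(tibble::tibble(compartment = cc, n_cells = n),
                     tibble::as_tibble_row(as.list(as.numeric(props)) |>
                                             setNames(lev_t)))
  })
  tf <- purrr::map_dfr(lev_t, function(tt) {
    sel <- type_labels == tt
    tibble::tibble(type = tt,
                   nodular_fraction = if (!any(sel)) NA_real_
                   else mean(compartments[sel] == "nodular"))
  })
  list(composition = comp, type_fractions = tf)
}
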