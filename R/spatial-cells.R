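#' Detect diffraction-limited transcript spots in a single-channel image
#'
#' Computes a difference-of-Gaussians band-pass response (`sigma` vs
#' `1.6 * sigma`) and returns local maxima above `threshold` as spot
#' coordinates. The default `sigma = 0.93` px matches the scale of
#' single-molecule FISH spots; detection thresholds in real experiments are
#' tuned per sample and fluorophore (typical useful range 0.004-0.0086 for
#' unit-amplitude spots), so `threshold` is a free parameter.
#'
#' @param image Numeric matrix (single channel); all pixels finite.
#' @param sigma Gaussian scale of the spot (px).
#' @param threshold Minimum DoG response at a local maximum.
#' @return Tibble with `x`, `y` (0-based pixel coordinates of the maximum)
#'   and `response`.
#' @export
detect_spots <- function(image, sigma = 0.93, threshold = 0.005) {
  assert_that(is.matrix(image) && is.numeric(image), "image must be a numeric matrix")
  assert_that(all(is.finite(image)), "image contains non-finite pixels")
  assert_that(sigma > 0, "sigma must be > 0")
  dog <- EBImage::gblur(image, sigma = sigma) -
    EBImage::gblur(image, sigma = 1.6 * sigma)
  # strict local maximum over the 8-neighborhood, computed by shifting
  nx <- nrow(dog); ny <- ncol(dog)
  pad <- matrix(-Inf, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- dog
  is_max <- matrix(TRUE, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- pad[(2:(nx + 1)) + dx, (2:(ny + 1)) + dy]
    is_max <- is_max & (dog >= nb)
  }
  hit <- which(is_max & dog >= threshold, arr.ind = TRUE)
  tibble::tibble(x = hit[, 1] - 1, y = hit[, 2] - 1,
                 response = dog[hit])
}

#' Segment nuclei from a DAPI-like image
#'
#' Threshold, Euclidean distance transform, and watershed on the distance
#' map, so touching near-circular nuclei are split at their waist. Regions
#' smaller than `min_area` pixels are dropped. This is a deliberately simple
#' geometric segmenter; any label mask from an external segmenter can be
#' used downstream instead.
#'
#' @param image Numeric matrix (single channel).
#' @param intensity_threshold Foreground threshold.
#' @param min_area Minimum region area (px).
#' @return Integer label matrix (0 = background) with unique positive
#'   labels.
#' @export
segment_nuclei <- function(image, intensity_threshold = 0.5, min_area = 20) {
  assert_that(is.matrix(image) && is.numeric(image), "image must be a numeric matrix")
  fg <- image > intensity_threshold
  if (!any(fg)) return(matrix(0L, nrow(image), ncol(image)))
  dm <- EBImage::distmap(EBImage::Image(fg * 1))
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes < min_area)
  if (length(drop) > 0) lab[lab %in% drop] <- 0L
  storage.mode(lab) <- "integer"
  relabel_consecutive(lab)
}

relabel_consecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (length(u) == 0) return(lab)
  map <- integer(max(u)); map[u] <- seq_along(u)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}

#' Assign transcript spots to segmented nuclei
#'
#' Each spot increments the (nucleus label, gene) count of the mask pixel
#' under it; spot `(x, y)` maps to pixel `(floor(x), floor(y))` (0-based).
#' Spots over background (label 0) are tallied as unassigned and excluded.
#' Spot conservation holds exactly: assigned + unassigned = input rows.
#'
#' @param spots Tibble with `x`, `y` (px) and `gene`.
#' @param mask Integer label matrix.
#' @param panel Optional character vector of allowed genes; spots with a
#'   gene outside the panel are an error.
#' @return A `spatial_cells` list: `counts` (cells x genes integer matrix,
#'   rows named `cell_<label>`), `metadata` (tibble: `cell_id`, `label`,
#'   `x`, `y` centroid px, `area_px`, `total_transcripts`), and
#'   `unassigned` (count of background spots).
#' @export
assign_spots_to_cells <- function(spots, mask, panel = NULL) {
  assert_that(all(c("x", "y", "gene") %in% names(spots)),
              "spots must have x, y, gene columns")
  if (!is.null(panel)) {
    bad <- setdiff(unique(spots$gene), panel)
    if (length(bad) > 0)
      rlang::abort(paste0("genes not in panel: ", paste(bad, collapse = ", ")))
  }
  nx <- nrow(mask); ny <- ncol(mask)
  px <- floor(spots$x); py <- floor(spots$y)
  assert_that(all(px >= 0 & px < nx & py >= 0 & py < ny),
              "spots outside mask bounds")
  lab <- mask[cbind(px + 1, py + 1)]
  unassigned <- sum(lab == 0L)

  labels <- sort(unique(mask[mask > 0]))
  genes <- sort(unique(spots$gene))
  counts <- matrix(0L, length(labels), length(genes),
                   dimnames = list(paste0("cell_", labels), genes))
  keep <- lab > 0L
  if (any(keep)) {
    tab <- table(factor(lab[keep], levels = labels),
                 factor(spots$gene[keep], levels = genes))
    counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                     dimnames = list(paste0("cell_", labels), genes))
  }

  pos <- which(mask > 0)
  ml <- mask[pos]
  ix <- (pos - 1) %% nx      # 0-based pixel x
  iy <- (pos - 1) %/% nx
  cx <- tapply(ix + 0.5, ml, mean)[as.character(labels)]
  cy <- tapply(iy + 0.5, ml, mean)[as.character(labels)]
  area <- tabulate(ml, nbins = max(labels))[labels]

  metadata <- tibble::tibble(
    cell_id = paste0("cell_", labels), label = labels,
    x = as.numeric(cx), y = as.numeric(cy), area_px = area,
    total_transcripts = as.integer(rowSums(counts)))
  structure(list(counts = counts, metadata = metadata,
                 unassigned = unassigned),
            class = "spatial_cells")
}

#' @exportS3Method base::print
print.spatial_cells <- function(x, ...) {
  cat("<spatial_cells> ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes; ", x$unassigned, " unassigned spots\n", sep = "")
  invisible(x)
}

#' Quality-filter spatially derived single cells
#'
#' Removes cells failing the transcript-count or nucleus-size criteria.
#' The removal rule is strict (`< min` or `> max`), so cells exactly on a
#' bound are kept. Defaults follow the established in-situ panel practice
#' of discarding cells with fewer than 5 or more than 100 transcripts and
#' nuclei smaller than 90 or larger than 2000 px.
#'
#' @param cells A `spatial_cells` object.
#' @param min_transcripts,max_transcripts Inclusive transcript-total bounds.
#' @param min_area,max_area Inclusive nucleus-area bounds (px).
#' @return A filtered `spatial_cells`; attribute `removed` is a tibble of
#'   removal counts per criterion.
#' @export
qc_filter_cells <- function(cells, min_transcripts = 5, max_transcripts = 100,
                            min_area = 90, max_area = 2000) {
  md <- cells$metadata
  low_t  <- md$total_transcripts < min_transcripts
  high_t <- md$total_transcripts > max_transcripts
  low_a  <- md$area_px < min_area
  high_a <- md$area_px > max_area
  keep <- !(low_t | high_t | low_a | high_a)
  if (!any(keep)) rlang::warn("all cells removed by QC filters")
  out <- cells
  out$counts <- cells$counts[keep, , drop = FALSE]
  out$metadata <- md[keep, , drop = FALSE]
  attr(out, "removed") <- tibble::tibble(
    criterion = c("low_transcripts", "high_transcripts",
                  "small_nucleus", "large_nucleus"),
    n = c(sum(low_t), sum(high_t), sum(low_a), sum(high_a)))
  out
}
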