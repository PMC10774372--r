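#' Simulate transcript spots and a nucleus label mask
#'
#' Rasterizes each cell as a circular nucleus on a 0-based integer pixel
#' grid (1 px = 1 um) and scatters its transcript counts uniformly over the
#' nucleus pixels, so with zero background the per-cell spot totals equal
#' the count-matrix row sums exactly. Background spots are laid down as a
#' Poisson process over the unlabeled area. Nuclei are non-overlapping by
#' construction of the hard-core tissue; overlapping nuclei are an error.
#'
#' @param tissue A `nodular_tissue` (or its `cells` tibble).
#' @param counts Cells x genes count matrix; rows matched to `cell_id`.
#' @param nucleus_radius Nucleus radius in pixels.
#' @param background_rate Background spot intensity (spots per px^2) over
#'   unlabeled pixels.
#' @param image_shape `c(nx, ny)` in pixels; defaults to the tissue field.
#'   Nucleus discs are clipped at the image border.
#' @param seed Integer seed.
#' @return List with `spots` (tibble: `x`, `y`, `gene`, and the truth
#'   column `source` = nucleus label or 0 for background), `mask` (integer
#'   nx x ny matrix, 0 = background), and `cell_table` (tibble: `cell_id`,
#'   `label`, `area_px`).
#' @export
simulate_spots_and_masks <- function(tissue, counts, nucleus_radius = 7,
                                     background_rate = 0,
                                     image_shape = NULL, seed = 1L) {
  cells <- if (inherits(tissue, "nodular_tissue")) tissue$cells else tissue
  assert_counts(counts)
  if (is.null(image_shape)) {
    cfg <- if (inherits(tissue, "nodular_tissue")) tissue$config else NULL
    image_shape <- if (!is.null(cfg)) c(ceiling(cfg$field_width),
                                        ceiling(cfg$field_height))
                   else ceiling(c(max(cells$x), max(cells$y)) + nucleus_radius)
  }
  nx <- image_shape[1]; ny <- image_shape[2]
  assert_that(all(cells$x >= 0 & cells$x <= nx & cells$y >= 0 & cells$y <= ny),
              "cell centers must lie inside the image")
  counts <- counts[cells$cell_id, , drop = FALSE]

  with_seed(seed, {
    mask <- matrix(0L, nx, ny)
    pix_list <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      cx <- cells$x[i]; cy <- cells$y[i]
      px <- max(0, floor(cx - nucleus_radius)):min(nx - 1, ceiling(cx + nucleus_radius))
      py <- max(0, floor(cy - nucleus_radius)):min(ny - 1, ceiling(cy + nucleus_radius))
      gx <- rep(px, times = length(py)); gy <- rep(py, each = length(px))
      keep <- (gx + 0.5 - cx)^2 + (gy + 0.5 - cy)^2 <= nucleus_radius^2
      gx <- gx[keep]; gy <- gy[keep]
      idx <- gx + 1L + gy * nx
      if (any(mask[idx] != 0L))
        rlang::abort("overlapping nuclei: min_cell_spacing must exceed 2 x nucleus_radius")
      mask[idx] <- i
      pix_list[[i]] <- cbind(gx, gy)
    }

    genes <- colnames(counts)
    tot <- rowSums(counts)
    n_spots <- sum(tot)
    sx <- sy <- numeric(n_spots)
    sgene <- character(n_spots)
    ssrc <- integer(n_spots)
    pos <- 0L
    for (i in seq_len(nrow(cells))) {
      n_i <- tot[i]
      if (n_i == 0) next
      pick <- pix_list[[i]][sample.int(nrow(pix_list[[i]]), n_i, replace = TRUE), ,
                            drop = FALSE]
      rng <- pos + seq_len(n_i)
      sx[rng] <- pick[, 1] + runif(n_i)
      sy[rng] <- pick[, 2] + runif(n_i)
      sgene[rng] <- rep(genes, times = counts[i, ])
      ssrc[rng] <- i
      pos <- pos + n_i
    }

    spots <- tibble::tibble(x = sx, y = sy, gene = sgene, source = ssrc)

    if (background_rate > 0) {
      free <- which(mask == 0L) - 1L
      n_bg <- rpois(1, background_rate * length(free))
      if (n_bg > 0) {
        pick <- free[sample.int(length(free), n_bg, replace = TRUE)]
        bx <- (pick %% nx) + runif(n_bg)
        by <- (pick %/% nx) + runif(n_bg)
        spots <- dplyr::bind_rows(spots, tibble::tibble(
          x = bx, y = by, gene = sample(genes, n_bg, replace = TRUE),
          source = 0L))
      }
    }

    area <- vapply(pix_list, nrow, integer(1))
    list(spots = spots, mask = mask,
         cell_table = tibble::tibble(cell_id = cells$cell_id,
                                     label = seq_len(nrow(cells)),
                                     area_px = area))
  })
}

#' Render a spot image with a Gaussian point-spread function
#'
#' Accumulates spot amplitudes on the pixel grid and convolves with an
#' isotropic Gaussian, emulating diffraction-limited single-molecule FISH
#' images at pixel resolution. Optionally adds white Gaussian noise.
#'
#' @param spots Tibble with `x`, `y` (px).
#' @param image_shape `c(nx, ny)`.
#' @param psf_sigma PSF standard deviation in pixels.
#' @param amplitude Total intensity per spot.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Seed for the noise draw.
#' @return Numeric nx x ny matrix.
#' @export
render_spot_image <- function(spots, image_shape, psf_sigma = 0.93,
                              amplitude = 1, noise_sd = 0, seed = 1L) {
  nx <- image_shape[1]; ny <- image_shape[2]
  img <- matrix(0, nx, ny)
  if (nrow(spots) > 0) {
    px <- pmin(pmax(floor(spots$x), 0), nx - 1)
    py <- pmin(pmax(floor(spots$y), 0), ny - 1)
    idx <- px + 1L + py * nx
    acc <- tapply(rep(amplitude, length(idx)), idx, sum)
    img[as.integer(names(acc))] <- acc
    img <- EBImage::gblur(img, sigma = psf_sigma)
  }
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(rnorm(nx * ny, 0, noise_sd), nx, ny))
  img
}

#' Render a DAPI-like nucleus image from a label mask
#'
#' @param mask Integer label matrix.
#' @param intensity Foreground intensity.
#' @param blur_sigma Gaussian blur applied to the binary nucleus image.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Seed for the noise draw.
#' @return Numeric matrix of the mask's dimensions.
#' @export
render_nucleus_image <- function(mask, intensity = 1, blur_sigma = 1,
                                 noise_sd = 0, seed = 1L) {
  img <- (mask > 0) * intensity
  if (blur_sigma > 0) img <- EBImage::gblur(img, sigma = blur_sigma)
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(rnorm(length(img), 0, noise_sd),
                                        nrow(mask), ncol(mask)))
  img
}
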