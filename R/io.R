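#' Read and write cell x gene count matrices (MatrixMarket + TSV metadata)
#'
#' @param counts Cells x genes integer matrix.
#' @param dir Output directory; writes `counts.mtx` (cells as rows),
#'   `cells.tsv` and `genes.tsv`.
#' @param metadata Optional per-cell tibble (must contain `cell_id`).
#' @param genes Optional gene annotation tibble (must contain `gene`).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(counts, dir, metadata = NULL, genes = NULL) {
  assert_counts(counts)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  md <- metadata %||% tibble::tibble(cell_id = rownames(counts))
  assert_that(identical(md$cell_id, rownames(counts)),
              "metadata cell_id must match count rows")
  write_tsv_plain(md, file.path(dir, "cells.tsv"))
  gn <- genes %||% tibble::tibble(gene = colnames(counts))
  assert_that(identical(gn$gene, colnames(counts)),
              "genes must match count columns")
  write_tsv_plain(gn, file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' @rdname write_counts
#' @return `read_counts()`: list with `counts`, `metadata`, `genes`.
#' @export
read_counts <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  md <- read_tsv_plain(file.path(dir, "cells.tsv"))
  gn <- read_tsv_plain(file.path(dir, "genes.tsv"))
  assert_that(nrow(m) == nrow(md) && ncol(m) == nrow(gn),
              "matrix dimensions disagree with metadata")
  dimnames(m) <- list(md$cell_id, gn$gene)
  storage.mode(m) <- "integer"
  list(counts = m, metadata = md, genes = gn)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

read_tsv_plain <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                      stringsAsFactors = FALSE))
}

#' Read and write transcript spot tables (CSV with x, y, gene)
#'
#' @param spots Tibble with `x`, `y`, `gene`.
#' @param path CSV path.
#' @return The path (write) or the spot tibble (read). A file missing a
#'   required column is a schema error naming the column.
#' @export
write_spots <- function(spots, path) {
  assert_that(all(c("x", "y", "gene") %in% names(spots)),
              "spots must have x, y, gene columns")
  utils::write.csv(spots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spots
#' @export
read_spots <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("x", "y", "gene"), names(df))
  if (length(missing_cols) > 0)
    rlang::abort(paste0("spot table missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  tibble::as_tibble(df)
}

#' Read and write nucleus label masks
#'
#' TIFF masks are stored as 16-bit grayscale (labels up to 65535 are
#' preserved exactly); `.csv` paths use a plain run-length encoding
#' (`row`, `start`, `end`, `label`, 1-based over the first matrix index)
#' that survives text-only storage.
#'
#' @param mask Integer label matrix.
#' @param path Destination: `.tif`/`.tiff` or `.csv`.
#' @return The path (write) or the integer label matrix (read).
#' @export
write_label_mask <- function(mask, path) {
  assert_that(max(mask) <= 65535, "labels exceed 16-bit range")
  if (grepl("\\.csv$", path)) {
    rl <- mask_to_rle(mask)
    utils::write.csv(rl, path, row.names = FALSE, quote = FALSE)
  } else {
    tiff::writeTIFF(t(mask) / 65535, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' @rdname write_label_mask
#' @param dim_hint For CSV masks, `c(nx, ny)`; defaults to the stored
#'   extent.
#' @export
read_label_mask <- function(path, dim_hint = NULL) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  if (grepl("\\.csv$", path)) {
    rl <- utils::read.csv(path)
    missing_cols <- setdiff(c("row", "start", "end", "label"), names(rl))
    if (length(missing_cols) > 0)
      rlang::abort(paste0("mask CSV missing column(s): ",
                          paste(missing_cols, collapse = ", ")))
    nx <- dim_hint[1] %||% max(rl$row)
    ny <- dim_hint[2] %||% max(rl$end)
    m <- matrix(0L, nx, ny)
    for (i in seq_len(nrow(rl)))
      m[rl$row[i], rl$start[i]:rl$end[i]] <- rl$label[i]
    m
  } else {
    v <- tiff::readTIFF(path)
    m <- t(round(v * 65535))
    storage.mode(m) <- "integer"
    m
  }
}

mask_to_rle <- function(mask) {
  out <- vector("list", nrow(mask))
  for (i in seq_len(nrow(mask))) {
    r <- rle(mask[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0L
    if (!any(keep)) next
    out[[i]] <- tibble::tibble(row = i, start = starts[keep],
                               end = ends[keep], label = r$values[keep])
  }
  dplyr::bind_rows(out)
}

#' Read and write gene sets in GMT format
#'
#' @param path GMT path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, "", 1))
}

#' @rdname read_gmt
#' @param gene_sets Named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED-like gene annotation TSV (gene, chrom, start)
#'
#' @param path TSV path with columns `gene`, `chrom`, `start` (bp).
#' @return Tibble with `gene`, `chrom`, `pos`.
#' @export
read_gene_annotation <- function(path) {
  df <- read_tsv_plain(path)
  missing_cols <- setdiff(c("gene", "chrom", "start"), names(df))
  if (length(missing_cols) > 0)
    rlang::abort(paste0("gene annotation missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  tibble::tibble(gene = df$gene, chrom = df$chrom, pos = df$start)
}

#' Read and write bulk expression matrices as TSV
#'
#' Genes as rows (first column `gene`), samples as columns.
#'
#' @param bulk Genes x samples matrix.
#' @param path TSV path.
#' @return The path (write) or the matrix (read).
#' @export
write_bulk <- function(bulk, path) {
  df <- data.frame(gene = rownames(bulk), as.data.frame(bulk),
                   check.names = FALSE)
  write_tsv_plain(df, path)
  invisible(path)
}

#' @rdname write_bulk
#' @export
read_bulk <- function(path) {
  df <- read_tsv_plain(path)
  assert_that("gene" %in% names(df), "bulk TSV missing column: gene")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  m
}
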