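#' @importFrom rlang %||% abort warn
#' @importFrom stats median prcomp rnbinom rpois runif rnorm rbinom sd
#'   quantile cor cor.test t.test wilcox.test p.adjust chisq.test fisher.test
#'   fft setNames complete.cases pt dist var
#' @importFrom utils head tail
NULL

# deterministic 31-bit sub-seed from a parent seed and a stage name
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 2654435761) %% 2147483647
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) rlang::abort(msg)

# counts: cells x genes matrix with rownames/colnames
assert_counts <- function(counts) {
  assert_that(is.matrix(counts) || inherits(counts, "Matrix"),
              "`counts` must be a cells x genes matrix")
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "`counts` must have cell rownames and gene colnames")
  invisible(counts)
}
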