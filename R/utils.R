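#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n
#' @importFrom stats median mad quantile cor sd rnorm runif rnbinom rmultinom
#'   rbinom p.adjust pt pchisq phyper lowess cmdscale hclust cutree as.dist
#'   setNames prcomp rgamma
NULL

# Local RNG scope: run `code` under a private seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

assert_count_matrix <- function(counts, what = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort(sprintf("`%s` must be a numeric matrix (genes x samples)", what))
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort(sprintf("`%s` must have row (gene) and column (sample) names", what))
  }
  if (anyDuplicated(rownames(counts))) {
    abort(sprintf("duplicate row ids in `%s`", what))
  }
  if (anyDuplicated(colnames(counts))) {
    abort(sprintf("duplicate sample ids in `%s`", what))
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort(sprintf("`%s` must be finite and non-negative", what))
  }
  invisible(counts)
}

geometric_mean <- function(x) exp(mean(log(x)))
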