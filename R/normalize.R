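#' TMM library normalisation factors
#'
#' Trimmed mean of M-values: the reference sample is the one whose 75th
#' percentile of CPM is closest to the mean 75th percentile; for every other
#' sample the log2 expression ratios (M) against the reference are doubly
#' trimmed (`trim_M` on M, `trim_A` on average abundance A) and combined by
#' an inverse-asymptotic-variance weighted mean. Factors are rescaled to
#' geometric mean 1, so sequencing depth itself is absorbed by the library
#' sizes, not the factors.
#'
#' @param counts genes x samples count matrix.
#' @param trim_M,trim_A two-sided trim fractions for the M and A values.
#' @return Named numeric vector of factors, one per sample.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  assert_count_matrix(counts)
  if (ncol(counts) < 2) abort("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    abort(sprintf("sample '%s' has zero library size",
                  colnames(counts)[which(lib == 0)[1]]))
  }
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  q75 <- apply(cpm, 2, quantile, probs = 0.75)
  ref <- which.min(abs(q75 - mean(q75)))

  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    2^tmm_one(counts[, s], counts[, ref], lib[s], lib[ref], trim_M, trim_A)
  }, numeric(1))
  f <- f / geometric_mean(f)
  setNames(f, colnames(counts))
}

# doubly trimmed, weighted mean M for one sample vs the reference
tmm_one <- function(y, r, Ly, Lr, trim_M, trim_A) {
  keep <- y > 0 & r > 0
  y <- y[keep]; r <- r[keep]
  M <- log2((y / Ly) / (r / Lr))
  A <- 0.5 * log2((y / Ly) * (r / Lr))
  if (max(A) - min(A) < 1e-10 || max(M) - min(M) < 1e-10) return(0)
  n <- length(M)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(0)
  w <- 1 / ((Ly - y) / (Ly * y) + (Lr - r) / (Lr * r))
  sum(w[keep2] * M[keep2]) / sum(w[keep2])
}

#' Convert counts to normalised expression units
#'
#' CPM divides by the effective library size (library size times TMM
#' factor); TPM first length-normalises and then rescales each sample to one
#' million; log2-CPM uses a prior count of 0.5 to stabilise zeros.
#'
#' @param counts genes x samples count matrix.
#' @param factors per-sample normalisation factors (default
#'   [tmm_factors()]).
#' @param units `"CPM"`, `"TPM"` or `"log2CPM"`.
#' @param lengths named gene lengths in bp; required for TPM.
#' @param prior prior count for log2CPM.
#' @return Matrix of the same shape with attributes `units`,
#'   `library_sizes` and `factors`.
#' @export
to_units <- function(counts, factors = tmm_factors(counts),
                     units = c("log2CPM", "CPM", "TPM"),
                     lengths = NULL, prior = 0.5) {
  units <- match.arg(units)
  assert_count_matrix(counts)
  lib <- colSums(counts)
  eff <- lib * factors[colnames(counts)]
  out <- switch(units,
    CPM = sweep(counts, 2, eff, "/") * 1e6,
    log2CPM = log2(sweep(counts + prior, 2, eff + 1, "/") * 1e6),
    TPM = {
      if (is.null(lengths)) abort("TPM requires gene lengths")
      missing <- setdiff(rownames(counts), names(lengths))
      if (length(missing) > 0) {
        abort(sprintf("missing lengths for genes: %s%s",
                      paste(utils::head(missing, 5), collapse = ", "),
                      if (length(missing) > 5) ", ..." else ""))
      }
      len <- lengths[rownames(counts)]
      if (any(len <= 0)) abort("gene lengths must be positive")
      rate <- counts / len
      sweep(rate, 2, colSums(rate), "/") * 1e6
    })
  structure(out, units = units, library_sizes = lib,
            factors = factors[colnames(counts)])
}

#' Remove family (batch) location effects from log-scale expression
#'
#' Per gene and family, subtracts the family mean and adds back the grand
#' mean — a location-only batch adjustment applied before network
#' construction. Idempotent; a family with a single sample is left
#' uncentred with a warning.
#'
#' @param expr log-scale genes x samples matrix.
#' @param samples sample tibble with `sample_id` and `family`.
#' @return Adjusted matrix of the same shape.
#' @export
adjust_family <- function(expr, samples) {
  stopifnot(is.matrix(expr))
  fam <- as.character(samples$family[match(colnames(expr),
                                           samples$sample_id)])
  if (anyNA(fam)) abort("samples table does not cover all expression columns")
  grand <- rowMeans(expr)
  out <- expr
  for (f in unique(fam)) {
    idx <- which(fam == f)
    if (length(idx) < 2) {
      warn(sprintf("family '%s' has a single sample; left uncentred", f))
      next
    }
    out[, idx] <- expr[, idx] - rowMeans(expr[, idx, drop = FALSE]) + grand
  }
  out
}

#' Leading log-fold-change distance between samples
#'
#' For each sample pair, the distance is the root-mean-square of the `top`
#' largest absolute log-expression differences, with the gene set chosen
#' per pair — the distance behind fold-change-driven multidimensional
#' scaling of RNA-seq samples.
#'
#' @param expr log2-scale genes x samples matrix.
#' @param top number of top genes per pair.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
leading_logfc_distance <- function(expr, top = 500) {
  stopifnot(is.matrix(expr))
  top <- min(top, nrow(expr))
  n <- ncol(expr)
  d <- matrix(0, n, n, dimnames = list(colnames(expr), colnames(expr)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dg <- abs(expr[, i] - expr[, j])
      sel <- sort(dg, decreasing = TRUE)[seq_len(top)]
      d[i, j] <- d[j, i] <- sqrt(mean(sel^2))
    }
  }
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distances and embeds samples on the top `k`
#' eigenvectors scaled by the square roots of their eigenvalues. Euclidean
#' distance matrices of rank at most `k` are reproduced exactly; strongly
#' non-Euclidean input (large negative eigenvalues) triggers a warning.
#'
#' @param d symmetric distance matrix.
#' @param k embedding dimension.
#' @param samples optional sample tibble joined onto the coordinates.
#' @return A tibble with `sample_id`, `dim1` ... `dimk`, any metadata
#'   columns, plus attribute `eig` (all eigenvalues).
#' @export
classical_mds <- function(d, k = 2, samples = NULL) {
  fit <- cmdscale(as.dist(d), k = k, eig = TRUE)
  neg <- fit$eig[fit$eig < 0]
  if (length(neg) > 0 && max(abs(neg)) > 1e-8 * max(abs(fit$eig))) {
    warn("distance matrix is non-Euclidean (negative eigenvalues)")
  }
  coords <- fit$points
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  out <- tibble(sample_id = rownames(coords), as_tibble(coords))
  if (!is.null(samples)) out <- left_join(out, samples, by = "sample_id")
  attr(out, "eig") <- fit$eig
  class(out) <- c("edanet_mds", class(out))
  out
}

#' @rdname classical_mds
#' @param object an `edanet_mds` tibble.
#' @param colour,shape column names mapped to colour and shape.
#' @param ... unused.
#' @export
autoplot.edanet_mds <- function(object, colour = "genotype",
                                shape = "family", ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$dim1, .data$dim2)) +
    ggplot2::labs(x = "MDS dimension 1", y = "MDS dimension 2")
  aes_extra <- list()
  if (colour %in% names(object)) aes_extra$colour <- rlang::sym(colour)
  if (shape %in% names(object)) aes_extra$shape <- rlang::sym(shape)
  p + ggplot2::geom_point(ggplot2::aes(!!!aes_extra), size = 3) +
    ggplot2::theme_minimal()
}
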