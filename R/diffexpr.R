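#' Build the genotype + family + sex design matrix
#'
#' Main-effects dummy coding with CC as the reference genotype; genotype
#' contrasts are then coefficient differences on the log2 scale.
#'
#' @param samples sample tibble with `genotype`, `family`, `sex`.
#' @return Design matrix, samples x coefficients.
#' @export
design_matrix <- function(samples) {
  df <- as.data.frame(samples)
  for (v in c("genotype", "family", "sex")) {
    if (!is.factor(df[[v]])) df[[v]] <- factor(df[[v]])
    df[[v]] <- droplevels(df[[v]])
  }
  terms <- c("genotype", "family", "sex")[vapply(
    c("genotype", "family", "sex"),
    function(v) nlevels(df[[v]]) > 1, logical(1))]
  X <- stats::model.matrix(
    stats::reformulate(if (length(terms)) terms else "1"), df)
  rownames(X) <- samples$sample_id
  if (qr(X)$rank < ncol(X)) abort("design matrix is not full rank")
  X
}

# contrast vector on the design's coefficients for one ordered genotype pair
contrast_vector <- function(design, contrast) {
  cn <- colnames(design)
  v <- setNames(numeric(length(cn)), cn)
  pick <- function(g) {
    col <- paste0("genotype", g)
    if (col %in% cn) col else NA_character_
  }
  a <- pick(contrast[1]); b <- pick(contrast[2])
  if (!is.na(a)) v[a] <- 1
  if (!is.na(b)) v[b] <- v[b] - 1
  # reference level contributes 0; both-NA means contrast of identical levels
  v
}

#' Estimate per-gene NB dispersions with an empirical-Bayes squeeze
#'
#' Raw dispersions come from an adjusted method-of-moments on the Poisson
#' GLM fit (floored at zero), a robust lowess of raw dispersion on log2 mean
#' count gives the trend, and tagwise values shrink the raw estimate toward
#' the trend with `prior_df` prior degrees of freedom: as `prior_df` grows
#' the tagwise value approaches the trend.
#'
#' @param counts filtered genes x samples count matrix.
#' @param design design matrix from [design_matrix()].
#' @param offsets per-sample log effective library sizes; default
#'   `log(colSums(counts) * tmm_factors(counts))`.
#' @param prior_df prior degrees of freedom of the squeeze.
#' @return A tibble: `gene_id`, `mean_count`, `raw`, `trend`, `tagwise`,
#'   `residual_df`, `prior_df`.
#' @export
estimate_dispersions <- function(counts, design,
                                 offsets = default_offsets(counts),
                                 prior_df = 10) {
  assert_count_matrix(counts)
  n <- ncol(counts); p <- ncol(design)
  if (n <= p) abort("no residual degrees of freedom (n_samples <= n_params)")
  d_res <- n - p
  raw <- numeric(nrow(counts))
  mu_bar <- numeric(nrow(counts))
  for (g in seq_len(nrow(counts))) {
    y <- counts[g, ]
    fit <- suppressWarnings(stats::glm.fit(design, y,
                                           family = stats::poisson(),
                                           offset = offsets))
    mu <- fit$fitted.values
    mu_bar[g] <- mean(mu)
    # E[(y - mu)^2] = mu + phi mu^2; adjust for fitted parameters
    raw[g] <- max(0, (n / d_res) * sum((y - mu)^2 - mu) / sum(mu^2))
  }
  lx <- log2(pmax(mu_bar, 1e-8))
  lo <- lowess(lx, raw, f = 0.5)
  trend <- pmax(stats::approx(lo$x, lo$y, xout = lx, rule = 2,
                              ties = mean)$y, 1e-4)
  tagwise <- (prior_df * trend + d_res * raw) / (prior_df + d_res)
  tibble(gene_id = rownames(counts), mean_count = mu_bar,
         raw = raw, trend = trend, tagwise = tagwise,
         residual_df = d_res, prior_df = prior_df)
}

#' @rdname estimate_dispersions
#' @export
default_offsets <- function(counts) {
  log(colSums(counts) * tmm_factors(counts))
}

#' Fit per-gene negative binomial GLMs
#'
#' Log-link IRLS with fixed per-gene dispersion (working weights
#' `mu / (1 + phi * mu)`), offsets equal to log effective library size, and
#' coefficient covariance from the weighted least squares at convergence.
#' Coefficients and standard errors are returned on the log2 scale. Genes
#' whose fit does not converge or sits on the boundary (separation, an
#' all-zero genotype cell) are flagged unstable and excluded from calling.
#'
#' @param counts filtered genes x samples count matrix.
#' @param design design matrix.
#' @param dispersions tibble from [estimate_dispersions()] (tagwise used),
#'   or a named numeric vector of per-gene dispersions.
#' @param offsets per-sample log effective library sizes.
#' @return An object of class `edanet_fit`: list with `coefficients` and
#'   `se` (genes x coefficients, log2), `cov` (list of coefficient
#'   covariance matrices, log2 scale), `residual_df`, `stable`, `design`,
#'   `offsets`, `dispersion`.
#' @export
fit_nb_glm <- function(counts, design, dispersions,
                       offsets = default_offsets(counts)) {
  assert_count_matrix(counts)
  phi <- if (is.data.frame(dispersions)) {
    setNames(dispersions$tagwise, dispersions$gene_id)[rownames(counts)]
  } else dispersions[rownames(counts)]
  if (anyNA(phi)) abort("dispersions missing for some genes")
  n <- ncol(counts); p <- ncol(design)
  if (n <= p) abort("no residual degrees of freedom")
  G <- nrow(counts)
  beta <- matrix(NA_real_, G, p, dimnames = list(rownames(counts),
                                                 colnames(design)))
  se <- beta
  covs <- vector("list", G); names(covs) <- rownames(counts)
  stable <- logical(G)
  ln2 <- log(2)
  for (g in seq_len(G)) {
    y <- counts[g, ]
    fam <- if (phi[g] < 1e-8) stats::poisson() else
      MASS::negative.binomial(theta = 1 / phi[g], link = "log")
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(
        design, y, family = fam, offset = offsets,
        control = list(epsilon = 1e-8, maxit = 50))),
      error = function(e) NULL)
    if (is.null(fit)) { stable[g] <- FALSE; next }
    b <- fit$coefficients
    # WLS covariance at convergence; family has fixed theta -> dispersion 1
    R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
    R[lower.tri(R)] <- 0
    V <- tryCatch(chol2inv(R), error = function(e) NULL)
    ok <- fit$converged && !is.null(V) && all(is.finite(b)) &&
      max(abs(b)) < 20 && all(diag(V) > 0) && all(is.finite(V))
    beta[g, ] <- b / ln2
    if (!is.null(V)) {
      covs[[g]] <- V / ln2^2
      se[g, ] <- sqrt(diag(V)) / ln2
    }
    stable[g] <- isTRUE(ok)
  }
  structure(
    list(coefficients = beta, se = se, cov = covs,
         residual_df = n - p, stable = stable,
         design = design, offsets = offsets,
         dispersion = setNames(phi, rownames(counts))),
    class = "edanet_fit")
}

#' @export
print.edanet_fit <- function(x, ...) {
  cat(sprintf(
    "<edanet_fit> %d genes, %d coefficients, residual df %d (%d unstable)\n",
    nrow(x$coefficients), ncol(x$coefficients), x$residual_df,
    sum(!x$stable)))
  invisible(x)
}

#' Fold-change-threshold (TREAT-style) test for one genotype contrast
#'
#' Tests H0: |log2FC| <= `tau` rather than log2FC = 0, so significant genes
#' exceed the fold-change threshold rather than merely differing from zero.
#' With the contrast estimate `b`, its standard error `s` and residual
#' degrees of freedom `d`, the p-value is
#' `P(T_d >= (|b| - tau)/s) + P(T_d >= (|b| + tau)/s)`, capped at 1;
#' `tau = 0` reduces to the ordinary two-sided t-test. The default
#' `tau = 0.585` corresponds to a 1.5-fold change (2^0.585 ~ 1.5).
#' Benjamini-Hochberg FDR is computed across the stable genes.
#'
#' @param fit an `edanet_fit`.
#' @param contrast ordered genotype pair, e.g. `c("LL", "CC")` for LL vs CC.
#' @param tau log2 fold-change threshold (>= 0).
#' @return A `DEResult` tibble: `gene_id`, `log2fc`, `se`, `df`, `p_value`,
#'   `fdr`, `stable`; attributes `contrast` and `tau`.
#' @export
treat_test <- function(fit, contrast, tau = 0.585) {
  stopifnot(inherits(fit, "edanet_fit"))
  if (tau < 0) abort("`tau` must be non-negative")
  cv <- contrast_vector(fit$design, contrast)
  b <- unname(drop(fit$coefficients %*% cv))
  s <- vapply(seq_along(b), function(g) {
    V <- fit$cov[[g]]
    if (is.null(V)) return(NA_real_)
    sqrt(drop(t(cv) %*% V %*% cv))
  }, numeric(1))
  d <- fit$residual_df
  p <- treat_pvalue(b, s, d, tau)
  p[!fit$stable | !is.finite(s) | s <= 0] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- p.adjust(p[ok], method = "BH")
  out <- tibble(gene_id = rownames(fit$coefficients),
                log2fc = b, se = s, df = d, p_value = p, fdr = fdr,
                stable = fit$stable)
  attr(out, "contrast") <- paste(contrast, collapse = "vs")
  attr(out, "tau") <- tau
  class(out) <- c("edanet_de", class(out))
  out
}

# two t tails against the composite null |beta| <= tau
treat_pvalue <- function(b, s, d, tau) {
  pmin(1, pt((abs(b) - tau) / s, df = d, lower.tail = FALSE) +
         pt((abs(b) + tau) / s, df = d, lower.tail = FALSE))
}

#' Call differentially expressed genes across genotype contrasts
#'
#' Applies the FDR cut per contrast and tabulates the pairwise overlaps of
#' the resulting DEG sets (the Venn counts of the three-contrast design).
#'
#' @param results named list of `DEResult` tibbles (one per contrast).
#' @param alpha FDR cut-off.
#' @return List with `sets` (named list of gene-id vectors), `counts`
#'   (tibble contrast/n) and `overlap` (tibble of pairwise overlap counts).
#' @export
call_degs <- function(results, alpha = 0.05) {
  sets <- lapply(results, function(r) r$gene_id[!is.na(r$fdr) & r$fdr < alpha])
  cn <- names(sets)
  pairs <- if (length(cn) >= 2) utils::combn(cn, 2, simplify = FALSE) else
    list()
  overlap <- purrr::map_dfr(pairs, function(pr) {
    tibble(set1 = pr[1], set2 = pr[2],
           n1 = length(sets[[pr[1]]]), n2 = length(sets[[pr[2]]]),
           n_overlap = length(intersect(sets[[pr[1]]], sets[[pr[2]]])))
  })
  list(sets = sets,
       counts = tibble(contrast = cn,
                       n = vapply(sets, length, integer(1))),
       overlap = overlap)
}

#' Run the three-contrast DE analysis in one call
#'
#' Convenience wrapper: dispersions, NB fits and TREAT tests for LL vs CC,
#' CL vs CC and LL vs CL.
#'
#' @inheritParams estimate_dispersions
#' @inheritParams treat_test
#' @param samples sample tibble with `genotype`, `family`, `sex` (rows
#'   matching the count columns).
#' @param contrasts list of ordered genotype pairs.
#' @param alpha FDR cut-off passed to [call_degs()].
#' @return List with `fit`, `dispersions`, `results` (named list of
#'   `DEResult`), and `degs` from [call_degs()].
#' @export
de_analysis <- function(counts, samples, tau = 0.585, alpha = 0.05,
                        contrasts = list(c("LL", "CC"), c("CL", "CC"),
                                         c("LL", "CL")),
                        offsets = default_offsets(counts),
                        prior_df = 10) {
  design <- design_matrix(samples)
  design <- design[colnames(counts), , drop = FALSE]
  disp <- estimate_dispersions(counts, design, offsets, prior_df)
  fit <- fit_nb_glm(counts, design, disp, offsets)
  results <- lapply(contrasts, function(ct) treat_test(fit, ct, tau))
  names(results) <- vapply(contrasts, paste, character(1), collapse = "vs")
  list(fit = fit, dispersions = disp, results = results,
       degs = call_degs(results, alpha))
}

#' @export
tidy.edanet_de <- function(x, ...) {
  out <- as_tibble(x)
  out$contrast <- attr(x, "contrast")
  out
}

#' @export
glance.edanet_de <- function(x, alpha = 0.05, ...) {
  tibble(contrast = attr(x, "contrast"), tau = attr(x, "tau"),
         n_genes = nrow(x),
         n_unstable = sum(!x$stable),
         n_deg = sum(!is.na(x$fdr) & x$fdr < alpha))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
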