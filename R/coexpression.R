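#' Biweight midcorrelation matrix
#'
#' Robust correlation between gene expression profiles: observations are
#' weighted by `(1 - u^2)^2` with `u = (x - median) / (9 * mad)`, so points
#' far from the median get zero weight. To keep the weighting from
#' discarding too much data, each side is capped: when more than
#' `max_p_outliers` of a profile's observations would fall beyond |u| = 1,
#' that side of `u` is rescaled so exactly that fraction does. Profiles
#' with zero median absolute deviation fall back to Pearson weighting
#' (logged via the `pearson_fallback` attribute); constant profiles give
#' NA and should be removed upstream.
#'
#' @param expr genes x samples matrix (log scale, family adjusted).
#' @param max_p_outliers maximum fraction per side allowed to receive zero
#'   weight, in `[0, 0.5]`.
#' @return Genes x genes correlation matrix in `[-1, 1]`, unit diagonal.
#' @export
bicor_matrix <- function(expr, max_p_outliers = 0.10) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 4) abort("bicor needs at least 4 samples")
  if (max_p_outliers < 0 || max_p_outliers > 0.5) {
    abort("`max_p_outliers` must lie in [0, 0.5]")
  }
  Z <- matrix(0, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  fallback <- logical(nrow(expr))
  for (g in seq_len(nrow(expr))) {
    x <- expr[g, ]
    med <- median(x)
    md <- median(abs(x - med))
    if (md == 0) {
      # no spread around the median: Pearson weighting for this gene
      s <- sd(x)
      if (s == 0) { Z[g, ] <- NA_real_; fallback[g] <- TRUE; next }
      xt <- x - mean(x)
      Z[g, ] <- xt / sqrt(sum(xt^2))
      fallback[g] <- TRUE
      next
    }
    u <- (x - med) / (9 * md)
    if (max_p_outliers < 0.5) {
      qL <- quantile(u, max_p_outliers, names = FALSE)
      if (qL < -1) u[u < 0] <- u[u < 0] / (-qL)
      qU <- quantile(u, 1 - max_p_outliers, names = FALSE)
      if (qU > 1) u[u > 0] <- u[u > 0] / qU
    }
    w <- (1 - u^2)^2 * (abs(u) < 1)
    xt <- (x - med) * w
    nrm <- sqrt(sum(xt^2))
    if (nrm == 0) { Z[g, ] <- NA_real_; fallback[g] <- TRUE; next }
    Z[g, ] <- xt / nrm
  }
  if (any(is.na(Z[, 1]) & apply(expr, 1, function(x) sd(x) == 0))) {
    warn("constant gene profiles give NA correlations; exclude them")
  }
  cr <- tcrossprod(Z)
  cr[cr > 1] <- 1; cr[cr < -1] <- -1
  diag(cr)[!is.na(diag(cr))] <- 1
  attr(cr, "pearson_fallback") <- rownames(expr)[fallback]
  cr
}

#' Signed weighted adjacency from a correlation matrix
#'
#' `a_ij = ((1 + cor_ij) / 2) ^ beta`: perfectly correlated genes get
#' adjacency 1, perfectly anti-correlated genes 0, uncorrelated genes
#' `0.5^beta`. The diagonal is zeroed for connectivity purposes.
#'
#' @param cor correlation matrix in `[-1, 1]`.
#' @param beta soft-threshold power (>= 1).
#' @param signed signed network (the only supported type; the flag is kept
#'   for config echo).
#' @return Adjacency matrix in `[0, 1]` with zero diagonal.
#' @export
adjacency_matrix <- function(cor, beta = 14, signed = TRUE) {
  stopifnot(is.matrix(cor))
  if (beta < 1) abort("`beta` must be >= 1")
  if (!signed) abort("only signed networks are supported")
  a <- ((1 + cor) / 2)^beta
  diag(a) <- 0
  a
}

#' Total connectivity (kTotal)
#'
#' A gene's total connectivity is the sum of its adjacencies with all
#' other genes — a standard proxy for pleiotropy.
#'
#' @param adj adjacency matrix with zero diagonal.
#' @return Named numeric vector, one value per gene.
#' @export
connectivity <- function(adj) {
  rowSums(adj)
}

#' Pick the soft threshold by scale-free topology fit
#'
#' For each candidate power the adjacency and connectivity distribution are
#' computed, connectivities are binned (10 bins), and `log10(freq)` is
#' regressed on `log10(mean k)`; the signed fit index is
#' `-sign(slope) * R^2`. The chosen power is the smallest candidate whose
#' signed R^2 reaches `r2_cut`; if none does, the argmax is returned with
#' `saturated = FALSE`.
#'
#' @param expr genes x samples matrix, or a precomputed correlation matrix
#'   via `cor_matrix`.
#' @param candidates candidate powers.
#' @param r2_cut signed R^2 saturation cut.
#' @param max_p_outliers passed to [bicor_matrix()].
#' @param cor_matrix optional precomputed correlation matrix.
#' @return List of class `edanet_sft`: `beta` (chosen), `saturated`,
#'   `table` (tibble: `beta`, `signed_r2`, `mean_k`, `median_k`, `max_k`).
#' @export
pick_soft_threshold <- function(expr, candidates = c(1:10, 12, 14, 16, 18, 20),
                                r2_cut = 0.85, max_p_outliers = 0.10,
                                cor_matrix = NULL) {
  cr <- cor_matrix %||% bicor_matrix(expr, max_p_outliers)
  if (nrow(cr) < 30) abort("soft-threshold fit needs at least 30 genes")
  rows <- purrr::map_dfr(candidates, function(beta) {
    k <- connectivity(adjacency_matrix(cr, beta))
    tibble(beta = beta, signed_r2 = scale_free_fit(k),
           mean_k = mean(k), median_k = median(k), max_k = max(k))
  })
  hit <- which(rows$signed_r2 >= r2_cut)
  saturated <- length(hit) > 0
  beta <- if (saturated) rows$beta[hit[1]] else
    rows$beta[which.max(rows$signed_r2)]
  structure(list(beta = beta, saturated = saturated, table = rows,
                 r2_cut = r2_cut),
            class = "edanet_sft")
}

# signed scale-free topology fit index from a connectivity vector
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  mean_k <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(freq[keep]) ~ log10(mean_k[keep]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' @export
print.edanet_sft <- function(x, ...) {
  cat(sprintf("<edanet_sft> chosen beta = %d (%s; signed R^2 cut %.2f)\n",
              x$beta,
              if (x$saturated) "saturated" else "argmax fallback",
              x$r2_cut))
  invisible(x)
}

#' @rdname pick_soft_threshold
#' @param object an `edanet_sft`.
#' @param ... unused.
#' @export
autoplot.edanet_sft <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(.data$beta, .data$signed_r2)) +
    ggplot2::geom_hline(yintercept = object$r2_cut, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "soft threshold (power)",
                  y = expression("signed scale-free fit" ~ R^2)) +
    ggplot2::theme_minimal()
}

#' Topological overlap matrix
#'
#' Credits two genes for shared neighbours:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal; values stay in `[0, 1]` and `1 - TOM` is the clustering
#' dissimilarity.
#'
#' @param adj symmetric adjacency in `[0, 1]` with zero diagonal.
#' @return TOM matrix.
#' @export
tom_similarity <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10)) {
    abort("adjacency must be symmetric")
  }
  a <- adj
  diag(a) <- 0
  L <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, a static cut at
#' `cut_height`, removal of clusters smaller than `min_size` (label `"M0"`,
#' the unassigned bucket), eigengene computation (first principal component
#' of the z-scored member expression, sign-oriented so the mean member
#' correlation is positive), and iterative merging of module pairs whose
#' eigengenes correlate at or above `merge_cor`. Final labels are `"M1"`,
#' `"M2"`, ... by decreasing size. Genes are ordered lexicographically
#' before clustering, so labels do not depend on input order.
#'
#' @param tom TOM matrix with gene dimnames.
#' @param expr genes x samples expression matrix (for eigengenes; same
#'   genes).
#' @param cut_height static tree cut height on `1 - TOM`.
#' @param min_size minimum module size.
#' @param merge_cor eigengene correlation at which modules merge.
#' @return List of class `edanet_modules`: `labels` (named character),
#'   `eigengenes` (samples x modules matrix), `sizes` (named integer).
#' @export
detect_modules <- function(tom, expr, cut_height = 0.99, min_size = 20,
                           merge_cor = 0.75) {
  genes <- rownames(tom)
  ord <- order(genes)
  tom <- tom[ord, ord]
  expr <- expr[rownames(tom), , drop = FALSE]
  hc <- hclust(as.dist(1 - tom), method = "average")
  cl <- cutree(hc, h = cut_height)
  labels <- setNames(rep("M0", length(cl)), rownames(tom))
  sizes <- table(cl)
  keep_cl <- names(sizes)[sizes >= min_size]
  mods <- list()
  for (cid in keep_cl) mods[[length(mods) + 1]] <- names(cl)[cl == cid]

  if (length(mods) > 0) {
    egs <- lapply(mods, function(members)
      module_eigengene(expr[members, , drop = FALSE]))
    # merge closest eigengene pair until all pairs are below merge_cor
    repeat {
      if (length(mods) < 2) break
      E <- do.call(cbind, egs)
      cc <- cor(E)
      diag(cc) <- -Inf
      best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      if (cc[best[1], best[2]] < merge_cor) break
      i <- min(best); j <- max(best)
      mods[[i]] <- sort(c(mods[[i]], mods[[j]]))
      egs[[i]] <- module_eigengene(expr[mods[[i]], , drop = FALSE])
      mods[[j]] <- NULL; egs[[j]] <- NULL
    }
    # label by decreasing size, ties by first member id
    sz <- vapply(mods, length, integer(1))
    first <- vapply(mods, function(m) sort(m)[1], character(1))
    o <- order(-sz, first)
    mods <- mods[o]; egs <- egs[o]
    for (m in seq_along(mods)) labels[mods[[m]]] <- sprintf("M%d", m)
    eigengenes <- do.call(cbind, egs)
    colnames(eigengenes) <- sprintf("M%d", seq_along(mods))
  } else {
    eigengenes <- matrix(numeric(0), nrow = ncol(expr), ncol = 0,
                         dimnames = list(colnames(expr), NULL))
  }
  structure(list(labels = labels,
                 eigengenes = eigengenes,
                 sizes = sort(table(labels), decreasing = TRUE)),
            class = "edanet_modules")
}

# first principal component of the z-scored member expression, unit norm,
# sign-oriented to positive mean member correlation
module_eigengene <- function(member_expr) {
  z <- t(scale(t(member_expr)))
  z[is.na(z)] <- 0
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  mc <- mean(cor(t(member_expr), e), na.rm = TRUE)
  if (!is.na(mc) && mc < 0) e <- -e
  setNames(e, colnames(member_expr))
}

#' Module membership (kME)
#'
#' Correlation of each profile with each module eigengene.
#'
#' @param profiles units x samples matrix (genes or exons).
#' @param eigengenes samples x modules matrix.
#' @param method correlation type, `"pearson"` or `"bicor"`.
#' @param max_p_outliers for `"bicor"`.
#' @return Units x modules correlation matrix (NA rows for constant
#'   profiles).
#' @export
kme <- function(profiles, eigengenes, method = c("bicor", "pearson"),
                max_p_outliers = 0.10) {
  method <- match.arg(method)
  if (ncol(eigengenes) == 0) {
    return(matrix(numeric(0), nrow = nrow(profiles), ncol = 0,
                  dimnames = list(rownames(profiles), NULL)))
  }
  stopifnot(ncol(profiles) == nrow(eigengenes))
  if (method == "pearson") {
    out <- suppressWarnings(cor(t(profiles), eigengenes))
  } else {
    joint <- rbind(profiles, t(eigengenes))
    cc <- bicor_matrix(joint, max_p_outliers)
    out <- cc[seq_len(nrow(profiles)),
              nrow(profiles) + seq_len(ncol(eigengenes)), drop = FALSE]
  }
  dimnames(out) <- list(rownames(profiles), colnames(eigengenes))
  out
}

#' Build the full signed co-expression network
#'
#' Correlation, soft threshold (fixed or picked), adjacency, TOM, modules,
#' kTotal and per-gene own-module kME in one call.
#'
#' @param expr genes x samples matrix (log scale, family adjusted);
#'   constant genes are dropped with a warning.
#' @param beta fixed power, or `NULL` to pick by scale-free fit.
#' @param candidates candidate powers when picking.
#' @param r2_cut scale-free fit cut.
#' @param max_p_outliers bicor side cap.
#' @param cut_height,min_size,merge_cor module detection parameters.
#' @param max_genes hard cap on network size (whole-matrix computation).
#' @return Object of class `edanet_network`: `module_table` tibble
#'   (`gene_id`, `module`, `k_total`, `kme_own`), `labels`, `eigengenes`,
#'   `k_total`, `sft` (NULL when `beta` fixed), `beta`, `adjacency`,
#'   `cor_method`, `dropped_genes`.
#' @export
build_network <- function(expr, beta = 14, candidates = c(1:10, 12, 14, 16,
                                                          18, 20),
                          r2_cut = 0.85, max_p_outliers = 0.10,
                          cut_height = 0.99, min_size = 20,
                          merge_cor = 0.75, max_genes = 6000) {
  stopifnot(is.matrix(expr))
  if (nrow(expr) > max_genes) {
    abort(sprintf(
      "network limited to %d genes (whole-matrix computation); got %d",
      max_genes, nrow(expr)))
  }
  const <- apply(expr, 1, sd) == 0
  if (any(const)) {
    warn(sprintf("%d constant gene(s) excluded from the network",
                 sum(const)))
    expr <- expr[!const, , drop = FALSE]
  }
  cr <- bicor_matrix(expr, max_p_outliers)
  sft <- NULL
  if (is.null(beta)) {
    sft <- pick_soft_threshold(expr, candidates, r2_cut, max_p_outliers,
                               cor_matrix = cr)
    beta <- sft$beta
  }
  adj <- adjacency_matrix(cr, beta)
  k_total <- connectivity(adj)
  tom <- tom_similarity(adj)
  mods <- detect_modules(tom, expr, cut_height, min_size, merge_cor)
  kme_m <- kme(expr, mods$eigengenes, method = "bicor",
               max_p_outliers = max_p_outliers)
  labels <- mods$labels[rownames(expr)]
  kme_own <- vapply(seq_len(nrow(expr)), function(i) {
    m <- labels[i]
    if (m == "M0" || !(m %in% colnames(kme_m))) NA_real_ else kme_m[i, m]
  }, numeric(1))
  structure(
    list(module_table = tibble(gene_id = rownames(expr),
                               module = unname(labels),
                               k_total = unname(k_total[rownames(expr)]),
                               kme_own = kme_own),
         labels = labels, eigengenes = mods$eigengenes,
         k_total = k_total, sft = sft, beta = beta,
         adjacency = adj, cor_method = "bicor",
         max_p_outliers = max_p_outliers,
         dropped_genes = rownames(expr)[const]),
    class = "edanet_network")
}

#' @export
print.edanet_network <- function(x, ...) {
  n_mod <- sum(colnames(x$eigengenes) != "M0")
  cat(sprintf(
    "<edanet_network> %d genes, beta = %d, %d modules (+ M0: %d genes)\n",
    nrow(x$module_table), x$beta, ncol(x$eigengenes),
    sum(x$labels == "M0")))
  invisible(x)
}

#' @export
tidy.edanet_network <- function(x, ...) x$module_table

#' @export
glance.edanet_network <- function(x, ...) {
  tibble(n_genes = nrow(x$module_table),
         beta = x$beta,
         n_modules = ncol(x$eigengenes),
         n_unassigned = sum(x$labels == "M0"),
         median_k_total = median(x$k_total))
}

#' Assign a gene's exons to modules (atomization)
#'
#' Treats each exon of a gene as its own expression unit: exon profiles are
#' normalised and family-adjusted exactly like the network input, and each
#' exon is assigned to the module whose eigengene it correlates with most,
#' provided that kME reaches `min_kme` (otherwise `"M0"`). This localises a
#' gene's module membership to specific exons — e.g. one exon following a
#' different module than the rest of its gene.
#'
#' @param gene_id gene to atomize.
#' @param ec [exon_counts] containing the gene.
#' @param net `edanet_network`.
#' @param samples sample tibble (for family adjustment).
#' @param factors per-sample normalisation factors of the gene-level
#'   matrix.
#' @param lib_sizes per-sample library sizes of the gene-level matrix.
#' @param min_kme minimum kME to leave M0.
#' @return Tibble: `exon_id`, `exon_order`, `module`, `kme_best`, plus one
#'   kME column per module.
#' @export
atomize_gene <- function(gene_id, ec, net, samples, factors = NULL,
                         lib_sizes = NULL, min_kme = 0.5) {
  stopifnot(inherits(ec, "exon_counts"), inherits(net, "edanet_network"))
  rows <- which(ec$gene_of_exon == gene_id)
  if (length(rows) == 0) abort(sprintf("gene '%s' not in exon matrix",
                                       gene_id))
  sample_ids <- rownames(net$eigengenes)
  counts <- ec$counts[rows, sample_ids, drop = FALSE]
  lib <- lib_sizes %||% colSums(ec$counts[, sample_ids, drop = FALSE])
  f <- factors %||% setNames(rep(1, length(sample_ids)), sample_ids)
  expr <- log2(sweep(counts + 0.5, 2, lib[sample_ids] * f[sample_ids] + 1,
                     "/") * 1e6)
  expr <- adjust_family(expr, samples)
  km <- kme(expr, net$eigengenes, method = net$cor_method,
            max_p_outliers = net$max_p_outliers)
  assigned <- apply(km, 1, function(r) {
    if (all(is.na(r))) return("M0")
    best <- which.max(r)
    if (r[best] >= min_kme) colnames(km)[best] else "M0"
  })
  out <- tibble(exon_id = rownames(counts),
                exon_order = unname(ec$exon_order[rownames(counts)]),
                module = unname(assigned),
                kme_best = apply(km, 1, function(r)
                  if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)))
  dplyr::bind_cols(out, as_tibble(km))
}

#' Extract a focal neighbourhood or module hub subnetwork
#'
#' Focal-gene mode returns the `n` genes with the largest adjacency to the
#' focal gene plus the focal gene itself; module mode returns the `n`
#' genes with the highest total connectivity within the module (its hub
#' genes). Edges are the pairwise adjacencies among the selected nodes.
#'
#' @param net `edanet_network`.
#' @param focal a gene id present in the network, or a module label
#'   (`"M1"`, ...).
#' @param n number of genes to select.
#' @return List with `nodes` (tibble: `gene_id`, `module`, `k_total`) and
#'   `edges` (tibble: `from`, `to`, `weight`).
#' @export
extract_subnetwork <- function(net, focal, n = 10) {
  stopifnot(inherits(net, "edanet_network"))
  adj <- net$adjacency
  genes <- rownames(adj)
  if (focal %in% genes) {
    a <- adj[focal, ]
    a <- a[names(a) != focal]
    sel <- c(focal, names(sort(a, decreasing = TRUE))[seq_len(min(n,
                                                                  length(a)))])
  } else if (focal %in% net$labels) {
    members <- names(net$labels)[net$labels == focal]
    if (length(members) < n) {
      warn(sprintf("module %s has only %d genes; returning all", focal,
                   length(members)))
    }
    k <- sort(net$k_total[members], decreasing = TRUE)
    sel <- names(k)[seq_len(min(n, length(k)))]
  } else {
    abort(sprintf("'%s' is neither a gene nor a module of the network",
                  focal))
  }
  sub <- adj[sel, sel, drop = FALSE]
  idx <- which(upper.tri(sub), arr.ind = TRUE)
  edges <- tibble(from = sel[idx[, 1]], to = sel[idx[, 2]],
                  weight = sub[idx])
  nodes <- tibble(gene_id = sel,
                  module = unname(net$labels[sel]),
                  k_total = unname(net$k_total[sel]))
  list(nodes = nodes, edges = arrange(edges, dplyr::desc(.data$weight)))
}
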