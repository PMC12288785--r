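#' Permutation test for a difference in gene-set medians
#'
#' Compares the median of a per-gene value (total connectivity, TPM, ...)
#' between two gene sets, or between one set and the whole universe. The
#' observed statistic is `median(values[setA]) - median(values[setB])`;
#' each of `B` iterations redraws random sets of the same sizes (without
#' replacement, drawn disjointly in two-set mode) and the p-value is the
#' fraction of iterations whose absolute difference is at least the
#' observed one. With zero exceedances the estimate is reported with a
#' floor flag (display "< 1/B"); the `(c+1)/(B+1)` estimator is available
#' via `add_one`.
#'
#' @param values named numeric vector over the gene universe.
#' @param set_a,set_b character vectors of gene ids; `set_b = NULL`
#'   compares `set_a` against the whole universe (which stays fixed across
#'   iterations).
#' @param B number of permutations.
#' @param seed integer seed.
#' @param add_one use the `(c+1)/(B+1)` estimator.
#' @return List of class `edanet_perm`: `observed`, `B`, `exceed`, `p`,
#'   `p_floor` (TRUE when no exceedances), `p_display`, `seed`, `mode`.
#' @export
perm_median_diff <- function(values, set_a, set_b = NULL, B = 10000,
                             seed = 1234, add_one = FALSE) {
  universe <- names(values)
  if (is.null(universe)) abort("`values` must be named by gene id")
  if (!all(set_a %in% universe)) abort("set_a outside the value universe")
  if (!is.null(set_b) && !all(set_b %in% universe)) {
    abort("set_b outside the value universe")
  }
  nA <- length(set_a)
  if (nA == 0) abort("set_a is empty")
  two_set <- !is.null(set_b)
  if (two_set && length(set_b) == 0) abort("set_b is empty")
  nB <- if (two_set) length(set_b) else NA_integer_
  if (nA > length(universe) ||
      (two_set && nA + nB > length(universe))) {
    abort("sets larger than the value universe")
  }
  med_all <- median(values)
  observed <- if (two_set) {
    median(values[set_a]) - median(values[set_b])
  } else {
    median(values[set_a]) - med_all
  }
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(B)) {
      if (two_set) {
        draw <- sample(universe, nA + nB)
        d <- median(values[draw[seq_len(nA)]]) -
          median(values[draw[nA + seq_len(nB)]])
      } else {
        d <- median(values[sample(universe, nA)]) - med_all
      }
      if (abs(d) >= abs(observed)) cnt <- cnt + 1L
    }
    cnt
  })
  perm_result(observed, exceed, B, seed, add_one,
              mode = if (two_set) "two_set" else "vs_universe")
}

#' Permutation + exact test for the overlap of two gene sets
#'
#' Draws independent random sets of sizes `n1` and `n2` from a universe of
#' `N` genes and counts how often their overlap reaches the observed one;
#' also returns the exact upper-tail hypergeometric probability
#' `P(X >= observed)` as a closed-form cross-check.
#'
#' @param N universe size.
#' @param n1,n2 set sizes.
#' @param observed_overlap observed intersection size.
#' @param B number of permutations.
#' @param seed integer seed.
#' @param add_one use the `(c+1)/(B+1)` estimator.
#' @return `edanet_perm` list with additional element `p_exact`.
#' @export
perm_overlap <- function(N, n1, n2, observed_overlap, B = 10000,
                         seed = 1234, add_one = FALSE) {
  if (n1 > N || n2 > N) abort("set sizes exceed the universe")
  if (observed_overlap > min(n1, n2)) {
    abort("observed overlap exceeds the smaller set")
  }
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(B)) {
      s1 <- sample.int(N, n1)
      s2 <- sample.int(N, n2)
      if (length(intersect(s1, s2)) >= observed_overlap) cnt <- cnt + 1L
    }
    cnt
  })
  out <- perm_result(observed_overlap, exceed, B, seed, add_one,
                     mode = "overlap")
  out$p_exact <- phyper(observed_overlap - 1, n1, N - n1, n2,
                        lower.tail = FALSE)
  out
}

perm_result <- function(observed, exceed, B, seed, add_one, mode) {
  p <- if (add_one) (exceed + 1) / (B + 1) else exceed / B
  floor_flag <- exceed == 0 && !add_one
  structure(
    list(observed = observed, B = B, exceed = exceed, p = p,
         p_floor = floor_flag,
         p_display = if (floor_flag) sprintf("< %g", 1 / B) else
           sprintf("%g", p),
         seed = seed, mode = mode),
    class = "edanet_perm")
}

#' @export
print.edanet_perm <- function(x, ...) {
  cat(sprintf("<edanet_perm mode=%s> observed = %g, p %s (%d/%d, seed %d)\n",
              x$mode, x$observed,
              if (x$p_floor) x$p_display else paste("=", x$p_display),
              x$exceed, x$B, x$seed))
  invisible(x)
}

#' @export
tidy.edanet_perm <- function(x, ...) {
  tibble(mode = x$mode, observed = x$observed, B = x$B,
         exceed = x$exceed, p = x$p, p_floor = x$p_floor,
         p_exact = x$p_exact %||% NA_real_, seed = x$seed)
}

#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the query set is enriched against a chosen
#' background (by design, the genes that passed the expression filter):
#' upper-tail hypergeometric p for the query/term overlap, BH adjustment
#' across terms. Terms with fewer than `min_term` background members are
#' skipped.
#'
#' @param sets named list of character vectors (terms); each may carry a
#'   `term_name` attribute (as from [read_gmt()]).
#' @param query character vector of gene ids, subset of `background`.
#' @param background character vector of gene ids (the tested universe).
#' @param min_term minimum term size within the background.
#' @param alpha FDR threshold for the `enriched` flag.
#' @return Tibble: `term_id`, `term_name`, `term_size`, `overlap`,
#'   `p_value`, `fdr`, `enriched`.
#' @export
ora <- function(sets, query, background, min_term = 3, alpha = 0.05) {
  if (length(background) == 0) abort("empty background")
  query <- unique(query)
  if (!all(query %in% background)) {
    abort("query must be a subset of the background")
  }
  N <- length(unique(background))
  n <- length(query)
  rows <- purrr::imap_dfr(sets, function(members, id) {
    K <- length(intersect(members, background))
    if (K < min_term) return(NULL)
    k <- length(intersect(members, query))
    tibble(term_id = id,
           term_name = attr(members, "term_name") %||% id,
           term_size = K, overlap = k,
           p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  if (nrow(rows) == 0) return(rows)
  rows$fdr <- p.adjust(rows$p_value, method = "BH")
  rows$enriched <- rows$fdr < alpha
  arrange(rows, .data$p_value)
}

#' Cross-tabulate DEGs and DSGs across co-expression modules
#'
#' Rows are the gene categories DSG-only, DEG-only, both, and the total
#' gene count; columns are every module containing at least one DEG or DSG
#' plus the unassigned bucket M0.
#'
#' @param deg_set,dsg_set character vectors of gene ids.
#' @param labels named character vector gene -> module (must cover both
#'   sets).
#' @return Tibble with a `category` column and one column per module.
#' @export
crosstab_modules <- function(deg_set, dsg_set, labels) {
  missing <- setdiff(union(deg_set, dsg_set), names(labels))
  if (length(missing) > 0) {
    abort(sprintf("module labels missing for: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  both <- intersect(deg_set, dsg_set)
  deg_only <- setdiff(deg_set, both)
  dsg_only <- setdiff(dsg_set, both)
  touched <- sort(unique(labels[union(deg_set, dsg_set)]))
  cols <- union(touched, "M0")
  # deterministic module order: M0 last, others by number
  num <- suppressWarnings(as.integer(sub("^M", "", setdiff(cols, "M0"))))
  cols <- c(setdiff(cols, "M0")[order(num)], "M0")
  tally <- function(set) {
    vapply(cols, function(m) sum(labels[set] == m), integer(1))
  }
  out <- tibble(category = c("DSG_only", "DEG_only", "both", "total_genes"))
  counts <- rbind(tally(dsg_only), tally(deg_only), tally(both),
                  vapply(cols, function(m) sum(labels == m), integer(1)))
  colnames(counts) <- cols
  dplyr::bind_cols(out, as_tibble(counts))
}
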