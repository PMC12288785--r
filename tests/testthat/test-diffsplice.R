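# build an exon_counts object with given per-genotype usage, multinomial
# partition of NB gene totals
usage_fixture <- function(samples, usage_cc, usage_ll = usage_cc,
                          n_null_genes = 30, gene_mu = 800, seed = 5) {
  withr::with_seed(seed, {
    n_s <- nrow(samples)
    ll <- samples$genotype == "LL"
    m_t <- length(usage_cc)
    genes <- c("target", paste0("null", seq_len(n_null_genes)))
    n_ex <- c(m_t, rep(3, n_null_genes))
    counts <- NULL
    gene_of <- character(0); ords <- integer(0); ids <- character(0)
    for (i in seq_along(genes)) {
      tot <- rnbinom(n_s, mu = gene_mu, size = 20)
      if (genes[i] == "target") {
        pcc <- usage_cc; pll <- usage_ll
      } else {
        p <- rgamma(3, 5); p <- p / sum(p)
        pcc <- p; pll <- p
      }
      ex <- vapply(seq_len(n_s), function(k)
        rmultinom(1, tot[k], if (ll[k]) pll else pcc)[, 1],
        numeric(n_ex[i]))
      counts <- rbind(counts, ex)
      gene_of <- c(gene_of, rep(genes[i], n_ex[i]))
      ords <- c(ords, seq_len(n_ex[i]))
      ids <- c(ids, sprintf("%s_e%d", genes[i], seq_len(n_ex[i])))
    }
    dimnames(counts) <- list(ids, samples$sample_id)
    exon_counts(counts, gene_of, ords)
  })
}

test_that("exons proportional to their gene show no usage signal", {
  sim <- small_sim(seed = 41)
  s <- sim$samples
  # deterministic proportional partition: zero usage effect by construction
  set.seed(6)
  tot <- matrix(rpois(20 * 36, 2000), 20, 36,
                dimnames = list(paste0("g", 1:20), s$sample_id))
  props <- c(0.5, 0.3, 0.2)
  counts <- do.call(rbind, lapply(seq_len(20), function(g)
    outer(props, tot[g, ])))
  ids <- as.vector(t(outer(paste0("g", 1:20), paste0("_e", 1:3), paste0)))
  counts <- counts[order(rep(seq_len(20), each = 3)), ]
  rownames(counts) <- ids
  colnames(counts) <- s$sample_id
  ec <- exon_counts(round(counts), rep(paste0("g", 1:20), each = 3),
                    rep(1:3, 20))
  fit <- fit_exon_glm(ec, s)
  st <- exon_usage_stats(fit, ec, c("LL", "CC"))
  expect_true(all(abs(st$usage_effect[st$testable]) < 0.05))
  expect_true(all(st$p_value[st$testable] > 0.5))
})

test_that("two-exon genes give antisymmetric usage effects", {
  sim <- small_sim(seed = 43)
  s <- sim$samples
  ec <- usage_fixture(s, usage_cc = c(0.6, 0.4),
                      usage_ll = c(0.4, 0.6), n_null_genes = 10)
  fit <- fit_exon_glm(ec, s)
  st <- exon_usage_stats(fit, ec, c("LL", "CC"))
  tg <- st[st$gene_id == "target", ]
  expect_equal(tg$usage_effect[1], -tg$usage_effect[2], tolerance = 1e-10)
  expect_equal(tg$t[1], -tg$t[2], tolerance = 1e-10)
})

test_that("a planted usage shift puts the target exon at the gene minimum p", {
  sim <- small_sim(seed = 47)
  s <- sim$samples
  # exon 1 gains +0.2 usage in LL, like differential usage of a first exon
  ec <- usage_fixture(s, usage_cc = c(0.3, 0.4, 0.3),
                      usage_ll = c(0.5, 0.4 * 0.5 / 0.7, 0.3 * 0.5 / 0.7))
  fit <- fit_exon_glm(ec, s)
  st <- exon_usage_stats(fit, ec, c("LL", "CC"))
  tg <- st[st$gene_id == "target" & st$testable, ]
  expect_identical(tg$exon_order[which.min(tg$p_value)], 1L)
  expect_lt(min(tg$p_value), 0.01)
})

test_that("single-exon genes are excluded with a reason code", {
  sim <- small_sim(seed = 53)
  s <- sim$samples
  set.seed(1)
  counts <- rbind(matrix(rpois(2 * 36, 500), 2, 36),
                  matrix(rpois(1 * 36, 500), 1, 36))
  rownames(counts) <- c("gA_e1", "gA_e2", "gB_e1")
  colnames(counts) <- s$sample_id
  ec <- exon_counts(counts, c("gA", "gA", "gB"), c(1, 2, 1))
  fit <- fit_exon_glm(ec, s)
  st <- exon_usage_stats(fit, ec, c("LL", "CC"))
  expect_false(any(st$testable[st$gene_id == "gB"]))
  expect_identical(st$reason[st$gene_id == "gB"], "single_testable_exon")
  expect_false("gB" %in% aggregate_gene_p(st, "simes")$gene_id)
})

test_that("Simes combination matches its direct formula and invariants", {
  expect_equal(simes_p(rep(0.2, 4)), 0.2)
  expect_equal(simes_p(c(0.01, 0.04, 0.90)), 0.03)
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(2:8, 1))
    m <- length(p)
    sp <- sort(p)
    brute <- min(vapply(seq_len(m), function(j) m * sp[j] / j, numeric(1)))
    expect_equal(simes_p(p), brute)
    expect_equal(simes_p(sample(p)), simes_p(p))  # order invariance
    expect_gte(simes_p(p), min(p))
    expect_lte(simes_p(p), 1)
  }
})

test_that("the union rule keeps genes found by either aggregation route", {
  sim <- small_sim(seed = 59)
  s <- sim$samples
  ec <- usage_fixture(s, usage_cc = c(0.3, 0.4, 0.3),
                      usage_ll = c(0.45, 0.4 * 0.55 / 0.7, 0.3 * 0.55 / 0.7),
                      n_null_genes = 40)
  fit <- fit_exon_glm(ec, s)
  st <- exon_usage_stats(fit, ec, c("LL", "CC"))
  ds <- call_dsgs(st, alpha = 0.05)
  expect_true(all(ds$dsg == (ds$dsg_gene_level | ds$dsg_simes)))
  union_set <- ds$gene_id[ds$dsg]
  expect_true(all(ds$gene_id[ds$dsg_simes] %in% union_set))
  expect_true(all(ds$gene_id[ds$dsg_gene_level] %in% union_set))
  expect_true("target" %in% union_set)
})

test_that("union sensitivity dominates each single route on planted DSGs", {
  sp <- recovery_splice()
  truth <- recovery_sim()$truth$dsg$gene_id
  r <- sp$results$LLvsCC
  sens <- function(set) mean(intersect(truth, r$gene_id) %in% set)
  s_union <- sens(r$gene_id[r$dsg])
  expect_gte(s_union, sens(r$gene_id[r$dsg_gene_level]))
  expect_gte(s_union, sens(r$gene_id[r$dsg_simes]))
})
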