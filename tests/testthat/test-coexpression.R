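# literal-formula biweight midcorrelation for two vectors (no side cap
# needed when u stays inside +/-1)
bicor_oracle <- function(x, y) {
  wvec <- function(v) {
    u <- (v - median(v)) / (9 * median(abs(v - median(v))))
    (v - median(v)) * (1 - u^2)^2 * (abs(u) < 1)
  }
  xt <- wvec(x); yt <- wvec(y)
  sum(xt * yt) / sqrt(sum(xt^2) * sum(yt^2))
}

test_that("bicor has correlation limits and matches the literal formula", {
  set.seed(13)
  x <- rnorm(12)
  m <- rbind(a = x, b = -x, c = rnorm(12))
  colnames(m) <- paste0("s", 1:12)
  cc <- bicor_matrix(m)
  expect_equal(cc["a", "a"], 1)
  expect_equal(cc["a", "b"], -1)
  expect_true(all(cc >= -1 & cc <= 1))

  # 6-point hand vectors against the independent transliteration
  h1 <- c(2.1, 3.5, 1.9, 4.2, 2.8, 3.1)
  h2 <- c(1.0, 2.2, 1.4, 3.9, 2.0, 2.5)
  hm <- rbind(h1 = h1, h2 = h2)
  colnames(hm) <- paste0("s", 1:6)
  expect_equal(bicor_matrix(hm, max_p_outliers = 0.5)["h1", "h2"],
               bicor_oracle(h1, h2), tolerance = 1e-12)
})

test_that("bicor tracks Pearson on clean data and resists outliers", {
  set.seed(14)
  z <- rnorm(30)
  m <- rbind(a = z + rnorm(30, sd = 0.5), b = z + rnorm(30, sd = 0.5),
             c = rnorm(30), d = rnorm(30))
  colnames(m) <- paste0("s", 1:30)
  bc <- bicor_matrix(m)
  pc <- cor(t(m))
  expect_lt(max(abs(bc - pc)), 0.05)

  # a single gross outlier barely moves bicor but drags Pearson
  a2 <- m["a", ]; b2 <- m["b", ]
  a2[1] <- 50; b2[1] <- -50
  m2 <- rbind(a = a2, b = b2)
  expect_lt(abs(bicor_matrix(m2)["a", "b"] - bc["a", "b"]), 0.15)
  expect_lt(cor(a2, b2), -0.5)
})

test_that("constant profiles yield NA correlations with a warning", {
  m <- rbind(a = rnorm(10), flat = rep(2, 10))
  colnames(m) <- paste0("s", 1:10)
  expect_warning(cc <- bicor_matrix(m), "constant")
  expect_true(is.na(cc["flat", "a"]))
})

test_that("signed adjacency maps correlations into [0,1]", {
  cr <- matrix(c(1, 0, -1, 0, 1, 0.5, -1, 0.5, 1), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  a1 <- adjacency_matrix(cr, beta = 1)
  expect_equal(a1["a", "b"], 0.5)
  expect_equal(a1["a", "c"], 0)
  a14 <- adjacency_matrix(cr, beta = 14)
  expect_equal(a14["b", "c"], 0.75^14)
  expect_equal(diag(a14), c(a = 0, b = 0, c = 0))
  expect_error(adjacency_matrix(cr, beta = 0.5), "beta")
})

test_that("TOM matches the triple-loop oracle and closed forms", {
  # 2 nodes: no third parties, TOM = adjacency
  a2 <- matrix(c(0, 0.7, 0.7, 0), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(tom_similarity(a2)["x", "y"], 0.7)

  # complete graph with unit weights
  a1 <- matrix(1, 4, 4) - diag(4)
  dimnames(a1) <- list(paste0("n", 1:4), paste0("n", 1:4))
  expect_true(all(tom_similarity(a1) == 1))

  tom_oracle <- function(a) {
    n <- nrow(a); out <- diag(n)
    k <- rowSums(a)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      num <- a[i, j]
      for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
      out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
    }
    out
  }
  set.seed(15)
  for (r in 1:5) {
    a <- matrix(runif(36), 6, 6); a <- (a + t(a)) / 2; diag(a) <- 0
    dimnames(a) <- list(paste0("g", 1:6), paste0("g", 1:6))
    expect_equal(unname(tom_similarity(a)), tom_oracle(a),
                 tolerance = 1e-12)
  }
  expect_error(tom_similarity(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("connectivity is the off-diagonal row sum", {
  a <- matrix(c(0, 0.5, 0.25, 0.5, 0, 1, 0.25, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(connectivity(a), c(a = 0.75, b = 1.5, c = 1.25))
  iso <- rbind(cbind(a, d = 0), d = 0)
  dimnames(iso) <- list(letters[1:4], letters[1:4])
  expect_equal(connectivity(iso)[["d"]], 0)
  set.seed(16)
  r <- matrix(runif(64), 8, 8); r <- (r + t(r)) / 2; diag(r) <- 0
  dimnames(r) <- list(paste0("g", 1:8), paste0("g", 1:8))
  expect_equal(connectivity(r), rowSums(r))
})

test_that("soft-threshold choice is self-consistent with its table", {
  sim <- fixture("sft_sim", function()
    simulate_dataset(sim_config(n_genes = 500, n_modules = 5,
                                module_size = 80, n_deg = 0, n_dsg = 0,
                                seed = 61)))
  f <- filter_low_expression(sim$counts)
  lc <- adjust_family(to_units(f, tmm_factors(f), "log2CPM"), sim$samples)
  sft <- pick_soft_threshold(lc, candidates = c(1, 2, 4, 6, 8, 10, 14))
  tab <- sft$table
  hit <- tab$beta[!is.na(tab$signed_r2) & tab$signed_r2 >= sft$r2_cut]
  if (sft$saturated) {
    expect_identical(sft$beta, hit[1])
  } else {
    expect_identical(sft$beta, tab$beta[which.max(tab$signed_r2)])
  }
  expect_error(pick_soft_threshold(lc[1:20, ]), "at least 30")
})

test_that("module detection separates perfect blocks and labels M0", {
  set.seed(18)
  z1 <- rnorm(40); z2 <- rnorm(40)
  expr <- rbind(
    t(sapply(1:25, function(i) 2 * z1 + rnorm(40, sd = 0.05))),
    t(sapply(1:25, function(i) -1.5 * z2 + rnorm(40, sd = 0.05))),
    matrix(rnorm(10 * 40), 10, 40))
  rownames(expr) <- c(paste0("a", 1:25), paste0("b", 1:25),
                      paste0("n", 1:10))
  colnames(expr) <- paste0("s", 1:40)
  cr <- bicor_matrix(expr)
  tom <- tom_similarity(adjacency_matrix(cr, 14))
  mods <- detect_modules(tom, expr, cut_height = 0.9, min_size = 15)
  lab <- mods$labels
  expect_identical(length(unique(lab[paste0("a", 1:25)])), 1L)
  expect_identical(length(unique(lab[paste0("b", 1:25)])), 1L)
  expect_false(unique(lab[paste0("a", 1:25)]) ==
                 unique(lab[paste0("b", 1:25)]))
  expect_true(all(unique(lab) %in% c("M0", "M1", "M2")))
  expect_true(all(lab[paste0("n", 1:10)] == "M0"))

  # labels are invariant to input gene order
  perm <- sample(rownames(expr))
  mods2 <- detect_modules(tom[perm, perm], expr[perm, ], cut_height = 0.9,
                          min_size = 15)
  expect_identical(mods2$labels[names(lab)], lab)
})

test_that("eigengenes and kME behave at their fixed points", {
  set.seed(19)
  z <- rnorm(16)
  expr <- t(sapply(1:20, function(i) 3 * z + rnorm(16, sd = 0.01)))
  rownames(expr) <- paste0("g", 1:20); colnames(expr) <- paste0("s", 1:16)
  eg <- edanet:::module_eigengene(expr)
  expect_equal(sum(eg^2), 1, tolerance = 1e-10)
  expect_gt(cor(eg, z), 0.999)  # sign-oriented to the members

  km <- kme(expr, cbind(M1 = eg), method = "pearson")
  expect_true(all(km[, "M1"] > 0.999))
  km_self <- kme(rbind(e = eg), cbind(M1 = eg), method = "pearson")
  expect_equal(km_self["e", "M1"], 1)

  profs <- matrix(rnorm(5 * 16), 5, 16,
                  dimnames = list(paste0("p", 1:5), colnames(expr)))
  expect_equal(unname(kme(profs, cbind(M1 = eg), method = "pearson")),
               unname(cor(t(profs), eg)), tolerance = 1e-12)
})

test_that("atomization assigns exons to the module they co-vary with", {
  net <- recovery_network()
  sim <- recovery_sim()
  s <- sim$samples
  eg <- net$eigengenes
  skip_if(ncol(eg) < 2, "need two modules")

  # synthetic gene: exon 1 follows module 1, exons 2-3 follow module 2
  lib <- setNames(rep(1e6, nrow(s)), s$sample_id)
  sc <- function(v) exp(log(2) * 4 * (v - min(v)) / diff(range(v)))
  e1 <- round(2000 * sc(eg[s$sample_id, 1]))
  e2 <- round(2000 * sc(eg[s$sample_id, 2]))
  counts <- rbind(x_e1 = e1, x_e2 = e2, x_e3 = round(e2 * 1.3))
  colnames(counts) <- s$sample_id
  ec <- exon_counts(counts, rep("x", 3), 1:3)
  res <- atomize_gene("x", ec, net, s, lib_sizes = lib)
  expect_identical(res$module[res$exon_order == 1], colnames(eg)[1])
  expect_identical(res$module[res$exon_order == 2], colnames(eg)[2])
  expect_identical(res$module[res$exon_order == 3], colnames(eg)[2])

  # pure noise exon lands in M0
  set.seed(20)
  nz <- matrix(rpois(2 * nrow(s), 200), 2, nrow(s),
               dimnames = list(c("y_e1", "y_e2"), s$sample_id))
  ecn <- exon_counts(nz, c("y", "y"), 1:2)
  resn <- atomize_gene("y", ecn, net, s, lib_sizes = lib, min_kme = 0.5)
  expect_true(all(resn$module == "M0"))
  expect_error(atomize_gene("absent", ecn, net, s), "not in exon matrix")
})

test_that("subnetwork extraction selects by adjacency and by kTotal", {
  net <- recovery_network()
  g <- net$module_table$gene_id[which.max(net$module_table$k_total)]
  sub <- extract_subnetwork(net, g, n = 10)
  expect_identical(nrow(sub$nodes), 11L)
  expect_identical(sub$nodes$gene_id[1], g)
  # sort-based oracle
  a <- net$adjacency[g, ]; a <- a[names(a) != g]
  expect_setequal(sub$nodes$gene_id[-1],
                  names(sort(a, decreasing = TRUE))[1:10])
  # edges are the pairwise adjacencies among selected nodes
  expect_equal(sub$edges$weight[1],
               net$adjacency[sub$edges$from[1], sub$edges$to[1]])

  mod <- names(sort(table(net$labels[net$labels != "M0"]),
                    decreasing = TRUE))[1]
  hubs <- extract_subnetwork(net, mod, n = 10)
  members <- names(net$labels)[net$labels == mod]
  expect_setequal(hubs$nodes$gene_id,
                  names(sort(net$k_total[members],
                             decreasing = TRUE))[1:10])
  tiny_mod <- names(which(table(net$labels) < 10))
  if (length(tiny_mod) > 0) {
    expect_warning(extract_subnetwork(net, tiny_mod[1], n = 10),
                   "returning all")
  }
  expect_error(extract_subnetwork(net, "nope"), "neither")
})
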