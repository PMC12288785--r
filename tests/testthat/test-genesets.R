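test_that("median-difference permutation p has the right fixed points", {
  v <- setNames(c(1, 2, 3, 4, 10, 20, 30, 40), paste0("g", 1:8))
  same <- perm_median_diff(v, c("g1", "g2"), c("g1", "g2"), B = 200,
                           seed = 1)
  expect_equal(same$observed, 0)
  expect_equal(same$p, 1)

  vs_all <- perm_median_diff(v, c("g5", "g6"), NULL, B = 100, seed = 1)
  expect_equal(vs_all$observed, median(c(10, 20)) - median(v))

  r1 <- perm_median_diff(v, c("g1", "g8"), c("g2", "g3"), B = 500, seed = 7)
  r2 <- perm_median_diff(v, c("g1", "g8"), c("g2", "g3"), B = 500, seed = 7)
  expect_identical(r1$exceed, r2$exceed)  # seed-reproducible
  expect_error(perm_median_diff(v, paste0("g", 1:8), paste0("g", 1:8),
                                B = 10, seed = 1), "larger than")
  expect_error(perm_median_diff(v, "zz", NULL, B = 10, seed = 1),
               "outside")
})

test_that("median-difference Monte Carlo matches full enumeration", {
  # universe of 8 values, |A| = |B| = 2: enumerate all disjoint pairs
  v <- setNames(c(0.4, 1.1, 2.3, 3.0, 4.8, 5.1, 6.9, 8.2), paste0("g", 1:8))
  setA <- c("g7", "g8"); setB <- c("g1", "g2")
  obs <- abs(median(v[setA]) - median(v[setB]))
  combA <- utils::combn(8, 2)
  hits <- 0; total <- 0
  for (i in seq_len(ncol(combA))) {
    rest <- setdiff(1:8, combA[, i])
    combB <- utils::combn(rest, 2)
    for (j in seq_len(ncol(combB))) {
      total <- total + 1
      d <- abs(median(v[combA[, i]]) - median(v[combB[, j]]))
      if (d >= obs - 1e-12) hits <- hits + 1
    }
  }
  p_exact <- hits / total
  res <- perm_median_diff(v, setA, setB, B = 10000, seed = 3)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(res$p - p_exact), 3 * se + 1e-12)
})

test_that("overlap permutation tracks the exact hypergeometric tail", {
  full <- perm_overlap(N = 12, n1 = 12, n2 = 5, observed_overlap = 5,
                       B = 200, seed = 2)
  expect_equal(full$p, 1)  # n1 = N: overlap always n2

  res <- perm_overlap(N = 10, n1 = 3, n2 = 4, observed_overlap = 2,
                      B = 10000, seed = 11)
  p_exact <- phyper(1, 3, 7, 4, lower.tail = FALSE)
  expect_equal(res$p_exact, p_exact)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(res$p - p_exact), 3 * se)

  # impossible observed overlap: p floored and displayed as < 1/B
  zero <- perm_overlap(N = 1000, n1 = 5, n2 = 5, observed_overlap = 5,
                       B = 1000, seed = 4)
  expect_true(zero$p_floor)
  expect_identical(zero$p_display, "< 0.001")
  add1 <- perm_overlap(N = 1000, n1 = 5, n2 = 5, observed_overlap = 5,
                       B = 1000, seed = 4, add_one = TRUE)
  expect_equal(add1$p, 1 / 1001)
  expect_error(perm_overlap(10, 3, 4, 5), "exceeds the smaller")
})

test_that("over-representation p-values equal the hypergeometric sum", {
  bg <- paste0("g", 1:20)
  sets <- list(T1 = structure(paste0("g", 1:5), term_name = "hit"),
               T2 = structure(paste0("g", 16:20), term_name = "miss"),
               T3 = structure(paste0("g", 1:2), term_name = "small"))
  query <- paste0("g", c(1, 2, 3, 6, 7))
  res <- ora(sets, query, bg, min_term = 3)
  # N = 20, K = 5, n = 5, k = 3: direct sum over the tail
  direct <- sum(vapply(3:5, function(k)
    choose(5, k) * choose(15, 5 - k) / choose(20, 5), numeric(1)))
  expect_equal(res$p_value[res$term_id == "T1"], direct, tolerance = 1e-12)
  # disjoint term: P(X >= 0) = 1
  expect_equal(res$p_value[res$term_id == "T2"], 1)
  # undersized term skipped
  expect_false("T3" %in% res$term_id)
  expect_error(ora(sets, c(query, "notinbg"), bg), "subset")
  expect_error(ora(sets, query, character(0)), "empty")
})

test_that("module cross-tabulation conserves its category counts", {
  labels <- setNames(c("M1", "M1", "M2", "M0", "M0", "M2", "M1", "M0"),
                     paste0("g", 1:8))
  deg <- c("g1", "g2", "g3", "g4")
  dsg <- c("g3", "g5", "g6")
  tab <- crosstab_modules(deg, dsg, labels)
  mat <- as.matrix(tab[, -1])
  expect_equal(sum(mat[tab$category == "DEG_only", ]), 3)
  expect_equal(sum(mat[tab$category == "DSG_only", ]), 2)
  expect_equal(sum(mat[tab$category == "both", ]), 1)
  expect_equal(mat[tab$category == "both", "M2"][[1]], 1)
  # brute-force tally oracle on random labels
  set.seed(23)
  lab2 <- setNames(sample(c("M0", "M1", "M2", "M3"), 50, TRUE),
                   paste0("g", 1:50))
  d2 <- sample(names(lab2), 12); s2 <- sample(names(lab2), 9)
  t2 <- crosstab_modules(d2, s2, lab2)
  for (m in setdiff(names(t2), "category")) {
    expect_equal(t2[[m]][t2$category == "DEG_only"],
                 sum(lab2[setdiff(d2, s2)] == m))
    expect_equal(t2[[m]][t2$category == "DSG_only"],
                 sum(lab2[setdiff(s2, d2)] == m))
    expect_equal(t2[[m]][t2$category == "total_genes"],
                 sum(lab2 == m))
  }
  # disjoint sets: the both row is all zero
  t3 <- crosstab_modules(c("g1", "g2"), c("g3", "g4"), labels)
  expect_true(all(as.matrix(t3[t3$category == "both", -1]) == 0))
})

test_that("Monte-Carlo p converges to the exact tail as B grows", {
  p_exact <- phyper(1, 3, 7, 4, lower.tail = FALSE)
  err <- vapply(c(100, 1000, 10000), function(B) {
    abs(perm_overlap(10, 3, 4, 2, B = B, seed = 31)$p - p_exact)
  }, numeric(1))
  expect_lt(err[3], err[1] + 0.05)
  expect_lt(err[3], 3 * sqrt(p_exact * (1 - p_exact) / 10000))
})
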