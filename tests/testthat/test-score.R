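test_that("guide depletion is the difference of log2 frequencies", {
  # f_A = -4, f_B = -6 -> +2
  m <- matrix(c(3, 60, 0, 0, 63, 0), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), c("A", "B")))
  m["gC", ] <- c(1, 1)
  d <- guide_depletion(m, "A", "B", min_freq = 0)
  expect_equal(d$score[1], log2(4 / sum(m[, "A"])) - log2(1 / sum(m[, "B"])))
  same <- matrix(c(5, 5, 5, 5), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("A", "B")))
  expect_equal(guide_depletion(same, "A", "B")$score, c(0, 0))
})

test_that("the read-frequency filter removes guides scarce in both samples", {
  n <- 11
  m <- matrix(10000L, n, 2, dimnames = list(sprintf("g%02d", 1:n),
                                            c("A", "B")))
  m[1, ] <- c(0L, 0L)   # frequency ~1e-6-ish in both
  d <- guide_depletion(m, "A", "B", min_freq = 1e-5)
  expect_false(d$passed_filter[1])
  expect_true(is.na(d$score[1]))
  expect_true(all(d$passed_filter[-1]))
  # passing in only one of the two samples suffices
  m[1, ] <- c(2L, 0L)
  d <- guide_depletion(m, "A", "B", min_freq = 1e-5)
  expect_true(d$passed_filter[1])
})

test_that("gene_score applies the top/bottom-three rule", {
  expect_equal(gene_score(c(6, 2, 1, -3, -4, -5)), -4)
  expect_equal(gene_score(c(3, 0, -2, -4)), -2)  # g1-3 vs g2-4 at n = 4
  expect_equal(gene_score(1.5), 1.5)
  expect_equal(gene_score(c(1, 2)), 1.5)
  expect_equal(gene_score(c(-1, 0, 1, 2, 5, 6)), 13 / 3)  # enrichment wins
  expect_equal(gene_score(c(-3, -1, 0, 1, 3)), c(-4 / 3))
  expect_error(gene_score(numeric(0)), "at least one")
})

test_that("gene_score ties return the depletion side", {
  expect_equal(gene_score(c(2, 2, 2, -2, -2, -2)), -2)
})

test_that("gene_score equals the independent brute-force rule", {
  withr::with_seed(31, {
    for (i in 1:1000) {
      n <- sample(1:12, 1)
      s <- round(rnorm(n, 0, 2), 3)
      expect_identical(gene_score(s), oracle_gene_score(s))
    }
  })
})

test_that("decreasing any single guide score never raises the gene score", {
  withr::with_seed(37, {
    for (i in 1:300) {
      n <- sample(1:12, 1)
      s <- rnorm(n, 0, 2)
      j <- sample(n, 1)
      s2 <- s
      s2[j] <- s2[j] - runif(1, 0, 3)
      expect_lte(gene_score(s2), gene_score(s))
    }
  })
})

test_that("vectorised column scorer agrees with gene_score", {
  withr::with_seed(41, {
    for (k in c(1, 2, 3, 4, 6, 9, 12)) {
      M <- matrix(rnorm(k * 50), nrow = k)
      expect_equal(crispriscreen:::col_gene_scores(M),
                   apply(M, 2, gene_score))
    }
  })
})

test_that("guides shared by two genes score in both genes", {
  gs <- matrix(c(-2, -1, 0), ncol = 1,
               dimnames = list(c("g1", "g2", "g3"), "rep1"))
  membership <- data.frame(guide_id = c("g1", "g2", "g2", "g3"),
                           gene_id = c("A", "A", "B", "B"))
  tab <- gene_score_table(gs, membership)
  expect_equal(tab$n["A", 1], 2L)
  expect_equal(tab$n["B", 1], 2L)
  expect_equal(tab$score["A", 1], mean(c(-2, -1)))
  expect_equal(tab$score["B", 1], mean(c(-1, 0)))
})

test_that("null ensemble preserves each gene's filtered guide count", {
  pool <- c(0, 3)
  counts <- c(geneA = 7L, geneB = 2L)
  null <- build_null_ensemble(pool, counts, n_iter = 50, seed = 3)
  expect_equal(unname(null$gene_counts[, 1]), c(7L, 2L))
  # k = 7 synthetic scores are means of three of {0,3}: multiples of 1
  a <- null$scores[[1]]["geneA", ]
  expect_true(all(a %in% c(0, 1, 2, 3)))
  # k = 2 scores are means of two draws: multiples of 1.5
  b <- null$scores[[1]]["geneB", ]
  expect_true(all(b %in% c(0, 1.5, 3)))
})

test_that("synthetic gene scores match exhaustive enumeration for small pools", {
  pool <- c(-2, -1, 0, 1, 2)
  null <- build_null_ensemble(pool, c(g = 2L), n_iter = 4000, seed = 5)
  emp <- table(null$scores[[1]][1, ]) / 4000
  # enumerate all 25 ordered pairs drawn with replacement
  grid <- expand.grid(a = pool, b = pool)
  want <- table((grid$a + grid$b) / 2) / 25
  expect_setequal(names(emp), names(want))
  expect_lt(max(abs(emp[names(want)] - want)), 0.03)
})

test_that("a degenerate scrambled pool yields a zero-sd null and fails z", {
  null <- build_null_ensemble(rep(1.5, 10), c(g1 = 3L, g2 = 5L),
                              n_iter = 20, seed = 7)
  expect_true(all(null$scores[[1]] == 1.5))
  expect_equal(unname(null$sd), 0)
  gs <- matrix(0, 2, 1, dimnames = list(c("g1", "g2"), "contrast1"))
  expect_error(gene_z_scores(gs, null), "zero standard deviation")
})

test_that("synthetic genes keep their drawn guides across contrasts", {
  # duplicate score columns expose the pairing: if a synthetic gene is
  # populated once per iteration, its two contrast scores must coincide
  withr::with_seed(12, v <- rnorm(100))
  null <- build_null_ensemble(
    cbind(rep1 = v, rep2 = v),
    matrix(6L, 5, 2, dimnames = list(paste0("g", 1:5), c("rep1", "rep2"))),
    n_iter = 30, seed = 3)
  expect_identical(null$scores$rep1, null$scores$rep2)
})

test_that("too few scrambled scores point to the permutation fallback", {
  expect_error(build_null_ensemble(c(1), c(g = 2L), n_iter = 5),
               "scrambled")
})

test_that("Stouffer combination follows the stated formula", {
  expect_equal(stouffer_z(c(1, 1, 1)), sqrt(3))
  expect_equal(stouffer_z(c(2, -2)), 0)
  expect_equal(stouffer_z(c(1.3)), 1.3)
  expect_equal(stouffer_z(c(1, NA, 1)), sqrt(2))
})

test_that("gene z-scores standardise against the null moments", {
  withr::with_seed(11, pool <- cbind(rep1 = rnorm(500), rep2 = rnorm(500)))
  null <- build_null_ensemble(pool,
                              matrix(5L, 10, 2,
                                     dimnames = list(paste0("g", 1:10),
                                                     c("rep1", "rep2"))),
                              n_iter = 100, seed = 13)
  gs <- matrix(null$mean["rep1"], 10, 2,
               dimnames = list(paste0("g", 1:10), c("rep1", "rep2")))
  gs[, 2] <- null$mean["rep2"]
  zz <- gene_z_scores(gs, null)
  expect_equal(unname(zz$z), matrix(0, 10, 2))
  expect_equal(unname(zz$combined_z), rep(0, 10))
  # combined z of the synthetic pool itself is standard-normal-like
  nz <- null_combined_z(null)
  expect_lt(abs(mean(nz)), 0.05)
  expect_lt(abs(sd(nz) - 1), 0.1)
})
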