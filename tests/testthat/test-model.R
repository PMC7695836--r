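# A small separable feature set: one informative binary feature plus noise.
make_toy_model_data <- function(n = 120, p_noise = 12, seed = 71,
                                flip = 0) {
  withr::with_seed(seed, {
    signal <- rep(c(0, 1), length.out = n)
    X <- cbind(signal = signal,
               matrix(runif(n * p_noise), n,
                      dimnames = list(NULL, paste0("noise", 1:p_noise))))
    y <- as.integer(signal == 1)
    if (flip > 0) {
      idx <- sample(n, round(flip * n))
      y[idx] <- 1L - y[idx]
    }
    rownames(X) <- sprintf("g%03d", 1:n)
    attr(X, "feature_groups") <- list(
      signal = "signal", noise = paste0("noise", 1:p_noise))
    list(X = X, y = y)
  })
}

test_that("extreme labelling keeps the stated tail fractions", {
  s <- stats::setNames(as.numeric(1:10), paste0("g", 1:10))
  lab <- label_extreme_guides(s)
  expect_equal(which(lab == 1L), c(g1 = 1L, g2 = 2L))
  expect_equal(which(lab == 0L), c(g9 = 9L, g10 = 10L))
  expect_equal(sum(is.na(lab)), 6)
})

test_that("labelling uses the floor convention at 20 percent", {
  s <- stats::setNames(rnorm(3507), sprintf("g%04d", 1:3507))
  lab <- label_extreme_guides(s)
  expect_equal(sum(lab == 1L, na.rm = TRUE), 701)  # floor(3507 * 0.2)
  expect_equal(sum(lab == 0L, na.rm = TRUE), 701)
})

test_that("degenerate scores cannot be labelled", {
  expect_error(label_extreme_guides(rep(1, 20)), "overlap")
  expect_error(label_extreme_guides(rnorm(5)), "at least 10")
})

test_that("a separable feature gives near-perfect cross-validated AUC", {
  d <- make_toy_model_data()
  fit <- train_efficacy_classifier(d$X, d$y, folds = 3, partitions = 2,
                                   n_select = 5, ntree = 100, seed = 3)
  expect_gt(fit$mean_auc, 0.99)
  expect_gt(fit$mean_auprc, 0.99)
})

test_that("permuted labels give chance-level AUC", {
  d <- make_toy_model_data(n = 150, seed = 73)
  withr::with_seed(74, y <- sample(d$y))
  fit <- train_efficacy_classifier(d$X, y, folds = 3, partitions = 3,
                                   n_select = 5, ntree = 100, seed = 5)
  expect_lt(abs(fit$mean_auc - 0.5), 0.12)
})

test_that("the report carries folds x partitions AUC values", {
  d <- make_toy_model_data(n = 60, seed = 75)
  fit <- train_efficacy_classifier(d$X, d$y, folds = 3, partitions = 10,
                                   n_select = 4, ntree = 50, seed = 7)
  expect_length(fit$fold_auc, 30)
  expect_length(fit$fold_auprc, 30)
  expect_length(fit$folds, 30)
})

test_that("feature selection and fitting never see held-out rows", {
  d <- make_toy_model_data(n = 90, seed = 76)
  fit <- train_efficacy_classifier(d$X, d$y, folds = 3, partitions = 2,
                                   n_select = 4, ntree = 50, seed = 9)
  for (p in 1:2) {
    tests <- lapply(fit$folds[sapply(fit$folds, `[[`, "partition") == p],
                    `[[`, "test")
    expect_equal(sort(unlist(tests)), 1:90)  # a partition of the rows
    expect_equal(sum(duplicated(unlist(tests))), 0)
  }
})

test_that("oversized n_select falls back to all features with a warning", {
  d <- make_toy_model_data(n = 60, seed = 77)
  expect_warning(
    fit <- train_efficacy_classifier(d$X, d$y, folds = 2, partitions = 1,
                                     n_select = 999, ntree = 30, seed = 1),
    "exceeds")
  expect_equal(fit$n_select, ncol(d$X))
})

test_that("percentage contributions follow the permutation formula", {
  expect_equal(percent_contribution(0.85, 0.80, 0.50), 100 * 0.05 / 0.35)
  expect_equal(round(percent_contribution(0.85, 0.80, 0.50), 2), 14.29)
  expect_equal(percent_contribution(0.9, 0.4, 0.4), 100)
  expect_error(percent_contribution(0.5, 0.5, 0.5), "uninformative")
})

test_that("contributions isolate the informative feature group", {
  d <- make_toy_model_data(n = 150, seed = 78)
  fit <- train_efficacy_classifier(d$X, d$y, folds = 3, partitions = 2,
                                   n_select = 6, ntree = 100, seed = 11)
  fc <- feature_contributions(fit, n_perm = 10, seed = 13)
  con <- fc$contributions
  expect_gt(con$contribution[con$group == "signal"], 80)
  noise <- con[con$group == "noise", ]
  expect_lt(abs(noise$contribution), max(3 * noise$sd, 10))
  expect_gt(fc$base_accuracy, fc$min_accuracy)
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # population of 10 guides, 4 with A at the position; the top 5 contain 4
  # of them: P(X >= 4) = choose(4,4) * choose(6,1) / choose(10,5) = 6/252
  ctx <- matrix("C", 10, 2)
  ctx[1:4, 1] <- "A"
  prob <- stats::setNames(seq(1, 0.1, length.out = 10), paste0("g", 1:10))
  # top half by probability = guides 1..5
  enr <- positional_nucleotide_enrichment(prob, ctx, top_q = 0.5)
  expect_equal(enr["pos01", "A"], -log10(6 / 252))
  expect_equal(10^(-enr["pos01", "A"]), 6 / 252, tolerance = 1e-12)
})

test_that("taking every guide as top gives p = 1 everywhere", {
  withr::with_seed(79, ctx <- matrix(sample(c("A", "C", "G", "T"), 60,
                                            replace = TRUE), 15, 4))
  prob <- stats::setNames(runif(15), paste0("g", 1:15))
  enr <- positional_nucleotide_enrichment(prob, ctx, top_q = 1)
  expect_true(all(enr == 0))
})

test_that("bases depleted from the top set get a negative sign", {
  ctx <- matrix("A", 12, 1)
  ctx[1:6, 1] <- "G"   # top half (high prob) all G, bottom all A
  prob <- stats::setNames(seq(1, 0.1, length.out = 12), paste0("g", 1:12))
  enr <- positional_nucleotide_enrichment(prob, ctx, top_q = 0.5)
  expect_gt(enr["pos01", "G"], 0)
  expect_lt(enr["pos01", "A"], 0)
})

test_that("enrichment p-values equal exact enumeration on small sets", {
  # brute-force check over all possible top-set compositions
  withr::with_seed(81, {
    ctx <- matrix(sample(c("A", "C"), 18, replace = TRUE), 18, 1)
    prob <- stats::setNames(runif(18), paste0("g", 1:18))
  })
  m <- floor(18 * 0.25)
  top <- order(-prob)[1:m]
  K <- sum(ctx[, 1] == "A")
  k <- sum(ctx[top, 1] == "A")
  enr <- positional_nucleotide_enrichment(prob, ctx, top_q = 0.25)
  over <- k * 18 >= K * m
  p_exact <- sum(vapply(0:m, function(x) {
    in_tail <- if (over) x >= k else x <= k
    if (!in_tail) return(0)
    choose(K, x) * choose(18 - K, m - x) / choose(18, m)
  }, numeric(1)))
  expect_equal(abs(enr["pos01", "A"]), -log10(p_exact), tolerance = 1e-10)
})
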