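#' Label the most and least efficient guides by depletion score
#'
#' The lowest \code{low_q} fraction of scores (strongest depletion) is
#' labelled efficient (1), the highest \code{high_q} fraction inefficient
#' (0), and the middle excluded (\code{NA}). Class sizes use the floor
#' convention; ties are broken by a stable sort on guide id.
#'
#' @param scores Named numeric vector of guide depletion scores.
#' @param low_q,high_q Tail fractions (default 0.20 each).
#' @return Integer vector (1 = efficient, 0 = inefficient, NA = excluded)
#'   aligned with \code{scores}.
#' @export
label_extreme_guides <- function(scores, low_q = 0.20, high_q = 0.20) {
  n <- length(scores)
  if (n < 10L) stop("need at least 10 scores to label extremes")
  stopifnot(low_q > 0, high_q > 0, low_q + high_q <= 1)
  ids <- names(scores) %||% as.character(seq_len(n))
  k_low <- floor(n * low_q)
  k_high <- floor(n * high_q)
  if (k_low < 1L || k_high < 1L) stop("quantile classes are empty")
  o <- order(scores, ids)
  low_cut <- scores[o[k_low]]
  high_cut <- scores[o[n - k_high + 1L]]
  if (low_cut >= high_cut)
    stop("quantile boundaries overlap: too few distinct score values")
  labels <- rep(NA_integer_, n)
  labels[o[seq_len(k_low)]] <- 1L
  labels[o[seq.int(n - k_high + 1L, n)]] <- 0L
  names(labels) <- names(scores)
  labels
}

# scikit-style chi2 univariate score for nonnegative features vs a binary
# class: observed per-class feature totals against totals expected from
# class frequencies.
chi2_scores <- function(X, y) {
  Y <- cbind(y == 0L, y == 1L)
  observed <- crossprod(Y, X)                     # 2 x p
  feature_tot <- colSums(X)
  expected <- outer(colMeans(Y), feature_tot)     # class freq x totals
  chi <- (observed - expected)^2 / expected
  chi[!is.finite(chi)] <- 0
  colSums(chi)
}

# min-max scale columns to [0,1] using training-split statistics (chi2
# requires nonnegative inputs; ranking is preserved)
minmax_fit <- function(X) {
  list(min = apply(X, 2L, min), range = apply(X, 2L, max) - apply(X, 2L, min))
}
minmax_apply <- function(X, sc) {
  rng <- ifelse(sc$range == 0, 1, sc$range)
  Z <- sweep(sweep(X, 2L, sc$min, "-"), 2L, rng, "/")
  pmin(pmax(Z, 0), 1)
}

auc_from_scores <- function(score, y) {
  r <- rank(score)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

auprc_from_scores <- function(score, y) {
  o <- order(score, decreasing = TRUE)
  yy <- y[o]
  tp <- cumsum(yy)
  prec <- tp / seq_along(yy)
  rec <- tp / sum(yy)
  sum(diff(c(0, rec)) * prec)
}

#' Train the cross-validated random-forest guide-efficacy classifier
#'
#' Under k-fold cross-validation repeated over several partitions, each
#' training split is min-max scaled, reduced to \code{n_select} features by
#' the chi-square univariate score computed on the training split only, and
#' used to fit a random forest; AUC and AUPRC are evaluated on the held-out
#' fold. Class prediction probabilities for every modelled guide are
#' averaged over its held-out predictions across partitions.
#'
#' @param features Feature matrix from \code{\link{extract_features}}.
#' @param labels Integer labels from \code{\link{label_extreme_guides}}
#'   (rows with \code{NA} are dropped).
#' @param folds Cross-validation folds (default 3).
#' @param partitions Number of independent fold partitions (default 10).
#' @param n_select Features retained by chi-square selection (default 130).
#' @param ntree Random-forest size (default 500).
#' @param seed Integer seed.
#' @param scores Optional observed guide scores; when given, the rank
#'   (Spearman) correlation between class probability and observed score is
#'   reported.
#' @return Object of class \code{efficacy_classifier}: per-fold AUC/AUPRC,
#'   their means and standard deviations, averaged class probabilities,
#'   optional Spearman correlation, and the fitted fold models needed for
#'   \code{\link{feature_contributions}}.
#' @export
train_efficacy_classifier <- function(features, labels, folds = 3,
                                      partitions = 10, n_select = 130,
                                      ntree = 500, seed = 1, scores = NULL) {
  keep <- !is.na(labels)
  X <- as.matrix(features)[keep, , drop = FALSE]
  y <- labels[keep]
  if (length(unique(y)) < 2L) stop("both classes must be nonempty")
  groups <- attr(features, "feature_groups")
  if (n_select > ncol(X)) {
    warning("n_select exceeds available features; using all ", ncol(X))
    n_select <- ncol(X)
  }
  n <- nrow(X)
  withr::with_seed(seed, {
    fold_models <- list()
    auc <- auprc <- numeric(0)
    prob_sum <- rep(0, n)
    for (p in seq_len(partitions)) {
      assignment <- sample(rep(seq_len(folds), length.out = n))
      for (f in seq_len(folds)) {
        test <- which(assignment == f)
        train <- which(assignment != f)
        sc <- minmax_fit(X[train, , drop = FALSE])
        Ztr <- minmax_apply(X[train, , drop = FALSE], sc)
        chi <- chi2_scores(Ztr, y[train])
        sel <- colnames(X)[order(-chi, colnames(X))[seq_len(n_select)]]
        rf <- randomForest::randomForest(
          x = Ztr[, sel, drop = FALSE],
          y = factor(y[train], levels = c(0L, 1L)), ntree = ntree)
        Zte <- minmax_apply(X[test, , drop = FALSE], sc)
        pr <- stats::predict(rf, Zte[, sel, drop = FALSE],
                             type = "prob")[, "1"]
        auc <- c(auc, auc_from_scores(pr, y[test]))
        auprc <- c(auprc, auprc_from_scores(pr, y[test]))
        prob_sum[test] <- prob_sum[test] + pr
        fold_models[[length(fold_models) + 1L]] <-
          list(model = rf, selected = sel, scaler = sc, test = test,
               partition = p, fold = f)
      }
    }
    prob <- prob_sum / partitions
    names(prob) <- rownames(X)
    spearman <- if (!is.null(scores))
      stats::cor(prob, scores[keep], method = "spearman") else NA_real_
    structure(list(fold_auc = auc, fold_auprc = auprc,
                   mean_auc = mean(auc), sd_auc = stats::sd(auc),
                   mean_auprc = mean(auprc), sd_auprc = stats::sd(auprc),
                   prob = prob, spearman = spearman,
                   folds = fold_models, X = X, y = y,
                   feature_groups = groups, n_select = n_select),
              class = "efficacy_classifier")
  })
}

#' @export
print.efficacy_classifier <- function(x, ...) {
  cat("Guide-efficacy random forest (", length(x$folds), " fold fits)\n",
      sep = "")
  cat(sprintf("  AUC   %.3f +/- %.3f\n", x$mean_auc, x$sd_auc))
  cat(sprintf("  AUPRC %.3f +/- %.3f\n", x$mean_auprc, x$sd_auprc))
  if (!is.na(x$spearman))
    cat(sprintf("  Spearman(prob, observed score) %.3f\n", x$spearman))
  invisible(x)
}

#' Percentage contribution of a feature from permutation accuracies
#'
#' \code{100 * (C_base - C_f) / (C_base - C_min)}: the accuracy lost when a
#' feature is permuted, as a percentage of the accuracy lost when all
#' features are permuted.
#'
#' @param c_base Mean test accuracy of the unpermuted model.
#' @param c_f Mean test accuracy with the feature (group) permuted.
#' @param c_min Mean test accuracy with all features permuted.
#' @return Percentage contribution.
#' @export
percent_contribution <- function(c_base, c_f, c_min) {
  if (isTRUE(all.equal(c_base, c_min)))
    stop("uninformative model: baseline accuracy equals fully permuted ",
         "accuracy")
  100 * (c_base - c_f) / (c_base - c_min)
}

#' Permutation feature-group contributions of the trained classifier
#'
#' For every fold model, held-out accuracy is measured with each feature
#' group's columns permuted jointly across guides (preserving within-group
#' structure), repeated \code{n_perm} times and averaged; the fully
#' permuted accuracy (every group permuted with its own draw) anchors the
#' denominator. Contributions are reported per group as
#' \code{\link{percent_contribution}}, averaged over fold models, with
#' standard deviations.
#'
#' @param fit An \code{\link{train_efficacy_classifier}} result.
#' @param n_perm Permutations per group per fold (default 30).
#' @param seed Integer seed.
#' @return List with \code{contributions} (data frame: group, contribution,
#'   sd) and \code{per_fold} (fold x group matrix).
#' @export
feature_contributions <- function(fit, n_perm = 30, seed = 1) {
  stopifnot(inherits(fit, "efficacy_classifier"))
  groups <- fit$feature_groups
  gnames <- names(groups)
  withr::with_seed(seed, {
    per_fold <- matrix(NA_real_, length(fit$folds), length(gnames),
                       dimnames = list(NULL, gnames))
    base_acc <- numeric(length(fit$folds))
    min_acc <- numeric(length(fit$folds))
    for (i in seq_along(fit$folds)) {
      fm <- fit$folds[[i]]
      Zte <- minmax_apply(fit$X[fm$test, , drop = FALSE], fm$scaler)
      yte <- fit$y[fm$test]
      acc <- function(Z) {
        pr <- stats::predict(fm$model, Z[, fm$selected, drop = FALSE],
                             type = "prob")[, "1"]
        mean((pr > 0.5) == (yte == 1L))
      }
      base_acc[i] <- acc(Zte)
      perm_group <- function(Z, cols) {
        cols <- intersect(cols, colnames(Z))
        Z[, cols] <- Z[sample(nrow(Z)), cols, drop = FALSE]
        Z
      }
      c_f <- vapply(gnames, function(g) {
        mean(vapply(seq_len(n_perm),
                    function(r) acc(perm_group(Zte, groups[[g]])),
                    numeric(1)))
      }, numeric(1))
      min_acc[i] <- mean(vapply(seq_len(n_perm), function(r) {
        Z <- Zte
        for (g in gnames) Z <- perm_group(Z, groups[[g]])
        acc(Z)
      }, numeric(1)))
      per_fold[i, ] <- vapply(gnames, function(g) {
        percent_contribution(base_acc[i], c_f[[g]], min_acc[i])
      }, numeric(1))
    }
    contributions <- data.frame(
      group = gnames,
      contribution = colMeans(per_fold),
      sd = apply(per_fold, 2L, stats::sd),
      row.names = NULL, stringsAsFactors = FALSE)
    list(contributions = contributions, per_fold = per_fold,
         base_accuracy = mean(base_acc), min_accuracy = mean(min_acc))
  })
}

#' Per-position nucleotide enrichment among predicted-efficient guides
#'
#' For each context position and base, a hypergeometric tail test compares
#' the count of that base among the top \code{top_q} fraction of guides by
#' predicted efficiency against all modelled guides. The result is the
#' signed \code{-log10 p}: positive for over-representation, negative for
#' under-representation. Positions where a guide's context is padded (N)
#' exclude that guide from the position's population.
#'
#' @param prob Named numeric vector of predicted class probabilities (as
#'   from \code{\link{train_efficacy_classifier}}).
#' @param context Character matrix of guide contexts (n x positions;
#'   the \code{context} attribute of \code{\link{extract_features}}).
#' @param top_q Fraction of guides taken as predicted-efficient (default
#'   0.20).
#' @return Numeric matrix (positions x bases A, C, G, T) of signed
#'   \code{-log10 p} values.
#' @export
positional_nucleotide_enrichment <- function(prob, context, top_q = 0.20) {
  context <- as.matrix(context)
  n <- length(prob)
  stopifnot(nrow(context) == n)
  m <- floor(n * top_q)
  stopifnot(m >= 1L)
  top <- order(-prob, seq_len(n))[seq_len(m)]
  bases <- c("A", "C", "G", "T")
  out <- matrix(NA_real_, ncol(context), 4L,
                dimnames = list(sprintf("pos%02d", seq_len(ncol(context))),
                                bases))
  for (j in seq_len(ncol(context))) {
    known <- context[, j] %in% bases
    if (!any(known)) {
      warning("position ", j, " has no informative context; excluded")
      next
    }
    nn <- sum(known)
    top_known <- intersect(top, which(known))
    mm <- length(top_known)
    for (b in bases) {
      K <- sum(context[known, j] == b)
      k <- sum(context[top_known, j] == b)
      if (k * nn >= K * mm) {  # over-represented (or exactly proportional)
        p <- stats::phyper(k - 1L, K, nn - K, mm, lower.tail = FALSE)
        out[j, b] <- -log10(p)
      } else {
        p <- stats::phyper(k, K, nn - K, mm)
        out[j, b] <- log10(p)
      }
    }
  }
  out
}
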