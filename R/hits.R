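#' Call hits at a target FDR from the scrambled-gene empirical null
#'
#' For each candidate threshold t (every observed combined z), the expected
#' number of false positives is the fraction of synthetic scrambled-gene z
#' values beyond t times the number of scored real genes, and
#' \code{FDR(t) = expected FP / max(1, observed hits)}. The FDR-versus-
#' threshold curve is made monotone by a cumulative-minimum (isotonic)
#' adjustment from the stringent end before the least stringent threshold
#' with \code{FDR <= target_fdr} is selected. Zero observed hits at a
#' threshold give FDR 0 by convention.
#'
#' @param combined_z Named numeric vector of per-gene combined z-scores.
#' @param null_z Numeric vector of synthetic scrambled-gene combined
#'   z-scores (see \code{\link{null_combined_z}}).
#' @param target_fdr Target false discovery rate (default 0.10).
#' @param direction \code{"depletion"} (hits are z <= threshold) or
#'   \code{"enrichment"} (z >= threshold).
#' @param conservative_null Apply two one-sided guards against the known
#'   failure modes of a finite empirical null (default \code{TRUE}).
#'   First, an Efron-style bulk calibration: the synthetic pool is
#'   rescaled about its median by the (MAD-based) ratio of observed to
#'   synthetic z dispersion whenever the observed bulk is wider, removing
#'   the shared scale error that a finite scrambled-control set imprints
#'   on every z. Second, a standard-normal tail floor: because the
#'   combined z is standardised by construction, the null tail fraction at
#'   any threshold is never taken below the N(0,1) tail, which protects
#'   the estimator where the empirical pool has no resolution (beyond
#'   roughly 1/n_controls). Both guards can only make hit calling more
#'   conservative; \code{FALSE} gives the raw empirical estimator.
#' @return Object of class \code{hit_call}: \code{threshold}, \code{hits}
#'   (gene ids), \code{fdr} (adjusted FDR at the threshold),
#'   \code{expected_fp}, \code{n_hits}, \code{min_achievable_fdr} and the
#'   full \code{curve} (threshold, hits, expected FP, raw and adjusted FDR).
#' @export
call_hits_empirical_fdr <- function(combined_z, null_z, target_fdr = 0.10,
                                    direction = c("depletion", "enrichment"),
                                    conservative_null = TRUE) {
  direction <- match.arg(direction)
  stopifnot(length(null_z) > 0)
  z <- combined_z[!is.na(combined_z)]
  # work on the depletion scale internally; flip for enrichment
  s <- if (direction == "depletion") z else -z
  ns <- if (direction == "depletion") null_z else -null_z
  scale_ratio <- 1
  if (conservative_null) {
    scale_ratio <- max(1, stats::mad(s) / stats::mad(ns))
    ns <- stats::median(ns) + (ns - stats::median(ns)) * scale_ratio
  }
  thr <- sort(unique(s))
  n_real <- length(s)
  hits_at <- vapply(thr, function(t) sum(s <= t), integer(1))
  null_frac <- vapply(thr, function(t) mean(ns <= t), numeric(1))
  if (conservative_null) {
    # the empirical far tail of a finite control pool is unreliable beyond
    # ~1/n_controls; the combined z is standardised by construction, so
    # the standard-normal tail is a conservative floor on the fraction
    null_frac <- pmax(null_frac, stats::pnorm(thr))
  }
  efp <- null_frac * n_real
  raw <- ifelse(hits_at == 0L, 0, efp / pmax(1L, hits_at))
  adj <- rev(cummin(rev(raw)))  # monotone non-increasing with stringency
  ok <- which(adj <= target_fdr)
  if (length(ok) > 0L) {
    pick <- max(ok)  # least stringent threshold meeting the target
    hit_ids <- names(s)[s <= thr[pick]]
    threshold <- if (direction == "depletion") thr[pick] else -thr[pick]
    res <- list(threshold = threshold, hits = hit_ids, fdr = adj[pick],
                expected_fp = efp[pick], n_hits = hits_at[pick])
  } else {
    res <- list(threshold = NA_real_, hits = character(0),
                fdr = NA_real_, expected_fp = NA_real_, n_hits = 0L)
  }
  curve <- data.frame(
    threshold = if (direction == "depletion") thr else rev(-thr),
    n_hits = if (direction == "depletion") hits_at else rev(hits_at),
    expected_fp = if (direction == "depletion") efp else rev(efp),
    fdr_raw = if (direction == "depletion") raw else rev(raw),
    fdr = if (direction == "depletion") adj else rev(adj))
  res$min_achievable_fdr <- min(adj)
  res$target_fdr <- target_fdr
  res$direction <- direction
  res$null_scale_ratio <- scale_ratio
  res$curve <- curve
  # Note: the conventional FDR = FP / (TP + FP) is used throughout.
  structure(res, class = "hit_call")
}

#' @export
print.hit_call <- function(x, ...) {
  cat("CRISPRi hit call (", x$direction, ")\n", sep = "")
  cat("  target FDR :", x$target_fdr, "\n")
  if (is.na(x$threshold)) {
    cat("  no threshold reaches the target; minimum achievable FDR ",
        signif(x$min_achievable_fdr, 3), "\n")
  } else {
    cat("  z threshold:", signif(x$threshold, 4), " hits:", x$n_hits,
        " estimated FDR:", signif(x$fdr, 3), "\n")
  }
  invisible(x)
}

#' Benchmark combined z-scores against a known positive gene set
#'
#' Sweeps a threshold over all observed z values, taking the true positive
#' rate from the labelled positive genes and the false positive rate from
#' the synthetic scrambled-gene pool. AUC is computed by the trapezoid rule.
#' The FDR-versus-threshold curve balances the classes by weighting the
#' positives so their effective size equals the negative pool before
#' computing \code{FDR = FP / (TP + FP)}.
#'
#' @param combined_z Named numeric vector of per-gene combined z-scores.
#' @param positives Character vector of known positive gene ids (must be a
#'   subset of the scored genes).
#' @param negatives_z Numeric vector of synthetic scrambled-gene combined
#'   z-scores.
#' @param direction \code{"depletion"} or \code{"enrichment"}.
#' @return Object of class \code{benchmark_report} with \code{roc} (TPR,
#'   FPR, FDR and counts per threshold) and \code{auc}.
#' @export
benchmark_against_gene_set <- function(combined_z, positives, negatives_z,
                                       direction = c("depletion",
                                                     "enrichment")) {
  direction <- match.arg(direction)
  z <- combined_z[!is.na(combined_z)]
  if (length(positives) == 0L) stop("empty positive gene set")
  missing <- setdiff(positives, names(z))
  if (length(missing) > 0L)
    stop("positives not among scored genes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  pos <- z[names(z) %in% positives]
  s_pos <- if (direction == "depletion") pos else -pos
  s_neg <- if (direction == "depletion") negatives_z else -negatives_z
  thr <- sort(unique(c(s_pos, s_neg)))
  tp <- vapply(thr, function(t) sum(s_pos <= t), integer(1))
  fp <- vapply(thr, function(t) sum(s_neg <= t), integer(1))
  tpr <- tp / length(s_pos)
  fpr <- fp / length(s_neg)
  w <- length(s_neg) / length(s_pos)  # oversample positives to pool size
  fdr <- ifelse(tp * w + fp == 0, 0, fp / (tp * w + fp))
  auc <- sum(diff(c(0, fpr, 1)) * (c(0, tpr) + c(tpr, 1)) / 2)
  structure(list(roc = data.frame(
    threshold = if (direction == "depletion") thr else -thr,
    tp = tp, fp = fp, tpr = tpr, fpr = fpr, fdr = fdr),
    auc = auc, n_positives = length(s_pos), n_negatives = length(s_neg),
    direction = direction), class = "benchmark_report")
}

#' Compare guide-score strata
#'
#' Per-group mean scores plus a two-sided rank-based test: a Wilcoxon
#' rank-sum test for two independent groups (or the signed-rank test when
#' \code{paired = TRUE}), and a Kruskal-Wallis test for three or more
#' groups.
#'
#' @param scores Numeric vector of guide scores.
#' @param groups Vector (coerced to factor) assigning each score to a
#'   stratum.
#' @param paired Use the paired signed-rank test (two groups of equal
#'   length).
#' @return List with \code{means}, \code{n}, \code{p_value} and
#'   \code{test}.
#' @export
compare_strata <- function(scores, groups, paired = FALSE) {
  keep <- !is.na(scores) & !is.na(groups)
  scores <- scores[keep]
  # declared factor levels are kept so that an empty stratum is reported
  groups <- if (is.factor(groups)) groups[keep] else factor(groups[keep])
  counts <- table(groups)
  if (any(counts == 0L))
    stop("empty stratum: ", paste(names(counts)[counts == 0L],
                                  collapse = ", "))
  if (nlevels(groups) < 2L) stop("need at least two strata")
  means <- tapply(scores, groups, mean)
  if (nlevels(groups) == 2L) {
    a <- scores[groups == levels(groups)[1]]
    b <- scores[groups == levels(groups)[2]]
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                              alternative = "two.sided"))
    test <- if (paired) "Wilcoxon signed-rank" else "Wilcoxon rank-sum"
  } else {
    ht <- stats::kruskal.test(scores, groups)
    test <- "Kruskal-Wallis"
  }
  list(means = means, n = counts, p_value = ht$p.value, test = test)
}

#' Rolling average of guide scores along a covariate
#'
#' Points are sorted by the covariate and both coordinates are averaged in
#' a sliding window of the stated count, producing the trend lines drawn
#' over distance-to-TSS and nucleosome-occupancy scatter plots.
#'
#' @param x Covariate values (e.g. distance to TSS).
#' @param y Guide scores.
#' @param window Window size in points (default 200).
#' @return Data frame with window-centre \code{x} and mean \code{y}.
#' @export
rolling_average <- function(x, y, window = 200) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (window < 2) stop("window must be at least 2")
  if (window > length(x)) stop("window exceeds the number of points")
  o <- order(x)
  x <- x[o]; y <- y[o]
  roll <- function(v) {
    cs <- cumsum(c(0, v))
    (cs[(window + 1):length(cs)] - cs[1:(length(cs) - window)]) / window
  }
  data.frame(x = roll(x), y = roll(y))
}
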