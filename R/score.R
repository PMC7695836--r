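#' Per-guide depletion/enrichment scores between two samples
#'
#' The score of a guide is the difference of its log2 read frequencies,
#' \code{f_A - f_B}, where \code{f = log2((count + 1) / total)}. Guides must
#' reach a raw (pseudocount-free) read frequency of at least \code{min_freq}
#' in at least one of the two samples; others are flagged
#' \code{passed_filter = FALSE} and their score is \code{NA}.
#'
#' @param counts Integer count matrix (guides x samples) with dimnames, or a
#'   two-column matrix/data frame of the two samples.
#' @param sample_a,sample_b Column names of the treatment (e.g. induced) and
#'   control (e.g. uninduced) samples.
#' @param min_freq Minimum raw read frequency (default 1e-5).
#' @return Data frame: \code{guide_id}, \code{score}, \code{passed_filter}.
#' @export
guide_depletion <- function(counts, sample_a, sample_b, min_freq = 1e-5) {
  counts <- as.matrix(counts)
  if (!all(c(sample_a, sample_b) %in% colnames(counts)))
    stop("samples ", sample_a, " / ", sample_b, " not found in counts")
  ca <- counts[, sample_a]; cb <- counts[, sample_b]
  if (is.null(rownames(counts)))
    stop("counts must carry guide ids as row names")
  ta <- sum(ca); tb <- sum(cb)
  if (ta == 0 || tb == 0) stop("a sample has zero assigned reads")
  passed <- (ca / ta >= min_freq) | (cb / tb >= min_freq)
  score <- log2((ca + 1) / ta) - log2((cb + 1) / tb)
  score[!passed] <- NA_real_
  data.frame(guide_id = rownames(counts), score = score,
             passed_filter = passed, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Gene-level depletion/enrichment score from its guide scores
#'
#' For more than three guide scores, the mean of the three highest and the
#' mean of the three lowest values are compared and the one with the larger
#' absolute value is returned (for four or five guides the two windows
#' overlap, e.g. guides 1-3 versus 2-4 at n = 4). With three or fewer
#' guides, the plain mean is returned. An exact tie in absolute value
#' returns the depletion (negative) mean, the screen's primary readout.
#'
#' @param scores Numeric vector of one gene's filtered guide scores.
#' @return A single signed score.
#' @export
gene_score <- function(scores) {
  scores <- scores[!is.na(scores)]
  n <- length(scores)
  if (n == 0L) stop("gene_score requires at least one guide score")
  if (n <= 3L) return(mean(scores))
  s <- sort(scores)
  mb <- mean(s[1:3])
  mt <- mean(s[(n - 2L):n])
  if (abs(mb) >= abs(mt)) mb else mt
}

# Vectorised gene_score over the columns of a k x m matrix (each column one
# synthetic gene with the same number k of guide scores).
col_gene_scores <- function(M) {
  k <- nrow(M)
  if (k <= 3L) return(colMeans(M))
  o <- order(col(M), M)
  S <- matrix(M[o], nrow = k)
  mb <- colMeans(S[1:3, , drop = FALSE])
  mt <- colMeans(S[(k - 2L):k, , drop = FALSE])
  ifelse(abs(mb) >= abs(mt), mb, mt)
}

#' Gene scores for every gene in every contrast
#'
#' Applies \code{\link{gene_score}} to the filtered guide scores of each
#' gene. Guides shared by two genes contribute to both genes.
#'
#' @param guide_scores Numeric matrix (guides x contrasts) of guide
#'   depletion scores, \code{NA} for filtered-out guides.
#' @param membership Data frame with \code{guide_id} and \code{gene_id}
#'   (one row per guide-gene pair, targeting guides only).
#' @return List with \code{score} (genes x contrasts matrix) and \code{n}
#'   (filtered guide count per gene per contrast).
#' @export
gene_score_table <- function(guide_scores, membership) {
  guide_scores <- as.matrix(guide_scores)
  membership <- membership[membership$guide_id %in% rownames(guide_scores), ,
                           drop = FALSE]
  genes <- sort(unique(membership$gene_id))
  contrasts <- colnames(guide_scores)
  score <- matrix(NA_real_, length(genes), ncol(guide_scores),
                  dimnames = list(genes, contrasts))
  nmat <- matrix(0L, length(genes), ncol(guide_scores),
                 dimnames = list(genes, contrasts))
  by_gene <- split(membership$guide_id, membership$gene_id)
  for (j in seq_len(ncol(guide_scores))) {
    col <- guide_scores[, j]
    for (g in genes) {
      s <- col[by_gene[[g]]]
      s <- s[!is.na(s)]
      nmat[g, j] <- length(s)
      if (length(s) > 0L) score[g, j] <- gene_score(s)
    }
  }
  list(score = score, n = nmat)
}

#' Build the synthetic scrambled-gene null ensemble
#'
#' For each iteration, every gene is repopulated with scrambled control
#' guides drawn (with replacement, count matching that gene's filtered
#' guide count) from the controls that pass the filter in every contrast;
#' the same drawn guides are then scored per contrast with
#' \code{\link{gene_score}}. Replacing each gene's guides once and carrying
#' them across replicates keeps the null's across-replicate correlation
#' structure identical to that of real genes, whose guides (and baseline
#' abundances) are likewise shared across replicates. Pooled per-contrast
#' moments of the synthetic gene scores are recorded.
#'
#' @param scrambled_scores Numeric matrix (scrambled guides x contrasts) of
#'   scrambled-control depletion scores (\code{NA} = filtered out), or a
#'   single numeric vector for one contrast.
#' @param gene_guide_counts Integer matrix (genes x contrasts) of filtered
#'   guide counts per gene, or a named vector for one contrast.
#' @param n_iter Number of resampling iterations (default 200).
#' @param seed Integer seed.
#' @return Object of class \code{null_ensemble}: per-contrast synthetic
#'   score matrices (genes x iterations), pooled means and standard
#'   deviations, and the guide counts used.
#' @export
build_null_ensemble <- function(scrambled_scores, gene_guide_counts,
                                n_iter = 200, seed = 1) {
  if (is.null(dim(scrambled_scores)))
    scrambled_scores <- matrix(scrambled_scores, ncol = 1L,
                               dimnames = list(NULL, "contrast1"))
  if (is.null(dim(gene_guide_counts)))
    gene_guide_counts <- matrix(gene_guide_counts, ncol = 1L,
                                dimnames = list(names(gene_guide_counts),
                                                colnames(scrambled_scores)))
  scrambled_scores <- as.matrix(scrambled_scores)
  gene_guide_counts <- as.matrix(gene_guide_counts)
  stopifnot(ncol(scrambled_scores) == ncol(gene_guide_counts), n_iter >= 1)
  contrasts <- colnames(scrambled_scores)
  genes <- rownames(gene_guide_counts)
  # a synthetic scrambled gene is populated ONCE per iteration: the same
  # drawn scrambled guides are scored in every contrast, so the null
  # carries the same across-replicate correlation structure (shared guide
  # identities and abundances) as real genes
  pass_all <- rowSums(is.na(scrambled_scores)) == 0L
  pool <- scrambled_scores[pass_all, , drop = FALSE]
  if (nrow(pool) < 2L)
    stop("fewer than two scrambled guide scores pass the filter in every ",
         "contrast; supply scrambled controls or use targeting-guide ",
         "scores explicitly as a permutation null")
  withr::with_seed(seed, {
    scores <- stats::setNames(
      rep(list(matrix(NA_real_, length(genes), n_iter,
                      dimnames = list(genes, NULL))), length(contrasts)),
      contrasts)
    pattern <- apply(gene_guide_counts, 1L, paste, collapse = ",")
    for (pat in unique(pattern)) {
      rows <- which(pattern == pat)
      kvec <- gene_guide_counts[rows[1], ]
      kmax <- max(kvec)
      if (kmax == 0L) next
      m <- length(rows) * n_iter
      idx <- matrix(sample.int(nrow(pool), kmax * m, replace = TRUE),
                    nrow = kmax)
      for (j in seq_along(contrasts)) {
        k <- kvec[j]
        if (k == 0L) next
        draws <- matrix(pool[idx[seq_len(k), , drop = FALSE], j], nrow = k)
        scores[[j]][rows, ] <- matrix(col_gene_scores(draws),
                                      nrow = length(rows))
      }
    }
    mu <- vapply(scores, function(s) mean(s[!is.na(s)]), numeric(1))
    sd <- vapply(scores, function(s) stats::sd(s[!is.na(s)]), numeric(1))
    structure(list(scores = scores, mean = mu, sd = sd, n_iter = n_iter,
                   gene_counts = gene_guide_counts),
              class = "null_ensemble")
  })
}

#' Stouffer combination of z-scores
#'
#' \code{sum(z) / sqrt(length(z))} over the non-missing entries.
#'
#' @param z Numeric vector of z-scores.
#' @param na.rm Drop missing values before combining.
#' @return A single combined z.
#' @export
stouffer_z <- function(z, na.rm = TRUE) {
  if (na.rm) z <- z[!is.na(z)]
  if (length(z) == 0L) return(NA_real_)
  sum(z) / sqrt(length(z))
}

#' Convert gene scores to z-scores against the scrambled-gene null
#'
#' Per contrast, \code{z = (score - null_mean) / null_sd} using the pooled
#' synthetic scrambled-gene moments of that contrast; the per-gene combined
#' z averages the replicate z-scores with Stouffer's method
#' (\code{sum(z) / sqrt(k)} over the k contrasts in which the gene was
#' scored).
#'
#' @param gene_scores Genes x contrasts matrix of gene scores (as from
#'   \code{\link{gene_score_table}}).
#' @param null A \code{\link{build_null_ensemble}} result.
#' @return List with \code{z} (genes x contrasts) and \code{combined_z}
#'   (named vector).
#' @export
gene_z_scores <- function(gene_scores, null) {
  gene_scores <- as.matrix(gene_scores)
  contrasts <- colnames(gene_scores)
  stopifnot(all(contrasts %in% names(null$mean)))
  sds <- null$sd[contrasts]
  if (any(sds == 0 | is.na(sds)))
    stop("null ensemble has zero standard deviation in contrast ",
         paste(contrasts[sds == 0 | is.na(sds)], collapse = ", "))
  z <- sweep(sweep(gene_scores, 2L, null$mean[contrasts], "-"),
             2L, sds, "/")
  combined <- apply(z, 1L, stouffer_z)
  combined[rowSums(!is.na(z)) == 0L] <- NA_real_
  list(z = z, combined_z = combined)
}

#' Combined z pool of the synthetic scrambled genes
#'
#' Standardises each contrast's synthetic gene scores by that contrast's
#' pooled null moments and combines them across contrasts with Stouffer's
#' method, mirroring exactly what \code{\link{gene_z_scores}} does to real
#' genes. The result is the empirical null distribution of the combined z.
#'
#' @param null A \code{\link{build_null_ensemble}} result.
#' @return Numeric vector of synthetic combined z values (one per synthetic
#'   gene per iteration).
#' @export
null_combined_z <- function(null) {
  contrasts <- names(null$scores)
  zsum <- NULL; k <- NULL
  for (cc in contrasts) {
    z <- (null$scores[[cc]] - null$mean[[cc]]) / null$sd[[cc]]
    miss <- is.na(z)
    z[miss] <- 0
    if (is.null(zsum)) {
      zsum <- z; k <- 1 - miss
    } else {
      zsum <- zsum + z; k <- k + (1 - miss)
    }
  }
  out <- as.vector(zsum / sqrt(k))
  out[is.finite(out)]
}
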