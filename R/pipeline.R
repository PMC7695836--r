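#' Score a CRISPRi screen end to end
#'
#' Runs the full statistical pipeline on a count table: per-replicate
#' induced-versus-uninduced guide depletion scores with the read-frequency
#' filter, gene scores from the top/bottom-three rule, the 200x resampled
#' scrambled-gene null, per-replicate z-scores and the Stouffer-combined
#' gene z, plus the matching synthetic combined-z null pool used for hit
#' calling.
#'
#' @param counts Integer matrix (guides x samples) with dimnames.
#' @param samples Data frame with \code{sample_id}, \code{condition}
#'   (\code{"induced"} / \code{"uninduced"}) and \code{replicate}.
#' @param library A \code{library_manifest} or guides data frame (long
#'   guide-gene format including scrambled controls).
#' @param min_freq Guide read-frequency filter (default 1e-5).
#' @param n_iter Null-ensemble iterations (default 200).
#' @param seed Seed for the null resampling.
#' @return Object of class \code{screen_scores}: \code{guide_scores} and
#'   \code{passed} matrices (guides x contrasts), \code{gene_scores},
#'   \code{gene_n}, \code{z}, \code{combined_z}, \code{null},
#'   \code{null_z} (synthetic combined-z pool) and \code{contrasts}.
#' @export
score_screen <- function(counts, samples, library, min_freq = 1e-5,
                         n_iter = 200, seed = 1) {
  counts <- as.matrix(counts)
  guides <- if (inherits(library, "library_manifest")) library$guides else library
  meta <- guide_meta(guides)
  stopifnot(all(meta$guide_id %in% rownames(counts)))
  reps <- sort(unique(samples$replicate))
  contrasts <- character(0)
  score_cols <- list()
  for (r in reps) {
    a <- samples$sample_id[samples$condition == "induced" &
                             samples$replicate == r]
    b <- samples$sample_id[samples$condition == "uninduced" &
                             samples$replicate == r]
    if (length(a) != 1L || length(b) != 1L) next
    id <- paste0("rep", r)
    contrasts <- c(contrasts, id)
    score_cols[[id]] <- guide_depletion(counts, a, b, min_freq = min_freq)
  }
  if (length(contrasts) == 0L)
    stop("no induced/uninduced replicate pairs found in samples")
  gs <- do.call(cbind, lapply(score_cols, `[[`, "score"))
  rownames(gs) <- score_cols[[1]]$guide_id
  colnames(gs) <- contrasts
  passed <- do.call(cbind, lapply(score_cols, `[[`, "passed_filter"))
  dimnames(passed) <- dimnames(gs)

  membership <- guides[!guides$scrambled, c("guide_id", "gene_id")]
  gene_tab <- gene_score_table(gs, membership)

  scram_ids <- meta$guide_id[meta$scrambled]
  if (length(scram_ids) == 0L)
    stop("library has no scrambled controls; the empirical null needs ",
         "them (or an explicit permutation pool)")
  null <- build_null_ensemble(gs[scram_ids, , drop = FALSE], gene_tab$n,
                              n_iter = n_iter, seed = seed)
  zz <- gene_z_scores(gene_tab$score, null)
  structure(list(guide_scores = gs, passed = passed,
                 gene_scores = gene_tab$score, gene_n = gene_tab$n,
                 z = zz$z, combined_z = zz$combined_z, null = null,
                 null_z = null_combined_z(null), contrasts = contrasts,
                 samples = samples),
            class = "screen_scores")
}

#' @export
print.screen_scores <- function(x, ...) {
  cat("CRISPRi screen scores\n")
  cat("  contrasts:", paste(x$contrasts, collapse = ", "), "\n")
  cat("  genes scored:", sum(!is.na(x$combined_z)), "\n")
  cat("  guides passing filter:",
      sum(rowSums(x$passed) > 0), "/", nrow(x$passed), "\n")
  invisible(x)
}

#' Call hits on a scored screen
#'
#' Thin wrapper around \code{\link{call_hits_empirical_fdr}} using the
#' screen's combined z and its synthetic scrambled-gene null pool.
#'
#' @param screen A \code{\link{score_screen}} result.
#' @param target_fdr Target FDR (default 0.10).
#' @param direction \code{"depletion"} or \code{"enrichment"}.
#' @return A \code{hit_call} object.
#' @export
call_hits <- function(screen, target_fdr = 0.10,
                      direction = c("depletion", "enrichment")) {
  stopifnot(inherits(screen, "screen_scores"))
  call_hits_empirical_fdr(screen$combined_z, screen$null_z,
                          target_fdr = target_fdr,
                          direction = match.arg(direction))
}

#' Mean observed depletion score per guide across contrasts
#'
#' Convenience accessor used when labelling guides for the efficacy
#' classifier: the mean of a guide's filtered depletion scores over the
#' screen's contrasts.
#'
#' @param screen A \code{\link{score_screen}} result.
#' @return Named numeric vector (NA for guides that never pass the filter).
#' @export
mean_guide_score <- function(screen) {
  stopifnot(inherits(screen, "screen_scores"))
  rowMeans(screen$guide_scores, na.rm = TRUE)
}
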