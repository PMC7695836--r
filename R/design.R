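#' Enumerate NGG PAM sites on both strands of a contig
#'
#' Returns, for each strand, the sorted 1-based coordinates (on the top
#' strand) of the N of every NGG PAM whose 20-nt spacer lies fully inside
#' the contig. Top-strand PAMs have their spacer immediately 5' of the PAM
#' on the top strand; bottom-strand PAMs appear as CCN on the top strand,
#' with the N of the PAM at the position of the N of CCN.
#'
#' @param seq A single DNA string.
#' @return A list with sorted integer vectors \code{plus} and \code{minus}.
#' @keywords internal
pam_sites <- function(seq) {
  L <- nchar(seq)
  gg <- gregexpr("(?=GG)", seq, perl = TRUE)[[1]]
  if (length(gg) == 1L && gg[1] == -1L) gg <- integer(0)
  plus <- as.integer(gg) - 1L              # N of NGG
  plus <- plus[plus >= 21L & plus + 2L <= L]
  cc <- gregexpr("(?=CC)", seq, perl = TRUE)[[1]]
  if (length(cc) == 1L && cc[1] == -1L) cc <- integer(0)
  minus <- as.integer(cc) + 2L             # N of CCN = N of bottom-strand NGG
  minus <- minus[minus - 2L >= 1L & minus + 20L <= L]
  list(plus = sort(plus), minus = sort(minus))
}

# spacer of a PAM site: 20 nt 5' of the PAM on the PAM-carrying strand,
# reported 5'->3' on that strand. p = coordinate of the N of NGG.
pam_spacer <- function(seq, p, strand) {
  ifelse(strand == "+",
         substring(seq, p - 20L, p - 1L),
         revcomp(substring(seq, p + 1L, p + 20L)))
}

#' Enumerate candidate CRISPRi spacers near gene TSSs
#'
#' Scans both strands of the genome for NGG PAMs and reports every PAM whose
#' signed distance to a gene's TSS (positive = upstream in that gene's
#' orientation) falls inside \code{window}. A PAM inside the shared
#' intergenic window of two divergent genes yields one row per gene, so the
#' guide carries both target genes.
#'
#' @param genome Named character vector of contigs (or a single string).
#' @param genes Data frame with \code{gene_id}, \code{strand}, \code{tss}
#'   (1-based) and optionally \code{chrom}.
#' @param window Length-2 numeric: allowed signed TSS distance range in bp;
#'   the default \code{c(0, 200)} is the yeast CRISPRi promoter window.
#' @return A data frame, one row per guide-gene pair: \code{guide_key},
#'   \code{chrom}, \code{spacer}, \code{pam_position} (1-based coordinate of
#'   the N of NGG on the top strand), \code{pam_strand}, \code{gene_id},
#'   \code{distance_to_tss}, \code{pam_same_strand_as_gene},
#'   \code{n_target_genes}.
#' @export
enumerate_candidates <- function(genome, genes, window = c(0, 200)) {
  genome <- as_genome(genome)
  stopifnot(is.data.frame(genes), length(window) == 2L,
            window[1] <= window[2])
  if (nrow(genes) == 0L) {
    return(data.frame(guide_key = character(0), chrom = character(0),
                      spacer = character(0), pam_position = integer(0),
                      pam_strand = character(0), gene_id = character(0),
                      distance_to_tss = integer(0),
                      pam_same_strand_as_gene = logical(0),
                      n_target_genes = integer(0)))
  }
  if (is.null(genes$chrom)) genes$chrom <- names(genome)[1]
  bad <- !(genes$chrom %in% names(genome))
  if (any(bad)) stop("unknown contig for gene ", genes$gene_id[which(bad)[1]])
  out <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    seq <- genome[[ci]]
    L <- nchar(seq)
    g <- genes[genes$chrom == contig, , drop = FALSE]
    if (nrow(g) == 0L) next
    oob <- g$tss < 1L | g$tss > L
    if (any(oob))
      stop("TSS of gene ", g$gene_id[which(oob)[1]],
           " is outside the bounds of contig ", contig)
    sites <- pam_sites(seq)
    rows <- vector("list", nrow(g))
    for (i in seq_len(nrow(g))) {
      tss <- g$tss[i]; gs <- g$strand[i]
      if (gs == "+") { lo <- tss - window[2]; hi <- tss - window[1] }
      else           { lo <- tss + window[1]; hi <- tss + window[2] }
      hits <- lapply(c("+", "-"), function(ps) {
        pos <- sites[[if (ps == "+") "plus" else "minus"]]
        pos <- pos[pos >= lo & pos <= hi]
        if (length(pos) == 0L) return(NULL)
        data.frame(chrom = contig, pam_position = pos, pam_strand = ps,
                   gene_id = g$gene_id[i],
                   distance_to_tss = if (gs == "+") tss - pos else pos - tss,
                   pam_same_strand_as_gene = ps == gs,
                   stringsAsFactors = FALSE)
      })
      rows[[i]] <- do.call(rbind, hits)
    }
    res <- do.call(rbind, rows)
    if (is.null(res)) next
    res$spacer <- pam_spacer(seq, res$pam_position, res$pam_strand)
    out[[ci]] <- res
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(chrom = character(0),
                                      pam_position = integer(0),
                                      pam_strand = character(0),
                                      gene_id = character(0),
                                      distance_to_tss = integer(0),
                                      pam_same_strand_as_gene = logical(0),
                                      spacer = character(0))
  res$guide_key <- paste(res$chrom, res$pam_position, res$pam_strand,
                         sep = ":")
  tab <- table(res$guide_key[!duplicated(paste(res$guide_key, res$gene_id))])
  res$n_target_genes <- as.integer(tab[res$guide_key])
  rownames(res) <- NULL
  res[, c("guide_key", "chrom", "spacer", "pam_position", "pam_strand",
          "gene_id", "distance_to_tss", "pam_same_strand_as_gene",
          "n_target_genes")]
}

# default window-widening schedule: extend the upstream bound in 50 bp steps
# to 400 bp, then admit 25 bp steps downstream of the TSS to -100 bp.
widen_schedule <- function(base = c(0, 200)) {
  ups <- seq(base[2], 400, by = 50)
  c(lapply(ups, function(u) c(base[1], u)),
    lapply(seq(25, 100, by = 25), function(d) c(-d, 400)))
}

#' Annotate candidates with nucleosome occupancy scores
#'
#' The score of a guide is the track value at its PAM position (nearest
#' position lookup, clamped to the track bounds).
#'
#' @param candidates Candidate data frame from
#'   \code{\link{enumerate_candidates}}.
#' @param nucleosome_track Numeric vector of per-position scores in
#'   \[0, 1\] (single contig), or a named list of such vectors per contig.
#' @return The candidate data frame with a \code{nucleosome_score} column.
#' @export
annotate_nucleosome <- function(candidates, nucleosome_track) {
  score_one <- function(track, pos) {
    track[pmin(pmax(round(pos), 1L), length(track))]
  }
  if (is.list(nucleosome_track)) {
    candidates$nucleosome_score <- NA_real_
    for (contig in unique(candidates$chrom)) {
      idx <- candidates$chrom == contig
      candidates$nucleosome_score[idx] <-
        score_one(nucleosome_track[[contig]], candidates$pam_position[idx])
    }
  } else {
    candidates$nucleosome_score <-
      score_one(nucleosome_track, candidates$pam_position)
  }
  candidates
}

#' Select guides per gene by nucleosome occupancy
#'
#' For each gene, candidates inside the promoter window are sorted by
#' ascending nucleosome score (ties broken by smaller absolute TSS distance,
#' then lexicographic spacer) and the top \code{per_gene} are chosen. Genes
#' with fewer than \code{per_gene} in-window candidates have their window
#' widened stepwise (upstream first, then downstream) until enough exist or
#' the schedule is exhausted. Genes whose chosen set includes a guide shared
#' with another gene receive up to \code{extras_for_shared} additional
#' guides unique to them. Guides shared between two genes are annotated with
#' both genes in the returned manifest.
#'
#' @param candidates Candidates from \code{\link{enumerate_candidates}},
#'   enumerated over a window at least as wide as the full widening schedule
#'   (\code{c(-100, 400)}) and annotated with nucleosome scores (see
#'   \code{\link{annotate_nucleosome}}).
#' @param nucleosome_track Optional track used to annotate candidates if
#'   they lack a \code{nucleosome_score} column.
#' @param per_gene Guides selected per gene in the base window (default 6).
#' @param extras_for_shared Additional unique guides for genes with
#'   shared-promoter guides (default 6).
#' @param max_per_gene Hard per-gene cap (default 12).
#' @param base_window Base promoter window (default \code{c(0, 200)}).
#' @return A \code{library_manifest}: list with \code{guides} (one row per
#'   guide-gene pair), \code{gene_summary} (per-gene count, designability
#'   and window stage used) and \code{params}.
#' @export
select_guides <- function(candidates, nucleosome_track = NULL, per_gene = 6,
                          extras_for_shared = 6, max_per_gene = 12,
                          base_window = c(0, 200)) {
  if (is.null(candidates$nucleosome_score)) {
    if (is.null(nucleosome_track))
      stop("candidates lack nucleosome scores and no track was supplied")
    candidates <- annotate_nucleosome(candidates, nucleosome_track)
  }
  schedule <- widen_schedule(base_window)
  genes <- sort(unique(candidates$gene_id))
  chosen_keys <- vector("list", length(genes))
  summary <- data.frame(gene_id = genes, n_guides = 0L, designable = TRUE,
                        window_stage = NA_integer_, stringsAsFactors = FALSE)
  # a guide is "common to two genes" when it sits inside the base promoter
  # window of both (candidates may be enumerated over the wider widening
  # range, where distant annotations do not imply co-targeting)
  candidates$in_base <- candidates$distance_to_tss >= base_window[1] &
    candidates$distance_to_tss <= base_window[2]
  base_rows <- candidates[candidates$in_base, , drop = FALSE]
  n_base <- table(base_rows$guide_key[!duplicated(
    paste(base_rows$guide_key, base_rows$gene_id))])
  candidates$n_base_targets <- as.integer(n_base[candidates$guide_key])
  candidates$n_base_targets[is.na(candidates$n_base_targets)] <- 0L
  cand_by_gene <- split(candidates, candidates$gene_id)

  rank_order <- function(df) {
    order(df$nucleosome_score, abs(df$distance_to_tss), df$spacer)
  }

  for (i in seq_along(genes)) {
    cg <- cand_by_gene[[genes[i]]]
    pool <- NULL; stage <- NA_integer_
    for (s in seq_along(schedule)) {
      w <- schedule[[s]]
      pool <- cg[cg$distance_to_tss >= w[1] & cg$distance_to_tss <= w[2], ,
                 drop = FALSE]
      stage <- s
      if (nrow(pool) >= per_gene) break
    }
    if (nrow(pool) == 0L) {
      summary$designable[i] <- FALSE
      next
    }
    summary$window_stage[i] <- stage
    pool <- pool[rank_order(pool), , drop = FALSE]
    picked <- utils::head(pool$guide_key, per_gene)
    if (any(pool$n_base_targets[pool$guide_key %in% picked] > 1L)) {
      uniq <- pool[pool$n_base_targets <= 1L &
                     !(pool$guide_key %in% picked), , drop = FALSE]
      room <- max_per_gene - length(picked)
      picked <- c(picked, utils::head(uniq$guide_key,
                                      min(extras_for_shared, room)))
    }
    chosen_keys[[i]] <- picked
  }

  keys <- unique(unlist(chosen_keys))
  # a selected guide is kept for (a) every gene that chose it and (b) every
  # gene whose base promoter window contains it: shared-promoter guides
  # contribute to both genes
  chose <- paste(rep(genes, lengths(chosen_keys)), unlist(chosen_keys))
  guides <- candidates[candidates$guide_key %in% keys &
                         (candidates$in_base |
                            paste(candidates$gene_id,
                                  candidates$guide_key) %in% chose), ,
                       drop = FALSE]
  guides <- guides[!duplicated(paste(guides$guide_key, guides$gene_id)), ,
                   drop = FALSE]
  tab2 <- table(guides$guide_key)
  guides$n_target_genes <- as.integer(tab2[guides$guide_key])
  ord <- order(guides$chrom, guides$pam_position, guides$pam_strand,
               guides$gene_id)
  guides <- guides[ord, , drop = FALSE]
  ukeys <- unique(guides$guide_key)
  ids <- sprintf("g%05d", seq_along(ukeys))
  guides$guide_id <- ids[match(guides$guide_key, ukeys)]
  guides$scrambled <- FALSE
  rownames(guides) <- NULL

  cnt <- table(guides$gene_id)
  summary$n_guides <- as.integer(ifelse(is.na(cnt[summary$gene_id]), 0L,
                                        cnt[summary$gene_id]))
  structure(list(guides = guides[, c("guide_id", "guide_key", "chrom",
                                     "spacer", "pam_position", "pam_strand",
                                     "gene_id", "distance_to_tss",
                                     "pam_same_strand_as_gene",
                                     "nucleosome_score", "n_target_genes",
                                     "scrambled")],
                 gene_summary = summary,
                 params = list(per_gene = per_gene,
                               extras_for_shared = extras_for_shared,
                               max_per_gene = max_per_gene,
                               base_window = base_window)),
            class = "library_manifest")
}

#' Generate scrambled non-targeting control guides
#'
#' Each control is a random permutation of the bases of a randomly chosen
#' real spacer, accepted only if its 20-mer occurs nowhere on either strand
#' of the genome (exact substring check, no PAM requirement) and is distinct
#' from previously accepted controls.
#'
#' @param spacers Character vector of real spacer sequences to shuffle.
#' @param genome Genome as a named character vector of contigs.
#' @param n Number of controls to generate.
#' @param seed Integer seed.
#' @param max_attempts Rejection budget (default \code{1000 * n}).
#' @return A data frame of scrambled guide records (\code{guide_id},
#'   \code{spacer}, \code{source_spacer}, \code{scrambled = TRUE}).
#' @export
generate_scrambled_controls <- function(spacers, genome, n = 500, seed = 1,
                                        max_attempts = 1000 * n) {
  stopifnot(n >= 0)
  if (n == 0L)
    return(data.frame(guide_id = character(0), spacer = character(0),
                      source_spacer = character(0), scrambled = logical(0)))
  genome <- as_genome(genome)
  haystack <- paste(c(genome, revcomp(genome)), collapse = "|")
  spacers <- unique(toupper(spacers))
  stopifnot(length(spacers) > 0L, all(nchar(spacers) == 20L))
  withr::with_seed(seed, {
    accepted <- character(0)
    sources <- character(0)
    attempts <- 0L
    while (length(accepted) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      src <- sample(spacers, 1L)
      perm <- paste(sample(strsplit(src, "")[[1]]), collapse = "")
      if (perm %in% accepted) next
      if (grepl(perm, haystack, fixed = TRUE)) next
      accepted <- c(accepted, perm)
      sources <- c(sources, src)
    }
    if (length(accepted) < n)
      stop("rejection budget exhausted after ", attempts, " attempts: only ",
           length(accepted), " of ", n,
           " scrambled controls absent from the genome")
    data.frame(guide_id = sprintf("scr%04d", seq_len(n)), spacer = accepted,
               source_spacer = sources, scrambled = TRUE,
               stringsAsFactors = FALSE)
  })
}

#' Design a complete CRISPRi guide library for a genome
#'
#' Convenience wrapper: enumerates candidates over the full widening range,
#' annotates nucleosome scores, runs per-gene selection and appends
#' scrambled non-targeting controls.
#'
#' @inheritParams select_guides
#' @param genome Named character vector of contigs.
#' @param genes Gene-model data frame (\code{gene_id}, \code{strand},
#'   \code{tss}, optional \code{chrom}).
#' @param nucleosome_track Per-position nucleosome scores.
#' @param n_scrambled Number of scrambled controls to append.
#' @param seed Seed for scrambled-control generation.
#' @return A \code{library_manifest} whose \code{guides} table includes the
#'   scrambled controls (with \code{gene_id = NA}).
#' @export
design_library <- function(genome, genes, nucleosome_track,
                           per_gene = 6, extras_for_shared = 6,
                           max_per_gene = 12, base_window = c(0, 200),
                           n_scrambled = 0, seed = 1) {
  cand <- enumerate_candidates(genome, genes, window = c(-100, 400))
  cand <- annotate_nucleosome(cand, nucleosome_track)
  manifest <- select_guides(cand, per_gene = per_gene,
                            extras_for_shared = extras_for_shared,
                            max_per_gene = max_per_gene,
                            base_window = base_window)
  if (n_scrambled > 0L) {
    scr <- generate_scrambled_controls(unique(manifest$guides$spacer),
                                       genome, n = n_scrambled, seed = seed)
    pad <- data.frame(guide_id = scr$guide_id, guide_key = scr$guide_id,
                      chrom = NA_character_, spacer = scr$spacer,
                      pam_position = NA_integer_, pam_strand = NA_character_,
                      gene_id = NA_character_, distance_to_tss = NA_real_,
                      pam_same_strand_as_gene = NA,
                      nucleosome_score = NA_real_, n_target_genes = 0L,
                      scrambled = TRUE, stringsAsFactors = FALSE)
    manifest$guides <- rbind(manifest$guides, pad)
  }
  manifest$params$n_scrambled <- n_scrambled
  manifest
}

#' Guide-level metadata of a library
#'
#' Collapses the long (guide-gene pair) table to one row per guide.
#'
#' @param library A \code{library_manifest} or its \code{guides} data frame.
#' @return Data frame with one row per unique guide.
#' @export
guide_meta <- function(library) {
  guides <- if (inherits(library, "library_manifest")) library$guides else library
  meta <- guides[!duplicated(guides$guide_id),
                 c("guide_id", "spacer", "chrom", "pam_position",
                   "pam_strand", "nucleosome_score", "scrambled")]
  rownames(meta) <- NULL
  meta
}

#' @export
print.library_manifest <- function(x, ...) {
  n_guides <- length(unique(x$guides$guide_id))
  n_scr <- sum(guide_meta(x)$scrambled)
  cat("CRISPRi library manifest\n")
  cat("  guides:", n_guides, "(", n_scr, "scrambled controls )\n")
  cat("  genes :", nrow(x$gene_summary), "designed;",
      sum(!x$gene_summary$designable), "not designable\n")
  cat("  guides per gene: median",
      stats::median(x$gene_summary$n_guides[x$gene_summary$designable]), "\n")
  invisible(x)
}
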