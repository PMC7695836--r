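#' Extract the 20-nt spacer region from amplicon reads
#'
#' Either a fixed offset or a 5' anchor sequence defines where the spacer
#' starts in each read. Reads too short to contain a full spacer (or lacking
#' the anchor) yield \code{NA} and are later counted as malformed.
#'
#' @param reads Character vector of read sequences.
#' @param offset 1-based start of the spacer within the read (ignored when
#'   \code{anchor5} is given).
#' @param anchor5 Optional fixed sequence immediately 5' of the spacer; the
#'   spacer is taken as the 20 nt after its first occurrence.
#' @param spacer_length Spacer length (20).
#' @return Character vector of extracted spacers (\code{NA} if absent).
#' @export
extract_spacers <- function(reads, offset = 1L, anchor5 = NULL,
                            spacer_length = 20L) {
  reads <- toupper(reads)
  if (!is.null(anchor5)) {
    pos <- regexpr(toupper(anchor5), reads, fixed = TRUE)
    start <- ifelse(pos > 0L, pos + nchar(anchor5), NA_integer_)
  } else {
    start <- rep(as.integer(offset), length(reads))
  }
  out <- substring(reads, start, start + spacer_length - 1L)
  out[is.na(start) | nchar(out) < spacer_length] <- NA_character_
  out
}

# Build the Hamming-distance-1 lookup for a spacer set: a key->guide map of
# every single-substitution variant, with keys reachable from more than one
# guide marked ambiguous and keys equal to an exact spacer removed (exact
# matches take precedence).
mismatch1_index <- function(spacers, guide_ids) {
  n <- length(spacers)
  keys <- character(0); gids <- character(0)
  for (pos in 1:20) {
    pre <- substr(spacers, 1L, pos - 1L)
    post <- substr(spacers, pos + 1L, 20L)
    cur <- substr(spacers, pos, pos)
    for (b in c("A", "C", "G", "T")) {
      keep <- cur != b
      if (!any(keep)) next
      keys <- c(keys, paste0(pre[keep], b, post[keep]))
      gids <- c(gids, guide_ids[keep])
    }
  }
  dup <- duplicated(paste(keys, gids))
  keys <- keys[!dup]; gids <- gids[!dup]
  exact <- keys %in% spacers
  keys <- keys[!exact]; gids <- gids[!exact]
  ambig <- unique(keys[duplicated(keys)])
  keep <- !(keys %in% ambig)
  list(keys = keys[keep], gids = gids[keep], ambiguous = ambig)
}

#' Count reads per library spacer with at most one mismatch
#'
#' Each read increments exactly one guide: its exact match if one exists,
#' otherwise its unique Hamming-distance-1 match. Reads with no match within
#' one substitution are unassigned; reads equidistant (distance 1) from two
#' or more spacers are ambiguous; reads shorter than the spacer (or missing,
#' \code{NA}) are malformed. Only substitutions are considered.
#'
#' The implementation indexes the 1-substitution neighbourhood of the
#' library and is behaviourally identical to an exhaustive Hamming search;
#' reads containing non-ACGT characters fall back to the exhaustive scan so
#' that ambiguity codes still count as ordinary mismatches.
#'
#' @param reads Character vector of extracted 20-nt read sequences.
#' @param library A \code{library_manifest}, a data frame with
#'   \code{guide_id} and \code{spacer}, or a named character vector of
#'   spacers (names = guide ids).
#' @param max_mismatch 0 (exact only) or 1.
#' @return A list with \code{counts} (named integer vector over all library
#'   guides) and \code{stats} (reads, assigned, unassigned, ambiguous,
#'   malformed).
#' @export
match_reads <- function(reads, library, max_mismatch = 1L) {
  stopifnot(max_mismatch %in% c(0L, 1L))
  if (inherits(library, "library_manifest") || is.data.frame(library)) {
    meta <- guide_meta(library)
    spacers <- toupper(meta$spacer); guide_ids <- meta$guide_id
  } else {
    spacers <- toupper(unname(library)); guide_ids <- names(library)
  }
  stopifnot(!is.null(guide_ids), all(nchar(spacers) == 20L))
  if (anyDuplicated(spacers))
    stop("library contains duplicated spacer sequences")
  reads <- toupper(reads)
  n_reads <- length(reads)
  counts <- stats::setNames(integer(length(guide_ids)), guide_ids)

  malformed <- is.na(reads) | nchar(reads) != 20L
  pending <- which(!malformed)
  assigned <- 0L; ambiguous <- 0L

  ex <- match(reads[pending], spacers)
  hit <- !is.na(ex)
  if (any(hit)) {
    t1 <- table(ex[hit])
    counts[as.integer(names(t1))] <- counts[as.integer(names(t1))] +
      as.integer(t1)
    assigned <- assigned + sum(hit)
  }
  pending <- pending[!hit]

  if (max_mismatch == 1L && length(pending) > 0L) {
    odd_idx <- pending[grepl("[^ACGT]", reads[pending])]
    reg_idx <- setdiff(pending, odd_idx)
    idx <- mismatch1_index(spacers, guide_ids)
    r <- reads[reg_idx]
    m <- match(r, idx$keys)
    hit <- !is.na(m)
    if (any(hit)) {
      t1 <- table(idx$gids[m[hit]])
      counts[names(t1)] <- counts[names(t1)] + as.integer(t1)
      assigned <- assigned + sum(hit)
    }
    ambiguous <- ambiguous + sum(r %in% idx$ambiguous)
    # exhaustive fallback for reads with non-ACGT characters, which can
    # still sit at Hamming distance 1 from a spacer
    if (length(odd_idx) > 0L) {
      sp_mat <- matrix(unlist(strsplit(spacers, "")), nrow = 20L)
      for (i in odd_idx) {
        d <- colSums(sp_mat != strsplit(reads[i], "")[[1]])
        best <- which(d == min(d))
        if (min(d) > 1L) next
        if (length(best) == 1L) {
          counts[best] <- counts[best] + 1L
          assigned <- assigned + 1L
        } else {
          ambiguous <- ambiguous + 1L
        }
      }
    }
  }
  unassigned <- n_reads - assigned - ambiguous - sum(malformed)
  list(counts = counts,
       stats = list(reads = n_reads, assigned = assigned,
                    unassigned = unassigned, ambiguous = ambiguous,
                    malformed = sum(malformed)))
}

#' Count a set of samples into a guide x sample matrix
#'
#' @param read_sets Named list: one character vector of extracted reads (or
#'   a FASTQ file path) per sample.
#' @param library Guide library (see \code{\link{match_reads}}).
#' @param max_mismatch Passed to \code{\link{match_reads}}.
#' @return List with \code{counts} (integer matrix) and per-sample
#'   \code{stats}.
#' @export
count_samples <- function(read_sets, library, max_mismatch = 1L) {
  stopifnot(is.list(read_sets), !is.null(names(read_sets)))
  res <- lapply(read_sets, function(r) {
    if (length(r) == 1L && !is.na(r) && file.exists(r)) r <- read_fastq(r)
    match_reads(r, library, max_mismatch)
  })
  counts <- do.call(cbind, lapply(res, `[[`, "counts"))
  colnames(counts) <- names(read_sets)
  list(counts = counts, stats = lapply(res, `[[`, "stats"))
}

#' Log2 read frequencies with a unit pseudocount
#'
#' \code{f = log2((count + 1) / total)} per guide per sample, where
#' \code{total} is that sample's column sum of assigned reads.
#'
#' @param counts Integer matrix (guides x samples) with row and column
#'   names.
#' @return Numeric matrix of the same shape.
#' @export
log_frequency <- function(counts) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero))
    stop("sample ", paste(colnames(counts)[zero], collapse = ", "),
         " has zero assigned reads")
  log2(sweep(counts + 1, 2L, totals, "/"))
}
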