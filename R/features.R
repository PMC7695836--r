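# Fixed 5' leader of the expressed sgRNA (approximate transcription start
# of the tetO-RPR1 cassette) and the constant S. pyogenes scaffold through
# the terminator; the folding substrate is leader + spacer + scaffold.
SGRNA_LEADER <- "GTCCCTATCAGTGATAGAGA"
SGRNA_SCAFFOLD <- paste0("GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTAT",
                         "CAACTTGAAAAAGTGGCACCGAGTCGGTGCTTTTTTCTCGAG")

#' Full sgRNA transcript sequence for a spacer
#'
#' @param spacer 20-nt spacer sequence(s).
#' @return Character vector: fixed 5' leader + spacer + scaffold.
#' @export
sgrna_sequence <- function(spacer) {
  paste0(SGRNA_LEADER, toupper(spacer), SGRNA_SCAFFOLD)
}

#' RNAfold-based folding backend
#'
#' Returns a function mapping sequences to minimum free energies
#' (kcal/mol) by invoking the ViennaRNA \code{RNAfold} executable. Use as
#' the \code{folding_backend} of \code{\link{extract_features}}; any
#' function with the same signature (character vector in, numeric vector
#' out) can stand in.
#'
#' @param exe Path to the RNAfold executable.
#' @return A function \code{function(sequences) -> numeric}.
#' @export
rnafold_backend <- function(exe = "RNAfold") {
  if (Sys.which(exe) == "" && !file.exists(exe))
    stop("RNAfold executable not found: ", exe)
  function(sequences) {
    out <- system2(exe, args = "--noPS", input = as.character(sequences),
                   stdout = TRUE)
    m <- regmatches(out, regexpr("\\(\\s*(-?[0-9.]+)\\)\\s*$", out))
    vals <- as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
    if (length(vals) != length(sequences))
      stop("RNAfold returned ", length(vals), " energies for ",
           length(sequences), " sequences")
    vals
  }
}

# 40-nt genomic context on the protospacer strand: 10 nt 5' of the spacer,
# the 20-nt spacer, and 10 nt 3' (beginning with the PAM). Positions past a
# contig end are padded with N.
guide_context <- function(guides, genome, flank = 10L) {
  genome <- as_genome(genome)
  n <- nrow(guides)
  out <- character(n)
  for (contig in unique(guides$chrom)) {
    idx <- which(guides$chrom == contig)
    seq <- genome[[contig]]
    L <- nchar(seq)
    p <- guides$pam_position[idx]
    plus <- guides$pam_strand[idx] == "+"
    # plus: top span (p-30)..(p+9); minus: (p-9)..(p+30), for flank = 10
    from <- ifelse(plus, p - 20L - flank, p - flank + 1L)
    to <- ifelse(plus, p + flank - 1L, p + 20L + flank)
    pad_l <- pmax(1L - from, 0L)
    pad_r <- pmax(to - L, 0L)
    raw <- substring(seq, pmax(from, 1L), pmin(to, L))
    raw <- paste0(strrep("N", pad_l), raw, strrep("N", pad_r))
    raw[!plus] <- revcomp(raw[!plus])
    out[idx] <- raw
  }
  out
}

#' Build the guide feature matrix for efficacy modelling
#'
#' Features per guide-gene record: absolute TSS distance and its sign;
#' nucleosome occupancy; PAM-strand flag; spacer GC fraction; longest
#' homopolymer run per base; one-hot mono-nucleotide indicators at each of
#' the 40 context positions (10 nt upstream, the 20-nt target, 10 nt
#' downstream on the protospacer strand); one-hot di-nucleotide indicators
#' at each adjacent position pair; and, when a folding backend is supplied,
#' the folding free energy of the full sgRNA transcript (fixed 5' leader +
#' spacer + scaffold). Without a backend the energy column is omitted with
#' a warning. Context positions falling off a contig end are padded with N
#' (all-zero one-hots) and flagged.
#'
#' @param guides Data frame of guide-gene records (needs \code{spacer},
#'   \code{chrom}, \code{pam_position}, \code{pam_strand},
#'   \code{distance_to_tss}, \code{pam_same_strand_as_gene},
#'   \code{nucleosome_score}).
#' @param genome Named character vector of contigs.
#' @param folding_backend \code{NULL} or a function mapping sequences to
#'   free energies (see \code{\link{rnafold_backend}}).
#' @param flank Context flank in nt (default 10).
#' @return Numeric feature matrix with attributes \code{feature_groups}
#'   (named list of column groups for contribution reporting),
#'   \code{context} (n x 40 character matrix) and \code{padded} (logical).
#' @export
extract_features <- function(guides, genome, folding_backend = NULL,
                             flank = 10L) {
  n <- nrow(guides)
  stopifnot(n > 0L)
  spacer <- toupper(guides$spacer)
  bases <- c("A", "C", "G", "T")

  gc <- (nchar(spacer) - nchar(gsub("[GC]", "", spacer))) / nchar(spacer)
  runs <- vapply(bases, function(b) {
    m <- gregexpr(paste0(b, "+"), spacer)
    vapply(m, function(x) {
      if (x[1] == -1L) 0L else max(attr(x, "match.length"))
    }, integer(1))
  }, integer(n))
  runs <- matrix(runs, nrow = n,
                 dimnames = list(NULL, paste0("run_", bases)))

  ctx <- guide_context(guides, genome, flank = flank)
  width <- 2L * flank + 20L
  C <- matrix(unlist(strsplit(ctx, "")), nrow = n, byrow = TRUE)
  padded <- rowSums(C == "N") > 0L
  if (any(padded))
    warning(sum(padded), " guide(s) within ", flank,
            " nt of a contig end; context padded with N")

  mono <- matrix(0, n, width * 4L)
  colnames(mono) <- paste0("mono_", rep(sprintf("%02d", seq_len(width)),
                                        each = 4L), "_", bases)
  for (j in seq_len(width)) for (b in seq_along(bases))
    mono[, (j - 1L) * 4L + b] <- as.numeric(C[, j] == bases[b])

  dinucs <- as.vector(outer(bases, bases, paste0))
  D <- matrix(paste0(C[, -width], C[, -1L]), nrow = n)
  di <- matrix(0, n, (width - 1L) * 16L)
  colnames(di) <- paste0("di_", rep(sprintf("%02d", seq_len(width - 1L)),
                                    each = 16L), "_",
                         rep(dinucs, width - 1L))
  for (j in seq_len(width - 1L)) for (b in seq_along(dinucs))
    di[, (j - 1L) * 16L + b] <- as.numeric(D[, j] == dinucs[b])

  X <- cbind(dist_abs = abs(guides$distance_to_tss),
             dist_sign = sign(guides$distance_to_tss),
             nucleosome_score = guides$nucleosome_score,
             pam_same_strand = as.numeric(guides$pam_same_strand_as_gene),
             gc = gc, runs, mono, di)
  groups <- list(distance = c("dist_abs", "dist_sign"),
                 nucleosome = "nucleosome_score",
                 strand = "pam_same_strand",
                 sequence = c("gc", colnames(runs), colnames(mono),
                              colnames(di)))
  if (!is.null(folding_backend)) {
    X <- cbind(X, delta_g = folding_backend(sgrna_sequence(spacer)))
    groups$energy <- "delta_g"
  } else {
    warning("no folding backend supplied; sgRNA folding free energy ",
            "feature omitted")
  }
  rownames(X) <- guides$guide_id
  attr(X, "feature_groups") <- groups
  attr(X, "context") <- C
  attr(X, "padded") <- padded
  X
}
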