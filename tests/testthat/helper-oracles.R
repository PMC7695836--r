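# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive results through different code
# paths than the package implementation.

# Gene-score rule, restated independently: sort descending, compare the
# mean of the first three against the mean of the last three by absolute
# value (ties -> the depletion side); three or fewer guides -> plain mean.
oracle_gene_score <- function(s) {
  s <- sort(s, decreasing = TRUE)
  n <- length(s)
  if (n <= 3) return(mean(s))
  top <- mean(s[1:3])
  bottom <- mean(s[(n - 2):n])
  if (abs(top) > abs(bottom)) top else bottom
}

# One-hot encoding of 20-nt sequences (A/C/G/T; anything else, e.g. N,
# encodes to all-zero and therefore mismatches every base).
onehot20 <- function(seqs) {
  ch <- matrix(unlist(strsplit(seqs, "")), ncol = 20L, byrow = TRUE)
  out <- matrix(0, length(seqs), 80L)
  bases <- c("A", "C", "G", "T")
  for (p in 1:20) for (b in 1:4)
    out[, (p - 1L) * 4L + b] <- as.numeric(ch[, p] == bases[b])
  out
}

# Exhaustive Hamming-distance matcher: every read against every spacer,
# distances via one-hot inner products, same assignment contract as
# match_reads (exact first, else unique distance-1, equal ties ambiguous).
oracle_match_counts <- function(reads, spacers, guide_ids,
                                block = 10000L) {
  counts <- stats::setNames(integer(length(spacers)), guide_ids)
  stats <- c(reads = length(reads), assigned = 0L, unassigned = 0L,
             ambiguous = 0L, malformed = 0L)
  malformed <- is.na(reads) | nchar(reads) != 20L
  stats["malformed"] <- sum(malformed)
  idx <- which(!malformed)
  S <- t(onehot20(spacers))
  for (start in seq(1L, length(idx), by = block)) {
    rows <- idx[start:min(start + block - 1L, length(idx))]
    D <- 20 - onehot20(reads[rows]) %*% S
    n0 <- rowSums(D == 0)
    n1 <- rowSums(D == 1)
    arg <- max.col(-D, ties.method = "first")
    assign <- (n0 == 1L) | (n0 == 0L & n1 == 1L)
    amb <- n0 == 0L & n1 >= 2L
    if (any(assign)) {
      t1 <- table(arg[assign])
      counts[as.integer(names(t1))] <- counts[as.integer(names(t1))] +
        as.integer(t1)
    }
    stats["assigned"] <- stats["assigned"] + sum(assign)
    stats["ambiguous"] <- stats["ambiguous"] + sum(amb)
  }
  stats["unassigned"] <- stats["reads"] - stats["assigned"] -
    stats["ambiguous"] - stats["malformed"]
  list(counts = counts, stats = as.list(stats))
}

# Exhaustive regular-expression PAM scan of both strands: returns the set
# of "pos:strand" keys of every NGG whose 20-nt spacer fits in the contig.
oracle_pam_scan <- function(seq) {
  L <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  plus <- integer(0); minus <- integer(0)
  for (p in seq_len(L)) {
    if (p >= 21L && p + 2L <= L && ch[p + 1L] == "G" && ch[p + 2L] == "G")
      plus <- c(plus, p)
    if (p - 2L >= 1L && p + 20L <= L && ch[p - 2L] == "C" &&
        ch[p - 1L] == "C")
      minus <- c(minus, p)
  }
  c(paste0(plus, ":+"), paste0(minus, ":-"))
}

random_spacers <- function(n, seed = 1) {
  withr::with_seed(seed, {
    unique(vapply(seq_len(n * 2), function(i)
      paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
            collapse = ""), character(1)))[seq_len(n)]
  })
}

mutate_reads <- function(spacers, n, n_mut = 1, seed = 1, alphabet = NULL) {
  alphabet <- alphabet %||% c("A", "C", "G", "T")
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      ch <- strsplit(sample(spacers, 1), "")[[1]]
      pos <- sample(20, n_mut)
      ch[pos] <- sample(alphabet, n_mut, replace = TRUE)
      paste(ch, collapse = "")
    }, character(1))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A minimal candidate table for selection tests (no genome needed).
make_candidates <- function(gene_id, n, nuc, dist = NULL, shared_with = NULL,
                            prefix = gene_id) {
  dist <- dist %||% seq(10, 10 + 5 * (n - 1), by = 5)
  data.frame(guide_key = paste0(prefix, "_k", seq_len(n)),
             chrom = "chr1",
             spacer = random_spacers(n, seed = nchar(prefix) + n),
             pam_position = seq_len(n) * 30L,
             pam_strand = "+",
             gene_id = gene_id,
             distance_to_tss = dist,
             pam_same_strand_as_gene = TRUE,
             n_target_genes = 1L,
             nucleosome_score = nuc,
             stringsAsFactors = FALSE)
}
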