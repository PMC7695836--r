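`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed for an independent random stream
#'
#' One user-facing seed governs genome construction, ground truth and
#' sequencing noise through separate derived streams, so regenerating one
#' component does not perturb the others.
#'
#' @param seed Integer master seed.
#' @param stream Integer stream index.
#' @return An integer seed below 2^31.
#' @keywords internal
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + stream * 7919) %% 2147483629)
}

with_stream <- function(seed, stream, code) {
  withr::with_seed(derive_seed(seed, stream), code)
}

#' Random DNA sequence with a given GC content
#' @param n Length in bp.
#' @param gc Fraction of G+C in \[0, 1\].
#' @return A single character string.
#' @keywords internal
random_dna <- function(n, gc = 0.38) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Reverse complement of DNA strings
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# Normalise a genome argument to a named character vector of contigs.
as_genome <- function(genome) {
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  stopifnot(is.character(genome), length(genome) >= 1L)
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  toupper(genome)
}
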