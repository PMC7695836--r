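#' Read and write screen data files
#'
#' Plain-text interchange for every artefact of the pipeline: genome FASTA,
#' gene models as GFF3 (1-based, inclusive) or BED (0-based, half-open),
#' nucleosome bedGraph, guide-library TSV, count-table TSV and simulation
#' configs as YAML/JSON. Standard formats are handled by Biostrings and
#' rtracklayer.
#'
#' @name screen_io
NULL

#' @rdname screen_io
#' @param genome Named character vector of contigs.
#' @param path Output file path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(as_genome(genome)),
                              path)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname screen_io
#' @param reads_path FASTQ file path (optionally gzipped).
#' @export
read_fastq <- function(reads_path) {
  as.character(Biostrings::readDNAStringSet(reads_path, format = "fastq"))
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom %||% "chr1",
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand,
    ID = genes$gene_id, Name = genes$gene_id, type = "gene")
}

#' @rdname screen_io
#' @param genes Gene-model data frame.
#' @export
write_genes_gff3 <- function(genes, path) {
  rtracklayer::export(genes_to_granges(genes), path, format = "gff3")
  invisible(path)
}

#' @rdname screen_io
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- data.frame(
    gene_id = gr$ID %||% gr$Name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes
}

#' @rdname screen_io
#' @export
write_genes_bed <- function(genes, path) {
  gr <- genes_to_granges(genes)
  names(gr) <- genes$gene_id
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname screen_io
#' @param track Numeric vector of per-position scores.
#' @param chrom Contig name.
#' @export
write_nucleosome_bedgraph <- function(track, path, chrom = "chr1") {
  r <- rle(track)
  ends <- cumsum(r$lengths)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = ends - r$lengths + 1L, end = ends),
    score = r$values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname screen_io
#' @export
read_nucleosome_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  len <- max(GenomicRanges::end(gr))
  track <- rep(NA_real_, len)
  for (i in seq_along(gr)) {
    track[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <-
      gr$score[i]
  }
  track
}

#' @rdname screen_io
#' @param library A \code{library_manifest} or guides data frame.
#' @export
write_library_tsv <- function(library, path) {
  guides <- if (inherits(library, "library_manifest")) library$guides else library
  utils::write.table(guides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_library_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @rdname screen_io
#' @export
write_spacer_fasta <- function(library, path) {
  meta <- guide_meta(library)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(meta$spacer, meta$guide_id)),
    path)
  invisible(path)
}

#' @rdname screen_io
#' @param counts Count matrix (guides x samples).
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(guide_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_count_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$guide_id
  storage.mode(m) <- "integer"
  m
}

#' @rdname screen_io
#' @param config A \code{\link{simulation_config}}.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_config_yaml <- function(path) {
  do.call(simulation_config, yaml::read_yaml(path))
}

#' Write all artefacts of a simulated screen to a directory
#'
#' Emits genome FASTA, gene models (GFF3 and BED), nucleosome bedGraph,
#' library TSV and spacer FASTA, count TSV, sample sheet, ground-truth TSV
#' and the config as YAML.
#'
#' @param sim A \code{\link{simulate_screen}} result.
#' @param outdir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "crispri_simulation"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(outdir, "genome.fa"))
  write_genes_gff3(sim$genes, file.path(outdir, "genes.gff3"))
  write_genes_bed(sim$genes, file.path(outdir, "genes.bed"))
  write_nucleosome_bedgraph(sim$nucleosome,
                            file.path(outdir, "nucleosome.bedgraph"))
  write_library_tsv(sim$library, file.path(outdir, "library.tsv"))
  write_spacer_fasta(sim$library, file.path(outdir, "spacers.fa"))
  write_count_table(sim$counts, file.path(outdir, "counts.tsv"))
  utils::write.table(sim$samples, file.path(outdir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$guides, file.path(outdir, "truth_guides.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, file.path(outdir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_config_yaml(sim$config, file.path(outdir, "config.yaml"))
  invisible(outdir)
}
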