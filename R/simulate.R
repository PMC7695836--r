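#' Configuration for a synthetic CRISPRi screen
#'
#' Bundles and validates all tunable parameters of the synthetic-screen
#' generator. Defaults emulate a single 24 h outgrowth of a pooled yeast
#' CRISPRi library: roughly 6 guides per gene after design, 500 scrambled
#' non-targeting controls, an average of 450 reads per library member and
#' three induced/uninduced replicate pairs, with guide efficacy peaking
#' 50 bp upstream of the TSS and falling off with nucleosome occupancy.
#'
#' @param n_genes Number of protein-coding genes to place on the synthetic
#'   chromosome.
#' @param genome_gc GC content of the genome in \[0, 1\].
#' @param gene_length Length of each gene body in bp.
#' @param intergenic_length Length of intergenic blocks in bp.
#' @param n_divergent_pairs Number of divergent gene pairs sharing a single
#'   intergenic region (their promoter windows overlap, so guides there can
#'   target both genes).
#' @param pam_density_floor Minimum number of candidate PAM-adjacent 20-mers
#'   required in every promoter window (0-200 bp upstream of the TSS).
#' @param frac_sensitive Fraction of genes that are dosage sensitive
#'   (nonzero fitness effect upon knockdown).
#' @param effect_size Fitness cost, in log2 units per unit guide efficacy,
#'   of knocking down a sensitive gene.
#' @param efficacy_peak_bp Distance upstream of the TSS (bp) at which the
#'   positional efficacy weight is maximal.
#' @param efficacy_window_bp Upstream distance at which the positional
#'   weight falls back to zero.
#' @param tau Effective number of doublings of induced outgrowth; the
#'   expected guide depletion is \code{-effect * efficacy * tau} log2 units.
#' @param depth_per_guide Mean sequencing reads per guide per sample.
#' @param n_replicates Number of induced/uninduced replicate pairs.
#' @param abundance_sigma Log-normal sigma of baseline guide abundances
#'   (library bottlenecking; unequal representation without changing
#'   expected depletion scores).
#' @param overdispersion Optional extra-multinomial noise; 0 gives pure
#'   multinomial sampling, larger values mix in Dirichlet-style jitter of
#'   the sampling probabilities with that coefficient of variation.
#' @param n_scrambled Number of scrambled non-targeting control guides.
#' @param seed Integer master seed; identical seeds give byte-identical
#'   outputs end-to-end.
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_genes = 500, genome_gc = 0.38,
                              gene_length = 500, intergenic_length = 300,
                              n_divergent_pairs = 0, pam_density_floor = 6,
                              frac_sensitive = 0.1, effect_size = 2,
                              efficacy_peak_bp = 50, efficacy_window_bp = 200,
                              tau = 1, depth_per_guide = 450,
                              n_replicates = 3, abundance_sigma = 0.5,
                              overdispersion = 0, n_scrambled = 500,
                              seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), genome_gc = genome_gc,
              gene_length = as.integer(gene_length),
              intergenic_length = as.integer(intergenic_length),
              n_divergent_pairs = as.integer(n_divergent_pairs),
              pam_density_floor = as.integer(pam_density_floor),
              frac_sensitive = frac_sensitive, effect_size = effect_size,
              efficacy_peak_bp = efficacy_peak_bp,
              efficacy_window_bp = efficacy_window_bp, tau = tau,
              depth_per_guide = depth_per_guide,
              n_replicates = as.integer(n_replicates),
              abundance_sigma = abundance_sigma,
              overdispersion = overdispersion,
              n_scrambled = as.integer(n_scrambled), seed = seed)
  stopifnot(cfg$n_genes >= 0L, cfg$gene_length > 0L,
            cfg$intergenic_length > 0L, cfg$n_divergent_pairs >= 0L,
            cfg$pam_density_floor >= 0L,
            cfg$genome_gc > 0, cfg$genome_gc < 1,
            cfg$frac_sensitive >= 0, cfg$frac_sensitive <= 1,
            cfg$effect_size >= 0, cfg$efficacy_peak_bp > 0,
            cfg$efficacy_window_bp > cfg$efficacy_peak_bp,
            cfg$tau > 0, cfg$depth_per_guide > 0, cfg$n_replicates >= 1L,
            cfg$abundance_sigma >= 0, cfg$overdispersion >= 0,
            cfg$n_scrambled >= 0L)
  structure(cfg, class = "simulation_config")
}

#' Positional efficacy weight of a CRISPRi guide
#'
#' Triangular weight over the distance between the PAM and the TSS:
#' zero at the TSS, maximal at \code{peak} bp upstream, and back to zero at
#' \code{width} bp upstream. Distances outside \[0, width\] get weight 0.
#'
#' @param distance Signed distance to the TSS in bp (positive = upstream).
#' @param peak Distance of maximal weight.
#' @param width Upstream distance where the weight reaches zero.
#' @return Numeric weights in \[0, 1\].
#' @export
positional_weight <- function(distance, peak = 50, width = 200) {
  w <- ifelse(distance < 0 | distance > width, 0,
              ifelse(distance <= peak, distance / peak,
                     (width - distance) / (width - peak)))
  w[is.na(distance)] <- 0
  w
}

#' Simulate a toy genome with gene models and a nucleosome track
#'
#' Lays out non-overlapping genes separated by intergenic blocks on a single
#' synthetic chromosome, optionally including divergent gene pairs that share
#' one intergenic region. Every promoter window (0-200 bp upstream of the
#' TSS) is guaranteed to contain at least \code{pam_density_floor} candidate
#' PAM-adjacent 20-mers; failing windows are locally redrawn, and an error is
#' raised if the geometry cannot satisfy the floor. A smooth nucleosome
#' occupancy track in \[0, 1\] is generated alongside.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A list with elements \code{genome} (named character vector of one
#'   contig), \code{genes} (data frame with \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{tss}, \code{pair_id}) and
#'   \code{nucleosome} (numeric vector, one score per genome position).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_stream(config$seed, 1L, .simulate_genome(config))
}

.simulate_genome <- function(cfg) {
  window <- c(0L, as.integer(cfg$efficacy_window_bp))
  if (cfg$pam_density_floor > 2L * (window[2] + 1L))
    stop("infeasible geometry: pam_density_floor exceeds the number of ",
         "positions in the promoter window")
  if (cfg$n_genes > 0L && cfg$intergenic_length < 40L)
    stop("infeasible geometry: intergenic_length too small for ",
         "pam_density_floor (promoter windows need designable sequence)")

  n_pairs <- min(cfg$n_divergent_pairs, cfg$n_genes %/% 2L)
  n_single <- cfg$n_genes - 2L * n_pairs

  # Block plan: alternating intergenic and gene blocks. Divergent pairs are
  # laid out as <-geneA | shared intergenic | geneB->, then singles with
  # random strand.
  blocks <- list()
  add <- function(type, len, gene_id = NA_character_, strand = NA_character_,
                  pair_id = NA_integer_) {
    blocks[[length(blocks) + 1L]] <<- list(type = type, len = as.integer(len),
                                           gene_id = gene_id, strand = strand,
                                           pair_id = pair_id)
  }
  add("intergenic", cfg$intergenic_length)
  gi <- 0L
  if (n_pairs > 0L) for (p in seq_len(n_pairs)) {
    gi <- gi + 1L
    add("gene", cfg$gene_length, sprintf("gene%04d", gi), "-", p)
    add("intergenic", cfg$intergenic_length)
    gi <- gi + 1L
    add("gene", cfg$gene_length, sprintf("gene%04d", gi), "+", p)
    add("intergenic", cfg$intergenic_length)
  }
  if (n_single > 0L) for (s in seq_len(n_single)) {
    gi <- gi + 1L
    add("gene", cfg$gene_length, sprintf("gene%04d", gi),
        sample(c("+", "-"), 1L))
    add("intergenic", cfg$intergenic_length)
  }

  lens <- vapply(blocks, `[[`, integer(1), "len")
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  total <- ends[length(ends)]
  seqs <- vapply(lens, random_dna, character(1), gc = cfg$genome_gc)

  is_gene <- vapply(blocks, function(b) b$type == "gene", logical(1))
  genes <- data.frame(
    gene_id = vapply(blocks[is_gene], `[[`, character(1), "gene_id"),
    chrom = rep("chr1", sum(is_gene)),
    start = starts[is_gene], end = ends[is_gene],
    strand = vapply(blocks[is_gene], `[[`, character(1), "strand"),
    pair_id = vapply(blocks[is_gene], `[[`, integer(1), "pair_id"),
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  if (nrow(genes) == 0L) genes$tss <- integer(0)

  count_in_range <- function(sorted_pos, lo, hi) {
    findInterval(hi, sorted_pos) - findInterval(lo - 1L, sorted_pos)
  }

  if (cfg$n_genes > 0L && cfg$pam_density_floor > 0L) {
    lo <- ifelse(genes$strand == "+", genes$tss - window[2],
                 genes$tss + window[1])
    hi <- ifelse(genes$strand == "+", genes$tss - window[1],
                 genes$tss + window[2])
    for (attempt in seq_len(25L)) {
      genome_str <- paste(seqs, collapse = "")
      sites <- pam_sites(genome_str)
      counts <- count_in_range(sites$plus, lo, hi) +
        count_in_range(sites$minus, lo, hi)
      failing <- which(counts < cfg$pam_density_floor)
      if (length(failing) == 0L) break
      if (attempt == 25L)
        stop("infeasible geometry: could not place ", cfg$pam_density_floor,
             " candidate PAMs in every promoter window; intergenic_length (",
             cfg$intergenic_length, " bp) or genome_gc (", cfg$genome_gc,
             ") is too small for pam_density_floor")
      # redraw every block overlapping a failing promoter window (plus the
      # 22 bp spacer overhang on each side)
      redraw <- rep(FALSE, length(blocks))
      for (g in failing) {
        if (genes$strand[g] == "+") {
          span <- c(genes$tss[g] - window[2] - 22L, genes$tss[g] + 22L)
        } else {
          span <- c(genes$tss[g] - 22L, genes$tss[g] + window[2] + 22L)
        }
        redraw <- redraw | (starts <= span[2] & ends >= span[1])
      }
      seqs[redraw] <- vapply(lens[redraw], random_dna, character(1),
                             gc = cfg$genome_gc)
    }
  }
  genome_str <- paste(seqs, collapse = "")

  # smooth nucleosome occupancy: uniform knots every 25 bp, linear interp,
  # attenuated over promoters to emulate the nucleosome-depleted regions
  # upstream of yeast TSSs (CRISPRi libraries draw their guides from
  # accessible promoter DNA, so in-library nucleosome scores sit low)
  knots <- seq(1L, total + 25L, by = 25L)
  vals <- stats::runif(length(knots))
  nuc <- stats::approx(knots, vals, xout = seq_len(total), rule = 2)$y
  if (nrow(genes) > 0L) {
    atten <- rep(1, total)
    ndr <- window[2] + 20L
    for (i in seq_len(nrow(genes))) {
      if (genes$strand[i] == "+") {
        span <- c(genes$tss[i] - ndr, genes$tss[i] + 20L)
      } else {
        span <- c(genes$tss[i] - 20L, genes$tss[i] + ndr)
      }
      span <- pmin(pmax(span, 1L), total)
      atten[span[1]:span[2]] <- pmin(atten[span[1]:span[2]], 0.3)
    }
    nuc <- nuc * atten
  }
  nuc <- pmin(pmax(nuc, 0), 1)

  list(genome = c(chr1 = genome_str), genes = genes, nucleosome = nuc)
}

#' Assign ground-truth effects and guide efficacies to a designed library
#'
#' A random subset of genes (fraction \code{frac_sensitive}) is made dosage
#' sensitive with fitness effect \code{effect_size} log2 units. Each
#' guide-gene pair gets efficacy \code{w(d) * (1 - nucleosome_score)}, where
#' \code{w} is the triangular positional weight (\code{\link{positional_weight}}).
#' The expected log2 depletion of a guide is
#' \code{-tau * sum(effect_g * efficacy_g)} over its target genes; scrambled
#' guides have efficacy 0 and expected depletion 0.
#'
#' @param library A \code{library_manifest} (see \code{\link{design_library}})
#'   or its \code{guides} data frame.
#' @param config A \code{\link{simulation_config}}.
#' @return A list with \code{genes} (gene_id, effect, sensitive),
#'   \code{pairs} (guide_id, gene_id, efficacy) and \code{guides}
#'   (guide_id, scrambled, efficacy, expected_depletion).
#' @export
simulate_truth <- function(library, config) {
  stopifnot(inherits(config, "simulation_config"))
  guides <- if (inherits(library, "library_manifest")) library$guides else library
  with_stream(config$seed, 2L, .simulate_truth(guides, config))
}

.simulate_truth <- function(guides, cfg) {
  targeting <- guides[!guides$scrambled, , drop = FALSE]
  gene_ids <- sort(unique(targeting$gene_id))
  n_sens <- round(cfg$frac_sensitive * length(gene_ids))
  sensitive <- if (n_sens > 0L) sample(gene_ids, n_sens) else character(0)
  genes <- data.frame(gene_id = gene_ids,
                      effect = ifelse(gene_ids %in% sensitive,
                                      cfg$effect_size, 0),
                      sensitive = gene_ids %in% sensitive,
                      stringsAsFactors = FALSE)

  pairs <- data.frame(guide_id = targeting$guide_id,
                      gene_id = targeting$gene_id,
                      efficacy = positional_weight(targeting$distance_to_tss,
                                                   cfg$efficacy_peak_bp,
                                                   cfg$efficacy_window_bp) *
                        (1 - targeting$nucleosome_score),
                      stringsAsFactors = FALSE)

  eff <- genes$effect[match(pairs$gene_id, genes$gene_id)]
  dep <- tapply(-cfg$tau * eff * pairs$efficacy, pairs$guide_id, sum)
  eff_max <- tapply(pairs$efficacy, pairs$guide_id, max)

  all_ids <- unique(guides$guide_id)
  scram <- tapply(guides$scrambled, guides$guide_id, any)[all_ids]
  out <- data.frame(guide_id = all_ids, scrambled = as.logical(scram),
                    efficacy = ifelse(scram, 0, eff_max[all_ids]),
                    expected_depletion = ifelse(scram, 0, dep[all_ids]),
                    stringsAsFactors = FALSE)
  out$efficacy[is.na(out$efficacy)] <- 0
  out$expected_depletion[is.na(out$expected_depletion)] <- 0
  rownames(out) <- NULL
  list(genes = genes, pairs = pairs, guides = out)
}

#' Simulate induced/uninduced screen count tables
#'
#' Baseline guide abundances are drawn log-normally (library bottlenecking).
#' Uninduced samples sample guides proportionally to baseline abundance;
#' induced samples scale each guide's abundance by
#' \code{2^expected_depletion} before renormalising. Each sample draws a
#' multinomial of size \code{depth_per_guide * n_guides}, optionally with
#' extra-multinomial jitter.
#'
#' @param library A \code{library_manifest} or guides data frame (used for
#'   the guide universe and scrambled flags).
#' @param truth Output of \code{\link{simulate_truth}} (or its \code{guides}
#'   data frame with \code{guide_id} and \code{expected_depletion}).
#' @param config A \code{\link{simulation_config}}.
#' @return A list with \code{counts} (integer matrix, guides x samples),
#'   \code{samples} (data frame: sample_id, condition, replicate) and
#'   \code{truth}.
#' @export
simulate_screen_counts <- function(library, truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  guides <- if (inherits(library, "library_manifest")) library$guides else library
  tg <- if (!is.null(truth$guides)) truth$guides else truth
  ids <- unique(guides$guide_id)
  if (length(ids) == 0L) stop("empty guide library")
  dep <- tg$expected_depletion[match(ids, tg$guide_id)]
  if (anyNA(dep)) stop("truth is missing expected depletion for some guides")
  with_stream(config$seed, 3L, {
    n <- length(ids)
    a <- stats::rlnorm(n, 0, config$abundance_sigma)
    p0 <- a / sum(a)
    p1 <- a * 2^(dep * 1)
    p1 <- p1 / sum(p1)
    depth <- round(config$depth_per_guide * n)
    samples <- data.frame(
      sample_id = c(t(outer(c("uninduced", "induced"),
                            seq_len(config$n_replicates), paste, sep = "_"))),
      condition = rep(c("uninduced", "induced"), config$n_replicates),
      replicate = rep(seq_len(config$n_replicates), each = 2L),
      stringsAsFactors = FALSE)
    counts <- matrix(0L, n, nrow(samples),
                     dimnames = list(ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      p <- if (samples$condition[j] == "induced") p1 else p0
      if (config$overdispersion > 0) {
        shape <- 1 / config$overdispersion^2
        p <- p * stats::rgamma(n, shape = shape, rate = shape)
        p <- p / sum(p)
      }
      counts[, j] <- stats::rmultinom(1L, depth, p)[, 1L]
    }
    list(counts = counts, samples = samples, truth = truth)
  })
}

#' Simulate a complete synthetic CRISPRi screen
#'
#' Orchestrates genome construction, guide-library design on that genome
#' (top-6 selection by nucleosome score in the promoter window, plus
#' scrambled controls), ground-truth assignment and count-table generation,
#' all driven by one master seed through independent derived streams.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A list of class \code{crispri_simulation} with \code{config},
#'   \code{genome}, \code{genes}, \code{nucleosome}, \code{library},
#'   \code{truth}, \code{counts} and \code{samples}.
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  gen <- simulate_genome(config)
  lib <- design_library(gen$genome, gen$genes, gen$nucleosome,
                        n_scrambled = config$n_scrambled,
                        seed = derive_seed(config$seed, 4L))
  truth <- simulate_truth(lib, config)
  cnt <- simulate_screen_counts(lib, truth, config)
  structure(list(config = config, genome = gen$genome, genes = gen$genes,
                 nucleosome = gen$nucleosome, library = lib, truth = truth,
                 counts = cnt$counts, samples = cnt$samples),
            class = "crispri_simulation")
}
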