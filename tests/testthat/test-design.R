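test_that("a single in-window AGG yields exactly one candidate", {
  # AT background carries no GG/CC; one AGG is planted with its N at 60
  seq <- paste(rep("AT", 50), collapse = "")
  substr(seq, 60, 62) <- "AGG"
  genes <- data.frame(gene_id = "geneA", strand = "+", tss = 100,
                      stringsAsFactors = FALSE)
  cand <- enumerate_candidates(c(chr1 = seq), genes)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$pam_position, 60)
  expect_equal(cand$pam_strand, "+")
  expect_equal(cand$distance_to_tss, 40)
  expect_equal(cand$spacer, substr(seq, 40, 59))
})

test_that("a sequence without GG or CC yields no candidates", {
  seq <- paste(rep("AT", 200), collapse = "")
  genes <- data.frame(gene_id = "geneA", strand = "+", tss = 300)
  expect_equal(nrow(enumerate_candidates(c(chr1 = seq), genes)), 0)
})

test_that("minus-strand PAMs are reported with the bottom-strand spacer", {
  seq <- paste(rep("AT", 50), collapse = "")
  substr(seq, 58, 60) <- "CCT"  # bottom-strand AGG with N at 60
  genes <- data.frame(gene_id = "geneA", strand = "+", tss = 100)
  cand <- enumerate_candidates(c(chr1 = seq), genes)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$pam_strand, "-")
  expect_equal(cand$pam_position, 60)
  expect_equal(cand$spacer, revcomp(substr(seq, 61, 80)))
  expect_false(cand$pam_same_strand_as_gene)
})

test_that("TSS outside the genome names the offending gene", {
  seq <- paste(rep("ATGC", 50), collapse = "")
  genes <- data.frame(gene_id = "geneBAD", strand = "+", tss = 999)
  expect_error(enumerate_candidates(c(chr1 = seq), genes), "geneBAD")
})

test_that("divergent genes annotate shared intergenic candidates twice", {
  withr::with_seed(9, seq <- random_dna(320, gc = 0.4))
  genes <- data.frame(gene_id = c("geneL", "geneR"),
                      strand = c("-", "+"), tss = c(40, 280))
  cand <- enumerate_candidates(c(chr1 = seq), genes)
  # interval-overlap oracle: a PAM at p serves both genes iff
  # 0 <= p - 40 <= 200 and 0 <= 280 - p <= 200
  shared_oracle <- with(cand[!duplicated(cand$guide_key), ],
                        pam_position >= 80 & pam_position <= 240)
  shared_pkg <- cand$n_target_genes[!duplicated(cand$guide_key)] == 2
  expect_gt(sum(shared_pkg), 0)
  expect_equal(shared_pkg, shared_oracle)
  two <- cand[cand$n_target_genes == 2, ]
  expect_true(all(table(two$guide_key) == 2))
})

test_that("candidate enumeration equals the exhaustive PAM scan", {
  cfg <- simulation_config(n_genes = 12, seed = 33)
  g <- simulate_genome(cfg)
  cand <- enumerate_candidates(g$genome, g$genes, window = c(-100, 400))
  keys_all <- oracle_pam_scan(g$genome[[1]])
  pos <- as.integer(sub(":.*", "", keys_all))
  strand <- sub(".*:", "", keys_all)
  expected <- character(0)
  for (i in seq_len(nrow(g$genes))) {
    d <- if (g$genes$strand[i] == "+") g$genes$tss[i] - pos
         else pos - g$genes$tss[i]
    keep <- d >= -100 & d <= 400
    expected <- union(expected, paste0(pos[keep], ":", strand[keep]))
  }
  got <- unique(paste0(cand$pam_position, ":", cand$pam_strand))
  expect_setequal(got, expected)
})

test_that("selection takes the six lowest nucleosome scores", {
  cand <- make_candidates("geneA", 10, nuc = (10:1) / 10)
  m <- select_guides(cand)
  expect_equal(m$gene_summary$n_guides, 6)
  expect_setequal(m$guides$guide_key, cand$guide_key[cand$nucleosome_score <= 0.6])
})

test_that("fewer candidates than the quota selects them all", {
  cand <- make_candidates("geneA", 4, nuc = c(0.1, 0.2, 0.3, 0.4))
  m <- select_guides(cand)
  expect_equal(m$gene_summary$n_guides, 4)
  expect_true(m$gene_summary$designable)
})

test_that("window widening recruits guides farther from the TSS", {
  cand <- rbind(make_candidates("geneA", 3, nuc = rep(0.1, 3),
                                dist = c(20, 60, 100)),
                make_candidates("geneA", 4, nuc = rep(0.2, 4),
                                dist = c(260, 300, 350, 390),
                                prefix = "far"))
  m <- select_guides(cand)
  expect_equal(m$gene_summary$n_guides, 6)
  expect_gte(m$gene_summary$window_stage, 2)
})

test_that("genes with no candidates are flagged not designable", {
  cand <- make_candidates("geneA", 2, nuc = c(0.1, 0.2))
  cand$gene_id <- "geneA"
  other <- make_candidates("geneB", 1, nuc = 0.5, dist = 3000,
                           prefix = "off")
  m <- select_guides(rbind(cand, other))
  gs <- m$gene_summary
  expect_false(gs$designable[gs$gene_id == "geneB"])
  expect_true(gs$designable[gs$gene_id == "geneA"])
})

test_that("shared-promoter genes gain up to six unique extras", {
  shared <- make_candidates("geneA", 6, nuc = (1:6) / 100, prefix = "sh")
  sharedB <- shared
  sharedB$gene_id <- "geneB"
  shared$n_target_genes <- sharedB$n_target_genes <- 2L
  uniqA <- make_candidates("geneA", 8, nuc = (7:14) / 100, prefix = "ua")
  uniqB <- make_candidates("geneB", 8, nuc = (7:14) / 100, prefix = "ub")
  m <- select_guides(rbind(shared, sharedB, uniqA, uniqB))
  expect_equal(sort(m$gene_summary$n_guides), c(12L, 12L))
  # the shared guides appear once each, annotated with both genes
  tab <- table(m$guides$guide_id)
  expect_equal(sum(tab == 2), 6)
})

test_that("selection is stable across repeated runs", {
  cfg <- simulation_config(n_genes = 10, seed = 17)
  g <- simulate_genome(cfg)
  cand <- enumerate_candidates(g$genome, g$genes, window = c(-100, 400))
  cand <- annotate_nucleosome(cand, g$nucleosome)
  m1 <- select_guides(cand)
  m2 <- select_guides(cand)
  expect_identical(m1$guides, m2$guides)
})

test_that("without shared promoters every gene gets exactly six guides", {
  # intergenic regions long enough that 200-bp windows cannot overlap
  cfg <- simulation_config(n_genes = 25, intergenic_length = 450,
                           seed = 19)
  g <- simulate_genome(cfg)
  lib <- design_library(g$genome, g$genes, g$nucleosome)
  expect_true(all(lib$gene_summary$n_guides == 6))
  expect_equal(median(lib$gene_summary$n_guides), 6)
  expect_true(all(lib$guides$n_target_genes == 1))
})

test_that("scrambled controls shuffle real spacers and avoid the genome", {
  withr::with_seed(4, genome <- c(chr1 = random_dna(2000, gc = 0.5)))
  spacers <- random_spacers(10, seed = 5)
  scr <- generate_scrambled_controls(spacers, genome, n = 3, seed = 6)
  expect_equal(nrow(scr), 3)
  both <- paste(c(genome, revcomp(genome)), collapse = "|")
  for (i in 1:3) {
    expect_false(grepl(scr$spacer[i], both, fixed = TRUE))
    expect_equal(sort(strsplit(scr$spacer[i], "")[[1]]),
                 sort(strsplit(scr$source_spacer[i], "")[[1]]))
  }
})

test_that("zero scrambled controls is an empty set", {
  expect_equal(nrow(generate_scrambled_controls("ACGTACGTACGTACGTACGT",
                                                c(chr1 = "ACGT"), n = 0)), 0)
})

test_that("an unsatisfiable scramble constraint exhausts its budget", {
  # the only permutation of poly-A is itself, and it sits in the genome
  genome <- c(chr1 = strrep("A", 40))
  expect_error(generate_scrambled_controls(strrep("A", 20), genome, n = 1,
                                           max_attempts = 50),
               "budget")
})
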