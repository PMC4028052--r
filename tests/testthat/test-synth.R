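test_that("generated genomes hit the requested GC content deterministically", {
  spec <- synth_spec(seed = 9, genome_length = 100000,
                     transcript_length_range = c(569L, 4661L))
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(as.character(g1), as.character(g2))
  gc <- sum(Biostrings::letterFrequency(g1, c("G", "C"))) / 100000
  expect_lt(abs(gc - 0.65), 0.01)

  pure <- synth_spec(seed = 9, genome_length = 50000, gc_content = 1.0)
  gp <- generate_genome(pure)
  expect_equal(sum(Biostrings::letterFrequency(gp, c("A", "T"))), 0)
})

test_that("infeasible specs are rejected", {
  expect_error(synth_spec(genome_length = 10000), "infeasible")
  expect_error(synth_spec(donor_mix = c(GC = 0.5, GT = 0.4)), "sum to 1")
  expect_error(synth_spec(intron_length_range = c(10L, 50L)), "min_intron")
  expect_error(
    generate_genes(synth_spec(seed = 1, genome_length = 47000, n_genes = 60,
                              exons_per_gene = c(4L, 4L)),
                   generate_genome(synth_spec(seed = 1, genome_length = 47000))),
    "insufficient genome space")
})

test_that("the whole fixture bundle is deterministic given the spec", {
  spec <- synth_spec(seed = 12, genome_length = 60000, n_genes = 6,
                     exons_per_gene = c(2L, 4L),
                     transcript_length_range = c(400L, 800L), n_fusions = 2L)
  a <- generate_genes(spec, generate_genome(spec))
  b <- generate_genes(spec, generate_genome(spec))
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as.character(a$transcripts), as.character(b$transcripts))
  expect_identical(a$truth$genes, b$truth$genes)
  fa <- generate_fusions(spec)
  fb <- generate_fusions(spec)
  expect_identical(as.character(fa$sequences), as.character(fb$sequences))
})

test_that("spliced transcripts equal exon extraction from genome and models", {
  spec <- synth_spec(seed = 13, genome_length = 90000, n_genes = 10,
                     exons_per_gene = c(1L, 8L),
                     transcript_length_range = c(400L, 1200L))
  gg <- generate_genes(spec, generate_genome(spec))
  expect_identical(as.character(spliced_transcript_seqs(gg$models, gg$genome)),
                   as.character(gg$transcripts))
  # both strands are represented
  strands <- vapply(names(gg$models), function(tx)
    as.character(BiocGenerics::strand(gg$models[[tx]]))[1], "")
  expect_true(all(c("+", "-") %in% strands))
})

test_that("planted gene truth matches the ORF extractor", {
  spec <- synth_spec(seed = 14, genome_length = 60000, n_genes = 5,
                     exons_per_gene = c(2L, 3L),
                     transcript_length_range = c(450L, 900L))
  gg <- generate_genes(spec, generate_genome(spec))
  tr <- gg$truth$genes
  for (i in seq_len(nrow(tr))) {
    o <- longest_orf(gg$transcripts[[i]])
    expect_equal(o$start, tr$orf_start[i])
    expect_equal(o$end, tr$orf_end[i])
    expect_equal(o$peptide, tr$peptide[i])
    expect_equal(o$strand, "+")
  }
})

test_that("zero planted retention and zero fusions behave as boundaries", {
  spec <- synth_spec(seed = 15, genome_length = 70000, n_genes = 8,
                     exons_per_gene = c(3L, 3L), retention_rate = 0,
                     transcript_length_range = c(400L, 700L), n_fusions = 0L)
  gg <- generate_genes(spec, generate_genome(spec))
  covr <- generate_coverage(spec, gg$models, gg$genome)
  expect_equal(length(covr$retained), 0L)
  r <- assess_retention(covr$not_retained, covr$coverage)
  expect_equal(r$summary$retained, 0L)
  expect_equal(length(generate_fusions(spec)$sequences), 0L)
})

test_that("fixture bundles are written as plain text and read back consistently", {
  spec <- synth_spec(seed = 16, genome_length = 60000, n_genes = 5,
                     exons_per_gene = c(2L, 3L),
                     transcript_length_range = c(400L, 700L), n_fusions = 2L,
                     n_unexplained = 2L)
  dir <- withr::local_tempdir()
  write_fixtures(spec, dir)
  expect_true(all(file.exists(file.path(
    dir, c("genome.fasta", "models.gtf", "transcripts.fasta", "fused.fasta",
           "coverage.bedgraph", "gold.fasta", "gold_pep.fasta", "truth.json")))))
  genome <- read_fasta(file.path(dir, "genome.fasta"))
  models <- read_gtf(file.path(dir, "models.gtf"))
  tx <- read_fasta(file.path(dir, "transcripts.fasta"))
  expect_identical(as.character(spliced_transcript_seqs(models, genome)),
                   as.character(tx))
  cov <- read_coverage(file.path(dir, "coverage.bedgraph"), genome)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(cov[[1]]), Biostrings::width(genome)[1])
  expect_equal(truth$n_junctions,
               length(extract_junctions(models, genome)))
})
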