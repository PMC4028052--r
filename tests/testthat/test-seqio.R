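test_that("FASTA read normalizes case and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgt", ">b desc", "GGCC", "aa"), f)
  x <- read_fasta(f)
  expect_equal(names(x), c("a", "b"))
  expect_equal(as.character(x), c(a = "ACGT", b = "GGCCAA"))

  writeLines(c(">a", "ACGT", ">a", "GG"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">a", "ACGT", ">b", ""), f)
  expect_error(read_fasta(f), "empty")
  writeLines(c(">a", "ACRT"), f)
  expect_error(read_fasta(f), "outside")
})

test_that("FASTA write then read is the identity", {
  withr::with_seed(101, {
    x <- dss(vapply(5:14, function(i) random_dna(50 + 7 * i), ""))
  })
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(x, f, width = 37)
  y <- read_fasta(f)
  expect_identical(as.character(y), as.character(x))
})

test_that("GTF exons are grouped, 1-based inclusive, and order-invariant", {
  f <- withr::local_tempfile(fileext = ".gtf")
  lines <- c(
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t300\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t500\t550\t.\t-\t.\tgene_id "g2"; transcript_id "t2";')
  writeLines(lines, f)
  m <- read_gtf(f)
  expect_equal(names(m), c("t1", "t2"))
  expect_equal(BiocGenerics::start(m[["t1"]]), c(100, 300))
  expect_equal(BiocGenerics::end(m[["t1"]]), c(200, 400))
  expect_equal(BiocGenerics::width(m[["t1"]]), c(101, 101))
  # the single intron spans 201..299, i.e. 99 bases
  expect_equal(BiocGenerics::start(m[["t1"]])[2] - BiocGenerics::end(m[["t1"]])[1] - 1, 99)
  expect_equal(length(m[["t2"]]), 1L)

  writeLines(lines[c(3, 2, 1)], f)
  m2 <- read_gtf(f)
  expect_identical(
    lapply(names(m), function(tx) as.data.frame(m[[tx]])),
    lapply(names(m), function(tx) as.data.frame(m2[[tx]])))
})

test_that("GTF rejects exons without transcript ids and overlapping exons", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines('chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1";', f)
  expect_error(read_gtf(f), "transcript_id")
  writeLines(c(
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    'chr1\tsrc\texon\t150\t300\t.\t+\t.\tgene_id "g"; transcript_id "t";'), f)
  expect_error(read_gtf(f), "overlapping")
})

test_that("GTF write then read round-trips transcript models", {
  spec <- synth_spec(seed = 3, genome_length = 60000, n_genes = 8,
                     exons_per_gene = c(1L, 6L),
                     transcript_length_range = c(400L, 900L))
  gg <- generate_genes(spec, generate_genome(spec))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(gg$models, f)
  m2 <- read_gtf(f)
  expect_equal(names(m2), names(gg$models))
  for (tx in names(m2)) {
    expect_equal(BiocGenerics::start(m2[[tx]]), BiocGenerics::start(gg$models[[tx]]))
    expect_equal(as.character(BiocGenerics::strand(m2[[tx]])),
                 as.character(BiocGenerics::strand(gg$models[[tx]])))
  }
})

test_that("bedGraph coverage is painted densely with absent positions at 0", {
  genome <- dss(c(chr1 = strrep("A", 100)))
  names(genome) <- "chr1"
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t10\t13\t50", f)
  cov <- read_coverage(f, genome)
  v <- as.integer(cov[["chr1"]])
  expect_equal(length(v), 100L)
  expect_equal(v[11:13], rep(50L, 3))   # 0-based half-open [10,13) -> bases 11..13
  expect_equal(sum(v), 150L)

  writeLines(character(0), f)
  expect_equal(sum(as.integer(read_coverage(f, genome)[["chr1"]])), 0L)
})

test_that("coverage totals match brute-force painting of random records", {
  genome <- dss(c(chr1 = strrep("G", 5000)))
  names(genome) <- "chr1"
  withr::with_seed(202, {
    starts <- sort(sample(seq(0, 4900, by = 25), 40))
    recs <- data.frame(start0 = starts,
                       end0 = starts + sample(5:20, 40, replace = TRUE),
                       depth = sample(1:80, 40, replace = TRUE))
  })
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(sprintf("chr1\t%d\t%d\t%d", recs$start0, recs$end0, recs$depth), f)
  cov <- read_coverage(f, genome)
  expect_identical(as.integer(cov[["chr1"]]), brute_force_paint(5000L, recs))
  expect_equal(sum(as.integer(cov[["chr1"]])),
               sum(recs$depth * (recs$end0 - recs$start0)))
})

test_that("coverage reader rejects bad records", {
  genome <- dss(c(chr1 = strrep("A", 100)))
  names(genome) <- "chr1"
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr2\t0\t5\t3", f)
  expect_error(read_coverage(f, genome), "unknown chrom")
  writeLines("chr1\t0\t5\t-3", f)
  expect_error(read_coverage(f, genome), "negative")
  writeLines("chr1\t90\t120\t3", f)
  expect_error(read_coverage(f, genome), "beyond")
  writeLines(c("chr1\t0\t10\t3", "chr1\t5\t15\t2"), f)
  expect_error(read_coverage(f, genome), "overlapping")
})

test_that("bedGraph write then read is the identity on coverage tracks", {
  genome <- dss(c(chr1 = strrep("A", 400)))
  names(genome) <- "chr1"
  withr::with_seed(7, {
    d <- integer(400)
    d[51:120] <- 4L; d[200:390] <- 61L; d[150] <- 1L
  })
  cov <- methods::as(stats::setNames(list(S4Vectors::Rle(d)), "chr1"), "SimpleRleList")
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(cov, f)
  cov2 <- read_coverage(f, genome)
  expect_identical(as.integer(cov2[["chr1"]]), d)
})
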