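# hand-built two-exon models on a tiny genome
mini_models <- function(intron_seq, strand = "+", flank = 40L) {
  g <- paste0(strrep("G", flank), intron_seq, strrep("C", flank))
  genome <- Biostrings::DNAStringSet(g)
  names(genome) <- "chrT"
  n <- nchar(intron_seq)
  ex <- GenomicRanges::GRanges("chrT", IRanges::IRanges(
    c(1L, flank + n + 1L), c(flank, flank + n + flank)), strand = strand)
  list(models = transcript_models(ex, c("t1", "t1")), genome = genome,
       intron = c(flank + 1L, flank + n))
}

intron_with <- function(donor_fwd, acceptor_fwd, len = 32L) {
  mid <- strrep("A", len - 4L)
  paste0(donor_fwd, mid, acceptor_fwd)
}

test_that("plus-strand junctions read donor and acceptor forward", {
  mm <- mini_models(intron_with("GT", "AG"))
  j <- extract_junctions(mm$models, mm$genome)
  expect_equal(length(j), 1L)
  expect_equal(j$donor, "GT")
  expect_equal(j$acceptor, "AG")
  expect_equal(c(BiocGenerics::start(j), BiocGenerics::end(j)), mm$intron)
})

test_that("minus-strand junctions are reverse-complemented", {
  # forward intron starts CT... and ends ...GC: on the minus strand this
  # is a GC donor with an AG acceptor
  mm <- mini_models(intron_with("CT", "GC"), strand = "-")
  j <- extract_junctions(mm$models, mm$genome)
  expect_equal(j$donor, "GC")
  expect_equal(j$acceptor, "AG")
})

test_that("shared junctions are deduplicated on genomic coordinates", {
  mm <- mini_models(intron_with("GT", "AG"))
  ex <- unlist(mm$models)
  # second isoform: same intron, different transcript id and longer 3' exon
  ex2 <- c(ex, GenomicRanges::GRanges("chrT", IRanges::IRanges(
    BiocGenerics::start(ex)[2], BiocGenerics::end(ex)[2] - 5L), strand = "+"))
  models <- transcript_models(
    GenomicRanges::GRanges(
      "chrT",
      IRanges::IRanges(BiocGenerics::start(ex2)[c(1, 2, 1, 3)],
                       BiocGenerics::end(ex2)[c(1, 2, 1, 3)]),
      strand = "+"),
    c("t1", "t1", "t2", "t2"))
  j <- extract_junctions(models, mm$genome)
  expect_equal(length(j), 1L)
  # union with itself adds nothing
  j2 <- extract_junctions(c(models, models[1]), mm$genome)
  expect_equal(length(j2), 1L)
})

test_that("introns shorter than the minimum are dropped with a warning", {
  mm <- mini_models(intron_with("GT", "AG", len = 12L))
  expect_warning(j <- extract_junctions(mm$models, mm$genome, min_intron = 30L),
                 "shorter")
  expect_equal(length(j), 0L)
})

test_that("junction tallies bin donors and acceptors with N going to other", {
  j <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 40, 80), width = 30))
  j$donor <- c("GT", "GC", "GC")
  j$acceptor <- c("AG", "AG", "AG")
  tal <- classify_junctions(j)
  expect_equal(tal$donors[["GC"]], 2L)
  expect_equal(tal$donors[["GT"]], 1L)
  expect_equal(tal$acceptors[["AG"]], 3L)
  expect_equal(tal$total, 3L)

  j$donor <- c("GA", "NN", "CC")
  j$acceptor <- c("AG", "AN", "TT")
  tal2 <- classify_junctions(j)
  expect_equal(tal2$donors[["GA"]], 1L)
  expect_equal(tal2$donors[["other"]], 2L)
  expect_equal(tal2$acceptors[["other"]], 2L)
})

test_that("the EST noise filter keeps only AG acceptors", {
  j <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 40), width = 30))
  j$donor <- c("GT", "GT")
  j$acceptor <- c("AG", "AC")
  expect_equal(length(filter_ag_acceptors(j)), 1L)
  expect_equal(filter_ag_acceptors(j)$acceptor, "AG")
  j$acceptor <- c("AG", "AG")
  expect_equal(length(filter_ag_acceptors(j)), 2L)
})

test_that("strand inference votes by AG acceptors", {
  plus <- mini_models(intron_with("GT", "AG"), strand = "*")
  expect_equal(infer_strand_by_acceptor(plus$models[[1]], plus$genome), "+")
  minus <- mini_models(intron_with("CT", "GC"), strand = "*")
  expect_equal(infer_strand_by_acceptor(minus$models[[1]], minus$genome), "-")
  # one vote each way: CT start and AG end
  tie <- mini_models(intron_with("CT", "AG"), strand = "*")
  expect_equal(infer_strand_by_acceptor(tie$models[[1]], tie$genome), "*")
  # unknown-strand models are oriented before extraction
  j <- extract_junctions(minus$models, minus$genome)
  expect_equal(as.character(BiocGenerics::strand(j)), "-")
  expect_equal(j$acceptor, "AG")
})

test_that("extraction is involutive under genome reverse complement", {
  spec <- synth_spec(seed = 33, genome_length = 60000, n_genes = 6,
                     exons_per_gene = c(3L, 4L),
                     transcript_length_range = c(400L, 800L))
  gg <- generate_genes(spec, generate_genome(spec))
  j1 <- extract_junctions(gg$models, gg$genome)
  # mirror: reverse-complement the genome and flip all model coordinates
  L <- Biostrings::width(gg$genome)[1]
  rc_genome <- Biostrings::reverseComplement(gg$genome)
  names(rc_genome) <- names(gg$genome)
  ex <- unlist(gg$models, use.names = FALSE)
  tid <- rep(names(gg$models), S4Vectors::elementNROWS(gg$models))
  flipped <- GenomicRanges::GRanges(
    "synth1",
    IRanges::IRanges(L - BiocGenerics::end(ex) + 1L,
                     L - BiocGenerics::start(ex) + 1L),
    strand = ifelse(as.character(BiocGenerics::strand(ex)) == "+", "-", "+"))
  j2 <- extract_junctions(transcript_models(flipped, tid), rc_genome)
  expect_equal(sort(table(j1$donor)), sort(table(j2$donor)))
  expect_equal(sort(table(j1$acceptor)), sort(table(j2$acceptor)))
})

test_that("planted donor mixes are recovered exactly", {
  spec <- synth_spec(seed = 34, genome_length = 80000, n_genes = 10,
                     exons_per_gene = c(3L, 3L),
                     transcript_length_range = c(400L, 800L))
  gg <- generate_genes(spec, generate_genome(spec))
  j <- extract_junctions(gg$models, gg$genome)
  expect_equal(length(j), 20L)
  tal <- classify_junctions(j)
  truth <- table(gg$truth$junctions$donor)
  for (d in names(truth))
    expect_equal(tal$donors[[d]], unname(truth[[d]]))
  expect_equal(tal$acceptors[["AG"]], 20L)
})
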