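# construct a transcript of length `len` whose longest ORF covers ~frac
planted_tx <- function(len, frac, seed) {
  txqc:::with_seed(seed, txqc:::synth_transcript(len, frac, gc = 0.65))
}

test_that("high ORF coverage, short parents, and low coverage hit the right rules", {
  # rule 1: ORF covering >= 80% is never split
  keep1 <- planted_tx(2500, 0.85, 601)
  d1 <- decide_split(keep1$seq)
  expect_equal(d1$verdict, "keep")
  expect_gte(d1$orf_coverage, 0.80)

  # rule 2: shorter than 2000 bp is never split, even at mid coverage
  keep2 <- planted_tx(1500, 0.40, 602)
  expect_equal(decide_split(keep2$seq)$verdict, "keep")

  # below 10% coverage: removed
  rm1 <- txqc:::with_seed(603, txqc:::noncoding_seq(3000, 0.65))
  d3 <- decide_split(rm1)
  expect_equal(d3$verdict, "remove")
  expect_lt(d3$orf_coverage, 0.10)

  # exactly 2000 bp is eligible for splitting; 1999 bp is not
  two <- paste0(planted_tx(1000, 0.40, 604)$seq, planted_tx(1000, 0.40, 605)$seq)
  expect_equal(nchar(two), 2000L)
  expect_equal(decide_split(two)$verdict, "split2")
  expect_equal(decide_split(substring(two, 1L, 1999L))$verdict, "keep")
})

test_that("opposite-strand fusions split in two with the strand flag set", {
  spec <- synth_spec(seed = 611, n_fusions = 3L)
  fus <- generate_fusions(spec)
  for (i in 1:3) {
    d <- decide_split(fus$sequences[[i]])
    expect_equal(d$verdict, "split2")
    expect_true(d$opposite_strand)
    expect_equal(nrow(d$children), 2L)
    # each child fully contains one participating ORF
    for (k in 1:2) {
      o <- d$orfs[order(d$orfs$start), ][k, ]
      expect_true(d$children$start[k] <= o$start && o$end <= d$children$end[k])
    }
    # children partition the parent
    expect_equal(d$children$start[1], 1L)
    expect_equal(d$children$end[2], nchar(as.character(fus$sequences[[i]])))
    expect_equal(d$children$start[2], d$children$end[1] + 1L)
  }
})

test_that("same-strand fusions split without the opposite-strand flag", {
  spec <- synth_spec(seed = 612, n_fusions = 3L)
  fus <- generate_fusions(spec, same_strand = TRUE)
  res <- split_collection(fus$sequences)
  expect_equal(res$report$split2, 3L)
  expect_equal(res$report$opposite_strand, 0L)
})

test_that("three non-overlapping large ORFs yield a three-way split", {
  parts <- lapply(1:3, function(i) planted_tx(900, 0.5, 620 + i))
  parent <- paste(vapply(parts, `[[`, "", "seq"), collapse = "")
  d <- decide_split(parent)
  expect_equal(d$verdict, "split3")
  expect_equal(nrow(d$children), 3L)
  ch <- substring(parent, d$children$start, d$children$end)
  expect_equal(paste(ch, collapse = ""), parent)
})

test_that("split children never exceed the parent and suffixes are positional", {
  spec <- synth_spec(seed = 613, n_fusions = 4L)
  fus <- generate_fusions(spec)
  res <- split_collection(fus$sequences)
  expect_equal(length(res$sequences), 8L)
  expect_equal(names(res$sequences)[1:2], c("fusion01.1", "fusion01.2"))
  for (i in 1:4) {
    parent <- as.character(fus$sequences[[i]])
    c1 <- as.character(res$sequences[[2 * i - 1]])
    c2 <- as.character(res$sequences[[2 * i]])
    expect_identical(paste0(c1, c2), parent)
    expect_gte(nchar(c1), 300L)
    expect_gte(nchar(c2), 300L)
  }
})

test_that("splitting is idempotent on its own output", {
  spec <- synth_spec(seed = 614, n_fusions = 4L)
  fus <- generate_fusions(spec)
  once <- split_collection(fus$sequences)
  twice <- split_collection(once$sequences)
  expect_equal(twice$report$split2 + twice$report$split3, 0L)
  expect_equal(twice$report$removed, 0L)
  expect_identical(as.character(twice$sequences), as.character(once$sequences))
})

test_that("raising the peptide threshold never increases splits", {
  spec <- synth_spec(seed = 615, n_fusions = 5L)
  fus <- generate_fusions(spec)
  n_splits <- function(min_aa) {
    r <- split_collection(fus$sequences, min_peptide_aa = min_aa)$report
    r$split2 + r$split3
  }
  s100 <- n_splits(100L)
  s150 <- n_splits(150L)
  s500 <- n_splits(500L)
  expect_gte(s100, s150)
  expect_gte(s150, s500)
  expect_equal(s500, 0L)
})

test_that("keep-everything and empty collections pass through unchanged", {
  spec <- synth_spec(seed = 616)
  keeps <- generate_plain_transcripts(spec, 3, length_range = c(2100L, 2400L),
                                      orf_frac_range = c(0.85, 0.9))
  res <- split_collection(keeps)
  expect_identical(as.character(res$sequences), as.character(keeps))
  expect_equal(res$report$keep, 3L)

  empty <- split_collection(Biostrings::DNAStringSet())
  expect_equal(length(empty$sequences), 0L)
  expect_equal(empty$report$keep + empty$report$split2 + empty$report$removed, 0L)
})

test_that("split verdicts validate their thresholds", {
  expect_error(decide_split("ACGTACGT", keep_cov = 0.1, remove_cov = 0.5),
               "remove_cov")
})
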