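# Independent oracles used across the suite. These deliberately avoid the
# code paths of the functions they check: ORF translation goes through
# seqinr, alignment scores through Biostrings::pairwiseAlignment, and the
# region/coverage oracles are plain base-R vector scans.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_oracle <- function(s) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
}

# codon-by-codon six-frame ORF scanner (stop-to-stop or Met-to-stop)
brute_force_orfs <- function(s, mode = "stop_to_stop", min_aa = 1L) {
  n <- nchar(s)
  rows <- list()
  for (str in c("+", "-")) {
    ss <- if (str == "+") s else revcomp_oracle(s)
    for (f in 0:2) {
      ncod <- (n - f) %/% 3L
      if (ncod < 1L) next
      aa <- character(ncod)
      for (k in seq_len(ncod)) {
        cod <- substr(ss, f + 3L * (k - 1L) + 1L, f + 3L * k)
        aa[k] <- if (grepl("N", cod)) "X"
                 else seqinr::translate(strsplit(cod, "")[[1]])
      }
      k <- 1L
      while (k <= ncod) {
        if (aa[k] == "*") { k <- k + 1L; next }
        j <- k
        while (j < ncod && aa[j + 1L] != "*") j <- j + 1L
        cs <- k; ce <- j
        if (mode == "met_to_stop") {
          m <- which(aa[cs:ce] == "M")
          cs <- if (length(m)) cs + m[1L] - 1L else NA_integer_
        }
        if (!is.na(cs) && ce - cs + 1L >= min_aa) {
          has_stop <- ce < ncod
          a <- f + 3L * (cs - 1L) + 1L
          b <- f + 3L * (ce + as.integer(has_stop))
          if (str == "-") { tmp <- a; a <- n - b + 1L; b <- n - tmp + 1L }
          rows[[length(rows) + 1L]] <- data.frame(
            strand = str, frame = f, start = a, end = b,
            aa_len = ce - cs + 1L,
            peptide = paste(aa[cs:ce], collapse = ""),
            stringsAsFactors = FALSE)
        }
        k <- j + 1L
      }
    }
  }
  if (!length(rows))
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      aa_len = integer(), peptide = character()))
  out <- do.call(rbind, rows)
  out[order(out$strand, out$frame, out$start), , drop = FALSE]
}

# canonical form for comparing ORF tables as sets
orf_set <- function(df) {
  df <- df[order(df$strand, df$frame, df$start),
           c("strand", "frame", "start", "end", "aa_len", "peptide")]
  rownames(df) <- NULL
  df
}

# optimal local alignment score under the hit-score model, via Biostrings
ALPHA5 <- c("A", "C", "G", "T", "N")
HIT_MAT <- local({
  m <- matrix(-1, 5, 5, dimnames = list(ALPHA5, ALPHA5))
  diag(m) <- 1
  m
})
dp_score_oracle <- function(q, t) {
  Biostrings::pairwiseAlignment(q, t, type = "local",
                                substitutionMatrix = HIT_MAT,
                                gapOpening = 1, gapExtension = 0,
                                scoreOnly = TRUE)
}

# base-by-base scan for maximal high-coverage runs outside exclusions
brute_force_regions <- function(depth, excluded, min_length, min_cov) {
  ok <- depth >= min_cov & !excluded
  out <- list()
  i <- 1L
  n <- length(depth)
  while (i <= n) {
    if (!ok[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && ok[j + 1L]) j <- j + 1L
    if (j - i + 1L >= min_length)
      out[[length(out) + 1L]] <- c(start = i, end = j)
    i <- j + 1L
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  as.data.frame(do.call(rbind, out))
}

# paint bedGraph-style records onto a depth vector
brute_force_paint <- function(n, records) {
  depth <- integer(n)
  for (r in seq_len(nrow(records)))
    depth[(records$start0[r] + 1L):records$end0[r]] <-
      depth[(records$start0[r] + 1L):records$end0[r]] + records$depth[r]
  depth
}

# small helper: named DNAStringSet from a character vector
dss <- function(x) {
  out <- Biostrings::DNAStringSet(x)
  if (is.null(names(x))) names(out) <- paste0("s", seq_along(x))
  out
}

# per-transcript genomic span of a GRangesList of exons
gene_spans <- function(models) {
  ids <- names(models)
  chrom <- vapply(ids, function(tx)
    as.character(GenomeInfoDb::seqnames(models[[tx]]))[1], "")
  st <- vapply(ids, function(tx) min(BiocGenerics::start(models[[tx]])), 0)
  en <- vapply(ids, function(tx) max(BiocGenerics::end(models[[tx]])), 0)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(st, en))
}

# merge scenario: 5 primaries; secondaries = 2 identical copies, 2
# contained 500-600 bp slices, 3 novel transcripts
merge_fixture <- function(seed = 710) {
  prim <- generate_plain_transcripts(synth_spec(seed = seed), 5,
                                     length_range = c(900L, 1300L),
                                     orf_frac_range = c(0.6, 0.8), prefix = "p")
  sec <- list()
  sec[["s_ident1"]] <- as.character(prim[[1]])
  sec[["s_ident2"]] <- as.character(prim[[2]])
  sec[["s_cont1"]] <- substr(as.character(prim[[3]]), 51, 550)
  sec[["s_cont2"]] <- substr(as.character(prim[[4]]), 101, 700)
  novel <- generate_plain_transcripts(synth_spec(seed = seed + 1), 3,
                                      length_range = c(500L, 800L),
                                      orf_frac_range = c(0.6, 0.8), prefix = "n")
  list(primary = prim, secondary = c(dss(unlist(sec)), novel))
}

# shared fixture for the gold-standard presence scenario: 20 planted
# genes; a collection carrying 17 intact, 2 frameshifted, 1 absent
presence_fixture <- function(seed = 7) {
  spec <- synth_spec(seed = seed, genome_length = 60000, n_genes = 20,
                     exons_per_gene = c(2L, 5L),
                     transcript_length_range = c(320L, 400L))
  gg <- generate_genes(spec, generate_genome(spec))
  tr <- gg$truth$genes
  coll <- as.character(gg$transcripts[1:19])
  for (i in 18:19)
    coll[i] <- frameshift_transcript(
      coll[i], position = (tr$orf_start[i] + tr$orf_end[i]) %/% 2L)
  collection <- Biostrings::DNAStringSet(coll)
  names(collection) <- paste0(tr$id[1:19], "_asm")
  gold_pep <- Biostrings::AAStringSet(tr$peptide)
  names(gold_pep) <- tr$id
  list(gold = gg$transcripts, gold_pep = gold_pep, collection = collection,
       truth = tr, intact = tr$id[1:17], frameshifted = tr$id[18:19],
       absent = tr$id[20])
}
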