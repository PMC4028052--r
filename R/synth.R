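#' Specification for a synthetic transcriptome fixture
#'
#' Describes a deterministic toy genome emulating the conditions this
#' toolkit targets: a GC-rich genome (default 65% GC) carrying
#' non-overlapping multi-exon genes whose splice donors follow a planted
#' mix dominated by the non-canonical GC dinucleotide (default
#' 56/40/4 GC/GT/GA, acceptors all AG), transcripts in the length range
#' of a curated gold-standard set (569-4661 bp, 1-17 exons), chimeras
#' fused through opposite-strand 3'-UTR overlaps, and coverage tracks
#' with a planted intron-retention rate (default 89%) plus planted
#' "unexplained" coverage islands. Identical specs produce byte-identical
#' fixtures.
#'
#' Planted features are written into the sequence (overwriting the
#' random background) rather than obtained by rejection sampling, so
#' planted counts are recovered exactly, not statistically.
#'
#' @param seed integer RNG seed; every generator derives its stream from
#'   it.
#' @param genome_length genome size in bases (must be at least 10x the
#'   longest transcript).
#' @param gc_content genome GC fraction.
#' @param chrom chromosome name.
#' @param n_genes number of gene loci.
#' @param exons_per_gene inclusive range of exon counts per gene.
#' @param transcript_length_range inclusive range of spliced transcript
#'   lengths (bp).
#' @param donor_mix named distribution over donor dinucleotides; must sum
#'   to 1. Acceptors are always AG.
#' @param min_intron,intron_length_range minimum and sampled range of
#'   intron lengths.
#' @param n_fusions number of fused (chimeric) transcripts.
#' @param fusion_overlap inclusive range of 3'-UTR overlap lengths (bp).
#' @param retention_rate fraction of introns covered end-to-end in the
#'   generated coverage track.
#' @param read_depth per-base depth over expressed exons.
#' @param n_unexplained number of planted coverage islands outside all
#'   gene loci.
#' @param unexplained_length inclusive length range of those islands
#'   (default at least 300 bp).
#' @param unexplained_depth their per-base depth (default 60).
#' @return an object of class `synth_spec` (a validated list).
#' @seealso [generate_genome()], [generate_genes()], [generate_fusions()],
#'   [generate_coverage()]
#' @export
synth_spec <- function(seed = 42L, genome_length = 500000L, gc_content = 0.65,
                       chrom = "synth1", n_genes = 100L,
                       exons_per_gene = c(1L, 17L),
                       transcript_length_range = c(569L, 4661L),
                       donor_mix = c(GC = 0.56, GT = 0.40, GA = 0.04),
                       min_intron = 30L, intron_length_range = c(30L, 150L),
                       n_fusions = 10L, fusion_overlap = c(20L, 100L),
                       retention_rate = 0.89, read_depth = 50L,
                       n_unexplained = 5L, unexplained_length = c(300L, 600L),
                       unexplained_depth = 60L) {
  if (abs(sum(donor_mix) - 1) > 1e-8) stop("donor_mix must sum to 1")
  if (is.null(names(donor_mix))) stop("donor_mix must be named")
  if (gc_content < 0 || gc_content > 1) stop("gc_content must be in [0, 1]")
  if (genome_length < 10 * transcript_length_range[2])
    stop("infeasible spec: genome_length must be at least 10x the longest transcript")
  if (intron_length_range[1] < min_intron)
    stop("intron_length_range must respect min_intron")
  if (retention_rate < 0 || retention_rate > 1)
    stop("retention_rate must be in [0, 1]")
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    gc_content = gc_content, chrom = chrom, n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    transcript_length_range = as.integer(transcript_length_range),
    donor_mix = donor_mix, min_intron = as.integer(min_intron),
    intron_length_range = as.integer(intron_length_range),
    n_fusions = as.integer(n_fusions),
    fusion_overlap = as.integer(fusion_overlap),
    retention_rate = retention_rate, read_depth = as.integer(read_depth),
    n_unexplained = as.integer(n_unexplained),
    unexplained_length = as.integer(unexplained_length),
    unexplained_depth = as.integer(unexplained_depth)),
    class = "synth_spec")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# A random 22-mer containing stop codons in all six reading frames:
# forward stops at offsets 0, 4, 8 (congruent to 0, 1, 2 mod 3) and
# reverse-complement stops at offsets 11, 15, 19. Interleaving such
# units into random sequence bounds the length of any accidental ORF in
# non-coding regions; randomizing the stop choices and filler bases
# keeps different transcripts from sharing a long common motif.
stop_unit <- function() {
  s <- sample(STOP_CODONS, 3L, replace = TRUE)
  t <- sample(c("TTA", "CTA", "TCA"), 3L, replace = TRUE)
  x <- sample(c("A", "C", "G", "T"), 4L, replace = TRUE)
  paste0(s[1], x[1], s[2], x[2], s[3], t[1], x[3], t[2], x[4], t[3])
}

rand_bases <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Non-coding sequence: random GC-rich bases with STOP_UNIT interleaved
# every 20-45 bases so no reading frame on either strand can run long.
noncoding_seq <- function(n, gc) {
  if (n <= 0L) return("")
  parts <- list()
  total <- 0L
  while (total < n) {
    sp <- rand_bases(sample_range(20L, 45L), gc)
    un <- stop_unit()
    parts[[length(parts) + 1L]] <- sp
    parts[[length(parts) + 1L]] <- un
    total <- total + nchar(sp) + nchar(un)
  }
  substring(paste(unlist(parts), collapse = ""), 1L, n)
}

# Sense-codon pairs that place a stop codon in each of the five reading
# frames other than the planted one (three minus-strand frames, the two
# shifted plus frames). Interleaved every ~10 codons they keep
# accidental ORFs in alternative frames far shorter than the planted ORF.
FRAME_BREAKERS <- list(
  c("TTA"),          # Leu; reverse-strand TAA, codon-aligned
  c("CTT", "ACC"),   # Leu+Thr; reverse-strand TAA, offset +1
  c("GCT", "TAC"),   # Ala+Tyr; reverse-strand TAA, offset +2
  c("ATA", "ACC"),   # Ile+Thr; plus-strand TAA in frame +1
  c("GCT", "AAC"))   # Ala+Asn; plus-strand TAA in frame +2

# n_codons stop-free sense codons with frame breakers interleaved
orf_codons <- function(n_codons, gc) {
  out <- character(0)
  brk <- 1L
  while (length(out) < n_codons) {
    if (length(out) %% 10L == 9L && n_codons - length(out) >= 2L) {
      out <- c(out, FRAME_BREAKERS[[brk]])
      brk <- brk %% length(FRAME_BREAKERS) + 1L
    } else {
      repeat {
        cod <- rand_bases(3L, gc)
        if (!cod %in% STOP_CODONS) break
      }
      out <- c(out, cod)
    }
  }
  out[seq_len(n_codons)]
}

# A transcript with one planted stop-to-stop ORF:
# [5'UTR][TAA][orf codons][TAG][3'UTR]. Returns the sequence and the
# coordinates the ORF extractor should report (interval includes the
# terminal stop codon). Retries a few draws until the planted ORF is
# verifiably the longest in all six frames.
synth_transcript <- function(len, orf_frac, gc, min_utr3 = 10L) {
  for (attempt in 1:25) {
    orf_nt <- 3L * max(20L, floor(orf_frac * len / 3))
    rest <- len - orf_nt - 6L
    if (rest < 20L + min_utr3) stop("transcript too short for requested ORF fraction")
    u5 <- max(10L, rest - min_utr3 - sample_range(0L, max(0L, rest - min_utr3 - 10L)))
    u3 <- rest - u5
    tx <- paste0(noncoding_seq(u5, gc), "TAA",
                 paste(orf_codons(orf_nt %/% 3L, gc), collapse = ""),
                 "TAG", noncoding_seq(u3, gc))
    o <- longest_orf(tx)
    if (nrow(o) == 1L && o$strand == "+" && o$start == u5 + 4L &&
        o$aa_len == orf_nt %/% 3L)
      return(list(seq = tx, orf_start = u5 + 4L, orf_end = u5 + 6L + orf_nt,
                  orf_nt = orf_nt, aa_len = orf_nt %/% 3L,
                  peptide = o$peptide))
  }
  stop("failed to plant a dominant ORF; widen the length/fraction ranges")
}

#' Generate a random GC-rich genome
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc_content`, split evenly
#' between G and C (and between A and T). Deterministic given the spec
#' seed.
#'
#' @param spec a [synth_spec()].
#' @return a `DNAStringSet` with one chromosome.
#' @export
generate_genome <- function(spec) {
  stopifnot(is(spec, "synth_spec"))
  with_seed(spec$seed, {
    g <- Biostrings::DNAStringSet(rand_bases(spec$genome_length, spec$gc_content))
    names(g) <- spec$chrom
    g
  })
}

#' Plant gene models with a known splice-junction mix into a genome
#'
#' Lays out `n_genes` non-overlapping loci on the genome, each a
#' multi-exon gene whose spliced transcript carries one planted
#' stop-to-stop ORF. Every intron's donor dinucleotide is drawn without
#' replacement from an exact largest-remainder allocation of
#' `spec$donor_mix` over the total intron count (so planted category
#' counts are recovered exactly, not in expectation); acceptors are all
#' AG. Dinucleotides are written into the (returned copy of the) genome.
#' About half the genes land on the minus strand.
#'
#' @param spec a [synth_spec()].
#' @param genome the `DNAStringSet` from [generate_genome()].
#' @return a list with:
#' * `genome`: the edited genome (use this downstream, not the input);
#' * `models`: a `GRangesList` of exons per transcript;
#' * `transcripts`: the spliced transcript sequences (`DNAStringSet`);
#' * `truth`: a list with `junctions` (a `GRanges` with the planted
#'   `donor` / `acceptor` of every intron) and `genes` (a per-gene
#'   data.frame recording strand, locus, transcript length, exon count,
#'   and the planted ORF interval and peptide).
#' @export
generate_genes <- function(spec, genome) {
  stopifnot(is(spec, "synth_spec"), is(genome, "DNAStringSet"))
  with_seed(spec$seed + 1L, {
    gchars <- strsplit(as.character(genome[[1L]]), "", fixed = TRUE)[[1L]]
    n_exons <- sample_range(spec$exons_per_gene[1], spec$exons_per_gene[2],
                            spec$n_genes)
    total_introns <- sum(n_exons - 1L)
    alloc <- allocate_counts(total_introns, spec$donor_mix)
    donor_pool <- sample(rep(names(alloc), alloc))
    donor_i <- 0L

    cursor <- sample_range(300L, 800L)
    exon_rows <- list(); junc_rows <- list(); gene_rows <- list()
    tx_seqs <- character(spec$n_genes)
    ids <- sprintf("gene%03d", seq_len(spec$n_genes))
    for (g in seq_len(spec$n_genes)) {
      L <- sample_range(spec$transcript_length_range[1], spec$transcript_length_range[2])
      k <- n_exons[g]
      L <- max(L, 35L * k + 60L)  # room for >=30 bp exons plus ORF overhead
      tx <- synth_transcript(L, orf_frac = runif(1, 0.55, 0.75), gc = spec$gc_content)
      strand <- sample(c("+", "-"), 1L)
      # exon widths (genomic order): random composition with parts >= 30
      extra <- L - 30L * k
      cuts <- if (k > 1L) sort(sample_range(0L, extra, k - 1L)) else integer(0)
      widths <- 30L + diff(c(0L, cuts, extra))
      ilens <- if (k > 1L)
        sample_range(spec$intron_length_range[1], spec$intron_length_range[2],
                     k - 1L) else integer(0)
      gene_span <- L + sum(ilens)
      gene_start <- cursor
      gene_end <- cursor + gene_span - 1L
      if (gene_end > spec$genome_length - 300L)
        stop("insufficient genome space for ", spec$n_genes, " genes")

      exonic <- if (strand == "+") tx$seq else revcomp_chr(tx$seq)
      pos <- gene_start
      off <- 0L
      for (e in seq_len(k)) {
        chunk <- substring(exonic, off + 1L, off + widths[e])
        gchars[pos:(pos + widths[e] - 1L)] <- strsplit(chunk, "", fixed = TRUE)[[1L]]
        exon_rows[[length(exon_rows) + 1L]] <-
          list(ids[g], pos, pos + widths[e] - 1L, strand)
        off <- off + widths[e]
        pos <- pos + widths[e]
        if (e < k) {
          ilen <- ilens[e]
          iseq <- noncoding_seq(ilen, spec$gc_content)
          donor_i <- donor_i + 1L
          donor <- donor_pool[donor_i]
          if (strand == "+") {
            substr(iseq, 1L, 2L) <- donor
            substr(iseq, ilen - 1L, ilen) <- "AG"
          } else {
            substr(iseq, 1L, 2L) <- "CT"                 # revcomp of AG
            substr(iseq, ilen - 1L, ilen) <- revcomp_chr(donor)
          }
          gchars[pos:(pos + ilen - 1L)] <- strsplit(iseq, "", fixed = TRUE)[[1L]]
          junc_rows[[length(junc_rows) + 1L]] <-
            list(ids[g], pos, pos + ilen - 1L, strand, donor)
          pos <- pos + ilen
        }
      }
      tx_seqs[g] <- tx$seq
      gene_rows[[g]] <- data.frame(
        id = ids[g], chrom = spec$chrom, strand = strand,
        gene_start = gene_start, gene_end = gene_end,
        tx_length = L, n_exons = k,
        orf_start = tx$orf_start, orf_end = tx$orf_end,
        aa_len = tx$aa_len, peptide = tx$peptide,
        stringsAsFactors = FALSE)
      cursor <- gene_end + 1L + sample_range(300L, 1000L)
    }

    genome2 <- Biostrings::DNAStringSet(paste(gchars, collapse = ""))
    names(genome2) <- spec$chrom
    ex <- GenomicRanges::GRanges(
      spec$chrom,
      IRanges::IRanges(vapply(exon_rows, `[[`, 0, 2L),
                       vapply(exon_rows, `[[`, 0, 3L)),
      strand = vapply(exon_rows, `[[`, "", 4L))
    models <- transcript_models(ex, vapply(exon_rows, `[[`, "", 1L))
    transcripts <- Biostrings::DNAStringSet(tx_seqs)
    names(transcripts) <- ids
    junctions <- if (length(junc_rows)) GenomicRanges::GRanges(
      spec$chrom,
      IRanges::IRanges(vapply(junc_rows, `[[`, 0, 2L),
                       vapply(junc_rows, `[[`, 0, 3L)),
      strand = vapply(junc_rows, `[[`, "", 4L),
      gene = vapply(junc_rows, `[[`, "", 1L),
      donor = vapply(junc_rows, `[[`, "", 5L),
      acceptor = "AG") else GenomicRanges::GRanges()
    list(genome = genome2, models = models, transcripts = transcripts,
         truth = list(junctions = junctions, genes = do.call(rbind, gene_rows)))
  })
}

#' Generate fused (chimeric) transcripts with known split points
#'
#' Builds `spec$n_fusions` chimeras of the kind produced when two genes
#' overlapping in their 3' UTRs are assembled into one transcript. Each
#' chimera joins two independent transcripts tail-to-tail through a
#' shared 3'-UTR overlap; by default the second constituent contributes
#' its reverse complement, so its ORF lies on the minus strand of the
#' chimera (`same_strand = TRUE` instead fuses head-to-tail on one
#' strand). Constituents are sized so that every chimera satisfies the
#' classic splitting preconditions: parent at least 2000 bp, each side
#' carrying an ORF of at least 100 aa, and longest-ORF coverage strictly
#' between 10% and 80%.
#'
#' @param spec a [synth_spec()].
#' @param same_strand fuse on the same strand instead of opposite
#'   strands (default `FALSE`).
#' @return a list with `sequences` (a `DNAStringSet`, names
#'   `fusion01`...) and `truth` (a data.frame per chimera: constituent
#'   lengths, overlap, intended split point, and the two planted ORF
#'   intervals on the parent with their strands).
#' @export
generate_fusions <- function(spec, same_strand = FALSE) {
  stopifnot(is(spec, "synth_spec"))
  with_seed(spec$seed + 2L, {
    n <- spec$n_fusions
    seqs <- character(n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      for (attempt in 1:25) {
        lenA <- sample_range(1050L, 1400L)
        lenB <- sample_range(1050L, 1400L)
        ov <- sample_range(spec$fusion_overlap[1], spec$fusion_overlap[2])
        fr <- runif(2, 0.32, 0.42)
        A <- synth_transcript(lenA, fr[1], spec$gc_content, min_utr3 = ov + 20L)
        B <- synth_transcript(lenB, fr[2], spec$gc_content, min_utr3 = ov + 20L)
        bseq <- B$seq
        substr(bseq, lenB - ov + 1L, lenB) <-
          revcomp_chr(substring(A$seq, lenA - ov + 1L, lenA))
        if (same_strand) {
          # B rides behind A on the plus strand, sharing the overlap
          parent <- paste0(A$seq, substring(bseq, ov + 1L, lenB))
          b_start <- lenA - ov + B$orf_start
          b_end <- lenA - ov + B$orf_end
          b_strand <- "+"
        } else {
          rb <- revcomp_chr(bseq)          # B transcribed from the minus strand
          parent <- paste0(A$seq, substring(rb, ov + 1L, lenB))
          b_start <- lenA - ov + (lenB - B$orf_end + 1L)
          b_end <- lenA - ov + (lenB - B$orf_start + 1L)
          b_strand <- "-"
        }
        plen <- nchar(parent)
        orfs <- find_orfs(parent, min_aa = 0L)
        big <- orfs[orfs$aa_len >= 100L, , drop = FALSE]
        cov <- if (nrow(orfs)) orfs$width[1L] / plen else 0
        planted_ok <- nrow(big) == 2L &&
          any(big$start == A$orf_start & big$end == A$orf_end & big$strand == "+") &&
          any(big$start == b_start & big$end == b_end & big$strand == b_strand)
        if (plen >= 2000L && planted_ok && cov > 0.10 && cov < 0.80) break
        if (attempt == 25L) stop("failed to construct fusion ", i)
      }
      seqs[i] <- parent
      rows[[i]] <- data.frame(
        id = sprintf("fusion%02d", i), length = nchar(parent),
        len_a = lenA, len_b = lenB, overlap = ov,
        split_point = lenA - ov %/% 2L,
        orf_a_start = A$orf_start, orf_a_end = A$orf_end, strand_a = "+",
        orf_b_start = b_start, orf_b_end = b_end, strand_b = b_strand,
        stringsAsFactors = FALSE)
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("fusion%02d", seq_len(n))
    list(sequences = out, truth = do.call(rbind, rows))
  })
}

#' Generate plain transcripts with a prescribed ORF coverage
#'
#' Intact controls (high ORF coverage) and low-coding decoys for
#' exercising the fusion splitter alongside [generate_fusions()]: a
#' control's longest ORF covers `orf_frac_range` of its length, while a
#' decoy (`orf_frac_range = NULL`) is non-coding background whose longest
#' accidental ORF stays under 10% of its length.
#'
#' @param spec a [synth_spec()] (supplies GC content and the RNG stream).
#' @param n number of transcripts.
#' @param length_range inclusive transcript length range.
#' @param orf_frac_range range of planted ORF coverage, or `NULL` for
#'   non-coding decoys.
#' @param prefix name prefix (default `"tx"`).
#' @return a named `DNAStringSet`.
#' @export
generate_plain_transcripts <- function(spec, n, length_range = c(2100L, 2800L),
                                       orf_frac_range = c(0.82, 0.9),
                                       prefix = "tx") {
  stopifnot(is(spec, "synth_spec"))
  with_seed(spec$seed + 4L, {
    seqs <- character(n)
    for (i in seq_len(n)) {
      L <- sample_range(length_range[1], length_range[2])
      if (is.null(orf_frac_range)) {
        for (attempt in 1:25) {
          s <- noncoding_seq(L, spec$gc_content)
          o <- longest_orf(s)
          if (nrow(o) == 0L || o$width / L < 0.10) break
          if (attempt == 25L) stop("failed to construct decoy ", i)
        }
        seqs[i] <- s
      } else {
        tx <- synth_transcript(L, runif(1, orf_frac_range[1], orf_frac_range[2]),
                               spec$gc_content)
        seqs[i] <- tx$seq
      }
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("%s%03d", prefix, seq_len(n))
    out
  })
}

#' Introduce a single-base frameshift into a transcript
#'
#' Inserts one base, emulating the sequencing/assembly errors that break
#' translations while leaving DNA-level detectability intact: the
#' frameshifted transcript still aligns to its source at high score, but
#' its longest ORF collapses to roughly half the planted peptide.
#'
#' @param sequence the transcript (character or `DNAString`).
#' @param position 1-based position after which the base is inserted
#'   (default: the middle of the sequence).
#' @param base the inserted base (default `"G"`).
#' @return the frameshifted sequence as a character string.
#' @export
frameshift_transcript <- function(sequence, position = NULL, base = "G") {
  s <- as_seq_string(sequence)
  if (is.null(position)) position <- nchar(s) %/% 2L
  stopifnot(position >= 1L, position < nchar(s))
  paste0(substring(s, 1L, position), base, substring(s, position + 1L, nchar(s)))
}

# introns (gaps between consecutive exons) of each model, genomic coords
introns_of <- function(models) {
  parts <- list()
  for (tx in names(models)) {
    g <- models[[tx]]
    if (length(g) < 2L) next
    g <- g[order(BiocGenerics::start(g))]
    istart <- BiocGenerics::end(g)[-length(g)] + 1L
    iend <- BiocGenerics::start(g)[-1L] - 1L
    ok <- iend >= istart
    if (!any(ok)) next
    parts[[tx]] <- GenomicRanges::GRanges(
      as.character(GenomeInfoDb::seqnames(g))[1],
      IRanges::IRanges(istart[ok], iend[ok]),
      strand = as.character(BiocGenerics::strand(g))[1])
  }
  if (!length(parts)) return(GenomicRanges::GRanges())
  unlist(methods::as(parts, "GRangesList"), use.names = FALSE)
}

#' Generate a coverage track with planted retention and coverage islands
#'
#' Paints exonic bases of every model at `spec$read_depth`, covers an
#' exact `spec$retention_rate` fraction of the introns end-to-end at a
#' depth between 1 and `read_depth - 1` (emulating intron retention),
#' leaves at least one zero-depth base inside every other intron, and
#' plants `spec$n_unexplained` coverage islands (length at least 300 bp,
#' depth `spec$unexplained_depth`) in intergenic space, separated from
#' every gene locus.
#'
#' The retained-intron count is exact by construction: introns are
#' shuffled and the first `round(retention_rate * n)` are retained.
#'
#' @param spec a [synth_spec()].
#' @param models the `GRangesList` from [generate_genes()].
#' @param genome the edited genome from [generate_genes()].
#' @return a list with `coverage` (an integer `RleList`), and the truth
#'   objects `retained` (a `GRanges` of the introns covered throughout),
#'   `not_retained`, and `unexplained` (a `GRanges` of the planted
#'   islands).
#' @export
generate_coverage <- function(spec, models, genome) {
  stopifnot(is(spec, "synth_spec"))
  lens <- chrom_lengths(genome)
  with_seed(spec$seed + 3L, {
    depth <- integer(lens[[spec$chrom]])
    ex <- unlist(models, use.names = FALSE)
    for (i in seq_along(ex))
      depth[BiocGenerics::start(ex)[i]:BiocGenerics::end(ex)[i]] <- spec$read_depth

    introns <- introns_of(models)
    n_int <- length(introns)
    n_ret <- round(spec$retention_rate * n_int)
    ord <- sample(n_int)
    ret_idx <- ord[seq_len(n_ret)]
    is_ret <- seq_len(n_int) %in% ret_idx
    for (i in seq_len(n_int)) {
      a <- BiocGenerics::start(introns)[i]; b <- BiocGenerics::end(introns)[i]
      d <- sample_range(1L, max(2L, spec$read_depth - 1L))
      depth[a:b] <- d
      if (!is_ret[i]) {
        z <- sample_range(a + 1L, b - 1L)   # introns are >= 30 bp
        depth[z] <- 0L
      }
    }

    # intergenic islands, kept clear of every gene locus
    u <- unlist(models, use.names = FALSE)
    f <- rep(names(models), S4Vectors::elementNROWS(models))
    loci <- IRanges::reduce(IRanges::IRanges(
      as.integer(tapply(BiocGenerics::start(u), f, min)),
      as.integer(tapply(BiocGenerics::end(u), f, max))))
    gaps <- IRanges::gaps(loci + 50L, start = 1L, end = lens[[spec$chrom]])
    pool <- data.frame(start = IRanges::start(gaps), end = IRanges::end(gaps))
    un_rows <- list()
    for (k in seq_len(spec$n_unexplained)) {
      w <- sample_range(spec$unexplained_length[1], spec$unexplained_length[2])
      cand <- which(pool$end - pool$start + 1L >= w + 12L)
      if (!length(cand))
        stop("not enough intergenic space for the requested coverage islands")
      g <- cand[sample.int(length(cand), 1L)]
      s0 <- pool$start[g] + 5L +
        sample_range(0L, pool$end[g] - pool$start[g] + 1L - w - 11L)
      depth[s0:(s0 + w - 1L)] <- spec$unexplained_depth
      un_rows[[k]] <- c(s0, s0 + w - 1L)
      # split the gap around the island (5 bp of zero depth on each side)
      pool <- rbind(pool[-g, , drop = FALSE],
                    data.frame(start = c(pool$start[g], s0 + w + 5L),
                               end = c(s0 - 6L, pool$end[g])))
    }
    un <- do.call(rbind, un_rows)
    cov <- methods::as(stats::setNames(list(S4Vectors::Rle(depth)), spec$chrom),
                       "SimpleRleList")
    list(coverage = cov,
         retained = introns[is_ret],
         not_retained = introns[!is_ret],
         unexplained = BiocGenerics::sort(GenomicRanges::GRanges(
           spec$chrom, IRanges::IRanges(un[, 1L], un[, 2L]))))
  })
}

#' Write a complete fixture bundle to disk
#'
#' Generates genome, gene models, transcripts, fusions and coverage from
#' one spec and writes them as plain-text files: `genome.fasta`,
#' `models.gtf`, `transcripts.fasta`, `fused.fasta`,
#' `coverage.bedgraph`, `gold.fasta`, `gold_pep.fasta` and
#' `truth.json`.
#'
#' @param spec a [synth_spec()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome0 <- generate_genome(spec)
  genes <- generate_genes(spec, genome0)
  fus <- generate_fusions(spec)
  covr <- generate_coverage(spec, genes$models, genes$genome)
  write_fasta(genes$genome, file.path(dir, "genome.fasta"))
  write_gtf(genes$models, file.path(dir, "models.gtf"))
  write_fasta(genes$transcripts, file.path(dir, "transcripts.fasta"))
  write_fasta(fus$sequences, file.path(dir, "fused.fasta"))
  write_bedgraph(covr$coverage, file.path(dir, "coverage.bedgraph"))
  write_fasta(genes$transcripts, file.path(dir, "gold.fasta"))
  peps <- Biostrings::AAStringSet(genes$truth$genes$peptide)
  names(peps) <- genes$truth$genes$id
  write_fasta(peps, file.path(dir, "gold_pep.fasta"))
  truth <- list(
    junction_donors = as.list(table(genes$truth$junctions$donor)),
    n_junctions = length(genes$truth$junctions),
    fusions = fus$truth,
    retained = length(covr$retained),
    n_introns = length(covr$retained) + length(covr$not_retained),
    unexplained = data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(covr$unexplained)),
      start = BiocGenerics::start(covr$unexplained),
      end = BiocGenerics::end(covr$unexplained)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
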