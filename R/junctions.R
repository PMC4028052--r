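#' Extract unique splice junctions from transcript models
#'
#' Each gap between consecutive exons of a model is an intron; its first
#' and last two bases in transcription direction are the splice donor and
#' acceptor dinucleotides (reverse-complemented genome sequence for
#' minus-strand models). Junctions shared by several isoforms are
#' deduplicated on their genomic coordinates and strand so alternate
#' splicing never counts the same junction twice.
#'
#' Models with unknown strand (`*`) are first oriented with
#' [infer_strand_by_acceptor()]; models that remain unresolved are read
#' on the plus strand.
#'
#' @param models a `GRangesList` of exons per transcript (see [read_gtf()]).
#' @param genome a named `DNAStringSet`.
#' @param min_intron minimum credible intron length; shorter gaps are
#'   dropped with a warning (default 30).
#' @return a `GRanges` of unique introns (1-based closed) with strand and
#'   metadata columns `donor` and `acceptor` (strand-oriented
#'   dinucleotides).
#' @seealso [classify_junctions()], [filter_ag_acceptors()]
#' @export
extract_junctions <- function(models, genome, min_intron = 30L) {
  stopifnot(is(models, "GRangesList"), is(genome, "DNAStringSet"))
  lens <- chrom_lengths(genome)
  parts <- list()
  for (tx in names(models)) {
    g <- models[[tx]]
    if (length(g) < 2L) next
    chrom <- as.character(GenomeInfoDb::seqnames(g))[1]
    if (!chrom %in% names(lens)) stop("chrom not in genome: ", chrom)
    str <- as.character(BiocGenerics::strand(g))[1]
    if (str == "*") str <- infer_strand_by_acceptor(g, genome)
    if (str == "*") str <- "+"
    g <- g[order(BiocGenerics::start(g))]
    istart <- BiocGenerics::end(g)[-length(g)] + 1L
    iend <- BiocGenerics::start(g)[-1L] - 1L
    ok <- iend >= istart   # zero-length gaps (abutting exons) are not introns
    istart <- istart[ok]; iend <- iend[ok]
    if (!length(istart)) next
    if (any(iend > lens[chrom]) || any(istart < 1L))
      stop("intron outside chromosome bounds in transcript ", tx)
    parts[[tx]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(istart, iend), strand = str)
  }
  if (!length(parts)) {
    gr <- GenomicRanges::GRanges()
    gr$donor <- character(0); gr$acceptor <- character(0)
    return(gr)
  }
  gr <- unlist(methods::as(parts, "GRangesList"), use.names = FALSE)
  short <- BiocGenerics::width(gr) < min_intron
  if (any(short)) {
    warning(sum(short), " intron(s) shorter than ", min_intron, " dropped")
    gr <- gr[!short]
  }
  gr <- unique(gr)
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  don <- character(length(gr)); acc <- character(length(gr))
  for (i in seq_along(gr)) {
    chrom <- as.character(GenomeInfoDb::seqnames(gr))[i]
    a <- BiocGenerics::start(gr)[i]; b <- BiocGenerics::end(gr)[i]
    first2 <- as.character(Biostrings::subseq(genome[[chrom]], a, a + 1L))
    last2 <- as.character(Biostrings::subseq(genome[[chrom]], b - 1L, b))
    if (as.character(BiocGenerics::strand(gr))[i] == "-") {
      don[i] <- revcomp_chr(last2)
      acc[i] <- revcomp_chr(first2)
    } else {
      don[i] <- first2
      acc[i] <- last2
    }
  }
  gr$donor <- don
  gr$acceptor <- acc
  gr
}

DONOR_CLASSES <- c("GC", "GT", "GA", "AT", "CT")
ACCEPTOR_CLASSES <- c("AG", "AC", "GC", "AT")

#' Tally splice junctions by donor and acceptor class
#'
#' Donors are binned into \{GC, GT, GA, AT, CT, other\} and acceptors into
#' \{AG, AC, GC, AT, other\}; any dinucleotide containing `N` falls into
#' `other`. In GC-rich genomes the non-canonical GC donor can dominate
#' the canonical GT while the acceptor stays almost entirely AG.
#'
#' @param junctions a `GRanges` from [extract_junctions()] (or any object
#'   with `donor` / `acceptor` metadata columns).
#' @return an object of class `junction_tally`: a list with `donors` and
#'   `acceptors` (named integer counts), `donor_pct` / `acceptor_pct`
#'   (rounded to integers for reporting) and `total`.
#' @export
classify_junctions <- function(junctions) {
  don <- junctions$donor
  acc <- junctions$acceptor
  if (is.null(don) || is.null(acc))
    stop("'junctions' must carry donor and acceptor columns")
  bin <- function(x, classes) {
    x[grepl("N", x, fixed = TRUE)] <- "other"
    x[!x %in% classes] <- "other"
    tab <- table(factor(x, levels = c(classes, "other")))
    stats::setNames(as.integer(tab), names(tab))
  }
  donors <- bin(don, DONOR_CLASSES)
  acceptors <- bin(acc, ACCEPTOR_CLASSES)
  structure(list(
    donors = donors, acceptors = acceptors, total = length(don),
    donor_pct = stats::setNames(as.integer(round(100 * donors / max(1L, length(don)))),
                                names(donors)),
    acceptor_pct = stats::setNames(as.integer(round(100 * acceptors / max(1L, length(acc)))),
                                   names(acceptors))),
    class = "junction_tally")
}

#' @export
print.junction_tally <- function(x, ...) {
  cat("junction_tally over", x$total, "unique junctions\n")
  cat("  donors:   ",
      paste(sprintf("%s %d (%d%%)", names(x$donors), x$donors, x$donor_pct),
            collapse = ", "), "\n")
  cat("  acceptors:",
      paste(sprintf("%s %d (%d%%)", names(x$acceptors), x$acceptors, x$acceptor_pct),
            collapse = ", "), "\n")
  invisible(x)
}

#' Keep only junctions with AG acceptors
#'
#' The standard noise filter for junctions derived from error-prone EST
#' alignments: donor statistics are only trusted where the acceptor is
#' the canonical AG.
#'
#' @param junctions a `GRanges` from [extract_junctions()].
#' @return the subset with `acceptor == "AG"`.
#' @export
filter_ag_acceptors <- function(junctions) {
  if (is.null(junctions$acceptor)) stop("'junctions' must carry an acceptor column")
  junctions[junctions$acceptor == "AG"]
}

#' Infer the strand of a strand-unknown model from its acceptors
#'
#' For alignments of unstranded cDNA (typical of ESTs) the transcribed
#' strand can usually be recovered from the splice acceptors: introns of
#' the true strand end in AG read in transcription direction. Each intron
#' votes `+` if its forward-strand sequence ends in `AG` and `-` if its
#' reverse-complement does (i.e. the forward sequence starts with `CT`);
#' the majority wins.
#'
#' @param model a `GRanges` of exons (one transcript) with at least one
#'   intron.
#' @param genome a named `DNAStringSet`.
#' @return `"+"`, `"-"`, or `"*"` on a tie.
#' @export
infer_strand_by_acceptor <- function(model, genome) {
  g <- model[order(BiocGenerics::start(model))]
  if (length(g) < 2L) stop("model has no intron")
  chrom <- as.character(GenomeInfoDb::seqnames(g))[1]
  istart <- BiocGenerics::end(g)[-length(g)] + 1L
  iend <- BiocGenerics::start(g)[-1L] - 1L
  plus <- 0L; minus <- 0L
  for (i in seq_along(istart)) {
    first2 <- as.character(Biostrings::subseq(genome[[chrom]], istart[i], istart[i] + 1L))
    last2 <- as.character(Biostrings::subseq(genome[[chrom]], iend[i] - 1L, iend[i]))
    if (last2 == "AG") plus <- plus + 1L
    if (first2 == "CT") minus <- minus + 1L
  }
  if (plus > minus) "+" else if (minus > plus) "-" else "*"
}
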