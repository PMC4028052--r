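#' Read a FASTA file into a DNAStringSet
#'
#' Sequences are uppercased on read and restricted to the \{A,C,G,T,N\}
#' alphabet. Duplicate record names and empty sequences are errors: both
#' almost always indicate a malformed or concatenated assembly file.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @param alphabet_check if `TRUE` (default), error on characters outside
#'   \{A,C,G,T,N\}.
#' @return a [Biostrings::DNAStringSet] named by record identifier (the
#'   first whitespace-delimited token of each header).
#' @seealso [write_fasta()], [read_protein_fasta()]
#' @export
read_fasta <- function(path, alphabet_check = TRUE) {
  x <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (any(nm == "")) stop("malformed FASTA header: empty identifier in ", path)
  if (anyDuplicated(nm))
    stop("duplicate sequence identifier(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(Biostrings::width(x) == 0L))
    stop("empty sequence(s) in ", path, ": ",
         paste(nm[Biostrings::width(x) == 0L], collapse = ", "))
  chr <- toupper(as.character(x))
  if (alphabet_check && any(grepl("[^ACGTN]", chr)))
    stop("sequence(s) with characters outside {A,C,G,T,N} in ", path)
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- nm
  out
}

#' Read a protein FASTA file into an AAStringSet
#'
#' @inheritParams read_fasta
#' @return a [Biostrings::AAStringSet] named by record identifier.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm))
    stop("duplicate sequence identifier(s) in ", path)
  names(x) <- nm
  x
}

#' Write sequences to a FASTA file
#'
#' @param x a named [Biostrings::XStringSet] (DNA or protein).
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Exon features are grouped by their `transcript_id` attribute into a
#' [GenomicRanges::GRangesList], one element per transcript, exons sorted
#' by start coordinate. GTF coordinates are 1-based inclusive, which is
#' also the in-memory convention, so no shifting occurs. Transcript strand
#' may be `+`, `-` or `*` (unknown, e.g. unstranded EST alignments).
#'
#' @param path path to a GTF file with `exon` features.
#' @return a named `GRangesList` of exons per transcript.
#' @seealso [write_gtf()], [transcript_models()], [extract_junctions()]
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  tid <- gr$transcript_id
  if (is.null(tid) || anyNA(tid) || any(tid == ""))
    stop("exon feature(s) without transcript_id attribute in ", path)
  transcript_models(gr, tid)
}

#' Assemble exon ranges into validated transcript models
#'
#' @param exons a `GRanges` of exons.
#' @param transcript_id character vector assigning each exon to a transcript.
#' @return a named `GRangesList`, exons sorted by start within each
#'   transcript; overlapping exons within one transcript are an error.
#' @export
transcript_models <- function(exons, transcript_id) {
  stopifnot(is(exons, "GRanges"), length(exons) == length(transcript_id))
  S4Vectors::mcols(exons) <- NULL
  grl <- GenomicRanges::split(exons, factor(transcript_id, levels = unique(transcript_id)))
  grl <- S4Vectors::endoapply(grl, function(g) g[order(BiocGenerics::start(g))])
  ov <- sum(S4Vectors::elementNROWS(IRanges::reduce(IRanges::ranges(grl), min.gapwidth = 0L)))
  if (ov != sum(S4Vectors::elementNROWS(grl))) {
    bad <- names(grl)[S4Vectors::elementNROWS(IRanges::reduce(IRanges::ranges(grl), min.gapwidth = 0L)) !=
                        S4Vectors::elementNROWS(grl)]
    stop("overlapping exons within transcript(s): ", paste(bad, collapse = ", "))
  }
  str_n <- vapply(as.list(BiocGenerics::strand(grl)),
                  function(s) length(unique(as.character(s))), integer(1))
  if (any(str_n > 1L))
    stop("mixed strand within transcript(s): ",
         paste(names(grl)[str_n > 1L], collapse = ", "))
  grl
}

#' Write transcript models to a GTF file
#'
#' @param models a `GRangesList` of exons per transcript (see [read_gtf()]).
#' @param path output path.
#' @param source source field for column 2 (default `"txqc"`).
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path, source = "txqc") {
  gr <- unlist(models, use.names = FALSE)
  tid <- rep(names(models), S4Vectors::elementNROWS(models))
  lines <- sprintf(
    "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    as.character(GenomeInfoDb::seqnames(gr)), source,
    BiocGenerics::start(gr), BiocGenerics::end(gr),
    as.character(BiocGenerics::strand(gr)), tid, tid)
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-base coverage track
#'
#' Reads a bedGraph (0-based half-open) or fixedStep wiggle file into a
#' dense per-base depth vector per chromosome (an integer
#' [IRanges::RleList]). Positions absent from the file have depth 0.
#' Overlapping bedGraph records are an error: depth records are expected
#' to partition the covered bases.
#'
#' @param path path to a bedGraph or wiggle file.
#' @param genome a named `DNAStringSet` (or named integer vector of
#'   chromosome lengths) defining the chromosomes and their lengths.
#' @param format `"bedGraph"` (default) or `"wig"`.
#' @return an `RleList` of non-negative integer depths, one run-length
#'   vector per chromosome, each of exactly the chromosome length.
#' @seealso [write_bedgraph()], [find_unexplained_regions()], [assess_retention()]
#' @export
read_coverage <- function(path, genome, format = c("bedGraph", "wig")) {
  format <- match.arg(format)
  lens <- chrom_lengths(genome)
  gr <- rtracklayer::import(path, format = format)
  if (length(gr)) {
    bad <- setdiff(as.character(GenomeInfoDb::seqnames(gr)), names(lens))
    if (length(bad)) stop("coverage record(s) on unknown chrom(s): ",
                          paste(unique(bad), collapse = ", "))
    if (any(gr$score < 0)) stop("negative depth in ", path)
    ends <- BiocGenerics::end(gr)
    if (any(ends > lens[as.character(GenomeInfoDb::seqnames(gr))]))
      stop("coverage record beyond chromosome end in ", path)
    if (sum(IRanges::width(IRanges::reduce(IRanges::ranges(gr)))) <
        sum(IRanges::width(gr)) && format == "bedGraph")
      stop("overlapping bedGraph records in ", path)
  }
  GenomeInfoDb::seqlevels(gr) <- names(lens)
  if (length(gr) == 0L) {
    cov <- methods::as(lapply(lens, function(n) S4Vectors::Rle(0L, n)),
                       "SimpleRleList")
    return(cov)
  }
  cov <- GenomicRanges::coverage(gr, weight = gr$score, width = as.list(lens))
  methods::as(lapply(cov, function(r) { S4Vectors::runValue(r) <- as.integer(S4Vectors::runValue(r)); r }),
              "SimpleRleList")
}

#' Write a coverage track as bedGraph
#'
#' Zero-depth runs are omitted; coordinates are converted to the 0-based
#' half-open on-disk convention.
#'
#' @param coverage an `RleList` of per-base depths (see [read_coverage()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(coverage, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(coverage)) {
    r <- coverage[[chrom]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, ends[-length(ends)])
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", chrom, starts[keep], ends[keep],
                         vals[keep]), con)
  }
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @param names optional name column (defaults to `names(gr)` or `"."`).
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, names = NULL) {
  if (is.null(names)) names <- if (is.null(base::names(gr))) rep(".", length(gr)) else base::names(gr)
  score <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                     as.character(GenomeInfoDb::seqnames(gr)),
                     BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                     names, score, as.character(BiocGenerics::strand(gr))),
             path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path path to a BED3+ file (0-based half-open on disk).
#' @return a `GRanges` (1-based closed in memory).
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "bed")
}

# chromosome lengths from a DNAStringSet or a named integer vector
chrom_lengths <- function(genome) {
  if (is(genome, "XStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    stats::setNames(as.integer(genome), names(genome))
  } else stop("'genome' must be a named DNAStringSet or named lengths vector")
}

#' Extract spliced transcript sequences from a genome
#'
#' Concatenates each model's exon sequences in genomic order and
#' reverse-complements the result for minus-strand models. Models with
#' unknown strand (`*`) are read as if on the plus strand.
#'
#' @param models a `GRangesList` of exons per transcript.
#' @param genome a named `DNAStringSet`.
#' @return a `DNAStringSet` of spliced transcript sequences, named by
#'   transcript.
#' @export
spliced_transcript_seqs <- function(models, genome) {
  stopifnot(is(genome, "DNAStringSet"))
  seqs <- vapply(names(models), function(tx) {
    g <- models[[tx]]
    chrom <- as.character(GenomeInfoDb::seqnames(g))[1]
    if (!chrom %in% names(genome)) stop("chrom not in genome: ", chrom)
    parts <- as.character(Biostrings::extractAt(genome[[chrom]], IRanges::ranges(g)))
    s <- paste(parts, collapse = "")
    if (as.character(BiocGenerics::strand(g))[1] == "-") revcomp_chr(s) else s
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}
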