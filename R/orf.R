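#' Enumerate open reading frames in all six frames
#'
#' Finds every maximal ORF on both strands of a transcript sequence under
#' one of two conventions:
#'
#' * `stop_to_stop` (default): an ORF is a maximal run of non-stop codons
#'   bounded by stop codons or by the sequence ends. No initial Met is
#'   required; this is the right convention for partial transcripts, where
#'   the true start codon is often missing from the assembly.
#' * `met_to_stop`: the suffix of a stop-to-stop ORF beginning at its
#'   first Met.
#'
#' Codons containing `N` translate to `X`; `X` counts as an ordinary
#' residue and never terminates an ORF, so holes in a draft genome do not
#' shatter reading frames. Terminal stop codons are excluded from the
#' peptide (and from `aa_len`) but included in the nucleotide interval
#' when present. Trailing bases short of a full codon are dropped.
#'
#' @param sequence a DNA sequence (character string, `DNAString`, or
#'   length-1 `DNAStringSet`) over \{A,C,G,T,N\}.
#' @param mode `"stop_to_stop"` or `"met_to_stop"`.
#' @param min_aa minimum peptide length in amino acids (default 1).
#' @return a data.frame with one row per ORF, sorted by peptide length
#'   descending with deterministic tie-breaks (`+` strand first, then
#'   smaller forward start). Columns: `strand` (+/-), `frame` (0-2 offset
#'   on the read strand), `start`, `end` (1-based closed interval on the
#'   forward coordinates of the input), `width`, `mode`, `aa_len`,
#'   `peptide`.
#' @seealso [longest_orf()], [orf_coverage()], [translate_longest_orfs()]
#' @examples
#' find_orfs("ATGAAATAG")            # peptide "MK", interval spans the stop
#' find_orfs("AAAAAAAAA", mode = "met_to_stop")  # no Met, no ORF
#' @export
find_orfs <- function(sequence, mode = c("stop_to_stop", "met_to_stop"),
                      min_aa = 1L) {
  mode <- match.arg(mode)
  s <- check_dna(as_seq_string(sequence))
  n <- nchar(s)
  if (n < 3L) stop("sequence shorter than one codon")
  if (min_aa < 0L) stop("min_aa must be >= 0")
  code <- Biostrings::GENETIC_CODE
  rc <- revcomp_chr(s)

  rows <- vector("list", 64L)
  nr <- 0L
  for (str in c("+", "-")) {
    ss <- if (str == "+") s else rc
    for (f in 0:2) {
      ncod <- (n - f) %/% 3L
      if (ncod < 1L) next
      cod_start <- f + 3L * (seq_len(ncod) - 1L) + 1L
      aa <- unname(code[substring(ss, cod_start, cod_start + 2L)])
      aa[is.na(aa)] <- "X"
      is_stop <- aa == "*"
      r <- rle(is_stop)
      seg_end <- cumsum(r$lengths)
      seg_start <- seg_end - r$lengths + 1L
      for (k in which(!r$values)) {
        cs <- seg_start[k]; ce <- seg_end[k]
        if (mode == "met_to_stop") {
          m <- which(aa[cs:ce] == "M")
          if (!length(m)) next
          cs <- cs + m[1L] - 1L
        }
        pep <- paste(aa[cs:ce], collapse = "")
        alen <- ce - cs + 1L
        if (alen < min_aa) next
        has_stop <- ce < ncod   # next codon, if any, is a stop
        a <- f + 3L * (cs - 1L) + 1L
        b <- f + 3L * (ce + as.integer(has_stop))
        if (str == "-") { tmp <- a; a <- n - b + 1L; b <- n - tmp + 1L }
        nr <- nr + 1L
        if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[nr]] <- list(str, f, a, b, alen, pep)
      }
    }
  }
  if (nr == 0L) {
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(), width = integer(),
                      mode = character(), aa_len = integer(),
                      peptide = character(), stringsAsFactors = FALSE))
  }
  rows <- rows[seq_len(nr)]
  out <- data.frame(
    strand = vapply(rows, `[[`, "", 1L),
    frame = vapply(rows, `[[`, 0L, 2L),
    start = vapply(rows, `[[`, 0L, 3L),
    end = vapply(rows, `[[`, 0L, 4L),
    aa_len = vapply(rows, `[[`, 0L, 5L),
    peptide = vapply(rows, `[[`, "", 6L),
    stringsAsFactors = FALSE)
  out$width <- out$end - out$start + 1L
  out$mode <- mode
  out <- out[order(-out$aa_len, out$strand != "+", out$start), ]
  rownames(out) <- NULL
  out[, c("strand", "frame", "start", "end", "width", "mode", "aa_len", "peptide")]
}

#' The longest open reading frame of a sequence
#'
#' Returns the first ORF in [find_orfs()] ordering: longest peptide, ties
#' broken deterministically (`+` strand before `-`, then smaller start).
#'
#' @inheritParams find_orfs
#' @return a one-row data.frame (see [find_orfs()]), or a zero-row
#'   data.frame if the sequence has no ORF under `mode`.
#' @export
longest_orf <- function(sequence, mode = c("stop_to_stop", "met_to_stop")) {
  mode <- match.arg(mode)
  orfs <- find_orfs(sequence, mode = mode, min_aa = 0L)
  utils::head(orfs, 1L)
}

#' Fraction of a transcript covered by an ORF
#'
#' @param sequence the transcript sequence the ORF was found on.
#' @param orf a one-row data.frame as returned by [longest_orf()].
#' @return interval length divided by sequence length, in \[0, 1\]; 0 for
#'   a zero-row `orf`.
#' @export
orf_coverage <- function(sequence, orf) {
  s <- as_seq_string(sequence)
  if (nrow(orf) == 0L) return(0)
  stopifnot(nrow(orf) == 1L)
  if (orf$start < 1L || orf$end > nchar(s))
    stop("ORF interval outside sequence")
  (orf$end - orf$start + 1L) / nchar(s)
}

#' Translate a collection by its longest ORFs
#'
#' The peptide export used for protein-level gold-standard checks: each
#' transcript is represented by the peptide of its longest ORF.
#'
#' @param x a `DNAStringSet`.
#' @param mode ORF convention, see [find_orfs()].
#' @param min_aa drop transcripts whose longest peptide is shorter than
#'   this (default 1).
#' @return an [Biostrings::AAStringSet] named like `x` (transcripts with
#'   no qualifying ORF are omitted).
#' @export
translate_longest_orfs <- function(x, mode = "stop_to_stop", min_aa = 1L) {
  stopifnot(is(x, "DNAStringSet"))
  peps <- vapply(seq_along(x), function(i) {
    o <- longest_orf(x[[i]], mode = mode)
    if (nrow(o) == 0L || o$aa_len < min_aa) NA_character_ else o$peptide
  }, character(1))
  keep <- !is.na(peps)
  out <- Biostrings::AAStringSet(peps[keep])
  names(out) <- names(x)[keep]
  out
}
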