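#' Decide whether a transcript is an artificial fusion and how to split it
#'
#' Applies a rule set over the longest stop-to-stop ORFs of a transcript
#' to detect chimeras, typically produced when two genes on opposite
#' strands overlap in their 3' UTRs and an assembler joins them:
#'
#' 1. If the longest ORF covers less than `remove_cov` of the sequence,
#'    the transcript is removed (likely junk with no real coding content).
#' 2. If the longest ORF covers at least `keep_cov`, it is kept intact.
#' 3. Transcripts shorter than `min_parent_len` are kept intact.
#' 4. Otherwise the top `max_orfs` ORFs with peptides of at least
#'    `min_peptide_aa` amino acids are examined: if two or three of them
#'    occupy pairwise non-overlapping transcript intervals and every
#'    resulting child is at least `min_child_len` long, the transcript is
#'    split into that many children. Cuts are placed at the midpoint of
#'    the gap between consecutive participating ORFs, so each child keeps
#'    its flanking UTR-like sequence.
#'
#' Overlap is evaluated on forward-projected intervals regardless of
#' strand: an ORF read on the minus strand still occupies the same
#' physical stretch of the transcript.
#'
#' @param sequence the transcript sequence (character, `DNAString`, or
#'   length-1 `DNAStringSet`).
#' @param keep_cov ORF-coverage fraction at or above which a transcript is
#'   never split (default 0.80).
#' @param remove_cov ORF-coverage fraction below which a transcript is
#'   removed (default 0.10).
#' @param min_parent_len minimum transcript length eligible for splitting
#'   (default 2000; a transcript of exactly 2000 bp is eligible).
#' @param min_child_len minimum length of each split product (default 300).
#' @param min_peptide_aa minimum participating peptide length (default 100).
#' @param max_orfs number of top ORFs examined (default 3).
#' @return an object of class `split_decision`: a list with `verdict`
#'   (`"keep"`, `"split2"`, `"split3"` or `"remove"`), `children` (a
#'   data.frame of 1-based closed child intervals on the parent; empty
#'   unless split), `orfs` (the participating ORF rows), and
#'   `opposite_strand` (`TRUE` if participating ORFs lie on both strands).
#' @seealso [split_collection()], [find_orfs()]
#' @export
decide_split <- function(sequence, keep_cov = 0.80, remove_cov = 0.10,
                         min_parent_len = 2000L, min_child_len = 300L,
                         min_peptide_aa = 100L, max_orfs = 3L) {
  if (remove_cov >= keep_cov) stop("remove_cov must be < keep_cov")
  s <- check_dna(as_seq_string(sequence))
  len <- nchar(s)
  orfs <- if (len >= 3L) find_orfs(s, mode = "stop_to_stop", min_aa = 0L)
          else find_orfs("AAA", min_aa = 0L)[0L, ]
  cov <- if (nrow(orfs)) orfs$width[1L] / len else 0

  decision <- function(verdict, children = NULL, orfs_used = orfs[0L, ]) {
    if (is.null(children))
      children <- data.frame(start = integer(), end = integer())
    structure(list(verdict = verdict, children = children, orfs = orfs_used,
                   opposite_strand = length(unique(orfs_used$strand)) > 1L,
                   length = len, orf_coverage = cov),
              class = "split_decision")
  }

  if (cov < remove_cov) return(decision("remove"))
  if (cov >= keep_cov) return(decision("keep"))
  if (len < min_parent_len) return(decision("keep"))

  cand <- utils::head(orfs, max_orfs)
  cand <- cand[cand$aa_len >= min_peptide_aa, , drop = FALSE]
  if (nrow(cand) < 2L) return(decision("keep"))

  overlaps <- function(a, b) a$start <= b$end && b$start <= a$end
  children_for <- function(rows) {
    rows <- rows[order(rows$start), , drop = FALSE]
    k <- nrow(rows)
    cuts <- integer(0)
    for (i in seq_len(k - 1L))
      cuts <- c(cuts, (rows$end[i] + rows$start[i + 1L]) %/% 2L)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, len)
    list(children = data.frame(start = starts, end = ends), orfs = rows)
  }
  qualifies <- function(rows) {
    k <- nrow(rows)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      if (overlaps(rows[i, ], rows[j, ])) return(NULL)
    ch <- children_for(rows)
    if (all(ch$children$end - ch$children$start + 1L >= min_child_len)) ch
    else NULL
  }

  if (nrow(cand) == 3L) {
    ch <- qualifies(cand)
    if (!is.null(ch)) return(decision("split3", ch$children, ch$orfs))
  }
  # best qualifying pair: highest total peptide length, then leftmost start
  best <- NULL; best_key <- NULL
  idx <- utils::combn(nrow(cand), 2L)
  for (c_i in seq_len(ncol(idx))) {
    rows <- cand[idx[, c_i], , drop = FALSE]
    ch <- qualifies(rows)
    if (is.null(ch)) next
    key <- c(-sum(rows$aa_len), min(rows$start))
    if (is.null(best) || key[1L] < best_key[1L] ||
        (key[1L] == best_key[1L] && key[2L] < best_key[2L])) {
      best <- ch; best_key <- key
    }
  }
  if (!is.null(best)) return(decision("split2", best$children, best$orfs))
  decision("keep")
}

#' @export
print.split_decision <- function(x, ...) {
  cat("split_decision:", x$verdict,
      sprintf("(length %d, longest-ORF coverage %.1f%%)\n",
              x$length, 100 * x$orf_coverage))
  if (nrow(x$children)) {
    cat("  children:",
        paste(sprintf("[%d,%d]", x$children$start, x$children$end),
              collapse = " "),
        if (x$opposite_strand) " [opposite strands]" else "", "\n")
  }
  invisible(x)
}

#' Split the fused transcripts of a collection
#'
#' Applies [decide_split()] to every transcript. Kept transcripts pass
#' through unchanged; split children are emitted in positional order with
#' suffixed identifiers (`parent.1`, `parent.2`, ...); removed transcripts
#' are dropped.
#'
#' @param x a named `DNAStringSet`.
#' @param ... parameters forwarded to [decide_split()].
#' @return a list with `sequences` (the refined `DNAStringSet`), `report`
#'   (an object of class `split_report`: verdict tallies plus the number
#'   of opposite-strand splits) and `decisions` (a per-transcript
#'   data.frame of verdicts).
#' @export
split_collection <- function(x, ...) {
  stopifnot(is(x, "DNAStringSet"))
  if (is.null(names(x)) && length(x)) stop("sequences must be named")
  out_seq <- character(0)
  out_nm <- character(0)
  verdicts <- character(length(x))
  opp <- logical(length(x))
  for (i in seq_along(x)) {
    s <- as.character(x[[i]])
    d <- decide_split(s, ...)
    verdicts[i] <- d$verdict
    opp[i] <- d$opposite_strand && d$verdict %in% c("split2", "split3")
    if (d$verdict == "keep") {
      out_seq <- c(out_seq, s); out_nm <- c(out_nm, names(x)[i])
    } else if (d$verdict %in% c("split2", "split3")) {
      ch <- substring(s, d$children$start, d$children$end)
      out_seq <- c(out_seq, ch)
      out_nm <- c(out_nm, paste0(names(x)[i], ".", seq_along(ch)))
    } # remove: drop
  }
  seqs <- Biostrings::DNAStringSet(out_seq)
  names(seqs) <- out_nm
  tally <- c(keep = sum(verdicts == "keep"),
             split2 = sum(verdicts == "split2"),
             split3 = sum(verdicts == "split3"),
             removed = sum(verdicts == "remove"),
             opposite_strand = sum(opp))
  report <- structure(as.list(tally), class = "split_report")
  list(sequences = seqs, report = report,
       decisions = data.frame(id = as.character(names(x)),
                              verdict = verdicts,
                              opposite_strand = opp,
                              stringsAsFactors = FALSE))
}

#' @export
print.split_report <- function(x, ...) {
  cat(sprintf(
    "split_report: %d kept, %d split in two, %d split in three, %d removed (%d opposite-strand splits)\n",
    x$keep, x$split2, x$split3, x$removed, x$opposite_strand))
  invisible(x)
}
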