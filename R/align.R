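#' Best local alignment under a match-based hit score
#'
#' Smith-Waterman local alignment with affine gap events: a gap of any
#' length costs `gap_open` plus `gap_extend` per base beyond the first.
#' Under the default scoring (match +1, mismatch -1, gap event -1,
#' extension 0) the optimal score equals
#' `matches - mismatches - gap events`, the classic match-based hit score
#' used to call a reference gene "present" in a transcript collection
#' (a score of at least 200 requires roughly 200 aligned matching bases).
#'
#' Both sequences must be of the same alphabet class (both DNA or both
#' protein). Characters are compared literally after uppercasing, so `N`
#' matches only `N`.
#'
#' @param query,target sequences (character, `XString`, or length-1
#'   `XStringSet`).
#' @param match,mismatch,gap_open,gap_extend scoring parameters; defaults
#'   +1 / -1 / -1 / 0.
#' @return an object of class `alignment_hit`: a list with `score`,
#'   `matches`, `mismatches`, `q_gap_count` / `t_gap_count` (gap events
#'   opened in query / target), `q_gap_bases` / `t_gap_bases`,
#'   `q_interval` and `t_interval` (1-based closed aligned spans; both
#'   zero-width when no positive-scoring alignment exists), `identity`
#'   (matches over aligned residue pairs) and the two gapped alignment
#'   strings.
#' @seealso [presence_check()], [dedupe()], [merge_collections()]
#' @export
align_local <- function(query, target, match = 1, mismatch = -1,
                        gap_open = -1, gap_extend = 0) {
  q <- as_alpha_string(query, "query")
  t <- as_alpha_string(target, "target")
  if (attr(q, "alpha") != attr(t, "alpha"))
    stop("query and target must both be DNA or both be protein")
  res <- .sw_align(as.character(q), as.character(t),
                   match, mismatch, gap_open, gap_extend)
  pairs <- res$matches + res$mismatches
  structure(list(
    score = res$score,
    matches = res$matches, mismatches = res$mismatches,
    q_gap_count = res$q_gap_count, t_gap_count = res$t_gap_count,
    q_gap_bases = res$q_gap_bases, t_gap_bases = res$t_gap_bases,
    q_interval = c(start = res$q_start, end = res$q_end),
    t_interval = c(start = res$t_start, end = res$t_end),
    identity = if (pairs > 0) res$matches / pairs else 0,
    q_aligned = res$q_aligned, t_aligned = res$t_aligned),
    class = "alignment_hit")
}

#' @export
print.alignment_hit <- function(x, ...) {
  cat(sprintf(
    "alignment_hit: score %g (%d matches, %d mismatches, %d gap events), query %d-%d, target %d-%d, identity %.1f%%\n",
    x$score, x$matches, x$mismatches, x$q_gap_count + x$t_gap_count,
    x$q_interval["start"], x$q_interval["end"],
    x$t_interval["start"], x$t_interval["end"], 100 * x$identity))
  invisible(x)
}

# uppercase and tag alphabet class ("dna" or "protein")
as_alpha_string <- function(x, arg) {
  alpha <- NA_character_
  if (is(x, "DNAString") || is(x, "DNAStringSet")) alpha <- "dna"
  if (is(x, "AAString") || is(x, "AAStringSet")) alpha <- "protein"
  s <- as_seq_string(x, arg)
  if (is.na(alpha))
    alpha <- if (!grepl("[^ACGTN]", s)) "dna" else "protein"
  if (alpha == "protein" && grepl("[^A-Z*]", s))
    stop("'", arg, "' contains non-sequence characters")
  structure(s, alpha = alpha)
}
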