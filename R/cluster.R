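#' Greedy identity-based redundancy removal
#'
#' Longest-first greedy clustering in the style of classic redundancy
#' removers: sequences are processed from longest to shortest (ties by
#' identifier) and each sequence joins the first existing cluster whose
#' representative it matches at `identity` or better over at least
#' `min_coverage` of its own length; otherwise it founds a new cluster.
#' Because processing is longest-first, every representative is the
#' longest member of its cluster. Identity is computed on the best local
#' alignment ([align_local()]) as matches over the aligned span of the
#' member.
#'
#' @param x a named `DNAStringSet` or `AAStringSet`.
#' @param identity identity threshold in (0.5, 1] (default 0.95).
#' @param min_coverage minimum fraction of the member's own length the
#'   alignment must span (default 0.80).
#' @return a list with `sequences` (representatives only, in founding
#'   order) and `assignment` (a data.frame: member, representative,
#'   identity).
#' @export
dedupe <- function(x, identity = 0.95, min_coverage = 0.80) {
  stopifnot(is(x, "XStringSet"))
  if (identity <= 0.5 || identity > 1) stop("identity must be in (0.5, 1]")
  ord <- order(-Biostrings::width(x), names(x))
  x <- x[ord]
  reps <- integer(0)           # indices into x
  member <- character(length(x))
  repr <- character(length(x))
  ident <- numeric(length(x))
  for (i in seq_along(x)) {
    assigned <- FALSE
    for (r in reps) {
      hit <- align_local(x[[i]], x[[r]])
      span <- hit$q_interval["end"] - hit$q_interval["start"] + 1
      if (span >= min_coverage * Biostrings::width(x)[i] &&
          hit$matches / span >= identity) {
        member[i] <- names(x)[i]; repr[i] <- names(x)[r]
        ident[i] <- hit$matches / span
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      member[i] <- names(x)[i]; repr[i] <- names(x)[i]; ident[i] <- 1
    }
  }
  list(sequences = x[reps],
       assignment = data.frame(member = member, representative = repr,
                               identity = ident, stringsAsFactors = FALSE))
}

#' Merge two transcript collections by identity and containment
#'
#' Combines the outputs of two clustering strategies: a primary
#' collection that defines longer, less redundant transcripts, and a
#' secondary collection that retains genes the primary lost. Each
#' secondary transcript is classified as:
#'
#' * `identical`: reciprocal match at `identity` or better covering at
#'   least `containment_cov` of both lengths;
#' * `contained`: match covering at least `containment_cov` of its own
#'   length within a longer primary transcript;
#' * `kept`: no good match - introduced into the output unchanged.
#'
#' Identical and contained transcripts are replaced by their matching
#' primary counterpart (each primary emitted once; ties between several
#' matching primaries are resolved by highest alignment score, then
#' smallest primary identifier). Transcripts shorter than `min_length`
#' in either input are dropped up front.
#'
#' @param primary,secondary named `DNAStringSet` collections.
#' @param identity identity threshold (default 0.98).
#' @param containment_cov coverage threshold (default 0.95).
#' @param min_length minimum transcript length considered (default 301).
#' @return a list with `sequences` (the merged `DNAStringSet`) and
#'   `report` (class `merge_report`: counts `identical_replaced`,
#'   `contained_replaced`, `secondary_kept`, `primary_total`,
#'   `primary_used`, `final_total`).
#' @export
merge_collections <- function(primary, secondary, identity = 0.98,
                              containment_cov = 0.95, min_length = 301L) {
  stopifnot(is(primary, "DNAStringSet"), is(secondary, "DNAStringSet"))
  if (identity <= 0.5 || identity > 1) stop("identity must be in (0.5, 1]")
  if (containment_cov <= 0.5 || containment_cov > 1)
    stop("containment_cov must be in (0.5, 1]")
  primary <- primary[Biostrings::width(primary) >= min_length]
  secondary <- secondary[Biostrings::width(secondary) >= min_length]

  class_of <- character(length(secondary))
  match_id <- character(length(secondary))
  pw <- Biostrings::width(primary)
  for (i in seq_along(secondary)) {
    slen <- Biostrings::width(secondary)[i]
    best_class <- "kept"; best_id <- NA_character_; best_score <- -Inf
    for (j in seq_along(primary)) {
      hit <- align_local(secondary[[i]], primary[[j]])
      q_span <- hit$q_interval["end"] - hit$q_interval["start"] + 1
      t_span <- hit$t_interval["end"] - hit$t_interval["start"] + 1
      if (q_span < 1 || hit$matches / q_span < identity) next
      if (q_span < containment_cov * slen) next
      cls <- if (t_span >= containment_cov * pw[j]) "identical" else "contained"
      if (hit$score > best_score ||
          (hit$score == best_score && (is.na(best_id) || names(primary)[j] < best_id))) {
        best_class <- cls; best_id <- names(primary)[j]; best_score <- hit$score
      }
    }
    class_of[i] <- best_class
    match_id[i] <- best_id
  }
  used <- unique(match_id[!is.na(match_id)])
  out <- c(primary[used], secondary[class_of == "kept"])
  report <- structure(list(
    identical_replaced = sum(class_of == "identical"),
    contained_replaced = sum(class_of == "contained"),
    secondary_kept = sum(class_of == "kept"),
    primary_total = length(primary),
    primary_used = length(used),
    final_total = length(out)), class = "merge_report")
  list(sequences = out, report = report,
       classification = data.frame(secondary = as.character(names(secondary)),
                                   class = class_of, primary = match_id,
                                   stringsAsFactors = FALSE))
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf(
    "merge_report: %d identical and %d contained secondary transcripts replaced by %d primary transcripts; %d kept unchanged; final collection %d\n",
    x$identical_replaced, x$contained_replaced, x$primary_used,
    x$secondary_kept, x$final_total))
  invisible(x)
}
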