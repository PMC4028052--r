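#' Check the presence of gold-standard genes in transcript collections
#'
#' A curated reference gene set is the most direct quality probe for an
#' automated transcriptome build: each reference is searched in each
#' collection and called found or missing, and a membership matrix
#' (Venn-ready) summarizes which collections recovered which genes.
#'
#' At the DNA level a gene is found if some collection sequence attains a
#' local-alignment hit score (see [align_local()]) of at least
#' `min_score`. At the protein level (collections are peptide sets, e.g.
#' from [translate_longest_orfs()]) a gene is found if some peptide aligns
#' at `min_identity` or better with aligned residue pairs covering at
#' least `min_coverage` of the reference peptide - a criterion that
#' catches frameshifted or wrong-frame translations (which align over
#' only part of the reference) while tolerating terminal truncation.
#'
#' @param reference a named `XStringSet` of reference genes (DNA) or
#'   peptides (protein level).
#' @param collections a named list of `XStringSet` collections.
#' @param level `"dna"` or `"protein"`.
#' @param min_score DNA-level hit-score threshold (default 200).
#' @param min_coverage,min_identity protein-level criterion (defaults
#'   0.80 and 0.95).
#' @param eligible optional named logical vector over reference genes;
#'   genes marked `FALSE` (e.g. genes with almost no reads in the
#'   underlying data) get status `no_input_support` and are excluded from
#'   summary denominators.
#' @return an object of class `presence_report`: a list with `status` (a
#'   gene x collection data.frame of status / best score / coverage /
#'   identity), `membership` (logical genes x collections matrix),
#'   and `summary` (per-collection found counts and eligible totals).
#' @export
presence_check <- function(reference, collections,
                           level = c("dna", "protein"),
                           min_score = 200, min_coverage = 0.80,
                           min_identity = 0.95, eligible = NULL) {
  level <- match.arg(level)
  stopifnot(is(reference, "XStringSet"), length(reference) > 0)
  if (is(collections, "XStringSet")) collections <- list(collection = collections)
  if (is.null(names(collections)) || any(names(collections) == ""))
    stop("collections must be a named list")
  genes <- names(reference)
  if (is.null(eligible)) eligible <- stats::setNames(rep(TRUE, length(genes)), genes)

  rows <- list()
  for (cn in names(collections)) {
    coll <- collections[[cn]]
    if (length(coll) == 0L)
      warning("collection '", cn, "' is empty; all genes reported missing")
    for (g in genes) {
      best <- NULL
      if (length(coll)) {
        for (i in seq_along(coll)) {
          hit <- align_local(coll[[i]], reference[[g]])
          if (is.null(best) || hit$score > best$score) { best <- hit; best$id <- names(coll)[i] }
        }
      }
      ref_len <- Biostrings::width(reference[names(reference) == g])[1]
      # aligned residue pairs over the reference length: gap-jumped span
      # does not count as coverage
      ref_cov <- if (is.null(best)) 0 else
        (best$matches + best$mismatches) / ref_len
      found <- if (!eligible[[g]]) FALSE
      else if (is.null(best)) FALSE
      else if (level == "dna") best$score >= min_score
      else ref_cov >= min_coverage && best$identity >= min_identity
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, collection = cn,
        status = if (!eligible[[g]]) "no_input_support"
                 else if (found) "found" else "missing",
        best_hit = if (is.null(best)) NA_character_ else best$id,
        best_score = if (is.null(best)) NA_real_ else best$score,
        ref_coverage = as.numeric(ref_cov),
        identity = if (is.null(best)) NA_real_ else best$identity,
        stringsAsFactors = FALSE)
    }
  }
  status <- do.call(rbind, rows)
  membership <- matrix(FALSE, length(genes), length(collections),
                       dimnames = list(genes, names(collections)))
  for (r in seq_len(nrow(status)))
    membership[status$gene[r], status$collection[r]] <- status$status[r] == "found"
  summary <- data.frame(
    collection = names(collections),
    found = colSums(membership),
    eligible = sum(eligible[genes]),
    total = length(genes),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(status = status, membership = membership,
                 summary = summary, level = level),
            class = "presence_report")
}

#' @export
print.presence_report <- function(x, ...) {
  cat("presence_report (", x$level, " level):\n", sep = "")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %s: %d / %d found (of %d genes, %d eligible)\n",
                x$summary$collection[i], x$summary$found[i],
                x$summary$eligible[i], x$summary$total[i],
                x$summary$eligible[i]))
  invisible(x)
}

#' Venn counts from a presence-report membership matrix
#'
#' @param report a `presence_report`.
#' @return a table of counts over membership patterns (one row per
#'   combination of collections, e.g. `"A&B"`), suitable for drawing a
#'   Venn diagram.
#' @export
venn_counts <- function(report) {
  m <- report$membership
  pat <- apply(m, 1L, function(r) {
    cols <- colnames(m)[r]
    if (!length(cols)) "none" else paste(cols, collapse = "&")
  })
  table(pattern = pat)
}

#' Characterize a transcript collection
#'
#' Length and ORF-coverage summaries of a transcript collection: the
#' length histogram over configurable bins, the fraction of each
#' transcript covered by its longest ORF, and medians of both.
#'
#' @param x a `DNAStringSet`.
#' @param length_breaks bin boundaries for the length histogram (right-
#'   closed; default bins: <=300, 301-500, 501-1000, >1000).
#' @param cov_breaks bin boundaries for the ORF-coverage histogram
#'   (default tenths).
#' @param mode ORF convention, see [find_orfs()].
#' @return an object of class `collection_stats`: a list with `n`,
#'   `length_median`, `length_hist`, `orf_cov_median`,
#'   `orf_aa_median`, `orf_cov_hist`, plus the per-transcript vectors
#'   `lengths` and `orf_cov`.
#' @export
characterize_collection <- function(x, length_breaks = c(0, 300, 500, 1000, Inf),
                                    cov_breaks = seq(0, 1, by = 0.1),
                                    mode = "stop_to_stop") {
  stopifnot(is(x, "DNAStringSet"))
  lens <- Biostrings::width(x)
  covs <- numeric(length(x))
  aa <- integer(length(x))
  for (i in seq_along(x)) {
    o <- longest_orf(x[[i]], mode = mode)
    covs[i] <- orf_coverage(x[[i]], o)
    aa[i] <- if (nrow(o)) o$aa_len else 0L
  }
  structure(list(
    n = length(x),
    length_median = stats::median(lens),
    length_hist = table(cut(lens, breaks = length_breaks)),
    orf_cov_median = stats::median(covs),
    orf_aa_median = stats::median(aa),
    orf_cov_hist = table(cut(covs, breaks = cov_breaks, include.lowest = TRUE)),
    lengths = lens, orf_cov = covs),
    class = "collection_stats")
}

#' @export
print.collection_stats <- function(x, ...) {
  cat(sprintf(
    "collection_stats: %d transcripts, median length %g bp, median ORF coverage %.0f%%\n",
    x$n, x$length_median, 100 * x$orf_cov_median))
  print(x$length_hist)
  invisible(x)
}
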