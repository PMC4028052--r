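#' Find unexplained transcribed regions in a coverage track
#'
#' Reports the maximal genomic intervals where read depth reaches
#' `min_cov` at every base, outside any excluded interval (typically the
#' exons of already-defined transcript models), filtered to a minimum
#' length. These "unexplained" regions are candidate transcripts the
#' model-building step missed; requiring substantial depth and length
#' (defaults: 50 reads over at least 300 bp) guards against permissive
#' region callers flooding the output.
#'
#' An exclusion falling inside a qualifying run splits it; each piece is
#' then tested against `min_length` independently.
#'
#' @param coverage an `RleList` of per-base depths (see [read_coverage()]).
#' @param exclude a `GRanges` of intervals to mask (strand ignored), or
#'   `NULL`.
#' @param min_length minimum region length in bases (default 300).
#' @param min_cov minimum per-base depth (default 50).
#' @return a `GRanges` sorted by (chrom, start) with metadata columns
#'   `min_depth` and `mean_depth`; reported bases never overlap
#'   `exclude`.
#' @export
find_unexplained_regions <- function(coverage, exclude = NULL,
                                     min_length = 300L, min_cov = 50L) {
  stopifnot(min_length >= 1L, min_cov >= 1L)
  if (!is.null(exclude)) {
    stopifnot(is(exclude, "GRanges"))
    bad <- setdiff(as.character(GenomeInfoDb::seqnames(exclude)), names(coverage))
    if (length(bad)) stop("exclusion interval(s) on chrom(s) absent from coverage: ",
                          paste(unique(bad), collapse = ", "))
  }
  out <- list()
  for (chrom in names(coverage)) {
    r <- coverage[[chrom]]
    masked <- r
    if (!is.null(exclude)) {
      ex <- IRanges::reduce(IRanges::ranges(
        exclude[as.character(GenomeInfoDb::seqnames(exclude)) == chrom]))
      ex <- IRanges::restrict(ex, start = 1L, end = length(r))
      if (length(ex))
        masked <- r * (IRanges::coverage(ex, width = length(r)) == 0L)
    }
    runs <- IRanges::slice(masked, lower = min_cov, rangesOnly = TRUE)
    runs <- runs[IRanges::width(runs) >= min_length]
    if (!length(runs)) next
    v <- IRanges::Views(masked, runs)
    out[[chrom]] <- GenomicRanges::GRanges(
      chrom, runs,
      min_depth = IRanges::viewMins(v),
      mean_depth = IRanges::viewMeans(v))
  }
  if (!length(out)) {
    gr <- GenomicRanges::GRanges()
    gr$min_depth <- integer(0); gr$mean_depth <- numeric(0)
    return(gr)
  }
  gr <- unlist(methods::as(out, "GRangesList"), use.names = FALSE)
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}
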