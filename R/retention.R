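#' Assess intron retention from per-base coverage
#'
#' An intron is called retained when reads cover it throughout its
#' length: every base has depth at least `depth_floor`. The covered
#' fraction is reported even though the call is binary, so the
#' sensitivity of the retained count to `depth_floor` can be examined in
#' libraries of different depth.
#'
#' @param introns a `GRanges` of introns (e.g. from [extract_junctions()]).
#' @param coverage an `RleList` of per-base depths (see [read_coverage()]).
#' @param depth_floor minimum depth for a base to count as covered
#'   (default 1).
#' @return an object of class `retention_report`: a list with `calls`
#'   (per-intron data.frame: chrom, start, end, strand, retained,
#'   fraction_covered, min_depth) and `summary` (retained count, total,
#'   fraction).
#' @export
assess_retention <- function(introns, coverage, depth_floor = 1L) {
  stopifnot(is(introns, "GRanges"), depth_floor >= 1L)
  chroms <- as.character(GenomeInfoDb::seqnames(introns))
  bad <- setdiff(chroms, names(coverage))
  if (length(bad)) stop("intron(s) on chrom(s) absent from coverage: ",
                        paste(unique(bad), collapse = ", "))
  n <- length(introns)
  frac <- numeric(n); mind <- integer(n)
  for (i in seq_len(n)) {
    r <- coverage[[chroms[i]]]
    a <- BiocGenerics::start(introns)[i]; b <- BiocGenerics::end(introns)[i]
    if (a < 1L || b > length(r)) stop("intron out of coverage bounds: index ", i)
    v <- S4Vectors::window(r, a, b)
    frac[i] <- sum(S4Vectors::runLength(v)[S4Vectors::runValue(v) >= depth_floor]) /
      (b - a + 1L)
    mind[i] <- min(S4Vectors::runValue(v))
  }
  calls <- data.frame(
    chrom = chroms,
    start = BiocGenerics::start(introns),
    end = BiocGenerics::end(introns),
    strand = as.character(BiocGenerics::strand(introns)),
    retained = frac == 1,
    fraction_covered = frac,
    min_depth = mind,
    stringsAsFactors = FALSE)
  structure(list(
    calls = calls,
    summary = list(retained = sum(calls$retained), total = n,
                   fraction = if (n) sum(calls$retained) / n else NA_real_)),
    class = "retention_report")
}

#' @export
print.retention_report <- function(x, ...) {
  cat(sprintf("retention_report: %d / %d introns retained (%.0f%%)\n",
              x$summary$retained, x$summary$total,
              100 * x$summary$fraction))
  invisible(x)
}
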