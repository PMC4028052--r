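# internal helpers

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# coerce a single sequence argument to one uppercase character string
as_seq_string <- function(x, arg = "sequence") {
  if (is(x, "XString")) x <- as.character(x)
  if (is(x, "XStringSet")) {
    if (length(x) != 1L) stop("'", arg, "' must be a single sequence")
    x <- as.character(x[[1L]])
  }
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("'", arg, "' must be a single character string or XString")
  toupper(x)
}

check_dna <- function(s, arg = "sequence") {
  if (grepl("[^ACGTN]", s))
    stop("'", arg, "' contains characters outside {A,C,G,T,N}")
  s
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# uniform integer draw(s) from [a, b], safe when a == b
sample_range <- function(a, b, n = 1L) {
  (a:b)[sample.int(b - a + 1L, n, replace = TRUE)]
}

# deterministic integer allocation of `total` items over `probs`
# (largest-remainder method): sums exactly to total.
allocate_counts <- function(total, probs) {
  stopifnot(abs(sum(probs) - 1) < 1e-8)
  raw <- total * probs
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(probs))
}
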