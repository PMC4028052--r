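---
title: "Auditing and refining de novo transcriptome assemblies with txqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing and refining de novo transcriptome assemblies with txqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(txqc)
  library(Biostrings)
})
```

## The problem

Automated transcriptome construction in non-model organisms stitches
together evidence from short reads, draft genomes and ESTs, and each
stitching step introduces characteristic artifacts. In GC-rich genomes
such as that of the coccolithophore *Emiliania huxleyi* (~65% GC) the
problems compound: the splice-donor landscape itself is non-canonical
(GC-AG junctions outnumber the textbook GT-AG), intron retention is
rampant, and genes that overlap in their 3' UTRs on opposite strands get
fused into single chimeric transcripts by the assembler. Quality control
against a small, manually curated "gold standard" gene set exposes these
faults — genes found at the DNA level but lost at the protein level are
the classic signature — and a handful of mechanical refinement rules
repairs a surprising share of them.

txqc implements those bespoke computational stages as reusable,
testable functions: ORF extraction under the stop-to-stop convention,
rule-based splitting of fused transcripts, presence checking with a
match-based local-alignment hit score, splice-junction classification,
unexplained-region detection from coverage, intron-retention calling,
greedy redundancy removal, and containment-aware merging of two
clustering outputs. A deterministic synthetic-fixture generator
reproduces the relevant genome conditions so that every stage can be
validated against planted truth without any external data.

## Coordinate conventions

All intervals inside the package are 1-based and closed, carried in
IRanges/GenomicRanges containers (`GRangesList` for transcript models,
`RleList` for per-base coverage). A single internal convention is the
cheapest insurance against the off-by-one bugs that multi-tool pipelines
are notorious for; the Bioconductor convention is chosen because every
container the package builds on speaks it natively. Conversion happens
only at file boundaries: GTF and wiggle files are 1-based inclusive on
disk, BED and bedGraph are 0-based half-open.

## Open reading frames: stop-to-stop, both strands

Assembled transcripts are frequently incomplete, so requiring an initial
Met would discard genuine coding sequence. An ORF is therefore a maximal
run of non-stop codons bounded by stop codons *or by the sequence ends*;
`find_orfs()` enumerates these in all six frames, and
`longest_orf()` takes the top of the ordering (peptide length
descending, then `+` strand before `-`, then smaller start — the
tie-break makes downstream splitting reproducible). The Met-to-stop
convention is available as an explicit mode; every Met-to-stop ORF is by
construction a suffix of a stop-to-stop ORF. Both strands are always
scanned, because opposite-strand fusions mean the relevant reading frame
may sit on either strand of an assembled contig.

Three small conventions matter for exactness:

* a terminal stop codon is excluded from the peptide (length thresholds
  refer to amino acids) but included in the nucleotide interval;
* codons containing `N` translate to `X`, and `X` never terminates an
  ORF — holes in a draft genome must not shatter reading frames;
* trailing bases short of a full codon are dropped.

```{r orf-example}
find_orfs("ATGAAATAG")[1:2, ]
```

## Splitting fused transcripts

`decide_split()` applies a fixed rule order to each transcript, using
the coverage of its longest stop-to-stop ORF:

1. coverage below 10% → **remove** (no credible coding content);
2. coverage at least 80% → **keep**;
3. length below 2000 bp → **keep** (a transcript of exactly 2000 bp is
   eligible for splitting);
4. otherwise examine the three longest ORFs with peptides of at least
   100 amino acids: if two or three occupy pairwise non-overlapping
   intervals and every resulting child is at least 300 bp, **split**.

The remove rule is applied first: it is stated as an unconditional rule
in its source procedure, and a transcript that is 97% junk should not be
rescued by being short. Where the cut should fall between two ORFs is
genuinely open; txqc cuts at the midpoint of the inter-ORF gap so that
both children keep their flanking UTR-like sequence — the 3'-UTR overlap
that caused the fusion remains inspectable in both children. Overlap
between ORFs is evaluated on forward-projected intervals regardless of
strand, since physical sequence ownership is what makes a split
well-formed. When three ORFs qualify all three pairwise conditions must
hold; otherwise the qualifying pair with the highest total peptide
length wins (ties: leftmost). Both the 300 bp child floor and the 100 aa
peptide floor are enforced; they coincide for perfectly coding children
(100 aa = 300 nt) and the intersection is the conservative reading.

## The hit score and presence checking

Presence of a curated gene in a collection is decided by the classic
match-based hit score of a best local alignment:

$$\mathrm{score} = \mathrm{matches} - \mathrm{mismatches} - \mathrm{gap\ events}$$

with a default threshold of 200, i.e. roughly 200 aligned identical
bases after penalties. `align_local()` computes an exact
Smith–Waterman–Gotoh optimum under this scoring (match +1, mismatch -1,
-1 per gap event, free gap extension) in compiled code, with a
deterministic leftmost tie-break, and reports the full tally (matches,
mismatches, gap events and bases, aligned spans).

One property of this scoring deserves a warning. Under *exhaustive*
optimization, free gap extension lets the DP chain colinear chance
matches between unrelated sequences: the optimal score between two
random GC-rich n-mers grows at roughly 0.37n (about 70 at 200 bp, 370 at
1000 bp). Seeded aligners never produce such alignments, so the
score-200 threshold behaves sensibly in practice on real data, but any
fixture that wants an "absent" gene to score below 200 must use
references short enough that chance chaining stays under threshold. The
bundled presence fixture uses 320–400 bp gold transcripts for exactly
this reason: intact and frameshifted copies score at or near their full
length (well above 200) while an absent gene's best chance score stays
near 150.

At the protein level the criterion is coverage and identity rather than
a raw score: a reference peptide is found if some collection peptide
aligns at 95% identity or better with aligned residue pairs covering at
least 80% of the reference. Coverage is counted over aligned residue
*pairs*, not the aligned span, because free-extension gaps can stretch a
span across unaligned territory. This criterion is what makes
frameshifts visible: a frameshifted transcript still aligns almost
end-to-end at the DNA level, but its longest-ORF translation covers only
about half the reference peptide, so the gene is found on DNA and lost
on protein — the diagnostic gap the whole QC loop revolves around.

## Splice junctions

`extract_junctions()` derives introns from the gaps between consecutive
exons of each model, deduplicates them on genomic coordinates and strand
(so alternative isoforms never count a junction twice), and reads the
donor and acceptor dinucleotides from the genome — reverse-complemented
for minus-strand models, since donor and acceptor are defined in
transcription direction. Introns shorter than 30 bp are rejected as
alignment artifacts. `classify_junctions()` bins donors into
{GC, GT, GA, AT, CT, other} and acceptors into {AG, AC, GC, AT, other},
the category sets used for reporting junction landscapes; percentages
are reported rounded to integers. Dinucleotides containing `N` go to
`other`. For strand-uncertain models (EST alignments),
`infer_strand_by_acceptor()` votes by which orientation yields AG
acceptors, and `filter_ag_acceptors()` implements the standard noise
filter of trusting donors only at AG acceptors.

## Coverage-based stages

`find_unexplained_regions()` reports the maximal intervals where
per-base depth reaches a floor at every base, outside any excluded
interval, filtered to a minimum length (defaults 50x and 300 bp — floors
tight enough to keep permissive region callers honest). "Minimum
coverage of 50 reads" is interpreted as per-base depth, the quantity a
depth track actually carries; an exclusion splits a run and each piece
is tested against the length floor independently. Regions are
strandless, as coverage tracks are unstranded.

`assess_retention()` automates the "reads throughout the intron"
criterion: an intron is retained when every base has depth at least
`depth_floor` (default 1, since the source criterion names no depth).
The covered fraction is reported alongside the binary call so the
retained count can be examined as the floor rises — it is monotonically
non-increasing in the floor.

## Redundancy and merging

`dedupe()` is greedy longest-first clustering: each sequence joins the
first cluster whose representative it matches at the identity threshold
over at least 80% of its own length, else founds a cluster. Processing
longest-first makes every representative the longest member of its
cluster; the contract is the output property (no residual redundancy at
the operating threshold), not internal equivalence with any particular
clustering program. `merge_collections()` reconciles two clustering
outputs: secondary transcripts that are identical to (reciprocal
high-identity, high-coverage match) or contained in (high-identity match
over their own length) a primary transcript are replaced by that primary
transcript, emitted once; everything else passes through unchanged.
"Good match" thresholds default to 0.98 identity over 0.95 coverage —
near-exact, because replaced pairs originate from the same underlying
reads — and when several primaries qualify the highest alignment score
wins (ties: smallest identifier). Transcripts of 300 bp or less are
dropped at the door, matching the length floor used for final
collections. Identity is computed as matches over the aligned span of
the query, which penalizes gap-chained pseudo-alignments.

## The synthetic-fixture generator

The generator exists so that every stage above can be validated against
*planted truth*, exactly, with no external data. `synth_spec()` fixes
the study conditions; its defaults are the conditions the toolkit
targets:

| parameter | default | meaning |
|---|---|---|
| `gc_content` | 0.65 | genome GC fraction |
| `exons_per_gene` | 1–17 | exon count range of gene loci |
| `transcript_length_range` | 569–4661 bp | spliced transcript lengths |
| `donor_mix` | GC 0.56, GT 0.40, GA 0.04 | planted splice-donor mix |
| acceptors | AG always | planted acceptor |
| `min_intron` | 30 bp | minimum intron length |
| `retention_rate` | 0.89 | fraction of introns covered end-to-end |
| `read_depth` | 50 | exonic depth |
| `fusion_overlap` | 20–100 bp | 3'-UTR overlap of chimeras |

Planting is by overwriting, not rejection sampling: donor dinucleotides
are drawn from an exact largest-remainder allocation of the mix over the
realized intron count and written into the genome, so recovered category
counts equal planted counts exactly, not in expectation. Likewise the
retained-intron subset is an exact `round(rate * n)` draw. Planted ORFs
are runs of stop-free sense codons with stop codons seeded immediately
flanking them; non-coding sequence (UTRs, introns, decoys) is random
GC-rich background interleaved every 20–45 bp with randomized 22-mers
carrying stop codons in all six frames, and the coding runs themselves
carry sense codons that place stops in the five non-planted frames every
~10 codons. Together these bound accidental ORFs to well under 100
amino acids, so the planted ORF is verifiably the longest — the
generator checks this property and redraws in the rare case it fails.
Fusions overlap two transcripts' 3' UTRs (opposite strands by default),
sized so every chimera satisfies the splitter's preconditions: parent
at least 2000 bp, each side at least 100 aa, longest-ORF coverage
strictly between 10% and 80%.

What the generator does **not** emulate: sequencing error, expression
heterogeneity, paralogy and repeats, genuine alternative splicing beyond
retention, polymorphism, and read-level artifacts (coverage is emitted
directly as bedGraph; consumers ingest depth, not alignments). Passing
the planted-truth suite therefore demonstrates that the decision logic
is implemented exactly as specified — it does not demonstrate robustness
to the biological messiness of real libraries, which is precisely why
the original QC loop used manually curated genes.

## Problem sizes and runtime choices

The validation suite runs everything at desk scale: a 500 kb genome with
100 six-exon genes (500 introns) for the junction landscape, 10 fusions
with 20 intact controls and 5 decoys for the splitter, a 20-gene gold
set (320–400 bp transcripts, 2–5 exons) for presence checking, 100
introns for retention, 100 random coverage tracks plus 5 planted islands
for the region finder, and oracle batteries of 1000 random sequences
(ORFs) and 200 planted-homology pairs (alignment). These sizes keep the
full suite in the low minutes on a single CPU while leaving every
planted count large enough that recovery is meaningful. The exhaustive
aligner refuses DP matrices beyond 3x10^7 cells (~5 kb x 5 kb); the
dataset-scale numbers of a real campaign (tens of thousands of
transcripts) are out of reach of exhaustive DP and are not the point of
this package — the decision logic is.

## Known limitations

* The alignment engine is exact but quadratic; collection-scale
  all-vs-all comparisons should go through a seeded aligner, with txqc
  consuming its hit tallies.
* Exon skipping and alternate donor/acceptor detection are out of scope:
  they need junction-spanning read evidence, which is outside the
  coverage-track input contract.
* `dedupe()` reimplements the decision rule of greedy identity
  clustering, not the short-word index of any particular tool, so
  cluster membership can differ from a specific program's output even
  when both outputs are redundancy-free at the threshold.
* Retention calls cannot distinguish genuine intron retention from
  unspliced pre-mRNA contamination; that is a biological question, not a
  computational one.
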