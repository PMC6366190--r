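---
title: "Methods: exact two-library small-RNA analysis with cumira"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact two-library small-RNA analysis with cumira}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cumira)
```

## Scope and model

`cumira` analyses the classic two-library small-RNA design: one
control and one treated library, sequenced to different depths, no
biological replicates. Because there are no replicates, dispersion
cannot be estimated and replicate-based count models are off the
table; the package instead uses the Audic–Claverie exact test, which
models the count of a tag in each library as Poisson sampling from a
shared underlying rate. Conditional on observing `x` reads in the
first library (total `N1`), the count `y` in the second (total `N2`)
follows

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}}.$$

### Numerical evaluation

All probabilities are computed in log space through `lgamma`, so
counts up to the ~650,000 reads that occur in deep libraries neither
overflow nor lose the small tails. Tail sums accumulate
log-sum-exp-wise in chunks and stop when a chunk raises the partial
sum by less than a relative 1e-12. Unit tests pin the point
probability against values computed with exact rational arithmetic
(integer powers and binomials over a common denominator) at relative
1e-10, and against a second independent route built from sums of
integer logarithms.

### Two-sided convention

The literature leaves the two-sided construction open, and the choice
matters: the bundled study's printed p-values for its two extreme
rows (21 vs 0 reads, and 0 vs 10 reads) are only reproduced
simultaneously by one convention, which the package therefore adopts
as its definition: for each orientation — conditioning on `x` with
ratio `N2/N1`, and conditioning on `y` with ratio `N1/N2` — take
twice the smaller of the lower and upper cumulative tails at the
observed count, then take the minimum over the two orientations and
clamp at 1. This construction is exactly symmetric:
`ac_two_sided_p(x, y, N1, N2) == ac_two_sided_p(y, x, N2, N1)`.
A pair with both counts zero is defined as p = 1 (never significant);
p-values that underflow double precision are reported at the smallest
positive double rather than 0 so the (0, 1] contract holds.

### Normalisation and calling

Expression is standardised to reads per million of the library's
**raw** read total (the bundled tables' standardised columns
round-trip exactly under this denominator, not under clean-read
totals), with a floor of 0.01 substituted for zero counts so
fold changes against an undetected miRNA stay finite. A tag is called
differentially expressed when `|log2(cu/ck)| >= 1` and `p < 0.05`,
with the stronger `**` label below p = 0.01 — the rule the published
tables themselves obey; both thresholds are configuration keys. No
multiple-testing correction is applied, matching the single-pair
design this reproduces; users comparing many tags in new studies may
well want to add one. One transcription note: the study's text speaks
of 118 known miRNAs analysed while its table prints 119 rows; the
package carries all printed rows and does not resolve the
discrepancy.

## Read cleaning and categorisation

Reads are trimmed at the leftmost exact match of the first
`min_overlap = 8` bases of the 3' adapter; reads without an adapter
hit are discarded (an insert shorter than the read implies the
adapter must be visible), as are inserts outside 18–30 nt, the
gel-excised size range of plant small-RNA libraries. Cleaned reads
collapse into unique tags with counts; count conservation across
every filtering stage is asserted in tests. Contaminant removal is
exact-sequence membership against user-supplied category sets applied
in precedence order (rRNA > tRNA > snRNA > snoRNA > ...), plus a
polyA rule that removes tags whose fraction of A bases reaches 0.8 —
the threshold is a configuration key since no standard value exists.
Alignment-based contaminant classification against Rfam/Repbase is
deliberately out of scope.

## Known-miRNA assignment

A tag is assigned to a mature reference when it has at most one
mismatch within the reference's first 16 nt and at most three overall.
The comparison geometry is 5'-anchored Hamming over the overlap with
3' overhangs (up to 2 nt) ignored: mature miRNA variants are
predominantly 3'-length variants, and the anchored comparison is the
simplest geometry consistent with a position-indexed mismatch rule.
Ties between references break by total mismatches, then first-16
mismatches, then name, so reference order never affects the result;
all co-optimal names are retained. Counts of distinct tags assigned
to the same reference are summed — necessary for table-style
per-miRNA count pairs, though the original study does not state its
aggregation. Families group by the integer in the name
(`miR169` collects letter variants and -5p/-3p arms).

## Hairpin discovery

Unannotated tags are exactly matched to the genome on both strands
(tags hitting more than 16 loci are set aside as repetitive), and
candidate windows are excised with flanks of 100/150/200 nt on one
side and 20 nt on the other — the mature arm may sit on either side
of the loop. These window parameters are configuration keys with the
stated defaults, chosen as a plain window scheme in the spirit of the
hairpin-scanning tools this stage replaces, whose exact defaults are
not documented.

### The folding engine

The default engine is the package's own dynamic-programming base-pair
maximisation (Rcpp): admissible pairs are GC (-3), AU (-2) and GU
(-1 pseudo-kcal/mol), a pair stacked directly on another earns a -1
bonus, a hairpin-closing pair pays +2, and loops shorter than 3 nt
are disallowed. The scale is calibrated so a perfect 20-bp GC
stem-loop scores -77, far below the -40 mark. The dynamic program is
verified against exhaustive enumeration of all nested structures on
short strings, and the traceback structure is independently re-scored
to equal the reported energy. ViennaRNA's `RNAfold` can be swapped in
(`engine = "vienna"`) when thermodynamic energies are wanted; MFEI
screening against the conventional 0.80 threshold is only
scale-faithful with a thermodynamic engine, which is why tests assert
MFEI arithmetic and the strict boundary (|MFEI| = 0.80 fails
"exceeding 0.80") rather than screening outcomes under pseudo-energies.

### Validation

Because a 140–240 nt window's random flanks fold into their own
structure, the stem-loop containing the mature tag is first cut out
(`excise_hairpin()`): from each terminal loop the stem extends
outward through stacked and bulged pairs and stops at multiloop
branches. The trimmed candidate is re-folded and must satisfy: mature
region entirely on one arm with no base in the terminal loop; at most
4 mature bases unpaired against the opposite arm; exactly one
terminal loop; |MFEI| > 0.80. All failed criteria are reported.
Negative controls in the test suite verify that windows around tags
planted in structure-free random sequence essentially never pass.

## Target prediction

The reverse complement of the miRNA slides along each transcript
without gaps (an ungapped reading of the short-BLAST-hit heritage of
plant target prediction); at each offset non-complementary positions
are counted, G:U wobbles counted as mismatches by default, and sites
with fewer than 4 mismatches are accepted. The Allen-style score
(mismatch 1, wobble 0.5, doubled at miRNA positions 2–13 from the 5'
end) is computed for every accepted site as an annotation rather than
a filter — the acceptance rule of the reproduced study is the plain
mismatch count, but both values are reported so either filter can be
applied downstream. Cleavage-clone summaries convert clone 5'-end
coordinates into positions along the complementary site (1-based from
the miRNA 5' end), discarding clones outside a 100-nt window centred
on the site, and report per-position counts and fractions.

Enrichment of the DE set against a user-supplied term map is the
one-sided hypergeometric upper tail (`stats::phyper`); tests
cross-check it against `fisher.test` and calibrate its type-I error
by simulation. The qPCR convenience `ddct_relative_expression()`
implements `2^-ddCt`.

## The synthetic generator

`make_toy_genome()` plants hairpin loci whose recovery is guaranteed
by construction: a random 21-nt mature arm, an 8–12 nt loop, and the
reverse-complement arm carrying up to two planted G:U wobbles,
separated by 120–220 nt random spacers. `simulate_libraries()` draws
per-miRNA counts as Poisson with mean `RPM x N/1e6` — Poisson rather
than negative binomial because that is the sampling model the exact
test assumes; a dispersion knob exists but defaults to 0 — and emits
each read as mature + 3' adapter, mixed with reads from planted
rRNA/tRNA decoy sets (30% of reads by default) so the filtering
stages have work to do. Default study conditions for the end-to-end
recovery experiment: 50 miRNAs, 10 truly DE at |log2FC| = 2,
baseline expression 50–500 RPM, both libraries at 10^6 reads. Under
these conditions the pipeline labels >= 9/10 planted DE miRNAs with
<= 2 false positives in >= 90% of 20 seeds; the type-I experiment
uses 10,000 null pairs at 100 RPM with the depth ratio 0.9315 of the
bundled study. What the generator does **not** emulate — sequencing
error, quality-score structure, isomiR heterogeneity, expression
correlation between miRNAs — bounds what passing tests say about
real libraries: they validate the statistics and the plumbing, not
robustness to platform artefacts.

## Problem sizes and reproducibility

Tests and the acceptance script run at desk scale by design: the
published tables are 119 + 54 count pairs; folding oracles enumerate
structures on <= 24 nt strings; simulated libraries hold a few
thousand reads each. Every stochastic step takes an explicit seed,
and fixed seed plus fixed configuration reproduce every output
bit for bit.

## Known limitations

- Single-pair design only: no replicates, no dispersion, no FDR.
- The internal folding engine's energies are pseudo-energies; MFEI
  values are comparable within an engine, not across engines.
- Exact-match contaminant sets and exact genome mapping; no
  mismatch-tolerant alignment of tags to the genome.
- No bulges in target sites; no multi-loop precursors; no
  star-read-support scoring for novel miRNAs.
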