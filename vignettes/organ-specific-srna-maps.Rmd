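---
title: "Methods: organ-specific small-RNA regulatory maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organ-specific small-RNA regulatory maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnamap)
```

# The analysis

`srnamap` implements an integrated screen over three sequencing layers of a
multi-organ plant experiment — RNA-seq (transcript expression), small-RNA-seq
(collapsed read libraries) and degradome/PARE-seq (5′ ends of uncapped RNA
fragments) — and assembles them into an organ-specific miRNA regulatory map.
The default experimental design is four organs (root, stem, leaf, flower)
with two biological replicates each. Every stage is a thresholded rule, and
every threshold is exposed through `pipeline_config()`.

## Normalization

Small-RNA and degradome abundances are expressed in RPM:
$\mathrm{RPM} = 10^6 \cdot c / T$ for raw count $c$ and library total $T$.
Transcript expression is RPKM:
$\mathrm{RPKM} = \frac{c}{(T/10^6)\,(L/10^3)}$ with $L$ the transcript length
in nt and $T$ the per-sample total of mapped reads, taken over all rows of
the supplied matrix. RPKM is therefore invariant under uniform scaling of a
sample's counts, which the tests assert. Reads and tags are placed on
transcripts by exact sense-strand matching only (a precursor transcript
carries its small RNAs in sense); antisense search exists behind a flag and
is off by default. All sequences are held in DNA space (U→T) internally and
converted back to U only for structure display.

## Organ-high transcripts

A transcript is high in organ $A$ versus organ $B$ when (i) its replicate
mean in $A$ is at least 5× the mean in $B$ (inclusive), (ii) a two-sample
two-tailed t-test gives $p < 0.05$, and (iii) the $A$ mean is at least
1 RPKM. An organ's set is the intersection of its three pairwise screens, so
per-organ sets are disjoint by construction. Three numerical choices were
genuinely open:

* **t-test flavour.** With $n = 2$ per group we use Student's
  pooled-variance test. Welch degrees of freedom are degenerate at this
  sample size (df collapses toward 1), while the pooled test keeps df = 2;
  it is also the conventional default for tiny balanced designs.
* **Zero variance.** If both groups are exactly constant the statistic is
  undefined; we take $p = 0$ when the means differ and $p = 1$ when they are
  equal, the limit behaviour of the statistic.
* **Zero denominator.** When the comparison organ's mean is exactly 0 the
  fold ratio is undefined; presence/absence is the strongest possible fold,
  so the fold criterion then reduces to the 1-RPKM floor.

No multiple-testing correction is applied: the screen is a fixed published
rule set, not an inferential procedure, and the planted-truth tests
characterise its operating point directly.

## Organ-specific small RNAs

A sequence is specific to an organ when it reaches 10 RPM in at least one
replicate of that organ and has a raw count of zero in every library of
every other organ. "Not detected" is read literally — a single raw read
elsewhere disqualifies — because the rule's purpose is exclusivity, not
enrichment; there is deliberately no RPM threshold on the exclusion side.

## The miRNA candidate catalog

Reference mature miRNAs are matched against the libraries by exact
full-length identity (no isomiR shifting, no mismatches): the screen treats
the reference as a lookup table of sequences, and fuzzy matching would blur
the redundancy-collapse step that follows. Entries undetected in all
libraries are discarded; entries sharing a sequence collapse into one
candidate that carries all source names. Renaming order is not dictated by
the screen itself, so we fix a deterministic one: descending total raw count
across libraries, ties broken lexicographically by sequence. The
accumulation filter keeps candidates whose organ-mean RPM (averaged over
replicates, then maximised over organs) is at least 5.

## Precursor structure screen

Secondary structures are consumed as dot-bracket strings (Vienna two-line
records); the package never folds RNA itself, so structure-stage results are
exactly reproducible from the supplied structures. `parse_dot_bracket()` is
a stack parser for pseudoknot-free structures; other bracket alphabets are
rejected.

A candidate locus passes the first screen when ≥ 50% of its positions are
paired *and* all its paired positions carry brackets of one direction (the
locus lies on one side of a helix). The second, historically manual, screen
is codified in `detect_stem_loop()`: the innermost hairpin enclosing the
locus's pairs is located by walking inward to the loop-closing pair
(multiloop-branched regions are rejected as not-a-hairpin) and the helix is
extended outward across interior loops/bulges of at most 12 nt per step;
the helix must carry at least 15 base pairs. Both parameters are
configurable; the defaults are the smallest values that accept a canonical
~21-bp plant pre-miRNA stem with typical bulges while rejecting incidental
short helices. Reproducibility demands an operational rule here even though
the original screen was by eye; this automated surrogate is deliberately
conservative.

The miRNA* call is the geometric consequence of Dicer's 2-nt 3′ overhangs:
for a mature locus $[s, e]$, the star locus is
$[\mathrm{partner}(e-2),\ \mathrm{partner}(s)+2]$. The call is rejected when
$s$ or $e-2$ is unpaired (a bulged duplex boundary), when the interval
leaves the transcript or overlaps the mature locus, or when the overhangs
measured back from the pairing map are not exactly (2, 2)
(`duplex_overhangs()` measures arbitrary candidate duplexes, and rejects
1-nt or 3-nt constructions). On perfect stems the call is an involution —
the star of the star is the mature locus — which the property tests verify
over random hairpins. A duplex with valid geometry whose star sequence is
absent from all libraries is kept with `star_detected = FALSE`: precursors
with unconfirmed star strands are biologically expected, and detection
status is evidence, not geometry.

## Phased miRNA-like RNAs

On long stems (≥ 40 helix pairs by default — room for at least two tandem
21-nt duplexes; no published register length exists for this
structure-anchored definition), library reads of 18–26 nt with perfect
placements fully inside one arm are collected, and "in phase" is
operationalised as exact head-to-tail adjacency: a chain extends while the
next locus starts exactly one past the previous end. An adjacency tolerance
(default 0, typically ±1) is exposed because cleavage registers in real
data slip by a nucleotide. Chains are seeded on whichever arm carries more
mapped loci and partners are derived through the duplex geometry rather
than independently chained, which avoids double-reporting each duplex.
Chained loci whose geometric partner is undetected stay in the block as
flagged singletons.

## Degradome validation

Precursor-processing evidence asks for tags whose 5′ ends sit exactly at a
duplex locus start, or one past its end (the two uncapped ends DCL1 leaves),
within a configurable tolerance (default 0).

Target validation applies three rules per degradome library. The candidate
cleavage position within a site's window is the position of the most
abundant placed signature (ties resolved toward the canonical position).

1. The mean RPM of distinct signatures at the candidate position must be at
   least 5× the mean RPM of distinct signatures placed elsewhere on the
   transcript. "Surrounding" averages over distinct signatures, not
   per-nucleotide positions; an empty surrounding set passes whenever the
   site signal is positive ($5 \times 0 = 0$).
2. The most abundant site signature must rank within the top 12 distinct
   signatures on the transcript, ties sharing the better rank (a site tied
   with the 12th-largest count passes). "Top 12" counts distinct
   signatures rather than distinct positions — the literal unit that
   "perfectly mapped" reads denote.
3. The candidate position must lie opposite miRNA nucleotide 10 or 11
   (AGO1 slices between guide nt 10 and 11; the tag's 5′-most base pairs
   with nt 10 in the canonical register).

A site is retained when all three rules hold in at least one library. Rule
verdicts are monotone in the fold and rank thresholds, which the tests
assert. A pair is *organ-specific* when supported in exactly one organ and
*vegetative-specific* when supported only outside the flower. The
historically manual target-plot screen is replaced by machine-readable
per-site reports: every rule component is emitted, and no manual gate
exists anywhere in the pipeline.

The bundled complementarity scorer (`score_site()`, `scan_targets()`) is
plumbing, not a reimplementation of any published predictor: gapless
antiparallel alignment with penalties mismatch 1.0, G:U wobble 0.5, doubled
at miRNA positions 2–13, site ceiling 4.0. Externally predicted site lists
can be supplied instead.

# The synthetic-data generator

`simulation_config()` fixes the study conditions all tests run under:

| parameter | default | what it encodes |
|---|---|---|
| organs × replicates | 4 × 2 | the standard multi-organ design |
| transcripts | 200 | expression-matrix rows |
| planted organ-high per organ | 5 at fold 8 | clear enrichment, comfortably past the 5× rule |
| replicate CV | 5% | clean biological replicates |
| hairpin arm / loop / flank | 60 / 6 / 30 nt | a canonical long-stem precursor |
| phased block | k = 3 duplexes | tandem 21-nt duplex chain on a long stem |
| organ-specific sRNAs | 3 per organ at 15 RPM | past the 10-RPM rule, absent elsewhere |
| background sRNAs | 300, detect prob 0.9, counts 1 + Geom(0.3) | a broadly shared low-count population |
| sRNA library total | 10⁶ | so counts read directly as RPM |
| degradome spike / background | 100 / 2 RPM | strong cleavage signal over uniform noise |

Structures are emitted *by construction* (flank·arm·loop·revcomp(arm)·flank
with the matching bracket string), never by folding, so structure-stage
tests are hermetic. Background sequences are sampled uniformly over
$\{A,C,G,T\}^{21}$ and rejected if they occur in any transcript or collide
with a planted sequence. The background is modelled as *shared* across
libraries with occasional dropout (90% detection), matching the observation
that organ sRNA populations overlap heavily; with these defaults a
background sequence essentially never mimics an organ-specific one (it
would need ≥ 10 RPM in one organ and six independent dropouts). Library
totals are padded to their configured size by a single filler sequence
shared by all libraries, so it can never register as organ-specific.
Everything derives from one seed; a fixed seed makes every emitted file
byte-identical, and `truth.json` records all planted features.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: sequencing error and adaptor artefacts,
isomiR heterogeneity, multi-locus gene families, imperfectly folded
precursors (structures are ideal stems apart from configured bulges),
RNA-seq assembly artefacts, and realistic degradome background structure.
The tests characterise the *rules*, not the noise robustness of upstream
sequencing.

# Problem sizes and runtime

The default bundle (200 transcripts, 9 structured transcripts, eight
libraries of ~320 distinct sequences, four degradome libraries) runs the
full pipeline in about a second; the test suite, including 100-hairpin
property sweeps and a 20-seed background Monte Carlo, completes in well
under a minute. These sizes were chosen so that planted-truth recovery is
exact and the whole suite is convenient to run interactively.

# Interfaces

This is an analysis package: the exported stage functions and
`run_pipeline()` *are* the command surface, each consuming and producing
the documented tabular types, and the run manifest (config echo, config
hash, package version, skipped stages) plus `summary.json` make a run
reproducible and comparable. A shell wrapper would add nothing beyond
`Rscript -e`, so none is shipped.

# Known limitations

* The stem-loop detector handles simple (unbranched) hairpins only;
  multiloop regions are rejected rather than decomposed.
* Exact-match placement means a single sequencing error drops a read; the
  screens are defined on collapsed exact counts.
* The gapless complementarity scorer cannot represent target bulges; use an
  external site list where bulged sites matter.
* Degradome RPM normalization defaults to the library's raw tag total;
  normalising by placed-tag totals is available via the `total` argument,
  as the choice is not fixed by the rule set.
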