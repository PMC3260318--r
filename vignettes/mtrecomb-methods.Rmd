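---
title: "Quantifying repeat-mediated recombination in multichromosomal organelle genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying repeat-mediated recombination in multichromosomal organelle genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtrecomb)
```

## The problem

Plant mitochondrial genomes recombine across their own dispersed repeats.
A pair of direct repeat copies on one circular chromosome can crossover to
yield two smaller subgenomic circles; two circles sharing a repeat can fuse
into one; inverted copies invert the segment between them. In many
angiosperms these interconversions run near equilibrium, so a "master
circle" assembly is only one of many coexisting arrangements. Some genomes
instead fragment into dozens of small, circular-mapping chromosomes that
are largely *autonomous* — they share no large repeats with the rest of
the genome, and the little recombination their short shared repeats
support is nearly undetectable.

Paired-end sequencing makes these dynamics measurable without assembling
every alternative arrangement. A sheared, size-selected library implies a
span between the two reads of a pair; read pairs whose mapped orientation
and span match the reference conformation support it, and pairs that are
inconsistent with the reference but exactly consistent with a predicted
crossover product support the recombinant conformation. `mtrecomb`
implements this assay, the repeat catalogue it depends on, the
chromosome-level structure reports built from it, a homology cascade for
classifying intergenic sequence, a census of species-unique indels, and a
ground-truthed simulator used to validate every stage.

## The junction-environment model

A two-copy repeat occupies four possible *junction environments*. Writing
`L_A | rep | R_A` and `L_B | rep | R_B` for the flank–repeat–flank
contexts of the two copies in the reference, a crossover exchanges the
flanks, producing the two recombinant environments `L_A | rep | R_B` and
`L_B | rep | R_A`.

A read pair is *informative* for a repeat when both reads map uniquely,
the pair is not a PCR duplicate, neither read touches the repeat interval,
and the two reads flank a repeat copy at a span compatible with the
library. Counting informative pairs gives

* `C1`, `C2` — consistent pairs spanning copy A and copy B (reference
  support), and
* `R1`, `R2` — inconsistent pairs that, projected through the segment map
  of the derived recombinant conformation, become proper, window-compatible
  pairs spanning a repeat copy there (recombinant support).

The recombinant-conformation frequency is

```
f = (R1 + R2) / (C1 + C2 + R1 + R2)
```

with all four support counts in one denominator. `f` is undefined (not
zero) when no informative pairs exist. `recomb_assay()` is the package's
central estimator and returns this per-repeat table as a classed object
with `print`, `summary`, `coef`, `confint` (exact binomial) and `plot`
methods.

Rather than hand-deriving the discordant-pair signature separately for
fission, inversion and fusion, `count_support()` constructs the
recombinant conformation explicitly with `derive_recombinant()` — which
returns both the variant sequence and a segment map back to reference
coordinates — and re-classifies candidate pairs inside the variant. One
code path therefore covers all three topologies, and the reversed-
orientation control is literally the same computation after flipping one
copy's strand.

## Read-pair classification

A pair is **consistent** if and only if both reads map to one chromosome,
on opposite strands facing inward, with an implied span inside the library
window; everything else is **inconsistent**. Window edges are inclusive.
The windows default to 1–6 kb for a 3-kb library and 4–16 kb for a 12-kb
library, the ranges used to reclassify proper-orientation pairs in the
original analysis; the strict mapper-internal consistency call that
preceded that reclassification is tool-internal and not reproducible, and
because the final windows fully determine the outcome the two steps
collapse into the single windowed test implemented here.

On a circle the implied span is the forward arc from the forward read's 5'
end to the reverse read's 5' end, inclusive of both ends. Since the
windows are far below half a chromosome length this coincides with the
"shorter arc" reading for every realistic configuration.

PCR duplicates are pairs sharing both 5' mapping positions (chromosome,
position, strand, both ends); one representative is kept. Ambiguous
(multi-mapping) reads are excluded from every numerator and denominator,
and tallied.

## Repeat eligibility for the assay

`filter_assayable()` applies, in order, with the first reason recorded:

1. **min_length** / **min_identity** — pairs shorter than 50 bp or below
   95% identity are not assayed.
2. **separation** — copies on one chromosome closer than the maximum
   library span: reference and recombinant spans would be confounded.
3. **correlated_repeat** — a longer repeat pair with one copy within the
   maximum span of each focal copy. The original description of
   "correlated" pairs is one sentence; this operationalisation (distance
   from each focal copy to one copy of the longer pair at most the
   maximum window) is an interpretation and the rule can be toggled.
4. **adjacent_repeat** — for short-span libraries only: a copy within
   100 bp of the start of another repeat copy longer than 500 bp, which
   would prevent unambiguous flank mapping.
5. **insufficient_support** — applied after counting: fewer than five
   consistent pairs spanning *each* copy (the support floor applies to
   `C1` and `C2` separately).
6. **subsampled_out** — an optional seeded subsample retaining a fraction
   (5% by default when enabled) of pairs shorter than 200 bp, a
   dataset-size measure for extremely repeat-dense genomes; off by
   default.

Repeats at least as long as the maximum library span cannot be assayed at
all (no read pair can bridge them) and are reported as such.

## The repeat finder

`find_repeat_pairs()` is a seed-and-extend self-comparison: every word of
the configured size (default 11) is indexed across all chromosomes; word
matches between distinct loci — forward/forward or forward/reverse-
complement — are grouped on (anti)diagonals, clustered, and extended.
Within each diagonal region the best-scoring contiguous stretch is
extracted, then the next non-overlapping one, and so on, so periodic
arrays yield each of their pairwise alignments; a gapped local alignment
(Biostrings' Smith–Waterman) refines each stretch when it can raise the
raw score. Default scoring is +1/match, −2/mismatch, gap open 5, gap
extend 2, reporting raw score ≥ 30.

Those defaults are a reconstruction, not a citation: the historical
self-comparison defaults behind the published catalogue are not stated
anywhere, and the only hard constraint is their visible consequence —
the shortest reportable hit is a perfect 30-bp repeat. Under this scoring
a perfect 30-mer scores exactly 30 and a perfect 29-mer cannot reach the
threshold without net-positive extension into its flanks, which the
simulator's planting rules make (essentially) impossible; see below.

Percent identity is matches divided by alignment columns, gaps counted as
columns — stated here because the quantity is routinely plotted but
rarely defined. Overlapping hits are reported as distinct pairs with no
chaining or merging; the only exclusions are the trivial self-alignment
of a locus with itself and duplicate descriptions of one alignment
(nested hits on the same diagonal). Nested hits on *different* diagonals
are genuinely distinct pairs of a periodic array and are kept.

`find_exact_repeats()` reports all maximal perfect pairs (extendable in
neither direction) above a length floor, with maximality verified on the
circle so that origin-wrapping repeats neither vanish nor duplicate. Its
output is checked against a brute-force dense diagonal-scan oracle in the
test suite.

Circularity is handled by extending each chromosome one length past the
origin for seeding and reducing reported coordinates modulo the length;
an interval with `end < start` wraps the origin.

Known limitations: hits whose every identity run is shorter than the word
size cannot seed (shared with every seeded aligner); seed words occurring
more than a cap (default 100) are skipped as low-complexity; gapped
refinement is windowed around the ungapped stretch, so a repeat broken by
many large indels may surface as several pairs rather than one.

## The simulator: what it emulates, and what it does not

`sim_genome()` builds random circular chromosomes at a target GC and
plants repeat families of chosen copy number, length, identity (copies
other than the first carry `round((1 − identity) · length)` substitutions)
and orientation. Planting forces the four bases flanking each copy, read
in copy orientation, to differ across copies (exact for up to four
copies). This makes the planted truth well-posed: boundaries are maximal,
the exact finder must recover them exactly, and score-positive extension
past a boundary would require ≥ 9 chance matches beyond four planted
mismatches (probability ≈ 4⁻⁹ per flank) — without this rule a chance
flank match genuinely lengthens the repeat and "planted length" would not
be a recoverable quantity.

`sim_read_pairs()` draws fragments uniformly around the circle(s) of a
weighted conformation mixture, with spans from a normal distribution with
mean equal to the nominal span and standard deviation one sixth of it,
truncated to `[read_length, 3 × nominal]`. The original study states only
nominal spans (~3 and ~12 kb); the spread is a free parameter chosen to
be unimodal and comfortably inside the consistency windows, not an
inferred one. Substitution errors are independent and uniform (default
1% per base — no indel or homopolymer model, since the assay consumes
mapping positions, not base identity); PCR duplicates are exact
coordinate re-draws of an earlier fragment (default rate 5%), matching
the dedup criterion. Everything is seeded; identical seeds give
byte-identical FASTA/FASTQ.

Accordingly, passing tests demonstrate correctness of the counting and
classification machinery under this generative model. They do not
demonstrate robustness to homopolymer-driven indel errors, quality-score
artefacts, chimeric library molecules (simulated chimera rate is zero, so
control frequencies of exactly 0 are expected), heteroplasmy, or
non-uniform fragmentation — all of which real libraries have in some
measure.

## Numerical and design choices

* Coordinates are 1-based closed intervals throughout (the R/Bioconductor
  convention); wrap-around circular intervals are stored with
  `end < start`.
* Window edges are inclusive; whether the original windows were inclusive
  is unstated, and at 1 bp resolution the choice is invisible in
  practice.
* The AT-content filter of the plastid search (hits above 72% AT are
  discarded as false positives of the sensitive scoring) is computed over
  the *hit*, not the whole intergenic region: the rule exists to veto
  individual spurious alignments, and a region-level average would let a
  short AT-rich hit hide inside a GC-normal region.
* Intergenic classification is per *position* with fixed precedence
  (plastid > mt-conserved > other-conserved > uncharacterized), so the
  category totals sum exactly to the intergenic total by construction —
  the layout of a coverage-partition table requires positional
  bookkeeping, and overlapping hits of different categories resolve by
  precedence rather than double-counting.
* The translated search uses six-frame translation against a standard
  protein substitution matrix (BLOSUM62, stop rows added at −4) with raw
  score ≥ 140; it approximates the original protein-level search, whose
  database is version-dependent and out of scope.
* Indel polarity is read off a designated outgroup row; events where the
  outgroup is itself gapped still count, with polarity "undetermined" —
  the census reports indels, not polarity. An insertion present in
  exactly one taxon is owned by that taxon and is unique only when every
  other taxon's gap run coincides with it exactly. Overlap is inclusive
  of single shared columns (the strictest reading of "did not overlap"),
  and events spanning feature boundaries are counted once.
* Frequencies are reported to four decimals; percent displays round half
  up to the nearest integer.
* `recomb_assay`'s recombinant environments 1 and 2 are ordered by the
  variant chromosome and position of the retained repeat copy — the
  labels are arbitrary but fixed, and the frequency is invariant under
  swapping copy A and copy B.

## Validation problem sizes

The test suite validates parameter recovery on simulated 200-kb circles
with one eligible 1-kb repeat pair and a 12-kb library, across mixture
weights 0, 0.02, 0.1, 0.25 and 0.5 at roughly 300 informative pairs per
weight, requiring agreement within three binomial standard errors
(exactly zero at weight 0); the reversed-orientation control on the same
data must read exactly zero, and planted inverted-orientation
recombination must appear in the control assay and not the direct one.
Autonomy labelling is validated on a six-chromosome design (two
autonomous circles sharing only 60-bp repeats with zero recombinant
support, four circles linked pairwise by 1-kb repeats with their fused
conformations present at substantial weight). Exact-repeat finding and
per-base repeat depth are checked against brute-force oracles on twenty
2-kb random genomes. These sizes were chosen as the smallest designs in
which every quantity under test is statistically well-resolved.

## Limitations

The assay measures *relative conformer abundance* around individual
repeat pairs; it does not reconstruct full alternative genome maps, assay
repeats longer than the library span (impossible by construction), or
model gene conversion separately from crossover. The partition cascade
reports homology to whatever databases it is given — with small or
synthetic databases the "other-conserved" category is only as meaningful
as the database. The simulator's error model is deliberately minimal; see
above for what that implies about test evidence.
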