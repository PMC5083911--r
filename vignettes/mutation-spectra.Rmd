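---
title: "Estimating TE mutation spectra from copy alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating TE mutation spectra from copy alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tespectrum)
```

## The model

A transposable-element (TE) family surveyed at one genomic locus across
many individuals yields a panel of element copies that diverged from a
shared ancestral sequence under little or no functional constraint. After
multiple alignment, each column either agrees across copies (no mutation
since the ancestor), shows a minority base (a substitution in the
minority copies), or shows a minority gap pattern (an indel). The
analysis here treats the alignment as the data and makes two modelling
commitments:

1. **Majority-rule ancestry.** A column's ancestral state is the allele
   carried by at least a fraction `major_threshold` (default 0.85) of
   copies; the minority state, at frequency at most `1 − major`, is the
   derived mutation, so every call has a direction (e.g. "A mutated to
   G", not just "A/G differ"). Columns without such a majority are
   *ambiguous* and excluded — with dozens of copies and a polymerase
   error rate far below the minority ceiling, a 15% minority cannot be
   artefactual, but a 40/60 split has no defensible direction. A
   designated ancestral copy, when available, anchors the call whenever
   it itself clears the threshold. This is deliberately not a
   phylogenetic reconstruction: with low per-copy divergence and
   star-like copy genealogies, frequency majority and parsimony coincide
   except at the ambiguous columns the rule refuses to call.
2. **Event, not observation, counting.** A mutation observed in several
   copies at the same position is one event carried by several copies
   (recurrence and identity-by-descent are not distinguishable here), so
   all downstream counts use deduplicated events. The deduplication key
   includes the derived allele: different changes at one site are
   different events.

### Thresholds

`major_threshold` is compared with `>=`, not strict `>`. With 20 copies
per population, a strict reading of an 85% majority makes 17/20 = 85%
uncallable, which cannot be intended; the boundary is included and the
threshold is a visible knob (`--major-threshold` on the shell wrapper).
`minor_threshold` defaults to `1 − major` and bounds the derived-allele
frequency of every call. `N` characters are missing data, excluded from
both numerator and denominator of the column frequencies.

### Two analysis scopes

Single-base substitutions are abundant, so they are called per
*group* — disjoint resampled panels, each holding a fixed number of
copies from every population (1 × 21 or 5 × 7 in the motivating design) —
giving independent replicate spectra whose cross-group mean ± SE and
tests are the reported summary. Indels and multi-base substitutions are
rare, so they are called once on the pooled copy set; `run_pipeline()`
applies both scopes automatically.

### Event definitions and coordinates

Within a copy, maximal runs of adjacent substituted ancestral positions
are one multi-base event (an `AG→GA` event is one 2-base change, not two
coincident singles); maximal per-copy gap runs over deletion columns are
one deletion; maximal per-copy occupied runs over insertion columns are
one insertion, with each distinct inserted sequence at a flank kept as
its own event. All reported coordinates are 1-based positions on the
ungapped ancestral sequence, and indels use the exclusive-flank
`start_end` dialect: the two positions *between which* the event lies,
so a deletion's length is always `end − start − 1` and an insertion is
`i_(i+1)`. This is the dialect of the published catalogs the package
ships; the arithmetic identity holds for every published deletion row,
which is what fixes the interpretation. Placement ambiguity inside
homopolymers or tandem repeats (a T deleted from TTT) does not alter the
reported interval — the aligned placement is reported — but
`indel_placement_range()` quantifies the equivalent-placement range for
any event.

### Classification

Single-base substitutions get one of the 12 ordered patterns, a
transition/transversion label, and strand-pooled pair counts
(A:T→G:C = A→G + T→C and so on), which express bias per base pair rather
than per sequenced strand. Inside an annotated ORF they also get a codon
position (`((pos − start) mod 3) + 1`) and a protein effect by
substituting the derived base into the ancestral codon under the
standard nuclear code: synonymous, missense, nonsense (sense → stop),
no-stop (stop → sense). A stop-to-different-stop change is synonymous —
the product (termination) is unchanged. Each event is classified against
the ancestral frame independently; frames broken by other copies'
upstream frameshifts are not propagated, since every event is a separate
mutation on the ancestral background. Multi-base substitutions are
counted as their own category and not forced into the 12-pattern
scheme. Indels touching an ORF are frameshift iff the number of
*ORF* bases inserted or deleted is not a multiple of 3; for a deletion
spanning ORF and flank only the ORF overlap counts. Multiple ORFs are
supported ("inside" means inside any one of them, codon context from the
containing ORF), which the Ty3/gypsy-style fixture needs: its long
published deletion removes ORF and inter-ORF sequence together and is
ORF-affecting, while nearby events sit in the inter-ORF gap.

## Statistics

Per-group category counts are summarized as mean and SE = SD/√(n groups)
with the sample (n − 1) SD — the conventional "mean ± SE" of a
4-replicate design. Comparisons use the tests the motivating study
names: a pooled-variance (Student) independent-sample t-test — Welch is
available by flag but pooled is the default reported flavour — and
one-way ANOVA on raw counts with Tukey HSD post hoc p-values from the
studentized range. Compact letter displays are built by insert-and-absorb
so that two groups share a letter **iff** their Tukey pair is
non-significant at the display's alpha; intransitive patterns simply
yield multi-letter groups. Degenerate inputs follow fixed conventions:
identical constant samples give t = 0, p = 1 (F = 0, p = 1), so empty
spectra do not produce NaNs.

## The simulator

`simulate_family()` generates the alignment the model assumes: a seeded
ancestral sequence with a target GC fraction (default 0.359, the
published composition of the piggyBac-like reference element) and a
clean reading frame per ORF; per copy, Poisson numbers of single-base
events per pattern placed uniformly on sites carrying the source base;
rare adjacent multi-base runs; and indels with a 1-bp-dominant length
mixture (55% single base, 35% short 2–30 bp, 10% long 30–300 bp,
matching the published catalogs' shape: mostly single-base events plus
deletions/insertions up to hundreds of bases). Defaults emulate the
study design: 21 populations × 4 copies, ~2.4 kb element, per-copy
pattern rates equal to the published per-group transition means (and the
published transversion total split evenly across the 8 patterns) divided
by the 21 copies of a group — so a group accumulates ~63 events with
transition:transversion ≈ 2.4:1 and A:T→G:C ≈ 2× G:C→A:T. The exact
per-copy divergence distribution of the real panels is unknown (the copy
sequences were not deposited), so these defaults are tuned to the
magnitude of the published group means and labelled as such.

Within a copy, planted events keep a one-base margin: two independently
planted adjacent substitutions would be indistinguishable from one
2-base event after run merging, and the truth ledger is meant to be
recoverable exactly. Each insertion event opens its own column block
(two copies inserting different sequences at one flank occupy different
columns, as an aligner would render distinct insertions); identical
events in several copies share one block and deduplicate into one
multi-carrier event. Per-column carrier counts are capped at the minor
threshold so planted events are always callable when the panel has at
least `1/minor` copies.

What the simulator deliberately does **not** model: alignment error (it
emits the true alignment; gap misplacement by a real aligner is a
separate concern), phylogenetic structure among copies (events are
independent across copies — no shared internal branches), heterozygous
two-allele loci, sequencing error, and methylation-dependent rate
variation. Passing tests therefore demonstrate correctness of the
calling and summarization machinery under known truth, not robustness
to misalignment or genealogical correlation in field data.

### Catalog fixtures

`build_catalog_fixture()` replants the two published event catalogs
(every indel with its printed interval and bases, every multi-base
substitution) on a seeded synthetic ancestral constrained to carry the
published bases at the published coordinates, one carrier copy per
event, 84 or 140 copies as in the study. Event positions that were not
published — the multi-base substitution coordinates and the ORF
boundaries — are package choices, placed so that every event falls in
its printed inside/outside region; for the Ty3/gypsy element two ORFs
(240–695, 780–1868 on a 1.9 kb fragment) are required to make the
printed regions mutually consistent. Re-calling the fixture reproduces
the printed catalogs row for row, which is the package's strongest
end-to-end check.

## Numerical and design choices

* Problem sizes in the test suite are chosen for single-CPU runs:
  brute-force oracle equivalence uses hundreds of random ≤ 10 × 50
  alignments, parameter recovery pools 100 replicates of a 1 kb / 14-copy
  family, and the Monte-Carlo power check uses 20 replicates at twice
  the default per-copy rate (a "large effect" regime where the GC-bias
  test should essentially always reject at the 0.01 level).
* Ambiguous columns consume an ancestral position unless their plurality
  character is a gap — an uncalled mostly-base column is still a
  position of the ancestral sequence, while an uncalled mostly-gap
  column is treated as insertion-like and skipped.
* A column whose minority contains both bases and gaps is labelled
  `substitution` in the profile, but calling is per-copy, so gap runs
  through such columns still yield deletion events; the label is a
  summary, not a gate.
* Grouping is seeded sampling without replacement within population; the
  real group memberships are unavailable, so real-data group means are
  reproducible only in distribution.
* Tie at the threshold boundary with a designated reference: the
  reference allele wins, honouring the designated ancestral copy.

## Limitations

The majority rule cannot see mutations above the minority ceiling
(a variant swept to 30% of copies is ambiguous, not called), direction
calls inherit any bias in the designated ancestral copy, and the
exclusive-flank dialect reports one placement for repeat-ambiguous
indels. Counts are of unique events, so recurrent identical mutations
are undercounted by design. None of these affect the simulator-based
validation, which plants events below the ceiling; all would matter for
saturated or deeply structured panels, which this design (tens of
substitutions per several-kb element) does not approach.
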