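---
title: "Characterizing annotated circular mitogenomes with mitocharacter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing annotated circular mitogenomes with mitocharacter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocharacter)
```

## What this package computes, and why

A newly sequenced vertebrate mitochondrial genome is conventionally
described by a small, standard set of statistics: per-region nucleotide
composition with AT- and GC-skew, codon usage of the 13 protein-coding
genes (PCGs) summarised as relative synonymous codon usage (RSCU),
start/stop-codon classification including the incomplete stops completed by
polyadenylation, the arithmetic of gene overlaps and intergenic spacers
around the circle, and — in birds — the classification of the control-region
neighbourhood into one of the named rearrangement classes. These numbers
are usually produced ad hoc in spreadsheet or GUI tools and are hard to
audit; published tables not infrequently contain internal inconsistencies.
`mitocharacter` makes the whole descriptive layer reproducible: annotations
go in (GenBank flat file or a tab-delimited feature table), every derived
quantity is recomputed from coordinates and sequence, and disagreements
with any "advisory" columns of the input are reported rather than adopted.

The package deliberately stops where inference starts. It prepares a
13-gene supermatrix and draws a neighbor-joining *preview* from
p-distances, but model selection, Bayesian and maximum-likelihood tree
estimation, de novo annotation, and tRNA secondary-structure analysis are
out of scope; they belong to the specialised tools that already do them
well.

## Conventions and definitions

**Coordinates** are 1-based and inclusive throughout, as in GenBank. On a
circular genome a feature with `start > stop` wraps the origin and has
length $(L - \mathrm{start} + 1) + \mathrm{stop}$ for genome length $L$.
Converters to other conventions exist only at I/O boundaries.

**Skews** are the standard strand-asymmetry measures
$$\mathrm{AT\text{-}skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\text{-}skew} = \frac{G - C}{G + C},$$
computed on the reference (heavy, H) strand. They are scale-invariant, so
counts and percentages give identical values; both are antisymmetric under
exchange of their arguments, which the test suite checks as a property.

**RSCU** for codon $c$ in a synonymous family $F$ is
$$\mathrm{RSCU}(c) = \frac{n_F \, x_c}{\sum_{k \in F} x_k},$$
the observed count relative to its expectation under uniform usage within
the family. Within every family with a positive total the values sum to
$n_F$ (mean 1) — an exact identity the tests assert before any rounding.

**Junction gaps** between adjacent features are
$\mathrm{gap} = \mathrm{start}_{next} - \mathrm{stop}_{prev} - 1$; negative
values are overlaps, positive values intergenic spacers, and on circular
genomes the wrap junction (last feature back to the first) is included —
without it the spacer-location count of a typical annotated bird mitogenome
comes out one short.

## Parameters that matter

* `family_map` (`"standard"`, default, or `"vertmito"`): which synonymous
  families RSCU is computed over. Published mitogenome RSCU tables almost
  universally follow the *standard* genetic-code grouping (six-member
  Leu/Ser/Arg families, a three-member UAA/UAG/UGA stop family) because
  that is what the common desktop software emits — and the bundled
  published table is exactly reproducible only under that grouping.
  Translation and stop-codon classification, by contrast, always use the
  vertebrate mitochondrial code (AGA/AGG stop, UGA = Trp, AUA = Met); an
  annotated `T(AA)` incomplete stop only makes sense under it.
* `codon_mode` (`"pcg_concat"`, default, or `"whole_genome_frame1"`): how
  the codon pool is constructed. The strand-oriented concatenation of the
  13 PCGs is the biologically meaningful pool (~3,800 codons for a typical
  annotation). The frame-1 reading of the whole 17.8 kb reference strand
  (5,942 codons for a 17,827 bp genome) is provided because at least one
  published table is evidently built that way despite its caption; both
  modes are first-class and the mode is recorded in report metadata.
* `orient_by_strand` (default `FALSE`): per-class composition is reported
  on the reference strand regardless of feature strand. Published
  composition tables generally do not state their convention and the
  multi-feature rows cannot be reproduced without the underlying sequence,
  so the choice is explicit, recorded in the output's attributes, and
  reversible with one flag.
* `remnant_threshold` (default 0.5): the avian gene-order nomenclature
  distinguishes a *duplicate CR* (two similar control-region copies) from a
  *remnant CR2* (a degenerate second copy) but gives no numeric rule. This
  package calls the second copy a remnant when it is shorter than 50% of
  the first. The value is an operational choice, configurable per call.
* Rounding: reports round half away from zero to 2 decimals
  (`round_half_up()`), the convention every checkable cell of the bundled
  published tables follows; internal arithmetic is full precision.

## The synthetic-data generator: what it emulates

`synthetic_spec()` + `generate_genome()` produce circular mitogenomes with
complete, recorded ground truth so that every pipeline stage can be tested
without downloading anything. The default spec is *architecture-isomorphic*
to a real duplicate-CR songbird mitogenome: 39 features with that genome's
gene order, per-gene lengths, strands and junction gaps (including the
10 bp atp8/atp6 overlap and the 311 bp trnT–CR1 spacer), a 17,827 bp
circle, and the real genome's whole-genome base composition
(A 29.45%, C 32.81%, G 14.48%, T 23.26%) as the background model. Three
alternative templates (`ancestral`, `remnant_CR2`, `duplicate_trnT_CR`)
realise the other named avian gene-order classes; their non-shared
parameters (a 1,158 bp single control region, a 60 bp remnant copy) are
round numbers chosen once as field-realistic, not tuned.

Overlapping genes make literal sequence synthesis overconstrained: two
features sharing bases cannot both carry independently drawn content. The
generator therefore fills the circle from the base-composition model,
writes each PCG's codon content (ATG start, body codons sampled from the
requested usage weights with the four vertebrate-mito stop codons excluded
in frame, and a complete TAA or a length-determined incomplete `T`/`TA`
tail), and then re-stamps every PCG's start and stop bases in a final pass
so the start/stop contract survives overlaps. Ground truth (per-class base
tallies, per-gene codon lists, junction gaps, gene-order class) is measured
on the realized sequence, so it is consistent with the emitted genome by
construction. A green round-trip test therefore establishes that every
analysis stage inverts the generator exactly — it does *not* establish
anything about biological realism of the sequence itself: there is no
substitution process, no codon structure in rRNA/tRNA features, and no
control-region repeat structure.

## Numerical and degenerate-input choices

* Characters outside A/C/G/T are excluded from composition denominators
  and counted separately; they propagate unchanged through sequence
  extraction and are flagged by `validate_annotation()`.
* Skews are `NA` (not an error) when a denominator is zero; empty
  sequences and annotations without features are errors.
* Incomplete terminal codons (1–2 nt) are never counted as codons; they
  appear only in the stop classification.
* Extremum ties (longest overlap/spacer, longest/shortest tRNA) are broken
  by first occurrence in genome order from position 1; shortest/longest
  tRNA ties are reported in full.
* Advisory `length`/`intergenic` columns of input tables are recomputed
  from coordinates; disagreements produce warnings and reconciliation
  notes listing the offending rows, never silent adoption — the bundled
  published annotation itself contains two such rows, which the notes
  surface.
* Neighbor joining canonicalises taxa to label order before agglomeration
  (deterministic tie-breaking) and clamps negative branch lengths to zero
  with a warning.
* The supermatrix module performs no alignment: per-gene blocks are
  3'-gap-padded to the longest copy. For closely related, equal-length
  mitogenome sets this equals the aligned matrix; for anything else,
  align externally per gene and concatenate the pre-aligned sequences.

## Known limitations

* The GenBank reader supports the single-record dialect that mitogenome
  submissions use (simple, `complement()`, and two-part origin-spanning
  `join()` locations); multi-record files and exotic location operators
  are out of scope.
* Gene-order classification relies on the canonical label vocabulary
  (`trnT`, `trnP`, `trnE`, `trnF`, control regions); annotations using
  unrecognised names pass through name normalisation unchanged and may
  classify as `unrecognized`.
* The p-distance/NJ preview is exactly that — a sanity check of the
  supermatrix, not a substitute for model-based inference.

## A worked example

```{r example, eval = FALSE}
library(mitocharacter)

# the bundled published annotation (no sequence ships with the package)
ann <- read_feature_table(system.file("extdata",
  "pchinensis_annotation.tsv", package = "mitocharacter"))
characterize(ann)

# a synthetic genome with full ground truth
g <- generate_genome(synthetic_spec(template = "duplicate_CR", seed = 42))
x <- characterize(g$annotation, g$sequence)
summary(x)
write_characterization(x, "report")
```
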