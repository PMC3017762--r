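---
title: "Methods: a simulated gene-family survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a simulated gene-family survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famforge)
```

famforge re-implements, as a single tested pipeline, the workflow of a
genome-wide gene-family survey: screen candidates for family membership,
locate duplications, build a phylogeny, extract conserved motifs, profile
expression, estimate selective pressure on duplicated pairs, and classify
each pair's post-duplication expression fate. This vignette explains the
models and decisions behind each stage, what the synthetic data generator
does and does not emulate, and the package's numerical conventions.

## The synthetic study design

Surveys of this kind are anchored to genome annotation releases and
expression atlases; their headline numbers (family size, duplicate counts,
differential-expression lists) are properties of those databases. The
package instead fixes a *synthetic study design* — `simulation_config()` —
whose defaults mirror the structure such a survey expects to find in a
large plant transporter family:

* a family of **84 genes** on 12 chromosomes, **44 of them in 14 tandem
  clusters** (one cluster of nine, two of four, five of three, six of two),
  and **11 segmental pairs** covering 21 genes, nine of which are also
  tandem members and one of which participates in two blocks — so that
  56/84 = 66.7% of the family derives from duplication;
* five subfamilies in the proportions 30 : 21 : 16 : 11 : 6;
* three conserved motifs (`NLVxYL`, `LYLxxxGxGGxK(R)xxxxxFGADQFD`,
  `FFNWY`) planted at homologous positions inside a domain window;
* a 24-sample whole-life expression panel (13 vegetative, 11 reproductive
  stages, labelled S through E3) with 3 replicates per sample and a
  replicate coefficient of variation of 0.15 — typical array replicate
  noise; pairs' divergence fates planted in the composition 2 D, 4 NOF,
  5 SF, 6 NF, with two pairs withheld from the matrix (the "no probe" case);
* codon divergence targets Ks = 0.8 at ω = 0.15 for designated paralog
  pairs, inside the range a published Ka/Ks table for such a family spans.

Everything is a deterministic function of the config seed.

### The codon simulator

`simulate_codon_pair()` and the family-sequence generator evolve coding
sequences by repeated single-nucleotide proposals: a random codon position
and a random alternative base (transitions may be up-weighted by `kappa`),
rejected outright if the result is a stop codon, accepted with relative
probability ω if nonsynonymous, and accepted unconditionally (ω ≤ 1) if
synonymous. Divergence is calibrated by counting accepted synonymous events
until the target Ks × (synonymous sites) is reached on each lineage, so the
realized synonymous divergence matches the requested Ks and the realized
nonsynonymous rate follows ω. `kappa` defaults to 1: the NG86 estimator the
package pairs this simulator with assumes no transition bias, so the
unbiased kernel is the right default for estimator-recovery experiments;
transition bias remains available as a parameter.

Family sequences descend one ancestral CDS down a known tree — subfamily
stems (Ks ≈ 0.9), unit stems for each cluster/segmental pair/singleton
(Ks ≈ 0.35), and designated pair branches of Ks/2 each — so designated
pairs are the closest relatives and should surface as cherries. Motif
codons are overwritten with synonymous re-encodings of the pattern
residues, keeping CDS and protein consistent.

### The expression generator

Signals are 2^(log2 mean) × multiplicative log-normal replicate noise with
the configured CV. Non-planted genes are *flat* across tissues: the planted
effects are the only true signal, which is what makes sensitivity and
false-positive rates well-defined. Planted preferential genes add
log2(fold) in one tissue; tissue-specific genes sit at a background level
(log2 = 3) everywhere except their tissue. Fate-planted pairs inherit one
shared ancestral tissue profile (per-tissue effects of SD 1.5 log2 units,
floored 2.5 log2 units above background so expressed tissues never straddle
the threshold): D copies share it; NOF silences one copy; SF splits the
tissues complementarily; NF adds a gain of fold 8 in 1–3 tissues of one
copy.

What the generator does **not** emulate: probe-level microarray artifacts,
normalization and batch effects, correlated tissue programs across genes,
indels (family proteins are generated aligned, with no gaps), genome
rearrangements, and realistic intergenic structure. Tests passing on this
design therefore demonstrate that the *methods* are implemented correctly
and recover clean planted signal at realistic noise; they do not certify
performance on raw microarray or annotation data.

## Stage-by-stage models and parameters

**Screening.** The domain profile is per-column log-odds (bits) against a
uniform 1/20 background with an additive pseudocount (default 1). A scan
slides the profile over every offset, allowing truncation at sequence ends;
*coverage* is the fraction of profile columns aligned with positive
log-odds, so a protein carrying 40% of the domain scores coverage ≈ 0.4.
The acceptance threshold is not hand-set: `calibrate_threshold()` takes the
99.9th percentile of best scores over residue-shuffled family sequences (a
composition-matched null). `min_coverage = 0.8` operationalizes "partial
domain"; exclusion terms default to retrotransposon/transposon; one
transcript per locus is kept (the longest), with the locus read as the id
minus a trailing `.N`.

**Duplication.** The tandem rule counts *all* intervening gene models
(family or not) and chains transitively, which is what lets clusters grow
to nine members; the maximum of 5 intervening genes is exposed as
`max_intervening`. Whether only non-family genes should be counted is
genuinely ambiguous in the field's verbal rule; counting all genes is the
stricter and simpler reading and is configurable. Segmental pairs require
both members inside a block's anchor span and within `max_pair_distance`
(default 500 kb) of the nearest anchor; every qualifying cross-pair is
reported, so a gene near a block that also spans a tandem cluster can
appear in more than one pair — deliberate, since real block databases
behave the same way.

**Phylogeny.** Distances are pairwise-deletion p-distances (an optional
Kimura correction, −ln(1 − p − p²/5), is available); NJ follows the
Saitou–Nei Q-criterion with the standard branch-length formulas, negative
lengths clamped to zero, and ties broken by the lexicographically smallest
pair of cluster representatives (each cluster represented by its smallest
leaf label), making the tree independent of input order. Bootstrap
resamples columns, rebuilds NJ per replicate (distances via precomputed
per-pair mismatch indicators, so each replicate costs two matrix–vector
products), and scores each internal bipartition as a percentage.
Subfamilies come from cutting the k−1 longest internal edges (ties by
support, then by smallest descendant label; pendant edges are used only
when internal edges run out, and a cut that would strand a leafless
component is skipped); this is a reproducible operationalization of what
surveys do by eye, with k = 5 as the default. Cherries are internal nodes
with exactly two leaf children; leaves hanging off a multifurcating root
are not sisters.

**Motifs.** Column conservation is the top residue frequency (gaps count
against it). Windows open at a column reaching the threshold (default 0.8)
and extend greedily while the window mean stays above it; `min_len`
defaults to 5. Consensus elements are fixed at top frequency ≥ 0.9, a
two-residue alternative (`K(R)`) when the top two reach 0.9 jointly, else
`x`. Logo heights are per-column relative entropy times residue frequency —
the displayed quantity of HMM-style logos — computed from frequency
profiles, not a full profile HMM with indel states, which the displayed
quantity does not require.

**Expression.** Calls use the two-fold + p < 0.05 convention throughout.
"Preferential" is read in its strictest form: the candidate sample must
exceed *every* other sample two-fold, and a Welch (unequal-variance) t-test
compares the sample's log2 replicates against the pooled log2 replicates of
all other samples. No multiple-testing correction is applied, matching the
convention of the surveys this follows; at the default design this is
conservative anyway because non-planted genes are flat. The
tissue-expression threshold defaults to twice the 25th percentile of
collapsed signals but can be passed explicitly (the simulator reports its
own threshold, background + 1.5 log2 units). Clustering is complete-linkage
on Euclidean distances of log2 mean profiles.

**Selection.** NG86 with the standard conventions: synonymous site counts
per codon from the fraction of single-base changes that preserve the amino
acid, with changes to stop codons counted as nonsynonymous so S + N = 3 per
codon exactly; differences averaged over all minimal mutational pathways,
excluding pathways through stop codons (falling back to all pathways if
every one is blocked); Jukes–Cantor correction −(3/4)·ln(1 − 4p/3), with
p ≥ 3/4 flagged saturated rather than extrapolated; codons containing gaps
or ambiguity skipped; zero observed differences give distance 0 even when
the corresponding site count is 0. Pathway counts are memoised, so
3000-codon comparisons are cheap. The estimator is deliberately the
fully-specified counting method rather than an ML codon model: printed-table
ratio checks are method-independent, and counting admits an exhaustive
enumeration oracle (the test suite enumerates all sense-codon pairs).

**Fates.** The published fate definitions are qualitative; the classifier
makes them explicit as a deterministic cascade: (1) NOF if one copy is
below the expression threshold everywhere; (2) D if log2 profiles correlate
≥ 0.9 *and* all per-tissue ratios are within 2-fold (a flat profile has no
shape, so correlation is defined as 1 and ratios decide); (3) SF if both
expressed-tissue sets are nonempty with Jaccard overlap < 0.25; (4) NF if
one copy gains ≥ 2-fold in ≥ 1 tissue while the expressed sets share at
least half their union; (5) otherwise unclassified. The cascade order
resolves overlapping definitions (a silenced copy trivially "differs
everywhere"; checking NOF first prevents that being read as NF). The
ancestral expression domain is unobservable, so SF is judged against the
pairwise union of expressed tissues as its proxy.

## Numerical conventions and problem sizes

Coordinates are 1-based inclusive everywhere; `-` is the only gap
character (`.` is rejected). Newick output carries supports as internal
node labels. Branch lengths are serialized at 15 significant digits, which
keeps round-trip error near machine precision (the additivity tests demand
< 1e-9). The test suite exercises NJ on 50 random additive matrices of up
to 8 taxa, the NG86 oracle on all 1830 sense-codon pairs, ω recovery on 20
replicate 3000-codon pairs per ω, expression calling on 500 genes, fate
classification on 100 pairs, and the full survey at its default size
(84 genes) with a reduced bootstrap in the unit tests; the acceptance
script runs the full design with the standard 1000 bootstrap replicates.
These sizes were chosen to make the statistical checks stable (stochastic
tolerances of 10–20%) while a full run stays in the tens of seconds.

## Known limitations

* The pipeline consumes alignments; it does not align. Synthetic families
  are generated gap-free, so alignment quality is untested here.
* NG86 saturates for Ks beyond ~1.5; the published extreme values (for
  example Ks = 57) cannot be re-derived from sequence by any counting
  method and are used only as printed inputs for ratio recomputation.
* Preferential/specific-call rarity in real surveys partly reflects
  correlated tissue programs the generator does not model; sensitivity and
  specificity here quantify performance on clean planted effects.
* Subfamily cutting by longest stems reproduces clean subfamily structure
  but is not guaranteed to match a by-eye partition of a real tree,
  especially under rate heterogeneity.
* The second-level "groups within subfamilies" seen in published trees
  have no stated criterion; they are available only as a second cut with a
  user-chosen k and are not validated.
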