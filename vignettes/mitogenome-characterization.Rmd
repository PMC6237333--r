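---
title: "Characterizing circular mitogenomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing circular mitogenomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mitochar` characterizes annotated circular mitochondrial genomes the way
comparative mitogenomics studies do: genome-architecture accounting from the
annotation table, composition and strand-skew statistics, codon usage and
RSCU under the vertebrate mitochondrial genetic code, Nei–Gojobori Ka/Ks,
control-region scanning, tRNA cloverleaf validation, and a concatenated
protein-coding-gene (PCG) phylogeny stage. A synthetic-data module generates
genomes, tRNAs and codon alignments with known ground truth, so every stage
is testable without network access. This vignette records the models, the
parameters that matter, and the design decisions behind them.

## Coordinates and annotation model

All coordinates are 1-based and inclusive on the heavy (H) strand, the
convention of published mitogenome annotation tables and GenBank flat files.
Light-strand (L) features are stored with genome-forward coordinates and
reverse complemented on extraction, so a gene's sequence always reads 5'→3'
in its own sense. Origin-spanning (wrap-around) features are rejected:
the annotations this package targets place the control region (CR) last,
ending exactly at the genome length. Duplicate tRNA names (the two leucines
and two serines) are disambiguated by anticodon when annotated, otherwise
numbered in coordinate order (`trnL1`/`trnL2`, `trnS1`/`trnS2`).

The shipped annotation of the *Hyporhamphus quoyi* mitogenome (GenBank
MG851912.1, 16,525 bp; `hquoyi_feature_table()`) is the package's worked
example: 13 PCGs, 22 tRNAs, 2 rRNAs, the light-strand replication origin
(OL) and the CR.

## Architecture accounting

For features sorted by start, the gap between consecutive features is
`next.start − prev.end − 1`: negative gaps are overlaps, positive gaps
spacers, zero abutting. On a circular table the closing pair (last feature
back to the first) is included. Whether the OL participates as a feature is
a flag (`ol_as_feature`): annotation tables list it as a feature, but the
classical reading of the trnN–trnC interval as "the longest spacer, which
forms the origin of the light strand" requires excluding it. The report
carries both views rather than choosing.

The published table reproduces, among others: total PCG length 11,433 bp,
an 11 bp atp8–atp6 overlap, a 7 bp nad4l–nad4 overlap, a 38 bp trnN–trnC
spacer, and 8 L-strand tRNAs. Recomputation from the table gives 16 overlap
locations (40 bp) and 10 spacers (64 bp, OL excluded); where prose summaries
of such tables disagree with the table's own arithmetic, this package
reports the recomputed values only.

## Composition and skews

AT skew = (A−T)/(A+T) and GC skew = (G−C)/(G+C), computed on H-strand
counts. `N` bases are excluded from numerators, denominators and
percentages; a zero denominator yields `NA` rather than an error, so
degenerate windows (e.g. AT-only stretches) are representable. Formatted
output rounds percentages to 2 and skews to 4 decimals — the precision these
tables are printed at — while raw doubles are preserved in JSON.

Codon-position composition of the concatenated PCGs cycles positions
1, 2, 3 within each gene independently; the 1–2 trailing nucleotides of an
incomplete terminal codon therefore land on positions 1 (and 2), keeping
positions well defined for the three genes ending in a bare `T`.

## Codon usage and RSCU

The vertebrate mitochondrial code (NCBI table 2: ATA→Met, TGA→Trp,
AGA/AGG→stop; 60 sense codons) is taken from Biostrings. CDS splitting
recognizes complete terminal stops and 1–2 nt incomplete stops (completed
to TAA by polyadenylation in vivo); an internal stop is a hard error naming
the offset, since it indicates a broken frame or annotation. RSCU for codon
*c* in a synonymous family of size *k* with total *n* is
`count_c / (n/k)`; families are defined by the code in use (Met is 2-fold,
Leu and Ser 6-fold), zero-total families report `NA` rather than 0, and the
mean RSCU over a used family is exactly 1. Codon counting excludes each
gene's initiation and termination codons by default, matching the
convention under which these studies report total codon counts; both
exclusions are configurable.

## Nei–Gojobori Ka/Ks

Site counting: at each codon position, the synonymous fraction is the share
of single-nucleotide neighbors coding the same amino acid, with stop-codon
neighbors removed from the denominator (a position whose neighbors are all
stops contributes 0). Differences between two codons are averaged over all
minimal mutational pathways that avoid stop intermediates; if every pathway
is blocked — possible only for a handful of sense-codon pairs — the average
over all orderings is used and flagged. Pathways are unweighted (classic
NG86); no transition/transversion weighting is applied at the counting
stage. S and N site totals are averaged over the two sequences, codons with
gaps, ambiguity or stops in either sequence are dropped pairwise, and
ps = Sd/S, pn = Nd/N are Jukes–Cantor corrected,
`d = −(3/4)·ln(1 − (4/3)p)`. Saturation (p ≥ 3/4) is reported as such,
never clamped; the Ka/Ks ratio is undefined when Ks = 0.

The test suite checks site and difference counting against independent
exhaustive-enumeration oracles over all 60×60 sense-codon pairs, and checks
parameter recovery on simulations (below).

## Control region and OL

Motif scanning matches each motif on both strands (positions are H-strand
window offsets) with a per-motif mismatch allowance. The shipped
conserved-block profile (CSB-F/E/D, CSB-1/2/3, TAS motifs ATGTA/TACAT, and
the short repetitive/conserved motifs reported in beloniform control
regions) is compiled from the general teleost D-loop literature; it is an
externally sourced, approximate default and fully user-replaceable — the
conserved-block consensus is genuinely variable across teleosts, and no
single profile is authoritative.

The tandem-repeat finder reports maximal exact tandem arrays (period
bounds and minimum copy number configurable; fractional final copies
allowed). Arrays spanning the same interval are reported once with their
smallest (primitive) period, so `AAAA` is one period-1 array with 4 copies,
not additionally a period-2 array. This is an exact-match scanner by
design: the alignment-scored model of full tandem-repeat finders is not
reproduced, because the analyses this package supports use the scan for a
present/absent call on short-period repeats. A mismatch-tolerant extension
is out of scope.

The OL hairpin check finds the longest terminal stem (first *s* bases
pairing the last *s*, Watson–Crick plus G·U, loop ≥ 3) — a constrained
base-pairing validation, not thermodynamic folding.

## tRNA cloverleaf validation

Folding is an exhaustive search over an architecture-constrained placement
grid, not general secondary-structure prediction: acceptor stem 6–9 bp
(real mitochondrial tRNAs reach 9 bp aminoacyl stems), DHU stem 0 or 3–4 bp
(loop 4–11 nt when present, a 2–8 nt connector when absent), anticodon stem
4–6 bp with a fixed 7 nt loop, TΨC stem 4–5 bp with a 3–9 nt loop,
connectors of 1–3 and 0–2 nt, a 3–23 nt variable region and a 0–4 nt
discriminator tail. The chosen fold maximizes paired positions
(Watson–Crick + G·U); ties prefer more acceptor pairs, fewer G·U pairs, the
most parsimonious stem declaration (no stem wider than needed to cover its
pairs), then the leftmost DHU placement. The parsimony tie-break matters:
several parameterizations can describe the same physical pairing, and
without it the widest description would win arbitrarily. A DHU arm pairing
fewer than 3 positions is reported absent — the signature of the DHU-less
mitochondrial serine tRNA. G·U pairs are counted over actually-paired
positions (DNA alphabet, U ≡ T).

A note on invariants: the total paired count is *not* invariant under
reverse complementing the input. G·U wobble pairs map to C·A non-pairs
under complementation, and the arm grid is asymmetric (a reversed T-arm
does not fit the DHU slot), so no such symmetry is asserted or tested.

## Phylogeny stage

The supermatrix concatenates pre-aligned per-gene FASTA (the pipeline
refuses ragged input rather than aligning), in canonical mitogenome gene
order when gene names are recognized, recording a partition map. Distances
(p, JC69, K2P with pairwise deletion), neighbor joining (negative branches
clamped to zero with the deficit recorded) and Robinson–Foulds distances
are delegated to `ape` — these are standard steps, not this package's
contribution; full ML/Bayesian inference is likewise out of scope, and the
supermatrix writers (relaxed PHYLIP, NEXUS with a partition block) exist so
external programs can be used for it. Bootstrap resampling draws columns
with replacement (optionally within partitions), rebuilds the NJ tree per
replicate, and reports per-bipartition support percentages; a single seed
fixes the whole resampling stream.

Monophyly testing roots on a stated outgroup and, for a non-monophyletic
group, reports the intruding taxa — the predicate form of the
"family X is paraphyletic with respect to family Y" claims these analyses
make. On the reference Beloniformes topology (one *Hyporhamphus* sister to
the flyingfishes), Hemiramphidae fails the test with the Exocoetidae taxa
as intruders, while Hemiramphidae + Exocoetidae passes.

## The synthetic-data generator

`generate_mitogenome()` emulates a typical teleost mitogenome: canonical
gene content and order (13 PCGs with the canonical lengths — 975, 1047,
1554, 691, 168, 684, 786, 351, 297, 1378, 1839, 522, 1141 bp — which
satisfy the incomplete-stop length arithmetic; ATG starts except cox1 with
GTG; TAA stops except one TAG and three incomplete `T` stops on
cox2/nad4/cytb), 22 designed cloverleaf tRNAs with trnS2 DHU-less and 16
planted G·U pairs, 2 rRNAs, a 38 bp hairpin OL and an 866 bp AT-rich CR
with planted conserved motifs. nad6 and the canonical eight tRNAs sit on
the L strand. Intergenic spacers of 0–2 bp are inserted; overlapping genes
are *not* generated, because overlapping CDS cannot be synthesized
independently — architecture tests that need overlaps use the real
annotation table instead. Defaults target whole-genome AT skew 0.03 and GC
skew −0.29, the measured values of the reference genome, achieved by
sampling coding sequence from mildly skewed base frequencies and then
polishing with A↔T and G↔C flips confined to unconstrained positions
(rRNAs, non-motif CR, spacers); the polish lands within 0.01 of target by
construction.

tRNA generation builds sequences on the folder's own layout with fully
Watson–Crick stems (plus requested wobble pairs), A/C-rich unpaired regions
(A and C pair with nothing in the allowed set, starving spurious stems),
and boundary guards that prevent stem extension into loops. Because
accidental complementarity elsewhere can still tie an alternative
placement, the generator verifies its design against the folder and
deterministically resamples the unpaired regions until the designed fold is
the recovered optimum. The independence of the folder's correctness
argument is preserved by testing it against a separately written
exhaustive-search oracle on sequences the generator did not produce.

Codon evolution is a Gillespie-style exact simulation per branch: each
single-nucleotide change carries relative rate κ (transitions) or 1
(transversions), multiplied by ω when nonsynonymous; stop codons are
forbidden states. Rates are normalized so branch lengths are expected
substitutions per codon at the ancestral composition. Defaults ω = 0.1,
κ = 2 represent the strong purifying selection these mitochondrial PCGs
show. No indels and no among-site rate heterogeneity are simulated, so
alignments are aligned by construction — a deliberate simplification:
passing tests demonstrate correctness of the estimators on model-true
data, not robustness to alignment error or rate variation in real data.
Under ω = 0 the realized substitutions are all synonymous (proteins stay
identical), but note the NG86 *estimate* of Nd need not be exactly zero:
pathway averaging between multiply-hit codons can traverse nonsynonymous
intermediates.

## Problem sizes and numerical choices

The test suite and analysis scripts run at desk scale, chosen to exercise
every code path while completing quickly on one CPU: 500-codon two-taxon
alignments for Ka/Ks recovery (recovered ratios fall within a factor of two
of ω over {0.05, 0.1, 0.5}); 50 random 5–10-taxon additive matrices for NJ
topology recovery; 100 bootstrap replicates — the number these studies
conventionally report — on an 8-taxon, ~11 kb supermatrix; 200 bp strings
against the brute-force tandem oracle; and full 60×60 sense-codon
enumeration for the Nei–Gojobori oracles. Skews are compared at 4 decimal
places, the precision at which they are printed. The JSON report is
deterministic (no timestamps; provenance carries an MD5 of the input
sequence, the package version and the full configuration), so identical
inputs produce byte-identical reports.

## Known limitations

* Wrap-around features and joined GenBank locations are rejected, so
  annotations with an origin-spanning CR need re-basing before use.
* The CSB profile is heuristic; conserved-block calls should be treated as
  candidates, not identifications.
* The tandem scanner is exact-match; diverged repeat copies will be missed.
* Cloverleaf validation assumes the canonical arm order; deviant
  mitochondrial tRNA architectures (beyond a missing DHU arm) are outside
  the grid.
* NJ + bootstrap is a desk-scale surrogate for full ML/Bayesian inference;
  topology claims on real data should be confirmed with external programs
  via the PHYLIP/NEXUS exports.
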