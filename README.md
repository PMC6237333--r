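# mitochar

Characterization and comparative phylogenomics of annotated circular
mitochondrial genomes, built around the analyses that mitogenome papers
report for a newly sequenced vertebrate mitochondrion: genome organization,
strand-asymmetry statistics, codon usage, selection pressure, non-coding
elements, tRNA secondary structure, and a concatenated protein-coding-gene
phylogeny with monophyly testing. It is aimed at researchers characterizing
a new mitogenome (typically a teleost fish) against its relatives, and it
ships a synthetic-data module so the whole pipeline is verifiable offline
with known ground truth.

The worked example throughout is the mitogenome of the garfish
*Hyporhamphus quoyi* (GenBank MG851912.1, 16,525 bp), whose published
annotation table and base counts are included as package data.

## What it computes

* **Architecture** — feature lengths, gene overlaps and intergenic spacers
  (gap = `next.start − prev.end − 1` between consecutive features, circular
  closure included), strand distribution, total PCG length.
* **Composition** — base counts and AT/GC skews, `AT skew = (A−T)/(A+T)`,
  `GC skew = (G−C)/(G+C)`, at genome / gene / concatenated-PCG /
  codon-position granularity, plus sliding-window skews.
* **Codon usage** — codon extraction under the vertebrate mitochondrial
  code (ATA→Met, TGA→Trp, AGA/AGG→stop), start/stop classification
  including incomplete `T`/`TA` stops, and RSCU
  (`RSCU_c = n_c / (family total / family size)`).
* **Selection** — Nei–Gojobori Ka/Ks: per-codon synonymous site fractions,
  pathway-averaged difference counts avoiding stop intermediates, and
  Jukes–Cantor correction `d = −(3/4)·ln(1 − (4/3)p)`.
* **Control region / OL** — motif and conserved-block scanning on both
  strands with mismatch allowances, exact tandem-repeat detection, and a
  stem-loop (hairpin) check for the light-strand replication origin.
* **tRNA structure** — architecture-constrained cloverleaf folding
  (acceptor 6–9 bp, DHU 0/3–4 bp, anticodon 4–6 bp + 7 nt loop, TΨC
  4–5 bp), DHU-less detection, G·U wobble-pair counting.
* **Phylogeny** — 13-PCG supermatrix with partitions, p/JC69/K2P distances,
  neighbor joining with bootstrap supports, Robinson–Foulds comparison, and
  a monophyly predicate that names intruding taxa.
* **Simulation** — synthetic mitogenomes (skew-targeted, fully annotated),
  designed cloverleaf tRNAs, and Gillespie codon evolution with ω and κ.

## Worked example

```r
library(mitochar)

ft <- hquoyi_feature_table()
architecture_report(ft)
#> Architecture: 16525 bp genome; PCG total 11433 bp
#>   overlaps: 16 locations, 40 bp; spacers: 9 locations, 26 bp (OL as feature)

lens <- feature_lengths(ft)
lens[c("rrnS", "rrnL", "OL", "CR", "nad5")]
#>  rrnS  rrnL    OL    CR  nad5
#>   944  1687    38   866  1839

# the 38 bp spacer hosting the light-strand origin appears when the OL
# is excluded from gap accounting
g <- adjacent_gaps(ft, ol_as_feature = FALSE)
g$spacers[g$spacers$upstream == "trnN", ]
#>   upstream downstream bp
#> 4     trnN       trnC 38

# strand skews from the published H-strand base counts
at_skew(4838, 4550); gc_skew(2534, 4603)
#> [1] 0.03067746
#> [1] -0.2898977
```

The genome is 16,525 bp with the canonical 13 PCGs + 22 tRNAs + 2 rRNAs +
OL + CR; the positive AT skew (0.0307) and strongly negative GC skew
(−0.2899) mean the heavy strand is A-rich and C-rich, the typical teleost
asymmetry. A full synthetic run, including RSCU, Ka/Ks and tRNA folding:

```r
sim <- generate_mitogenome(simulation_config(seed = 1))
rep <- characterize(sim$table, sim$record)
rep$trna$result$dhu_less    # "trnS2"  (the DHU-less serine tRNA)
rep$trna$result$gu_total    # 16 wobble pairs, as planted
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
package's study-style results, writing tables under `results/`:

1. `01_genome_architecture.R` — organization of the *H. quoyi* annotation
2. `02_composition_skews.R` — skews and the 27-genome comparative summary
3. `03_synthetic_genome.R` — synthetic reference genome + full report
4. `04_codon_usage.R` — codon counts and RSCU
5. `05_selection_kaks.R` — per-gene Ka/Ks and ω recovery
6. `06_phylogeny.R` — supermatrix, NJ/bootstrap, Hemiramphidae paraphyly

Run each with `Rscript analysis/<script>`.

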