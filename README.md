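# barcodegap

Species delimitation and phylogeography from DNA barcodes.

Invasive insect complexes — the motivating system is the chilli thrips
*Scirtothrips dorsalis* complex — often hide several cryptic species behind
one morphospecies. `barcodegap` implements the full analytical workflow for
resolving such complexes from aligned COI barcodes and characterising the
population history of the species it finds:

1. **Haplotype processing** — retain samples with ≥ 640 unambiguous sites of
   the Folmer region, truncate, collapse to unique haplotypes.
2. **Numt screening** — flag nuclear mitochondrial pseudogenes by in-frame
   stop codons (invertebrate mitochondrial code, stop-minimizing frame) and
   by transversion excess against a count-weighted cluster consensus.
3. **Model-corrected distances** — p, JC69, K2P, TN93 closed forms and a
   constrained GTR+I (TIM3-style exchangeability constraints, fixed
   invariant-site proportion) pairwise ML distance.
4. **Barcode-gap delimitation** — histogram analysis of all pairwise
   distances (0.25% bins), natural breaks as runs of empty bins, and
   single-linkage clustering at a cut-off (`auto` = first gap midpoint).
5. **Tree evaluation** — monophyly + posterior support of each putative
   species on support-annotated newick trees (unrooted bipartition
   semantics); Bayes factors `BF = 2(lnL1 − lnL0) + (P1 − P0)·ln(0.01)`
   with the ≥ 10 decision rule; consolidation of putative species by
   externally computed multispecies-coalescent speciation posteriors.
6. **Population genetics** — haplotype/nucleotide diversity, Tajima's D,
   Fu & Li's D*/F*, Fu's Fs (Ewens sampling distribution), R2, with
   coalescent-simulation p-values; exact tests of differentiation; AMOVA
   with Φ statistics and permutation tests.
7. **Mismatch expansions** — stationary / sudden-demographic / spatial
   expectations, SSD fitting with parametric bootstrap (p_SSD, raggedness),
   and dating via τ = 2ut with 13.5 generations/year and a 6.5%/My pairwise
   divergence rate.
8. **Synthetic data** — a coalescent generator (species scaffolds at target
   divergences, expansion demographies, planted numts, truth records) so
   every stage is verifiable without downloads.

## Worked example

Simulate a three-species complex (divergence levels 5% and 12%, ten samples
per species) with one planted pseudogene, then run the delimitation stages:

```r
library(barcodegap)

cx  <- simulate_species_complex(list(seed = 7, numt = list(count = 1, mode = "stop")))
tab <- collapse_haplotypes(cx$alignment, min_len = 640)
tab
#> Haplotype table: 10 haplotypes from 31 samples ( 0 excluded )

rep <- screen_numts(tab)
rep$haplotype[rep$flagged]
#> [1] "H10"                       # the planted numt
tab <- drop_flagged_haplotypes(tab, rep)

dm <- distance_matrix(tab, model = "jc69")
g  <- detect_gaps(distance_histogram(dm))
g
#> Distance histogram: 36 pairs, bin width 0.0025
#> Breaks (midpoints): 2.62%, 8.25%, 11.75%

part <- cluster_at_threshold(dm, g$breaks$midpoint[1])
n_species(part)
#> [1] 3
```

The first natural break falls at 2.62% sequence divergence — the classic
barcode gap between intra- and inter-specific distances — and clustering at
it recovers the three planted species exactly. Population statistics for one
recovered species, with coalescent-null p-values:

```r
seqs <- expand_haplotypes(tab)
sp   <- setNames(part$species[match(tab$membership, part$haplotype)],
                 names(tab$membership))
one  <- seqs[sp[rownames(seqs)] == "H1", ]
basic_diversity(one)[c("n", "S", "HD", "pi")]
#> n = 10, S = 2, HD = 0.69, pi = 0.0014

st <- neutrality_stats(one)
round(st, 2)
#>     D Dstar Fstar    Fs    R2
#>  0.93  1.03  0.77  0.30  0.23
round(neutral_null(10, S = 2, reps = 2000, seed = 1,
                   observed = as.list(st))$p, 3)
#>     D Dstar Fstar    Fs    R2
#> 0.378 0.379 0.378 0.671 0.733   # no expansion signal, as planted
```

Dating a demographic expansion from a fitted mismatch τ:

```r
date_expansion(6.74)
#> Expansion dating: tau = 6.74 ->  162,019 years before present
```

The whole workflow — filtering, screening, distances, gap detection,
clustering, optional tree checks and posterior consolidation, per-population
statistics, mismatch fitting and dating — runs end to end from one (YAML or
list) config via `run_pipeline()`, persisting every intermediate artifact
plus a machine-readable `summary.json`.

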