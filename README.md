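# mitocomp

Comparative dynamics of plant mitochondrial genomes, for people studying
organellar genome evolution: how dispersed repeats accumulate and age, how
fast shared sequence between mitogenomes decays with divergence time, how
variable synonymous and nonsynonymous substitution rates are across
lineages, and how read depth identifies genes that have moved from the
mitochondrion to the nucleus.

Plant mitogenomes (gymnosperms especially) rearrange and turn over far
faster than they accumulate point mutations. `mitocomp` implements the
quantitative core of such a comparative analysis as reusable, tested R
functions:

- **Dispersed-repeat discovery** by seed-and-extend self-alignment: exact
  7-mer seeds on both strands, two-stage (ungapped, then gapped) x-drop
  extension with match +2 / mismatch −3 / affine gaps 5 + 2k, and a
  Karlin–Altschul E-value filter at E ≤ 1e-6
  (E = K·m·n·e^(−λs), with λ and K computed numerically for the scoring
  system). Repetitive totals count every base once, no matter how many
  copies cover it.
- **Repeat age profiling** with the Kimura 2-parameter distance
  d = −½ ln(1−2P−Q) − ¼ ln(1−2Q) over ungapped alignment columns, size
  classes <100 / 100–1,000 / ≥1,000 bp and age classes
  recent (~0) / intermediate (<0.2) / ancient (≥0.2).
- **Shared-DNA quantification**: directional coverage of each genome by
  cross-genome alignments, and the decay of the mean shared percentage
  with divergence time (Pearson r, two-sided t-test with n−2 df,
  least-squares line).
- **Substitution rates**: absolute rates R = d/(T·10⁶) per site per year
  from per-branch dS/dN and branch ages, fold-range summaries over
  species, clade ratios, and a pairwise Nei–Gojobori (1986) dN/dS
  estimator (pathway averaging, Jukes–Cantor correction) for synthetic
  validation.
- **Origin classification** of candidate transferred genes from
  read-depth profiles, calibrated by spike-in references (single-copy
  nuclear, plastid, and the annotated mitochondrial genes), by nearest
  class anchor in log2 space with a two-fold ambiguity band.
- **RNA-editing set statistics**: per-species C-to-U site counts,
  species-unique fractions keyed by gene + alignment column, and
  predicted-vs-observed validation overlap.
- **A seeded synthetic-data generator** (random genomes, planted repeat
  families mutated under the K2P process, shared-block genome pairs,
  three-class depth panels, codon pairs with target dS/dN) with truth
  tables, so every stage is testable with no downloads.

The package ships transcriptions of published comparative summary tables
for 20 seed-plant mitogenomes under `inst/extdata/` (genome sizes,
per-branch rates and divergence times, pairwise shared-DNA percentages,
repeat content), which the reproduction pipeline consumes.

## Worked example

Simulate a repeat-rich genome, scan it, and summarise:

```r
library(mitocomp)

g    <- genGenome(50000, gc = 0.47, seed = 8, id = "toy_mito")
fam  <- plantRepeatFamily(g, n_copies = 6, length = 800,
                          target_k2p = 0.03, seed = 9)
hits <- findDispersedRepeats(fam$genome)
hits
#> RepeatHits on 'toy_mito' (50000 bp, linear): 15 repeat pair(s)
#>   size classes: 0 small / 15 medium / 0 large

summarizeRepeats(fam$genome, hits)
#> RepeatSummary for 'toy_mito' (50000 bp)
#>   merged repetitive: 4863 bp (9.73%)
#>   pairs: 15 total = 0 small + 15 medium + 0 large

head(hitTable(hits)[, c("q_start", "s_start", "strand", "length",
                        "k2p", "size_class", "age_class")], 3)
#>   q_start s_start strand length        k2p size_class    age_class
#> 1    3756   13289      +    798 0.02037795     medium intermediate
#> 2    3756   28486      +    800 0.01903251     medium intermediate
#> 3    3756   39598      -    800 0.02544963     medium intermediate
```

Six planted copies give the full 6·5/2 = 15 pairs, in direct and inverted
orientation; the merged total (~4.9 kb) counts the six 800 bp loci once
each, and the K2P distances scatter around the planted 0.03 — the family
is classified "intermediate" age, as it should be at that divergence.

The headline comparative numbers recompute from the bundled tables:

```r
nums <- reproduceComparativeNumbers()
cat(sprintf("decay r = %.2f (p = %.3f); repeat~size r = %.2f; dS fold = %d\n",
            nums$shared_decay_r, nums$shared_decay_p,
            nums$repeat_size_correlation_r, nums$ds_fold_all_species))
#> decay r = -0.53 (p = 0.033); repeat~size r = 0.99; dS fold = 46
```

i.e. shared DNA between mitogenome pairs decays significantly with
divergence time, repeat content tracks genome size almost perfectly, and
synonymous divergence spans a 46-fold range across the 20 species.

A thin command-line wrapper (`exec/mitocomp`) exposes the stages as
subcommands (`simulate`, `repeats`, `shared`, `rates`, `origin`,
`editing`, `reproduce`), each writing its outputs plus a run manifest
(inputs, checksums, seed, version, timestamps).

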