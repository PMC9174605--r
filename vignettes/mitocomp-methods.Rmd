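---
title: "Methods: comparative dynamics of plant mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative dynamics of plant mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

Plant mitochondrial genomes recombine and rearrange far faster than they
accumulate point substitutions, and they exchange sequence with the nucleus
and the plastid. `mitocomp` implements the quantitative core of a
comparative analysis of this dynamic: dispersed-repeat discovery with age
profiling, pairwise shared-DNA decay, absolute substitution rates,
read-depth classification of cyto-nuclear gene transfer, and RNA-editing
set statistics. This vignette explains each model, the tunable parameters,
and the choices made where the design was genuinely open.

## Dispersed-repeat discovery

A dispersed repeat is a sequence present at two or more non-adjacent loci
of the same genome, in direct or inverted orientation. Discovery is by
self-alignment: exact 7-mer seeds (both strands) are extended into gapped
local alignments, and hits are kept when their Karlin–Altschul E-value
is at most 1e-6. The scoring system is the classic small-word nucleotide
configuration: match +2, mismatch −3, affine gaps (a gap of length $k$
costs $5 + 2k$), x-drop 20. All of these are `scanParams()` arguments.

Extension is two-stage, as in blastn: a cheap ungapped x-drop extension
runs first, and the gapped dynamic program (with traceback, needed for the
K2P distance of the pair) runs only when the ungapped score reaches
`gap_trigger` (default 25). At the genome sizes this scanner targets,
seeds below the trigger cannot reach the E-value cutoff, so the heuristic
does not change the reported hit set.

E-values use $E = K m n e^{-\lambda s}$ with $\lambda$ solved from
$\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$ by root finding and $K$ from
the lattice-case convolution series; for the +1/−2 system the code
reproduces the published ungapped constants ($\lambda = 1.33$,
$K = 0.621$), which is the correctness check in the test-suite. The
E-value cutoff implies a detection-length floor: in a 5 kb genome a
perfect duplication must be roughly 25 bp to reach E ≤ 1e-6, so
duplications near the 7 bp word size are invisible by design — the filter,
not the seeding, is the sensitivity limit.

Three guards keep the self-scan meaningful:

* **Low-complexity seeds** are skipped when the dinucleotide Shannon
  entropy of a 12 bp window anchored at the seed falls below 1 bit (an
  analogue of DUST). The 12 bp window is deliberate: a dinucleotide
  microsatellite run scores 0.994 bit over 11 dinucleotides and is
  masked, while the 7-mer alone can never drop below 1 bit for an
  alternating run. Homopolymer genomes produce no hits at all.
* **Near-diagonal artifacts**: in self-comparison, a seed just off the
  main diagonal can rebuild the trivial self-identity through two cheap
  gaps. Plus-strand hits whose two intervals overlap by more than half
  the shorter copy are therefore discarded; a dispersed repeat has two
  distinct loci, and heavily overlapping direct duplications are
  tandem-repeat territory (out of scope here, as tandem repeats and
  transposable elements enter the analysis only as input tables).
* **Palindromes**: a minus-strand self-hit whose two intervals coincide
  is an inverted repeat with a short spacer, aligned to itself. Such hits
  are re-anchored to their two arms (first half of the alignment columns
  versus the reverse-complemented second half) and rescored, so a planted
  inverted pair is reported as one proper pair rather than dropped.

`N` never matches anything, including `N`: seeds containing `N` are not
formed and `N` columns score as mismatches, which avoids inflated repeat
calls in padded assemblies. Circular molecules are scanned with the first
$w-1$ bases appended so seeds spanning the origin are found; reported
coordinates are taken modulo the genome length, with origin-spanning
intervals keeping `end > length` and the interval-merging layer doing the
wrap. A repeat copy that spans the origin by more than the seed pad is
found as split hits; coverage accounting is unaffected.

Mirror duplicates — self-comparison reports every pair twice — are
collapsed to one record with the query copy first. Repetitive-content
totals merge the query- and subject-side intervals of all hits jointly
and count every base once (`mergedRepetitiveBp()`), the literal reading
of overlap-once accounting; the test-suite pins this to a per-base bitmap
oracle.

## Repeat size and age classes

Pairs are binned by the length of the shorter copy: small (< 100 bp),
medium (100–1,000 bp), large (≥ 1,000 bp). Exactly 1,000 bp is large,
because the large-class bound is the explicit "≥ 1,000" one.

Ages come from the Kimura 2-parameter distance over the ungapped
alignment columns,
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$,
with $P$ the transition and $Q$ the transversion fraction; gap and `N`
columns are excluded entirely since the distance is defined on
substitutions. When either logarithm's argument is non-positive the
distance is saturated and reported as `Inf`, excluded from the density
multisets. Age classes: recent ($d \le \varepsilon$), intermediate
($\varepsilon < d < 0.2$), ancient ($d \ge 0.2$). The "essentially zero"
threshold is operationalised as $\varepsilon = 0.005$ — at most one
substitution per 200 sites — because a literal 0 is untestable on finite
alignments; $\varepsilon$ is a `scanParams()` argument so its sensitivity
can be explored.

## Shared DNA and its decay

Two genomes are aligned with the same scanner in cross-genome mode.
Directional coverage is the bp of genome 1 covered by the merged
query-side intervals (and vice versa), each as a percentage of its own
genome; the mean percentage is the arithmetic mean of the two directions
— the convention that reproduces published per-direction tables where the
two lengths differ. A genome shares exactly 100% with itself regardless
of repeat content, because coverage is merged before it is totalled.

The decay fit is an unweighted Pearson correlation and least-squares line
of mean shared percentage against divergence time, with the two-sided
t-test $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df. At least three pairs are
required — with two points $|r|$ is 1 by construction and the test has
zero degrees of freedom — and zero variance in either variable flags the
fit as degenerate instead of returning a number.

## Substitution rates

Per-branch synonymous and nonsynonymous divergences ($d_S$, $d_N$) and
branch ages in million years are inputs (maximum-likelihood branch fits
and tree dating are upstream of this package). The absolute rates are
simply $R = d / (T \times 10^6)$ per site per year. Fold ranges are
max/min over terminal species rows only — internal-branch and
clade-summary rows are excluded — rounded half-up to an integer, which is
what reproduces the published integer folds exactly. Clade-level summary
rows are consumed as given and never recomputed from member species,
since the aggregation that produced them is not specified by the source
tables; they serve only the clade-ratio quotients.

For synthetic testing the package carries a pairwise Nei–Gojobori (1986)
estimator: per-codon synonymous site counts averaged over both sequences
(a change to a stop codon counts as nonsynonymous), observed differences
resolved by averaging over all minimal mutational pathways with pathways
through stop codons excluded (all pathways are used if every one is
excluded), and the Jukes–Cantor correction $d = -\tfrac34\ln(1-4p/3)$
applied separately to $p_S$ and $p_N$, with saturation at $p \ge 3/4$
reported as `Inf`. NG86 was chosen over ML or YN00-style estimators
because it is fully specified, deterministic, and checkable by exhaustive
pathway enumeration — which is exactly how the tests check it. The
genetic code defaults to the standard code, which plant mitochondria use.

## Depth-based origin classification

In a plant cell the plastid, mitochondrial and nuclear genomes differ in
copy number by orders of magnitude (plastid highest, nuclear lowest), so
the median mapped-read depth of a gene indicates its compartment. The
classifier anchors the three classes at the median depth of a single-copy
nuclear spike-in (e.g. *LEAFY*), the median of per-gene medians of the
annotated mitochondrial genes (robust to their several-fold spread), and
the median of a plastid spike-in (e.g. *matK*). A gene goes to the anchor
minimising $|\log_2(\text{median}/\text{anchor})|$; when the two smallest
distances differ by less than 1 log2 unit (a two-fold band, conservative
against order-of-magnitude class gaps) the call is ambiguous, as is any
gene with zero coverage. The nearest-anchor rule in log space is this
package's formalisation of "similar depth to the nuclear spike-in"; no
numeric rule is stated in the source analyses. Calls are scale-invariant
and length-invariant; genes landing on the nuclear anchor but more than
3-fold above it are flagged as possible multi-copy insertions. Read
mapping and alignment-score filtering are upstream: the module consumes
per-position depth tables and documents, rather than implements, the
input filter.

## RNA-editing set statistics

Editing tables are sets of (species, gene, alignment column) triples for
C-to-U sites; duplicates collapse. Site homology across species is keyed
by alignment column within a gene — the cross-species alignment is an
input — because that is the only reproducible keying. A site is
species-unique iff no other species has a site at the same (gene,
column); unique percentages are computed per species (clade-level
aggregation would change the denominators and is left to the caller).
Validation overlap reports $|P \cap O|$ and its percentage of the
predicted set, rounded to the nearest integer; the count is symmetric,
the percentage deliberately not.

## The synthetic-data generator

Every generator takes a mandatory seed and is a pure function of its
arguments, and every one returns a truth table sufficient to score the
downstream stage without re-deriving ground truth.

* `genGenome()`: i.i.d. bases at a target GC.
* `plantRepeatFamily()`: a random source segment copied to non-overlapping
  random loci (rejection sampling, 1,000 retries) on random strands, each
  copy mutated at half the target K2P distance so the expected pairwise
  distance among copies is the target. The mutation process applies the
  exact transition/transversion probabilities of the continuous-time K2P
  model at the requested divergence ($Q = (1-e^{-4\beta t})/2$, etc.), so
  the K2P estimator is unbiased at any divergence rather than only in the
  small-distance limit; the transition/transversion rate ratio defaults
  to $\kappa = 2$.
* `genSharedPair()`: shared blocks (default 2 kb) totalling a target
  fraction of each genome, laid out by stick-breaking so any fraction up
  to exact tiling (fraction 1 gives identical genomes at divergence 0) is
  placeable, with the copies mutated to the target divergence and the
  remainder independent.
* `genDepthProfiles()`: per-position depths from a counting-noise model —
  Poisson by default, negative binomial under overdispersion, since real
  depth data are overdispersed. Class means default to observed spike-in
  anchors from a conifer resequencing experiment (nuclear 15×,
  mitochondrial 600×, plastid 14,395×), with mitochondrial reference
  means log-spaced around their class mean to emulate the several-fold
  spread of real mitochondrial genes.
* `genCodonPair()`: a stop-free ancestor evolved along two branches, with
  per-branch synonymous/nonsynonymous substitution counts drawn Poisson
  at intensities that invert the Jukes–Cantor correction of the targets,
  individual changes sampled κ-weighted and rejected if they create stops
  or fall in the exhausted category. Targets must be below 0.5
  (saturation guard).

What the generator does **not** emulate: recombination and rearrangement,
horizontal transfer, read-level errors, alignment uncertainty in the
editing tables, and real repeat family structure (nested, truncated and
shuffled copies). Passing the synthetic suite therefore demonstrates that
the estimators recover planted signal under their own model assumptions —
it does not certify performance on real assemblies, where low-complexity
content, chimeric joins and assembly artifacts dominate error budgets.

## Numerical choices and problem sizes

Tie-breaks in the gapped extension prefer substitutions over gaps at
equal score. The half-up integer rounding used for fold ranges and
validation percentages is `floor(x + 0.5)`, not banker's rounding.
Degenerate inputs are handled explicitly: genomes shorter than the word
size warn and return no hits; empty predicted sets flag rather than
divide by zero; saturated distances are `Inf` sentinels excluded from
summaries.

The test-suite and the acceptance script run at desk scale, chosen so the
statistical checks are well-powered while the whole suite stays fast:
5 kb genomes for the 200-fixture recall sweep, 30–50 kb genomes for
family-K2P and coverage checks, 40 kb genome pairs for the shared-DNA
recovery grid, 5,000 codons for NG86 recovery, 120-gene panels for the
depth classifier. Recall is asserted on planted duplications of 50 bp and
above — beyond the E-value detection floor discussed earlier, and still
far above twice the word size.

## Known limitations

* The scanner is not NCBI BLASTN and makes no claim of numeric hit-list
  equivalence; it honours the same word size, E-value model and default
  scoring, which is what the repeat statistics depend on.
* Whether "number of dispersed repeats" counts pairs or distinct loci is
  ambiguous in published tables; this package counts collapsed pairs and
  exposes the per-hit table so either convention can be derived.
* Repetitive totals here merge dispersed-repeat intervals only; published
  totals that merge across repeat categories (with tandem repeats and
  transposable elements) need those annotations as extra inputs.
* Clade-level rate rows are opaque inputs; if their aggregation rule were
  known, fold ranges over clades could be recomputed from species rows
  instead.
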