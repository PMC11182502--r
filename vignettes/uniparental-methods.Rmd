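---
title: "Methods: uniparental-marker population structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uniparental-marker population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uniparental)
```

## Scope and data model

`uniparental` analyses the two uniparentally inherited, non-recombining
compartments of the human genome: complete mitogenome sequences (maternal)
and SNP haplotypes from the male-specific region of the Y chromosome
(MSY, paternal). Because neither locus recombines, each sample carries a
single haplotype, and population structure can be summarised by haplotype
identity and pairwise sequence distances.

Two input shapes are supported, with a common downstream path:

* an aligned FASTA of complete mitogenomes (equal-length rows over
  `A,C,G,T,N,-`), with an optional named reference row that carries the
  coordinate frame (RSRS or rCRS numbering);
* a biallelic SNP table (samples x sites, strictly increasing 1-based
  positions, a configurable missing token).

All coordinates in the package are 1-based and range-inclusive.

## Masking

Homopolymer stretches and repeat regions of the mitogenome align
unreliably and are conventionally removed before haplotype comparison.
`default_mtdna_mask()` holds the eight standard regions — the HVS-II
poly-C (np 303–317), CA repeat (np 514–523), C-stretch 1 (np 568–573),
a 12S rRNA homopolymer (np 956–965), the historical position np 3107, a
second C-stretch (np 5895–5899), the 9-bp indel region (np 8272–8289) and
the HVS-I poly-C (np 16180–16195) — 81 reference positions in total. The
9-bp indel region is masked as a range rather than recoded as a
presence/absence character, keeping haplotype identity purely
substitution-based.

`apply_mask()` additionally removes every column containing at least one
`N`, and every column containing a gap, across the whole analysis sample
set (*complete deletion*). The alternative — pairwise deletion — would let
each statistic see a different site set; complete deletion guarantees that
haplotype identity, nucleotide diversity and Φ~ST~ are computed on one
common set of columns and are therefore mutually consistent. The choice of
sample set matters: adding a sample with an `N` can shrink the retained
column set, so `effective_length` and the removed-column log are always
reported, letting users reproduce either a per-population or a
dataset-wide masking convention. Gap columns are removed under the same
rule because alignment insertions relative to the reference carry no
reference coordinate and cannot be addressed by coordinate ranges.

For SNP tables, `drop_missing_sites()` removes any site with one or more
missing calls, again wholesale, because the concatenated haplotype string
of every sample must be complete. Haplotype identity is exact string
match; IUPAC ambiguity codes are rejected at read time rather than
matched fuzzily.

## Diversity estimators

With haplotype counts $c_i$, $n = \sum_i c_i$ and $p_i = c_i/n$:

$$\hat H = \frac{n}{n-1}\Big(1 - \sum_i p_i^2\Big)$$

(Nei 1987, unbiased), with sampling variance

$$V(\hat H) = \frac{2}{n(n-1)}\Big[2(n-2)\Big(\sum_i p_i^3 -
\big(\sum_i p_i^2\big)^2\Big) + \sum_i p_i^2 - \big(\sum_i p_i^2\big)^2\Big].$$

$\hat H$ is the probability that two samples drawn without replacement
differ: 0 iff the population is fixed for one haplotype, exactly 1 when
all samples are distinct.

Nucleotide diversity is per retained site,
$\hat\pi = \sum_{i<j} d_{ij} / \binom{n}{2} L$ with $d_{ij}$ the Hamming
distance over retained columns and $L$ the effective length, with
variance by Nei (1987, eq. 10.9)

$$V(\hat\pi) = \frac{n+1}{3(n-1)L}\,\hat\pi +
\frac{2(n^2+n+3)}{9n(n-1)}\,\hat\pi^2 .$$

The mean number of pairwise differences, $MPD = \hat\pi L$, is reported in
raw site counts. Per-site normalisation for $\pi$ and raw counts for MPD
follow the reporting conventions of the population-genetic literature for
~16.5 kb mitogenomes; because $L$ is always carried in the output, either
normalisation can be reconstructed (for SNP panels, where the callable
length is debatable, this is essential). `percent_from_mean()` re-expresses
a statistic as $100(x_p - \bar x)/\bar x$ for across-population display.

Both estimators require $n \ge 2$; populations of size 1 are reported
with flagged `NA` values rather than silently dropped or zeroed.

## Haplotype sharing

The sharing statistic is the proportion of identical-sequence pairs.
Between populations $A$ and $B$ all $n_A n_B$ cross pairs are counted,

$$S(A,B) = \frac{\sum_h c_A(h)\, c_B(h)}{n_A n_B},$$

within a population the unordered pairs,

$$S(A,A) = \frac{\sum_h \binom{c_A(h)}{2}}{\binom{n_A}{2}}.$$

These denominators were a genuinely open design point (the statistic has
no canonical reference formula); this pair is the only convention that
(i) keeps the matrix symmetric, (ii) never counts self-pairs, and
(iii) makes the diagonal exactly 1 for a population fixed for a single
haplotype — so within- and between-entries are displayable on one colour
scale. The convention is recorded here so that published within-population
values can arbitrate it against real data. Size-1 populations get a
flagged `NA` diagonal: a single sequence carries no within-population
sharing evidence, and a 0 would fabricate apparent diversity.

## Pairwise Φ~ST~ and permutation tests

Population differentiation uses the two-group AMOVA with squared pairwise
distances (Excoffier et al. 1992), the convention used for haplotypic
data by the standard AMOVA software. For each population pair,

$$SS_{total} = \tfrac{1}{N}\sum_{i<j} d_{ij}^2,\qquad
SS_{within} = \sum_g \tfrac{1}{n_g} \sum_{i<j\in g} d_{ij}^2,$$

$\sigma^2_w = SS_{within}/(N-2)$,
$\sigma^2_a = (SS_{among} - \sigma^2_w)/n_c$ with
$n_c = N - (n_1^2+n_2^2)/N$, and
$\Phi_{ST} = \sigma^2_a/(\sigma^2_a+\sigma^2_w)$.
An independent explicit-enumeration implementation of these sums of
squares guards the algebra in the test suite.

Significance comes from permuting individuals between the two populations
(haplotypes intact) and recomputing Φ~ST~, with the add-one correction
$p = (1+\#\{\Phi^{perm}\ge\Phi^{obs}\})/(1+B)$. $B$ defaults to 1000 —
permutation tests stabilise with more permutations at negligible cost
here. The add-one form keeps the test valid ($p \ge 1/(B+1)$, never 0) at
the price of slight conservatism; for very small groups the permutation
space itself bounds the attainable p-value (e.g. two groups of three
cannot go below ~0.1). Significance marks use a plain p > 0.05 threshold
per pair with no multiple-testing correction, matching the common display
convention for pairwise Φ~ST~ heatmaps; with many pairs this inflates the
family-wise error rate, which is why the raw p-value matrix is always
written alongside.

Negative Φ~ST~ estimates are legitimate sampling outcomes around zero and
are reported as computed. Only for ordination input does
`phist_for_nmds()` clamp them to 0 and then lift off-diagonal exact zeros
by 10^-6^, because NMDS requires positive dissimilarities; both matrices
are available.

## Ordination

**NMDS.** `nmds()` performs Kruskal non-metric MDS via `MASS::isoMDS`,
initialised from classical (metric) scaling. When the double-centred
matrix of a Φ~ST~-like input is rank-deficient, the initial configuration
is padded and perturbed by a fixed (seed-free, hence reproducible)
sinusoidal jitter of relative magnitude 10^-4^, which `isoMDS` would
otherwise reject. Stress-1 is reported in percent. `isoMDS` is a local
optimiser: stress can fail to decrease with added dimensions from a single
start, so `n_restarts` runs seeded random initialisations and keeps the
best solution; the monotonicity property is checked in the test suite with
10 restarts. The practical reading of stress follows the usual rule of
thumb (< 5 % excellent, > 20 % untrustworthy), and a high 2-D stress is
the signal to move to three dimensions.

**Correspondence analysis.** `correspondence_analysis()` implements
classical CA by SVD of the standardised residual matrix
$S = D_r^{-1/2}(P - rc^T)D_c^{-1/2}$, returning principal and standard
coordinates for rows (populations) and columns (haplogroups), per-axis
inertia $\sigma_k^2$ and total inertia $\chi^2/n$. Axes with singular
values below $10^{-12}$ of the leading one are dropped as numerical noise
(an independence table keeps one ~zero axis so that the object remains
well-formed). A table whose rows sum to 1 is treated as row-wise relative
frequencies and re-expressed with uniform pseudo-counts of 1000 per row,
and flagged: CA needs relative row weights, and uniform pseudo-counts make
every population count equally, which is exactly the analysis performed
when one speaks of ordination "based on haplogroup frequencies". Note that
CA of raw counts and CA of per-row frequencies are *not* the same
analysis — row masses differ — which is why the rescaling is explicit and
flagged rather than silent. The test suite checks the identities that do
hold: invariance under uniform scaling of the whole table, distributional
equivalence (merging rows with proportional profiles), and the Parseval
decomposition of inertia, cross-checked against `vegan::cca`.

## Haplogroup tables

Haplogroup *calling* (HaploGrep2/yhaplo against PhyloTree/ISOGG) is out of
scope; assignments are consumed as input. A trailing `*` marks a paragroup
(assigned to the clade but to none of its defined subclades) and is kept
distinct from the bare label in all tabulations. Major-group rollups use
longest-prefix matching with the star stripped for matching purposes; the
shipped rule files for mtDNA and MSY major groups are a practical
reconstruction of common binnings, not an authoritative nomenclature, and
can be replaced by any two-column prefix/major table.

## The simulator

`simulate_dataset()` is a forward-time Wright–Fisher island model with
separate sexes, chosen over coalescent machinery because it is
transparent, fast at the scales used here, and expresses sex-specific
migration directly as marriage-driven relocation. Per generation, in
order: adults migrate (each individual at most once, uniform destination
among the other demes, sex-specific probability); each deme produces a
fixed number of offspring per sex, drawing mothers and fathers uniformly
among its post-migration residents (if migration empties a deme of one
sex, parents of that sex are drawn metapopulation-wide for that
generation); offspring sequences then mutate by per-site Bernoulli
substitution — uniform among the other three bases for mtDNA, allele flips
for the biallelic MSY sites. A finite-sites model suffices because every
downstream statistic depends only on identity and Hamming structure.
Founders carry independent random sequences and a lineage label inherited
with the marker, so with mutation rate 0 the haplotype partition provably
equals the founder partition, and lineage labels double as
pseudo-haplogroups for exercising the haplogroup and CA modules.

Residence presets encode postmarital residence as migration asymmetry:
matrilocal means husbands relocate (`m_male = 0.2 > m_female = 0.02`),
patrilocal is the exact mirror, neutral sets both to 0.1. The default
scale — 10 demes of 50 + 50, 200 generations, μ = 10^-4^ per site,
L = 1000, 20 samples per deme per sex — was chosen once as a realistic
desk-scale regime: village-sized demes, mutation supply θ per deme of
order 1–10, and enough generations for migration–drift balance to shape
within-deme diversity. No empirical migration rates exist for these
groups; the presets are illustrative by construction.

`residence_contrast()` runs mirror matrilocal/patrilocal pairs and
reports replicate means of within-deme haplotype diversity per marker
with a bootstrap interval on the difference. The expectation it makes
testable: relocating husbands homogenise Y lineages among demes, so
within-deme MSY diversity should exceed the patrilocal mirror's, and
mtDNA the reverse. What the simulator does *not* emulate — admixture with
unsampled neighbours, population growth, marriage preferences beyond the
uniform island model, selection, heteroplasmy, sequencing error — is
precisely why a real population can deviate from this clean prediction
while the simulated property still holds.

## Problem sizes and determinism

Every stochastic routine takes an explicit integer seed and is exactly
reproducible from it; the simulator uses only R's integer-state RNG (no
time-based entropy), so outputs are platform-stable. The test suite runs
the oracle comparisons at n ≤ 8 sequences (exact enumeration), the
permutation-null calibration at 500 single-deme replicates with 99
permutations each, and the residence contrast at 20 replicate pairs of
the default preset — sizes chosen so the whole suite completes in a
couple of minutes while leaving the stochastic checks well-powered.

## Known limitations

* Sharing and Φ~ST~ p-values are not corrected for multiple testing.
* The AMOVA is strictly two-group per pair; hierarchical (3-level)
  designs are out of scope.
* CA axes carry no significance machinery.
* The within-population sharing denominator is a documented convention
  (see above), not a community standard; compare conventions before
  comparing numbers across software.
* Haplogroup rollup rules are a reconstruction; users with a preferred
  nomenclature should supply their own rule table.
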