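# uniparental

Population-structure analysis of uniparentally inherited markers —
complete mitogenome sequences (maternal) and Y-chromosomal SNP haplotypes
(MSY, paternal) — aimed at questions of the kind that arise in human
population genetics of Southeast Asia: do language communities share
haplotypes with their geographic neighbours or with distant speakers of
related languages, and do maternal and paternal lineages tell the same
story (sex-biased migration, matrilocal vs patrilocal residence)?

Because neither marker recombines, every individual carries a single
haplotype and the analysis chain is:

1. **Masking / filtering** — remove the unreliable mitogenome regions
   (HVS-I/HVS-II poly-C stretches, CA repeat, 9-bp indel region, …; 81
   reference positions in 8 ranges via `default_mtdna_mask()`), all
   N- and gap-containing columns; drop SNP sites with missing calls.
2. **Haplotype collapsing** — equivalence classes of exact sequence
   identity over retained columns (`collapse_haplotypes()`,
   `genotype_haplotypes()`).
3. **Diversity** — Nei (1987) unbiased haplotype diversity
   *H* = *n*(1 − Σ*p*²)/(*n* − 1) with its variance, per-site nucleotide
   diversity π = Σ<sub>i&lt;j</sub> d<sub>ij</sub>/(C(n,2)·L) with the
   Nei eq. 10.9 variance, mean pairwise differences MPD = π·L, and
   percent-from-mean summaries (`diversity_summary()`).
4. **Haplotype sharing** — proportion of identical-sequence pairs within
   (Σ C(c,2)/C(n,2)) and between (Σ c<sub>A</sub>c<sub>B</sub>/n<sub>A</sub>n<sub>B</sub>)
   populations (`sharing_matrix()`).
5. **Φ<sub>ST</sub>** — two-group AMOVA on squared Hamming distances
   (Excoffier 1992) with permutation p-values (`pairwise_phist()`).
6. **Ordination** — Kruskal NMDS of the Φ<sub>ST</sub> matrix (stress in
   percent; `nmds()`), and correspondence analysis of
   population × haplogroup frequency tables with per-axis inertia
   (`correspondence_analysis()`, fed by `frequency_table()` /
   `rollup()`).
7. **Simulation** — a forward-time Wright–Fisher island model with
   sex-specific migration (`simulate_dataset()`,
   `residence_contrast()`), which generates mtDNA-like alignments,
   MSY-like SNP tables, metadata and pseudo-haplogroups, and makes the
   matrilocality prediction (higher within-group MSY diversity where
   husbands relocate) a testable property.

`run_pipeline()` chains stages 1–6 from a YAML/R config and writes TSV
matrices plus a JSON manifest of every parameter and seed.

## Worked example

Simulate four demes under matrilocal residence (male migration 0.2,
female 0.02), then run the analysis chain:

```r
library(uniparental)

cfg <- simulation_config(n_demes = 4, sample_size = 12, generations = 150,
                         residence_mode = "matrilocal", seed = 7)
sim <- simulate_dataset(cfg)
sim
#> <simulated_dataset> 4 demes, 96 mtDNA samples x 1000 sites, 48 MSY samples x 1000 sites (matrilocal, seed 7)

masked <- apply_mask(sim$mt_alignment, mask_spec(integer(), integer()))
diversity_summary(masked, sim$metadata)[, c("population", "n", "k", "H", "pi", "MPD")]
#>   population  n  k     H     pi   MPD
#> 1     deme01 24 13 0.935 0.2206 220.6
#> 2     deme02 24 14 0.938 0.0164  16.4
#> 3     deme03 24 16 0.957 0.2973 297.3
#> 4     deme04 24 18 0.964 0.0204  20.4
```

`n` sequences collapse to `k` haplotypes; `H` near 1 means two random
sequences almost always differ. π here is large compared to real
mitogenomes (~0.002) because simulator founders are independent random
sequences — demes that retain several divergent founding lineages
(deme01, deme03) show it, and MPD = π × 1000 sites.

```r
pr <- pairwise_phist(masked, sim$metadata, n_permutations = 199, seed = 7)
round(pr$phi_st, 4)
#>         deme01 deme02  deme03 deme04
#> deme01  0.0000 0.1372 -0.0226 0.1333
#> deme02  0.1372 0.0000  0.2161 0.0797
#> deme03 -0.0226 0.2161  0.0000 0.2128
#> deme04  0.1333 0.0797  0.2128 0.0000
round(pr$p_values, 4)
#>        deme01 deme02 deme03 deme04
#> deme01     NA  0.005  0.695  0.005
#> deme02  0.005     NA  0.010  0.050
#> deme03  0.695  0.010     NA  0.030
#> deme04  0.005  0.050  0.030     NA

ord <- nmds(phist_for_nmds(pr), k = 2)
cat(sprintf("stress: %.3f%%\n", ord$stress))
#> stress: 0.000%
```

deme01 and deme03 are genetically indistinguishable (Φ<sub>ST</sub> ≈ 0,
permutation p = 0.70 — a slightly negative estimate is ordinary sampling
noise around zero); the other pairs differentiate at Φ<sub>ST</sub>
0.08–0.22 with small p-values. Four points embed in two dimensions with
zero stress, so the NMDS map is a faithful picture of the
Φ<sub>ST</sub> ranks.

The sharing matrix (`sharing_matrix(collapse_haplotypes(masked,
sim$metadata))`) shows within-deme sharing of 0.04–0.07 on the diagonal
and near-zero between demes, the signature of mostly-private haplotypes.

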