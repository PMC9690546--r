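# breedgate

SNP-based breed assignment at the breed boundary.

Breed registries must decide whether a candidate animal belongs to the
reference population (RP) of its breed or carries too much foreign
background. `breedgate` implements two standardized assignment scores built
for that decision, each anchored at two genomes a breeder can point to:
**0** for the breed's interior and **1** for the *outgroup* — the single
genetically closest individual of the nearest related breed. Anything
scoring beyond 1 lies on the other breed's side of the boundary.

* **IBS-central** — from the pairwise identity-by-state matrix, each animal
  gets `IBS_sum`, the sum of its similarities to everyone else. The RP
  member with the maximal sum is the *central animal* (score 0); scores are
  normalized shortfalls
  `(IBS_max_of_sums − IBS_sum_i) / (IBS_max_of_sums − IBS_sum_outgroup)`,
  so the outgroup scores exactly 1.
* **PCA-distance** — individuals are embedded by principal coordinates of
  the IBS matrix (double-centering + eigendecomposition, coordinates scaled
  by √eigenvalue); each animal's Euclidean distance to the component-wise
  **median** of the RP is divided by the outgroup's distance. Recomputed
  from scratch at every assignment step.

Around the scores, the package provides the full working pipeline:
PLINK PED/MAP text I/O and dataset merging with call-rate filtering
(`read_plink_text()`, `merge_intersect()`), per-marker Fst screening plus
composite-LD pruning to build breed-informative panels
(`select_informative()`), block-mosaic and dilution-series simulators of
admixed genomes (`build_mosaic()`, `dilution_series()`), a
Rannala–Mountain / Paetkau Monte-Carlo inclusion-probability comparator
(`paetkau_inclusion()`), a Balding–Nichols multi-breed genotype generator
(`simulate_breeds()`, `paper_like_fixture()`), and a driver for the
expanding-RP assignment protocol with "dotted ball" polar exports
(`expanding_rp_protocol()`, `export_scores_polar()`).

## Worked example

Score a 70-member focal breed against the nearest member of its closest
relative breed, on a simulated study system:

```r
library(breedgate)

fix <- paper_like_fixture(seed = 1)
fix$ds
#> <genotype_dataset> 136 samples x 2400 markers, 8 breeds, 0.00% missing
fix$outgroup_id
#> [1] "HWV3"

focal <- fix$ds$samples$sample_id[fix$ds$samples$breed == fix$focal]
ibs <- pairwise_ibs(fix$ds, c(focal, fix$outgroup_id))
ibs
#> <ibs_matrix> 71 individuals, off-diagonal range 0.6975-0.7902

cs <- central_scores(ibs, rp_ids = focal, outgroup_id = fix$outgroup_id)
head(cs[order(-cs$score), c("sample_id", "ibs_sum", "score")], 6)
#>    sample_id  ibs_sum     score
#> 71      HWV3 49.84771 1.0000000
#> 68     HSV68 51.47333 0.4792445
#> 38     HSV38 51.49958 0.4708356
#> 24     HSV24 51.82937 0.3651895
#> 30     HSV30 52.16875 0.2564736
#> 40     HSV40 52.19146 0.2491991
```

The outgroup sits at exactly 1 and the four planted peripheral animals
(`HSV24`, `HSV30`, `HSV38`, `HSV68` — simulated 25–40% mosaics with the
relative breed) top the ranking while staying inside the boundary; every
other member scores ≤ 0.25. The same animals protrude under PCA-distance:

```r
pd <- distance_scores(embed_ibs(ibs, k = 3), focal, fix$outgroup_id)
head(pd[order(-pd$score), ], 6)
#>    sample_id  distance     score
#> 71      HWV3 0.4955187 1.0000000
#> 30     HSV30 0.2983263 0.6020484
#> 38     HSV38 0.2498454 0.5042099
#> 68     HSV68 0.2193213 0.4426095
#> 24     HSV24 0.2122976 0.4284350
#> 39     HSV39 0.1864186 0.3762090
```

Diluting a peripheral member's genome by the outgroup in 10% steps degrades
its IBS-central score monotonically toward the boundary:

```r
ds2 <- dilution_series(fix$ds, "HSV68", fix$outgroup_id)
# each artificial genome scored singly against the remaining 69 members:
#> dil_HSV68_00 dil_HSV68_10 dil_HSV68_20 dil_HSV68_30 dil_HSV68_40
#>        0.479        0.529        0.532        0.716        0.597
#> dil_HSV68_50 dil_HSV68_60 dil_HSV68_70 dil_HSV68_80 dil_HSV68_90
#>        0.777        0.720        0.801        0.841        0.929
```

And the Bayesian comparator gives seeded, reproducible inclusion
probabilities:

```r
paetkau_inclusion("HSV45", fix$ds, focal, n_sim = 10000, seed = 17)
#> <inclusion_result> HSV45: logL = -1753.40, inclusion p = 0.0174 (n_sim = 10000)
```

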