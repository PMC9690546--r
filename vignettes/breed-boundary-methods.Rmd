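---
title: "Balancing at the breed boundary: the models behind breedgate"
author: "breedgate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balancing at the breed boundary: the models behind breedgate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedgate)
```

## The problem

Breed registries face a recurring decision: does a candidate animal belong to
the reference population (RP) of its claimed breed, or does its genome carry
enough foreign background that admitting it would blur the breed? breedgate
implements two standardized SNP-based assignment scores designed for exactly
this "balancing at the breed boundary" decision, together with everything
needed to exercise them: PLINK text I/O, call-rate filtering and dataset
merging, construction of breed-informative marker panels, artificial admixed
genomes for calibrating thresholds, and a Bayesian assignment comparator of
the kind breed managers already run in GeneClass-style software.

Both scores share one design idea: anchor the scale at two genomes that are
meaningful to a breeder. Zero is the breed's own interior — the most
representative animal (IBS-central) or the multivariate median of the RP
(PCA-distance). One is the *outgroup*: the single genetically closest
individual of the most closely related breed. Whatever lies beyond 1 is, by
construction, on the other breed's side of the boundary.

## IBS-central

The pairwise identity-by-state (IBS) similarity of two diploid genotypes
over the loci both have called is

$$\mathrm{IBS} = \frac{n_{\mathrm{IBS2}} + \tfrac12\, n_{\mathrm{IBS1}}}{n},$$

where IBS2 loci have identical genotypes, IBS1 share one allele, and IBS0
are opposite homozygotes. `pairwise_ibs()` evaluates this per pair over
pairwise-complete loci (PLINK's convention for missing data). Pair values
are constants: inserting a new animal only adds one row
(`insert_and_rescore()`), but every row sum must then be recomputed.

Each animal is summarized by `ibs_sum`, the sum of its off-diagonal row. The
RP member with the maximal sum is the **central animal** — the genome most
similar to everyone else, and a natural candidate for whole-genome
sequencing as the breed's reference. Scores are normalized shortfalls from
that maximum:

$$\mathrm{score}_i \;=\; \frac{\mathrm{IBS\_max\_of\_sums} - \mathrm{IBS\_sum}_i}
{\mathrm{IBS\_max\_of\_sums} - \mathrm{IBS\_sum}_{\mathrm{outgroup}}}.$$

The central animal scores exactly 0, the outgroup exactly 1. An animal even
less similar to the population than the outgroup scores above 1; we report
such values as they are rather than clamping, because exceeding the anchor
is precisely the signal that an animal sits beyond the breed boundary. By
default the row sums run over every individual present in the matrix
(RP members, co-evaluated candidates, the outgroup); a strict RP-only
summing mode (`sum_over_rp_only = TRUE`) is available and is the mode in
which control animals provably cannot perturb RP members' scores. Ties for
the central animal are broken by earliest matrix order and reported with a
message; they essentially only arise in engineered data.

## PCA-distance

`embed_ibs()` turns the IBS similarity matrix into coordinates by classical
principal-coordinate analysis: double-center the matrix, eigendecompose,
keep the top *k* nonnegative eigenvalues, and scale eigenvectors by the
square roots of their eigenvalues, so that Euclidean distances between rows
reproduce the similarity-induced metric (at full rank,
$d^2_{ij} = g_{ii} + g_{jj} - 2g_{ij}$ on the centered matrix — one of the
package's oracle tests). Component signs are fixed by making each column's
largest-magnitude entry positive; all scores are distance-based and thus
sign-invariant anyway.

The reference point is the component-wise **median** of the RP members'
coordinates (midpoint convention for even RP sizes) — the median, not the
mean, so a few peripheral members cannot drag the reference point towards
themselves. Scores are Euclidean distances to that median divided by the
outgroup's distance. *k* defaults to 3, the dimensionality usually plotted
and sufficient once the panel is breed-informative; it is configurable, and
distances are non-decreasing in *k* (nested sums of squares).

Crucially, the method *re-embeds at every assignment step*
(`reassess_with_candidates()`): coordinates, median, and all distances are
recomputed whenever the RP grows or a candidate is offered. Candidates
influence the embedding but never the median.

### Why candidates are evaluated one at a time

A dilution series (below) produces ten artificial genomes that share
60–100% of their markers. Offering them to the RP *simultaneously* lets
them vouch for each other: their mutual IBS inflates each other's row sums,
and in the embedding they form a dense cluster that captures a top
principal axis, distorting everyone's coordinates. Both effects are
artefacts of co-evaluating near-copies, not of the scores. The protocol
driver therefore scores each batch against the current RP and the fixed
controls only, and the dilution analyses evaluate each artificial genome
singly (`insert_and_rescore()` for IBS-central, a one-candidate
re-embedding for PCA-distance).

## The breed-informative panel

`select_informative()` screens markers in two stages with the defaults used
throughout the package: retain markers whose two-group Wright/Nei
$F_{ST}$ between the focal breed and the pooled remaining breeds is at
least 0.4 (ties retained), then prune linkage disequilibrium by a greedy
map-order scan per chromosome, dropping any marker whose squared dosage
correlation (composite LD, computable without phasing) with an
already-kept marker is at least 0.5. The $F_{ST}$ estimator is the
frequency-based form
$F_{ST} = (H_T - H_S)/H_T$ with $H_T = 2\bar p(1-\bar p)$ and
$H_S$ the mean of the two group heterozygosities; markers with $H_T = 0$
are unscorable and reported as `NA`. Design choices where conventions vary:

* the contrast is one pooled focal-vs-rest comparison (a per-breed-minimum
  mode exists behind `per_breed_min = TRUE`);
* "LD threshold 0.5" is interpreted as $r^2 \ge 0.5$;
* pruning compares against all kept markers on the chromosome — panels
  after an $F_{ST} \ge 0.4$ screen are small, so no window is needed;
* the merge call-rate filter is strictly "> 0.95", and allele-label swaps
  between datasets are harmonized by flipping dosages while strand flips
  are rejected rather than guessed.

## Artificial admixed genomes

`build_mosaic()` assembles a genome block-by-block along the marker serial
order (markers sorted by chromosome, then position; blocks may span
chromosome ends). The canonical schedule takes 38 consecutive markers from
each of 24 donors plus 12 from a 25th, filling a 924-marker panel exactly —
the package's provenance test checks every cell.

`dilution_series()` emulates progressive introgression: for each fraction
*f* it replaces $\lfloor f L + 0.5 \rfloor$ of the target's *L* marker
calls with a donor's calls, in blocks of 38 markers. Half-up rounding makes
the counts on the 10% grid exact (92, 185, 277, … on a 924-marker panel).
Under the default `interleaved` strategy the replaced blocks are spaced
evenly across the genome — admixture from a real backcross is genome-wide —
while `prefix` replaces the leading blocks for a strictly sequential
reading. Appended genomes get breed label `"ADMIX"` so they can never
silently enter reference statistics.

## The Bayesian assignment comparator

`rm_genotype_loglik()` implements the Rannala–Mountain genotype likelihood
with a uniform Dirichlet prior over the two alleles at each marker: with
$x$ copies of an allele among $n$ counted reference alleles, the first
candidate copy of that allele has posterior-predictive probability
$(x + \tfrac12)/(n+1)$, the second $(x' + \tfrac12 + [\text{same}])/(n+2)$
(Pólya urn), heterozygotes carrying the factor 2. The three genotype
probabilities sum to one for *any* count table — an identity the tests
verify across random tables. When a candidate is itself an RP member its
alleles are removed from the counts first (leave-one-out).

`paetkau_inclusion()` wraps the likelihood in the Paetkau-style Monte-Carlo
exclusion test: simulate genotypes from the *observed* RP allele
frequencies (the null of "this candidate is just another member"), score
them with the same likelihood restricted to the candidate's called
markers, and report the add-one rank
$(1 + \#\{\text{sim} \le \text{candidate}\})/(n_{\mathrm{sim}}+1)$.
The estimator never returns an exact zero at finite $n_{\mathrm{sim}}$;
printed zeros in assignment software are an artefact of its simulation
count. $n_{\mathrm{sim}}$ defaults to 10,000 and a seed is mandatory, so
reports are reproducible.

## The synthetic study system

Real multi-breed genotype panels are access-restricted, so the package
ships a generator that emulates the study system it was built around:
`simulate_breeds()` draws Balding–Nichols breeds (per marker, an ancestral
frequency $p \sim U(0.05, 0.5)$; each breed's frequency from a Beta with
mean $p$ and variance $F p(1-p)$; genotypes binomial), with optional
uniform missingness and markers laid out on contiguous chromosomes.
No LD is simulated — LD-pruning tests plant explicit duplicated or flipped
markers instead.

`paper_like_fixture()` composes the full study shape: a 70-member focal
breed ($F = 0.15$), six distant breeds of 10 ($F = 0.25$), and a 6-member
close-relative breed whose frequencies are a *founder admixture* of 60%
pointer-breed and 40% focal-breed frequencies followed by strong
post-founding drift ($F = 0.2$) — mirroring a young breed created by
crossbreeding and then bred closed from a narrow founder base. Two
modelling details deserve emphasis because naive alternatives fail in
instructive ways:

* **A second, individual-level drift layer** ($F = 0.015$ within every
  breed) gives members persistent identities: a core and a genuine
  periphery. Plain Balding–Nichols members are exchangeable draws from one
  frequency vector, and an outgroup separated only by a small breed-level
  drift is then statistically indistinguishable from the members
  themselves — the score normalization degenerates.
* **Post-founding drift restores breed-typical homozygosity.** A frequency
  *mixture* sits near 0.5 at many loci and would make the relative breed
  unrealistically heterozygous; heterozygous genotypes are never IBS0 and
  therefore deceptively IBS-similar to everyone. Drift pushes the mixture
  frequencies back toward the extremes, as it did historically.

Four focal members are planted as 25–40% mosaics with relative-breed
donors, in short (8-marker) seeded-random tracts — historical background
admixture is many generations old, hence short tracts at arbitrary
positions, unlike the 38-marker grid of the artificial dilution series.
These planted animals reproduce the study's peripheral purebreds: they
surface as the top outliers under both scores while remaining inside the
boundary. The outgroup is chosen exactly as in the study protocol: the
relative-breed member with the highest mean IBS to the focal breed.

The default sizes (2,400 markers, 136 animals) keep every analysis,
including five-seed property suites, comfortably interactive while leaving
the planted structure statistically unambiguous.

### What the generator does *not* emulate

No linkage disequilibrium, no pedigree or family structure, no genotyping
artefacts beyond uniform missingness, and — importantly — no foreign
haplotypes in directions outside the simulated breed space. One observed
real-data behaviour depends on exactly those ingredients: diluted copies of
the most protruding real animal *overshot* the outgroup anchor (scores
above 1) at 60–80% replacement. In this generator a genome progressively
replaced by the outgroup's own calls converges to the outgroup from the
inside, so its standardized distance saturates just below 1 regardless of
embedding dimension. Passing dilution tests here demonstrate monotone
sensitivity to introgression; they cannot, by construction, demonstrate the
overshoot, which requires genuinely foreign background of a kind the
generator does not span.

## The expanding-RP protocol

`expanding_rp_protocol()` drives the assignment workflow: start from an
initial RP (default 30), offer a batch (default 2) of new candidates plus
the fixed negative controls (the outgroup and any artificial admixed
genomes) at each step, record everyone's score, then absorb the batch into
the RP. Everything is recomputed from scratch each step, so the central
animal and the median can and do move. Two policy decisions follow the
conservative practice the method was designed around: thresholds (defaults
0.6 for PCA-distance, 0.4 for IBS-central) only *annotate* the output, and
nothing is ever auto-excluded — flagged animals stay in, and removal is a
human decision best taken at large RP sizes. Candidate order is taken as
given; step numbering is contiguous. The polar export
(`export_scores_polar()`) writes the "dotted ball" view of a column:
radius = score, deterministic golden-angle spacing by rank, colour bands at
0.2-wide intervals with the outgroup banded separately.

## Numerical conventions

* Half-up rounding for dilution counts; exact integer block arithmetic for
  mosaics.
* Pairwise-complete loci for IBS and LD; per-pair errors when two samples
  share no called marker.
* IBS values are computed with the same counting formula the definition
  states, so independent per-locus recounts agree bitwise.
* Eigen-decomposition on the symmetrized centered matrix; negative
  eigenvalues truncated at zero for coordinate scaling; degenerate
  (all-equal) matrices flagged.
* Central-animal ties: earliest order, with a message. Degenerate
  normalizations (outgroup sum equal to the RP maximum, or outgroup at the
  median) are errors, not silent NaNs.
* All simulation entry points take explicit seeds and restore the caller's
  RNG state.
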