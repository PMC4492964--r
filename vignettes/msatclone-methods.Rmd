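---
title: "Methods: clonal lineages and population structure from microsatellites"
author: "msatclone developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal lineages and population structure from microsatellites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatclone)
```

## The problem

Many reef-building corals propagate both sexually and by fragmentation, so
a field sample of colonies mixes distinct genetic individuals (genets) with
clonal copies of the same genet (ramets). Some species additionally split
into sympatric types — distinguishable, for example, by the length of a
mitochondrial non-coding region (here labelled mt-L and mt-S) — whose degree
of genetic isolation is an open question. Multilocus microsatellite
genotypes answer both questions at once, provided the analysis (i) collapses
clones before any population-level statistic, and (ii) treats single-locus
discrepancies between otherwise identical colonies as somatic mutations or
scoring errors rather than as distinct genotypes.

`msatclone` implements that entire analysis as a tested pipeline: genotype
containers and the three common file dialects, clone (multilocus-lineage)
assignment, locus QC, diversity statistics with Hardy–Weinberg and linkage
testing, $F_{ST}$ with permutation, admixture-model Bayesian clustering with
$\Delta K$ model choice and replicate merging, DAPC, and tandem-repeat
discovery for marker development. Because the motivating data sets of this
kind are typically unpublished, the package ships a synthetic-data generator
whose planted truth backs every test.

## Data model

A `genotype_matrix` stores, per colony and locus, an unordered pair of
allele sizes in base pairs (fragment sizes as scored, including any
universal fluorescent-tail extension — sizes are comparable only within a
locus). 0 codes a missing allele; a genotype is either fully typed or fully
missing, and half-calls are rejected at parse time because codominant
diploid scoring produces either two calls or none. Pairs are canonicalized
ascending since phase is meaningless for fragment data.

Three dialects are read and written explicitly (no sniffing): a GenAlEx-style
CSV (counts line, title line, two columns per locus), STRUCTURE's
one-row-per-individual format (integer allele codes with missing = −9; the
code→bp dictionary is persisted in a sidecar TSV so conversion is lossless),
and Genepop (3-digit allele codes, `Pop` separators; population labels
round-trip through a `pops:` clause in the free-text title line, which plain
Genepop readers ignore).

## Clonal lineage assignment

Two colonies are clone-mates when their genotypes disagree at no more than
one locus among the loci typed in both (`max_mismatch = 1`); the lone
divergent locus is attributed to a somatic mutation or a scoring error.
Because the published rule is pairwise, chains (A~B, B~C, A≁C) need a
convention: `assign_mlls()` takes the transitive (single-linkage) closure,
so MLLs are equivalence classes — the standard genet-assignment behaviour.
The tests verify the closure against an independent boolean
matrix-powering oracle. A comparability floor (`min_compared = 5`, our
choice; the source analysis is silent) turns pairs that share too few typed
loci into errors instead of vacuous matches.

Clonality is summarized as $N_{MLL}/N$. QC flags derived from within-MLL
variation follow the two-stage practice: during marker characterization on
the reference type a variable locus is dropped outright; afterwards only the
deviant call is zeroed. The deviant sample is the carrier of the minority
genotype within its MLL; when the split is even (a two-ramet lineage) the
first-encountered member is taken as the lineage reference — an arbitrary
but deterministic tie-break, so tests compare flags at (lineage, locus)
resolution.

## Diversity statistics and tests

All statistics are computed after collapsing each MLL to its
first-encountered colony. Per locus: allele count $N_A$; expected
heterozygosity $H_E = 1 - \sum_i p_i^2$ (uncorrected, matching the
spreadsheet-toolchain convention the printed tables use — the printed
$F_{IS}$ values reproduce only under this convention); observed
heterozygosity $H_O$; and $F_{IS} = (H_E - H_O)/H_E$, reported as `NA` (not
0) for monomorphic loci.

Hardy–Weinberg deviation uses the chi-square goodness of fit of genotype
counts against $np_i^2$ and $2np_ip_j$ on $k(k-1)/2$ degrees of freedom.
An exact test would behave better at small counts, but chi-square matches
the named toolchain's behaviour; results carry a `low_count` flag when
expected counts are unreliable rather than being suppressed. Under null
simulation at $n = 100$ with two alleles the empirical size at
$\alpha = 0.05$ sits inside [0.03, 0.08] (computed in the acceptance suite).

Linkage disequilibrium is tested with a log-likelihood-ratio $G$ statistic
on the two-locus genotype table and a permutation null
($p = (1 + \#\{G^* \ge G\})/(n_{perm}+1)$), replacing the unreproducible
"default conditions" of a Markov-chain exact engine with a seedable test of
the same null hypothesis. One honest caveat, found during calibration and
worth knowing: with highly polymorphic loci and modest samples the
two-locus table is so sparse that almost every cell holds 0 or 1, and the
$G$ statistic then takes only a handful of distinct values across
permutations (singleton cells contribute permutation-invariant terms). The
permutation p-value remains valid but becomes conservative. Calibration is
therefore demonstrated in the well-filled regime (biallelic loci,
$n = 100$); multiple testing across locus pairs is controlled by
Benjamini–Hochberg at $q = 0.05$.

## $F_{ST}$ between types

The package's default estimator is the Weir–Cockerham analysis-of-variance
$\theta$, combined across loci and alleles as a ratio of summed components.
This was a genuinely open design point, resolved as follows. The
heterozygosity-based index $(H_T - H_S)/H_T$ on pooled frequencies — also
available via `estimator = "nei"`, and reported per locus in every result —
has expectation $F/(2-F)$ with two demes under an island-type divergence
model with parameter $F$ (e.g. 0.111 at $F = 0.2$), plus an upward
finite-sample distortion at clone-collapsed sample sizes of 10 + 7. It
therefore cannot recover the generating divergence parameter, which is the
package's own acceptance target for this module; $\theta$ corrects for both
finite samples and the finite number of groups and recovers $F$ within
±0.03 across $F \in \{0, 0.02, 0.08, 0.2\}$ (acceptance suite). Small
negative estimates are clamped to 0 with a warning. Significance comes from
permuting type labels across MLLs; with 999 permutations the attainable
floor is $p = 0.001$, matching the convention in which that value is
reported as a minimum.

## Admixture-model clustering

`run_admixture()` is a from-scratch Gibbs sampler for the admixture model
with independent allele frequencies between clusters: each individual $i$
has membership vector $q_i$ over $K$ clusters; each allele copy carries an
origin $z$; cluster allele frequencies $p_{k\ell}$ have a symmetric
Dirichlet($\lambda$) prior. Updates per sweep:

1. $z \mid p, q$: multinomial with $\Pr(z = k) \propto q_{ik}\,p_{k\ell a}$;
2. $p \mid z$: Dirichlet($\lambda$ + cluster allele counts);
3. $q \mid z, \alpha$: Dirichlet($\alpha$ + per-individual origin counts);
4. $\alpha$: random-walk Metropolis with a uniform prior on
   $(0, \alpha_{max})$, one $\alpha$ shared across clusters.

Missing allele copies are skipped in every update. Hyperparameters follow
the reference toolchain's defaults ($\lambda = 1$, $\alpha_0 = 1$,
$\alpha_{max} = 10$, proposal sd 0.025), since the motivating analysis
states only its model choices. The per-iteration data log-likelihood is
recorded post burn-in; the model-choice score is
$\ln P(D) = \bar L - \mathrm{Var}(L)/2$ with the population variance
(denominator $n$) — the harmonic-approximation estimator. Every stored
state is verified in the tests against a brute-force likelihood computation
on a tiny instance, and chains are bit-for-bit reproducible from a seed
(the C++ core draws from R's RNG). Posterior-mean $Q$ uses every 10th
post-burn-in sample (memory; negligible estimator effect). Non-convergence
of $\alpha$ (post-burn-in range exceeding $\alpha_{max}/2$) is flagged as a
warning, mirroring the practice of checking the mean and range of
$\alpha$ per $K$.

Production-scale runs of the motivating kind use burn-in 100,000 and
1,000,000 replications with 10 iterations per $K$ over $K = 1..6$; the
package defaults and the acceptance suite scale this to 5,000 + 20,000,
which the small MLL-level data sets (≈17 individuals, 11 loci) mix well
within — the stochastic recovery targets tolerate this scaling and the
replicate sd of $\ln P(D)$ stays small.

Model choice across $K$ uses Evanno's
$\Delta K = |L''(K)| / \mathrm{sd}(L(K))$ over replicate runs; $\Delta K$
is undefined at the boundary $K$ values and wherever the replicate sd is 0,
and those entries are excluded from the argmax. Replicate $Q$ matrices are
merged CLUMPP-style: greedy incremental alignment over runs, exhaustive
over column permutations (fine for $K \le 6$), then an elementwise mean
with rows renormalized.

## DAPC

Genotypes are encoded as allele dosage (0 / 0.5 / 1 per allele column;
missing imputed by column mean so untyped loci are neutral), columns are
centered, principal axes come from the covariance eigendecomposition, and
linear discriminants are computed on the retained PC scores (ridge
regularization with a warning if the within-group scatter is singular).
PC retention follows the stability rule of at most one-third of the number
of MLLs (17 MLLs → 5 PCs); no cross-validation is offered because the rule
is the point. With two groups exactly one discriminant axis exists.
`dapc_loo()` provides leave-one-out reassignment as a separability
calibration (≈ chance for undifferentiated groups).

## The synthetic stated world

`simulate_dataset()` emulates the structure the analysis assumes, at the
scale the motivating study reports: two types at Balding–Nichols divergence
$F$ (population frequencies Dirichlet-centred on ancestral frequencies with
concentration $(1-F)/F$; ancestral frequencies symmetric Dirichlet(1),
giving realistic $H_E \approx 0.6$–0.9 at 8 alleles), 10 + 7 genets sampled
as 53 + 44 colonies, 11 loci of 3/4-bp repeat units with sizes on a
per-locus ladder inside 150–450 bp. Defaults: $F = 0.08$ (the reported
between-type differentiation), somatic-mutation probability 0.02 per ramet
(a single locus shifts one allele by ±1 repeat unit — stepwise, the
conservative generator for near-miss clones), scoring-error probability
0.005 per call (replacement by a random in-locus allele), missing-call
probability 0.01 per genotype. Balding–Nichols was chosen because its $F$
parameter is the expected $F_{ST}$ under an ANOVA-type estimator, giving a
clean recovery target.

What the generator does **not** emulate — hence what a green test does not
establish: mutation-model realism beyond single-step shifts, size
homoplasy between types, null alleles, linkage (loci are independent,
consistent with the no-LD finding in data of this kind), spatial structure,
and genotyping noise correlated within plates or loci. Tests passing on
this world certify the algorithms, not any particular field data set.

`simulate_repeat_sequences()` plants perfect tandem repeats in random
flanks that are rejection-sampled to contain no competing run of ≥4 units
and whose boundary bases cannot extend the planted periodicity, so
discovery must recover exactly the planted coordinates, motif and phase.

## Tandem-repeat discovery conventions

Only perfect runs of 3- and 4-base motifs are detected (the unit lengths
used for marker design here; imperfect compound arrays surface as their
perfect sub-runs). A maximal periodic region whose length is not an exact
unit multiple admits several placements of the repeat window; hits are
left-anchored with the trailing partial unit trimmed, and same-unit hits
are made non-overlapping left to right, which keeps abutting compound
blocks (e.g. two tetramer motifs back to back) as two separate hits.
Motifs that are powers of a shorter motif (homopolymers, dinucleotide
squares) are excluded at these unit lengths. Candidate selection applies
the marker-design thresholds: 3-mers at ≥10 units, 4-mers at ≥8.

## Numerical choices and degenerate inputs

* Monomorphic loci: $F_{IS}$ is `NA`; $F_{ST}$ skips the locus and errors
  only when every locus is monomorphic; the HWE test refuses them.
* Permutation p-values use the add-one convention and respect the
  $1/(n_{perm}+1)$ floor.
* Comparisons of permuted statistics to the observed use a $10^{-12}$
  slack so exact ties (common for discrete tables) count as ≥.
* `ln_pd()` on a constant trace returns the mean (variance 0).
* All randomness flows through R's RNG, including inside the C++ sampler,
  so a single `set.seed()`/`seed =` reproduces any result; the pipeline
  expands one master seed into fixed per-stage seeds.

## Limitations

Probability-of-identity statistics, null-allele estimation, rarefied
allelic richness, AMOVA, the correlated-allele-frequency and linkage
clustering models, and $K$-means group inference for DAPC are out of scope.
The chi-square HWE test and the permutation LD test are documented
substitutes for exact-test engines; their calibration regimes are stated
above. The Evanno statistic cannot, by construction, evaluate $K = 1$.
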