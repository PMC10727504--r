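---
title: "Models and methods in mscflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mscflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscflow)
```

`mscflow` implements a full-likelihood pipeline for studying speciation
with gene flow under the multispecies coalescent (MSC): representing
species trees and introgression networks, simulating gene trees and
sequences, Bayesian blockwise inference, triplet isolation-with-migration
maximum likelihood, and downstream summaries.  This vignette describes the
models, the numerical choices, and the reasoning behind the design
decisions that were genuinely open.

## The models

**MSC.** Gene genealogies evolve backwards in time inside a species tree.
Within a population of mutation-scaled size θ = 4Nμ, each pair of lineages
coalesces at rate 2/θ (k lineages: total rate k(k−1)/θ); at a species
divergence the daughter populations merge into the ancestor.  All times are
expected substitutions per site (τ), so no generation or year units appear
anywhere inside the machinery; conversion to absolute ages happens only in
`calibrate_age()` via a mutation rate per site per generation and a
generations-per-year constant.

**MSC-I.** Pulse introgression is represented by *bidirectional pairs*: two
attachment (hybridization) nodes inserted on two branches at one shared
event time, with two directed arrows.  A lineage that reaches an attachment
node from below follows the donor branch with probability φ and its own
ancestor with probability 1 − φ.  The shared-time convention is forced by
the parameter-counting identities this class of models reports: an
8-species tree with six bidirectional pairs has 12 φ + 13 τ + 15 θ = 40
free parameters, and with one pair 25 — counts that only work out if each
pair contributes a single time and, under the *linked* θ convention, if the
populations on either side of an attachment node share the θ of their
branch (so θ parameters number tips + divergence nodes).
`count_free_parameters()` implements exactly these conventions, with an
`independent` variant that gives each post-event segment its own θ.

**MSC-M.** Continuous migration at rate M (expected migrants per
generation) is handled in two places: the simulator (a lineage in
population j jumps backwards into population i at rate 4·M[i→j]/θ_j, where
M[i→j] are *forward* migrants from i to j), and the triplet
isolation-with-migration likelihood below.  Full MSC-M MCMC with
migration-history augmentation for many populations is out of scope; the
triplet ML analysis plus simulation-based checks covers the use the
pipeline makes of continuous migration.

## Likelihood machinery

Per-locus sequence likelihoods use Felsenstein pruning under the
equal-rates (JC69) model, with P(same) = 1/4 + (3/4)e^(−4t/3).  IUPAC
ambiguity codes — including the unphased-diploid heterozygotes the locus
extractor produces — enter as partial likelihoods equal to 1 over their
compatible base set.  This treats the two alleles of a heterozygote as an
ambiguous single sequence rather than integrating over phase; it is a
deliberate simplification, adequate at the low heterozygosities (< 1%)
typical of the data the pipeline emulates.  Pruning runs in C++ over
compressed site patterns with per-pattern rescaling to avoid underflow.

The MSC/MSC-I gene-tree log-density is computed by a single sweep over the
merged timeline of species events and coalescences: each coalescence in
population θ contributes log(2/θ), each interval with k lineages
contributes −k(k−1)Δt/θ, and each hybrid-node crossing contributes log φ or
log(1−φ) according to the lineage's recorded path indicator.  Impossible
configurations (e.g. cross-species coalescence below the split) give −∞;
a *missing* indicator is an error, because the density is then ill-defined.
Tied event times are processed child-before-parent, which makes
zero-length internal branches (star trees) exact rather than degenerate.

## Priors

The root age gets a diffuse gamma prior (default G(7, 200), mean 0.035
substitutions/site) and every θ a gamma prior (default G(4, 200), mean
0.02); migration rates, where used, default to G(2, 10) (mean 0.2); φ is
uniform on (0, 1).  Given the root age, non-root divergence times are
*uniform-Dirichlet*: flat over the order-constrained region.  The
normalizing constant is computed exactly with the forest hook-length
formula — the flat density is ∏h(v)/τ₀^k over non-root divergence nodes v,
where h(v) counts divergence nodes in v's subtree — and the
integrates-to-one property is verified by quadrature in the tests.  Each
shared introgression time is uniform on its feasible window given the
divergence times.  The precise density of the "uniform-Dirichlet" prior is
defined here by this flat-over-polytope reading; it is exercised only
through the normalization test and prior-recovery MCMC.

## MCMC

`run_mcmc()` is a Metropolis–Hastings sampler over model parameters and
per-locus gene trees:

* multiplier moves for each θ and the root age, sliding-window moves for
  non-root divergence times and shared introgression times;
* per-locus gene-tree updates: an *independence resimulation* proposal
  (draw a fresh genealogy from the coalescent prior at the current
  parameters, accept on the likelihood ratio) plus a within-epoch node-age
  slide.  Resimulation replaces a constrained subtree-prune-regraft kernel:
  it has the same stationary distribution, moves topology and hybrid-path
  indicators jointly, and needs no reattachment bookkeeping.  Age slides
  are confined to the time slice between adjacent species events so the
  population paths and crossing sets they touch stay fixed;
* hybrid-path indicator flips (density-only Metropolis steps), and Gibbs
  updates of each φ from Beta(1 + donor crossings, 1 + ancestral
  crossings);
* a whole-model scaling ("mixing") move multiplying all times and θ by a
  common factor, with the exact identity that scaling changes each locus
  density by −(coalescences)·log c;
* when the species topology is free, a rooted nearest-neighbour-interchange
  (NNI) move with node ages carried over.  The proposal is symmetric;
  states whose age assignments or gene trees are incompatible are rejected
  by the prior/density.  An enumerated per-topology jump scheme was
  considered for ≤ 5 taxa but NNI is simpler and mixes well here because
  gene trees discordant with the current species tree can always coalesce
  above the species root, letting the chain tunnel between topologies.

Moves whose acceptance depends on the gene-tree densities only through θ or
φ use per-population sufficient statistics (coalescence counts, waiting
sums, crossing counts) collected in one C++ pass per sweep, so their cost
is independent of the number of loci.  Proposal step sizes are tuned toward
30% acceptance during burn-in and frozen afterwards.  Shared introgression
time moves can change which lineages cross which hybrid nodes; newly
required indicators are drawn Bernoulli(φ) as part of the proposal and the
Hastings ratio corrects for drawn and dropped indicators exactly.

`infer_block_species_tree()` runs several independent chains from random
starting topologies, discards runs whose topology posterior is further than
a total-variation distance of 0.1 (inclusive) from the coordinate-wise
median posterior — the threshold is this package's choice; at least the
closest run is always kept — and combines the remainder with equal weight
into the block posterior and MAP tree.

`marginal_loglik_ti()` estimates log marginal likelihoods by thermodynamic
integration: power-posterior chains at Gauss–Legendre points β ∈ (0, 1)
(32 by default), integrating the posterior mean log-likelihood over β.
Log Bayes factors are differences of log marginal likelihoods;
`smooth_bayes_factors()` applies the standard local-quadratic smoothing
(tricube weights over the nearest 40% of points) used to stabilize noisy
blockwise estimates.

## Triplet isolation with migration

For a species triplet ((S1, S2), S3) with gene flow between S1 and S2, the
per-locus data are the five JC69 site-pattern classes of three sampled
sequences (all equal; ingroup pair equal; each mixed pair; all distinct —
the full 64 patterns collapse to these five by the base symmetry of the
equal-rates model).  At each locus one configuration (123, 113, 223) is
drawn with probabilities 0.5/0.25/0.25 (renormalized over feasible ones)
and sequences are picked at random; sequences here are haploid/phased,
matching how such data are prepared upstream.

The likelihood integrates, per locus, the joint probability of the site
patterns over the shared genealogy: which pair coalesces first and the two
coalescent ages.  Before the S1–S2 divergence at τ₁ the two ingroup
lineages follow a four-state continuous-time Markov chain over the
populations they occupy (backward migration rates 4M/θ, coalescence rates
2/θ), evaluated through its eigendecomposition (with a matrix-exponential
fallback when the eigenvector basis is ill-conditioned); between τ₁ and the
root τ₀ they coalesce at rate 2/θ₅; above τ₀ all remaining lineages
coalesce at pairwise rate 2/θ₄.  Ages are integrated with Gauss–Legendre
nodes on bounded intervals and Gauss–Laguerre nodes against the exponential
tails (32 and 16 points for reporting; 16 and 8 during optimization, where
both models of a comparison always share a grid).  Model M0 has six free
parameters (τ₁, τ₀, θ₁, θ₂, θ₄, θ₅ — no θ₃, since at most one outgroup
sequence is sampled per locus); M2 adds M₁₂ and M₂₁.

Fitting uses box-constrained quasi-Newton optimization from dispersed
random starts (optionally warm-started, e.g. M2 from the M0 optimum).
Restarts whose optimum sits within 10⁻⁴ relative distance of a box bound
are flagged "extreme" and excluded from the argmax, with one deliberate
exception: M = 0 is the null hypothesis itself, not an optimization
failure, so only the *upper* bound counts for migration rates — otherwise
every correct null fit would be discarded and M2 could appear worse than
its own submodel.  M0 and M2 are compared by a likelihood-ratio test
against χ²(2 df) at the 1% level (conservative under the boundary null), and
`internal_branch_diag()` flags fits whose internal branch Δτ = τ₀ − τ₁
falls below 1% of τ₀ — the star-tree signature of a misspecified branching
order.

## Locus extraction

Coordinates are 0-based half-open internally (BED native; VCF and GFF-style
1-based inputs are converted on read).  Coding loci coincide with CDS and
must be ≥ 100 bp after repeat exclusion; noncoding loci are carved from the
CDS/repeat complement into 100–1000 bp pieces; loci are kept ≥ 2 kb apart
by a deterministic greedy left-to-right scan, applied per class because
coding and noncoding datasets are analysed separately (configurable regions
— e.g. inversion interiors where recombination is suppressed — can relax
the spacing).  Genotypes pass iff QUAL ≥ 20, GQ ≥ 20 and
max(meanDP/2, d) ≤ DP ≤ 2·meanDP with d halved for females on the Z
chromosome; meanDP is the per-sample mean depth over the chromosome,
computed once.  Sites within 5 bp of an indel are masked.  Heterozygous
diploid genotypes become IUPAC codes in a single unphased sequence.  A
locus is rejected when more than 50% of its cells are missing — evaluated
*before* column removal, the stricter of the two possible readings; the
monotonicity property tests make this choice easy to revisit — or when 10
or fewer complete columns remain.  The joint mode takes constant sites from
the reference, masks low-depth sites as `-` and non-SNP or low-quality
variants (QD < 2 or MQ < 40) as `N`, drops sequences over 50% missing and
all-missing columns, and rejects loci with fewer than two sequences.

## The synthetic-data generator

`sim_block_dataset()` emulates the structure of blockwise multilocus
data: blocks of 200 well-spaced, freely recombining loci by default, each a
short alignment (lengths drawn uniformly on 100–1000 bp), one to a few
sequences per species, optionally collapsed to unphased diploids.  Default
parameter magnitudes mirror butterfly-scale estimates (τ of order
0.002–0.035, θ of order 0.002–0.02).  Per-locus RNG streams derive from
(master seed, locus index), so datasets are bit-reproducible.  What the
generator does *not* emulate: within-locus recombination, selection, rate
variation across sites or branches, alignment error, or missing data beyond
what the extractor's filters introduce.  Tests passing on these data
therefore validate the estimators under their own assumptions; robustness
to violations (e.g. intralocus recombination) is a property claimed by the
wider literature, not re-established here.

## Numerical choices and desk-scale sizes

Likelihoods and densities are computed in log space throughout; pruning
rescales per pattern; the triplet likelihood does a per-locus
log-sum-exp over genealogy quadrature atoms; per-locus class-count vectors
are deduplicated before optimization.  Chain lengths in the test suite are
desk-scale choices (hundreds to a few thousand sweeps per block of 40–50
loci, 2–3 independent runs; 20 replicate blocks for recovery studies;
200 null datasets for LRT calibration; n = 20,000 for simulator-vs-analytics
comparisons), chosen so the whole battery runs on one CPU in minutes while
keeping Monte-Carlo error bands (3 standard errors, or "≥ 18 of 20"
small-sample tolerances) meaningful.  Real genomic analyses
of this kind run chains orders of magnitude longer; nothing in the
implementation caps problem size.

## Known limitations

* JC69 only; no GTR/HKY or among-site rate variation (by design — the
  models the pipeline targets assume none).
* Heterozygote ambiguity codes approximate full diploid phase integration.
* MSC-M posterior sampling for > 3 populations is not implemented; the
  triplet ML path covers migration-rate estimation.
* The species-topology sampler is exercised on small taxon sets (≤ 6);
  larger searches work but mix slowly and are not part of the test battery.
* Multiple posterior peaks are visible through per-run summaries
  (`block_posterior$runs`), but no automatic peak splitter is provided.
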