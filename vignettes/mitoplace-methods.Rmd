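---
title: "Methods: placing ancient environmental DNA on mitochondrial pangenome graphs"
author: "mitoplace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: placing ancient environmental DNA on mitochondrial pangenome graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ancient environmental DNA (aeDNA) from sediments and permafrost is a
mixture of short, chemically damaged fragments from many organisms.
After a coarse taxonomic pre-filter (e.g. all reads assigned to one
family), two questions remain that standard classifiers answer poorly:
*which* species — possibly several closely related ones, possibly an
ancestral lineage with no modern representative — contributed the
fragments, and *in what proportions*. mitoplace answers both by placing
the fragments on the branches of a fixed mitochondrial phylogeny and
estimating a mixture over placements by Markov chain Monte Carlo, with a
likelihood that accounts simultaneously for evolutionary divergence,
post-mortem deamination and sequencing error.

The input contract matches field practice: a multiple sequence alignment
of mitogenomes for the taxon of interest (aligned FASTA), a rooted tree
with branch lengths in expected substitutions per site (Newick), and a
FASTQ of fragments that have been adapter-trimmed, merged and
deduplicated, pre-filtered to the taxon. The package has no model of
spurious off-taxon reads; the pre-filter is the user's responsibility.

## Reference database

**Ancestral paths.** Every tree node — leaf and internal — owns one
reference path in the pangenome graph, so ancestral lineages are
first-class placement targets. Internal-node sequences are
reconstructed per alignment column as the marginal maximum-likelihood
base under the same HKY85 model used downstream (Felsenstein pruning
with the root at stationarity), with exact ties broken toward the
alphabetically first base so the reconstruction is deterministic.
Gap/non-gap states are reconstructed separately by Fitch parsimony on
the gap indicator, ties resolved toward non-gap. This is a deliberately
simple, testable reconstruction; it is validated against a brute-force
sum over internal-state assignments on small trees, but it is not
claimed to match any particular external reconstruction pipeline
node-for-node.

**Graph construction.** The builder partitions alignment columns into
maximal runs inducing the same partition of records (records grouped by
residue, gapped records separate) and collapses each run into one node
per distinct non-gap allele. Edges follow record adjacency; each record
becomes a path. The only property the likelihood needs is the
path-spelling identity — concatenating node sequences along a path
reproduces the degapped record exactly — and that property is tested on
randomized gappy alignments. Coordinates are 0-based with half-open
intervals throughout. Mitogenome circularity is ignored (sequences are
linear); users may rotate references so fragment ends avoid the
junction. Ambiguous bases (`N`) are accepted in the MSA container but
not in graph records.

**Signature nodes.** A node traversed by exactly one path is a
signature node for that path; fragments touching a signature set are
direct evidence for the corresponding reference. A set whose touching
fragments exceed 1% of all aligned fragments counts toward the initial
source estimate `k0` (floored at 1). The 1% rule suppresses spurious
sets arising from sequencing noise on sparse data.

## Alignment

Fragments are aligned to every reference path, in both orientations,
with affine-gap local alignment (defaults: match +1, mismatch −1, a gap
of length L costs 2 + L). True graph alignment is unnecessary here:
mitogenome graphs are small, and best-per-path alignment is exact for
any alignment realizable within a path, which is how placement
likelihood consumes it. The best hit is projected onto graph nodes and
offsets; ties between paths are broken by tree pre-order and
orientation ties prefer forward, so output is deterministic. Per-base
events are classified as match, mismatch, insertion, deletion, softclip
or unresolved (`N`). Reads scoring below `0.8 × read length` are
unmapped; the threshold is configurable and recorded. Multi-mapping is
resolved by keeping the single best alignment only. Damage is *not*
given alignment-stage bonuses (no C/T half-matches): deamination enters
only through the likelihood, which keeps the aligner generic and the
damage model in one place. The scoring implementation is checked
against an independent Smith-Waterman implementation
(`Biostrings::pairwiseAlignment`) on hundreds of randomized instances.

## The likelihood

A placement lives on a branch between ancestral node $N_A$ and derived
node $N_D$ with relative position $\beta \in [0,1]$; the distances are
$t_A = \beta t$ and $t_D = (1-\beta)t$. For a fragment $r$ with aligned
bases $b_i$,

$$P(r \mid \beta) = (1-\beta)\prod_i P(b_i \mid N_A, t_A) +
  \beta\prod_i P(b_i \mid N_D, t_D),$$

and for $k$ sources with proportions $\theta$ on the simplex, each
fragment is marginalized over its unknown origin,
$P(D \mid \theta, \beta) = \prod_r \sum_j \theta_j P(r \mid \beta_j)$.
$\theta$ enters as a genuine mixture weight; a formulation that drops
$\theta$ from the per-read sum under the flat prior would make the
proportions unidentifiable.

Per aligned base on a node traversed by the evaluated path, the full
observation chain is marginalized over all 16 intermediate states —
never shortcut formulas, so a substitution later reverted by
deamination is counted correctly:

$$P(b \mid b_g, t) = \sum_{b_s}\sum_{b_d}
  P_{\mathrm{HKY}}(b_s \mid b_g, t)\;
  P_{\mathrm{dam}}(b_d \mid b_s; p_5, p_3)\;
  P_{\mathrm{err}}(b \mid b_d, \epsilon),$$

with $P_{\mathrm{err}} = 1-\epsilon$ on the diagonal and $\epsilon/3$
off it, $\epsilon = 10^{-Q/10}$ from the base quality. The damage
matrix applies C→T at rate $\delta_5(p_5)$ (distance from the 5′ end)
and G→A at rate $\delta_3(p_3)$ (distance from the 3′ end),
simultaneously for every base using its two distances; A and T never
deaminate. Bases on nodes the path does not traverse use a fixed
mixture — 6/7 scored as sequencing error at $\epsilon/3$ and 1/7 as
match at $1-\epsilon$ — reflecting that an unsupported node is usually
genuine divergence but occasionally error. Insertions and deletions
carry probability 0.02 per inserted/deleted base; unresolved bases and
softclips are errors at $\epsilon/3$.

Corner cases made explicit: deletions carry no read base (hence no
quality), so they score 0.02 on every path regardless of node support;
insertions, softclips and unresolved bases carry no graph node and are
likewise path-independent. Only match/mismatch bases switch between the
supported (HKY·damage·error) and unsupported channels. For
reverse-complement alignments the chain is evaluated in the fragment's
frame (graph base complemented), which keeps C→T damage anchored to the
fragment's own 5′ end; base frequencies are not strand-symmetrized.
Per-base probabilities are floored at $10^{-12}$ before the logarithm
(quality-zero bases exist in simulated data), products are computed
with multiplicative rescaling, and the two-term combination uses
log-sum-exp.

**HKY85.** Closed-form transition probabilities (the equal-transition
special case of TN93), rate-normalized so branch lengths are expected
substitutions per site, verified against numerical matrix exponentials
to $10^{-10}$. Stationary frequencies are estimated from the reference
base counts; $\kappa$ defaults to 2 — the transition bias typical of
vertebrate mitochondria — and is configurable. The exact
branch-scaling recipe of published databases is not reproducible from
first principles; the normalized-HKY convention here is the documented
substitute.

## Inference

The sampler is plain Metropolis-Hastings with flat priors, so the
posterior is proportional to the likelihood. Moves, chosen per
iteration: with probability 0.2 a *branch hop* (one source moves to a
uniformly chosen adjacent branch — parent, sibling or child — with
fresh $\beta \sim U(0,1)$; Hastings ratio $|nbr(\mathrm{cur})| /
|nbr(\mathrm{new})|$); otherwise, half the time a reflected Gaussian
step on one $\beta$ (sd 0.1; symmetric), half the time a
logistic-normal step on $\theta$ (sd 0.3 in additive-log-ratio space,
with the exact Jacobian correction). These kernel constants are package
choices; the correctness criterion is that chain visit frequencies on a
discretized toy posterior match numerically exact integration within
2%, which is tested. Only the HKY matrices depend on a proposed
placement; damage/error factors are precomputed per base, and bases
with identical (graph base, damage/error vector) class are collapsed to
count-weighted classes per fragment and path, which is what makes
$10^5$ iterations on thousands of fragments take seconds.

`k0` comes from signature sets; the sampler runs for every
$k = 1..k_0$ (extendable with `force_k`, mirroring forcing a higher
count on sparse data) and the k-curve of best log-likelihoods is always
reported. Selection makes the visual "no significant increase"
criterion explicit: the smallest $k$ whose gain to $k+1$ falls below
$\tau = 2\ln(n)/2$ (two parameters — a branch position and a
proportion — per added source; BIC-flavoured) is chosen, and users can
override. Initialization is signature-based by default (sources start
on the parent branches of the most-hit signature sets, $\beta = 0.5$,
uniform $\theta$); random initialization is available but converges
poorly for many sources, which is why signature initialization is the
default. A non-finite initial likelihood triggers bounded random
re-initialization.

Diagnostics: 5/50/95% quantiles for every $\theta_i$ and $\beta_i$,
per-branch visit frequencies, the MAP state, and per-parameter
effective sample sizes computed as $N / (1 + 2\sum\hat\rho_k)$ with
Geyer's initial-positive-sequence truncation (a constant series is
reported as ESS = N with a note). Any ESS below 200 raises a warning:
tail quantiles are then poorly estimated and more iterations are
advised. Label switching is resolved at summary time by ordering
sources by posterior mean proportion. One chain is run per $k$ by
default (the `chains` argument supports more); on a single CPU the
iteration budget is better spent on one long chain, and the toy-posterior
test pins kernel correctness independently.

## Synthetic data

The generator emulates the published simulation design without
downloading genomes. Reference sets: a random coalescent-shaped tree
whose branch lengths are rescaled so the *expected* mean pairwise
identity under HKY hits the target (e.g. 0.93, typical of congeneric
mitogenomes); sequences are then simulated down the tree without
indels, keeping the true ancestral sequences as ground truth. The
realized identity must land within ±1% or the set is rejected.
Fragments: source drawn from the specified mixture, log-normal lengths
($\mu = 3.7344$, $\sigma = 0.35$, mean ≈ 44.5 bp, truncated to
[20 bp, reference length]), uniform start and strand, terminal
deamination applied on the fragment's own strand (C→T by 5′ distance,
G→A by 3′ distance), then sequencing errors at the quality-implied
rate (constant Phred 30 by default). The default damage profile decays
geometrically from 0.25 at the terminal base, halving per position over
10 positions with a 0.01 residual — magnitudes routinely estimated from
well-preserved ancient samples.

What the simulations do *not* emulate: indel evolution between
references (real mitogenome alignments contain gaps; the graph builder
and likelihood handle them, but recovery claims are made on gapless
reference sets), microbial or off-taxon background reads, library
artifacts beyond deamination, and quality-score variation along reads.
Passing tests therefore demonstrate correct inference under the model's
own assumptions at realistic divergences, damage and coverages — not
robustness to violations of the pre-filtering contract.

## The simulation studies

The packaged experiments (`experiment_single_source`,
`experiment_two_source`, `experiment_three_source`,
`recovery_harness`) reproduce the simulation designs at desk scale on
one CPU; `scripts/acceptance.R` runs all three. Study conditions are
fixed in the function defaults: 16.5 kb references (so fragment counts
map onto the familiar coverage scale at ~44 bp mean length), $10^5$
iterations, 10% burn-in.

* **Single source, downsampling.** A 7-taxon reference set at mean
  identity 0.93; the source is an internal node, chosen
  deterministically as the one with the *median* parent branch length —
  a typical mid-tree ancestral state. (Choosing the most isolated
  internal node instead makes the task artificially easy and defeats
  the purpose of a downsampling study.) 500 fragments are simulated
  and downsampled to {500, 250, 75, 50, 10}; recovery at a level means
  the MAP placement's nearest node (derived node for $\beta \ge 0.5$,
  ancestral otherwise) equals the true source in a majority of 10
  replicate data sets.
* **Two sources.** Two references at ~93.1% identity, 1,000 fragments,
  ratios 95:5, 85:15, 75:25, 55:45; $k = 2$; recovery of both branches
  and of the majority proportion.
* **Three sources.** A 6-taxon set; the two leaves of the
  longest-stalked cherry carry 47% and 33%, and a non-adjacent internal
  node (again the longest-stalked among the remaining candidates)
  carries 20%; 1,500 fragments, $k = 3$ with signature initialization.

## Numerical and design choices, in one place

* Scoring defaults (+1/−1, gap 2 + L, threshold 0.8·L) are explicit
  and logged; they are not tuned per dataset.
* Indel likelihood 0.02 is applied per inserted/deleted base (the
  per-event reading is indistinguishable for the single-base indels
  that dominate short-read alignments).
* Probability floor $10^{-12}$; product rescaling threshold
  $10^{-280}$; simplex tolerance $10^{-12}$.
* Damage profiles store one rate per position per channel with a flat
  residual beyond the table (the last row); 12-substitution tables are
  accepted and reduced to their C→T/G→A columns.
* Deterministic tie-breaks everywhere: alphabetical bases in
  reconstruction, tree pre-order for path ties, forward orientation,
  first-maximum in MAP extraction.
* One integer seed controls reference simulation, fragment simulation,
  initialization and the sampler; derived seeds are simple offsets, and
  every output records its seed.

## Known limitations

* Best-per-path alignment cannot represent alignments that would cross
  between paths mid-read (recombination-like artifacts); irrelevant for
  non-recombining mitochondria but a real restriction elsewhere.
* The unsupported-base constants (6/7, 1/7) and the indel probability
  are fixed model constants, not estimated from data.
* No contamination source class: a modern contaminant will be absorbed
  into the mixture rather than flagged.
* Ancestral reconstruction quality degrades for poorly resolved or
  highly divergent taxa, and placements onto reconstructed ancestral
  paths inherit that uncertainty.
* The k-selection threshold is a default, not a decision rule with
  guaranteed error control; the full k-curve is always reported so the
  user can apply judgement.
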