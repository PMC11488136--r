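# mitoplace

Phylogenetic placement and mixture deconvolution of ancient
environmental DNA (aeDNA) on mitochondrial pangenome graphs.

Sedimentary and other environmental ancient DNA is a mixture of short,
deaminated fragments, often from several closely related species of one
family — or from lineages ancestral to every modern reference. After a
coarse taxonomic pre-filter, mitoplace answers the two questions that
standard read classifiers cannot: **which sources** (including
ancestral states) contributed the fragments, and **in what
proportions**.

It does so by:

1. building a pangenome graph from a reference mitogenome alignment and
   a rooted tree, with one reference path per tree node — internal
   nodes get marginally reconstructed ancestral sequences, so ancestral
   lineages are first-class placement targets;
2. aligning each fragment to every reference path (affine-gap local
   alignment, both strands) and projecting it onto graph nodes;
3. estimating, by Metropolis-Hastings sampling, the number of sources
   k, each source's continuous position β on a tree branch, and the
   mixture proportions θ, under the damage-aware likelihood

   P(r | β) = (1−β) ∏ᵢ P(bᵢ | N_A, βt) + β ∏ᵢ P(bᵢ | N_D, (1−β)t),

   where each per-base term marginalizes the full chain
   HKY85 substitution → terminal C→T / G→A deamination → sequencing
   error over all 16 intermediate states, and fragments are
   marginalized over their unknown source:
   P(D | θ, β) = ∏_r Σⱼ θⱼ P(r | βⱼ).

The number of sources is initialized from **signature nodes** (graph
nodes private to one reference path; sets with >1% of aligned fragments
count), the sampler runs for every k up to that estimate, and a k-curve
of best log-likelihoods with an explicit selection threshold, credible
intervals, per-branch visit frequencies and effective-sample-size
diagnostics (warning below ESS 200) are reported.

A simulator for ancient-DNA experiments with known ground truth is
included: coalescent reference sets calibrated to a target pairwise
identity, log-normal fragment lengths (μ = 3.7344, σ = 0.35), terminal
deamination and quality-derived errors.

## Worked example

Simulate a 60:40 mixture of two species at ~93% mitogenome identity,
with realistic deamination, and deconvolve it:

```r
library(mitoplace)

refs  <- make_reference_set(n_taxa = 4, target_identity = 0.93,
                            seed = 3, length = 2000)
model <- hky_model(kappa = 2, pi = msa_base_freq(refs$msa))
ext   <- reconstruct_ancestral_paths(refs$msa, refs$tree, model)
graph <- build_graph_from_msa(ext, refs$tree)

prof <- default_damage_profile()
sim  <- simulate_fragments(refs, c(T1 = 0.6, T4 = 0.4), n = 400,
                           profile = prof, seed = 5)

aln <- align_fragments(sim$reads, graph)
fit <- mitoplace(aln, graph, refs$tree, model = model, profile = prof,
                 config = mcmc_config(iterations = 20000, seed = 9))
fit
```

```
mitoplace fit: 400 aligned fragments, k0 = 2, selected k = 2
mitoplace diagnostics: k = 2 (18000 post-burn-in samples)
  source 1: theta 0.613 [0.570, 0.655], MAP branch -> T1 (beta 1.00)
  source 2: theta 0.387 [0.345, 0.430], MAP branch -> T4 (beta 1.00)
  WARNING: ESS < 200 for some parameter
```

Reading the output: the signature-node scan proposed two sources
(`k0 = 2`) and the k-curve confirmed them (the k = 1 fit is ~616
log-likelihood units worse). The mixing proportions are recovered as
0.613/0.387 (truth 0.6/0.4) with 90% credible intervals, and both MAP
placements sit at β = 1 on the correct terminal branches — i.e. the
sources *are* the leaves T1 and T4, not positions part-way toward
their ancestors. The ESS warning flags the short 20,000-iteration
demonstration chain; production runs default to 10⁵ iterations.

```r
print(as.data.frame(fit$kcurve), row.names = FALSE)
#>  k best_logl selected
#>  1  -2164.13    FALSE
#>  2  -1548.10     TRUE
coef(fit)
#>   theta.1   theta.2
#> 0.6132755 0.3867245
```

A placement of β = 0.x on the branch into an internal node would
instead indicate an ancestral (or ancestral-like) source; the bundled
experiments show this for fragments simulated from reconstructed
ancestral sequences.

`run_end_to_end()` wraps build → align → infer → summarize on file
inputs and writes a results directory (GFA graph, signature table,
alignment TSV, per-k traces, k-curve, diagnostics, summary JSON and a
reproducibility manifest). A thin command-line front end with
`build`, `align`, `simulate`, `infer` and `run` subcommands is
installed at `inst/cli/mitoplace`.

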