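## Heavy simulation experiments shared between the property suite and
## the acceptance tests; each is computed once per test run.

single_source_experiment <- function() {
  if (is.null(.fix$single)) {
    .fix$single <- experiment_single_source(seed = 42)
  }
  .fix$single
}

two_source_mixtures <- function() {
  if (is.null(.fix$two)) {
    .fix$two <- experiment_two_source(seed = 42)
  }
  .fix$two
}

three_source_experiment <- function() {
  if (is.null(.fix$three)) {
    .fix$three <- experiment_three_source(seed = 42)
  }
  .fix$three
}

## Ten seeded replicates of the balanced two-source recovery, sharing
## one reference pair (the replicate randomness is in the fragments and
## the chains).
two_source_replicates <- function(n_rep = 10) {
  if (is.null(.fix$two_reps)) {
    refs <- make_reference_set(2, 0.93, seed = 1234, length = 16500)
    db <- mitoplace:::build_reference_db(refs)
    leaves <- mitoplace:::tree_leaf_labels(db$tree)
    prof <- default_damage_profile()
    .fix$two_reps <- lapply(seq_len(n_rep), function(r) {
      sim <- simulate_fragments(refs, stats::setNames(c(0.55, 0.45), leaves),
                                1000, profile = prof, seed = 1000 + r)
      aln <- align_fragments(sim$reads, db$graph)
      tr <- run_mcmc(aln, db$graph, db$tree, db$model, prof, k = 2,
                     config = mcmc_config(iterations = 5e4, seed = 2000 + r,
                                          init = "signature"))
      d <- suppressWarnings(summarize_posterior(tr))
      hits <- mitoplace:::placement_nearest_node(db$tree$branches,
                                                d$map$branch, d$map$beta)
      list(theta_major = d$summary$theta_mean[1],
           branches_ok = setequal(hits, leaves))
    })
  }
  .fix$two_reps
}

## Toy discretized posterior: exhaustive (numerically exact) integration
## versus chain visit frequencies; cached for reuse.
toy_mcmc_discrepancy <- function() {
  if (is.null(.fix$toy_mcmc)) {
    g <- toy_graph()
    tr <- toy_tree()
    m <- hky_model(2, rep(0.25, 4))
    prof <- uniform_profile(0.05)
    set.seed(123)
    reads <- vapply(1:5, function(i) {
      ref <- path_sequence(g, sample(c("A", "N1"), 1))
      substr(ref, 1, 4)
    }, character(1))
    aln <- align_fragments(
      read_set(sprintf("f%d", 1:5), reads,
               vapply(nchar(reads), function(l) strrep("I", l),
                      character(1))),
      g, min_score_frac = 0.5)
    prep <- mitoplace:::prepare_likelihood_data(aln, g, tr, m, prof)
    nbins <- 10
    grid_mass <- function(branch) {
      edges <- seq(0, 1, length.out = nbins + 1)
      vapply(seq_len(nbins), function(bin) {
        xs <- seq(edges[bin], edges[bin + 1], length.out = 41)
        ys <- vapply(xs, function(b) {
          exp(sum(mitoplace:::.frag_logliks_cpp(prep$lik, prep$treec,
                                                prep$pi, prep$kappa,
                                                branch - 1L, b)))
        }, numeric(1))
        h <- xs[2] - xs[1]
        h / 3 * (ys[1] + ys[41] + 4 * sum(ys[seq(2, 40, 2)]) +
                   2 * sum(ys[seq(3, 39, 2)]))
      }, numeric(1))
    }
    mass <- cbind(grid_mass(1), grid_mass(2))
    post <- mass / sum(mass)
    cfg <- mcmc_config(iterations = 1e5, seed = 7, burnin = 0.1)
    trc <- run_mcmc(aln, g, tr, m, prof, k = 1, config = cfg)
    keep <- trc[-(1:1e4), ]
    emp <- matrix(0, nbins, 2)
    bins <- pmin(floor(keep$beta.1 * nbins) + 1, nbins)
    for (br in 1:2) {
      emp[, br] <- tabulate(bins[keep$branch.1 == br], nbins) / nrow(keep)
    }
    .fix$toy_mcmc <- max(abs(emp - post))
  }
  .fix$toy_mcmc
}
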