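## Simulation experiments with known truth: one-command reproductions of
## the single-, two- and three-source recovery studies at desk scale.

## Internal source node for single-source experiments: the non-root
## internal node with the median parent-branch length -- a typical
## mid-tree ancestral state rather than the most (or least)
## identifiable one. Chosen deterministically.
pick_internal_source <- function(tree) {
  ints <- setdiff(tree_internal_labels(tree), tree_root_label(tree))
  if (length(ints) == 0L) stop("tree has no non-root internal node")
  plen <- tree$branches$length[vapply(ints, parent_branch, integer(1),
                                      tree = tree)]
  ints[order(plen)[ceiling(length(plen) / 2)]]
}

## A cherry (internal node whose children are both leaves) with the
## longest parent branch; returns list(parent, leaves).
pick_cherry <- function(tree) {
  br <- tree$branches
  leaves <- tree_leaf_labels(tree)
  ints <- tree_internal_labels(tree)
  cherries <- Filter(function(lab) {
    ch <- br$dec[br$anc == lab]
    length(ch) == 2L && all(ch %in% leaves)
  }, setdiff(ints, tree_root_label(tree)))
  if (length(cherries) == 0L) stop("tree has no cherry")
  plen <- br$length[vapply(cherries, parent_branch, integer(1), tree = tree)]
  best <- cherries[which.max(plen)]
  list(parent = best, leaves = br$dec[br$anc == best])
}

## Build database (ancestral reconstruction + graph) for a simulated
## reference set, using base frequencies estimated from the leaf MSA.
build_reference_db <- function(refs, kappa = 2) {
  model <- hky_model(kappa, msa_base_freq(refs$msa))
  ext <- reconstruct_ancestral_paths(refs$msa, refs$tree, model)
  graph <- build_graph_from_msa(ext, refs$tree)
  list(model = model, msa = ext, graph = graph, tree = refs$tree)
}

#' Single-source downsampling experiment
#'
#' Simulates fragments from one ancestral (internal-node) source of a
#' synthetic reference set and asks down to how few fragments the MAP
#' branch placement still recovers the true node. Fragments are drawn
#' once per replicate at the largest level and downsampled, mirroring
#' a coverage titration of one library.
#'
#' @param seed Integer seed; replicate seeds are derived from it.
#' @param levels Fragment counts, largest first
#'   (default \code{c(500, 250, 75, 50, 10)}).
#' @param replicates Number of replicate data sets (default 10).
#' @param n_taxa,identity,ref_length Reference-set conditions
#'   (default: 7 taxa at mean pairwise identity 0.93 over 16.5 kb).
#' @param iterations MCMC iterations per level (default 1e5).
#' @param profile Damage profile applied in simulation and likelihood.
#' @return A list: \code{per_level} (data.frame of correct counts),
#'   \code{smallest_recovered} (smallest level in the maximal run of
#'   majority-correct levels, walking down from the largest),
#'   \code{coverage} (approximate per-level coverage), and
#'   \code{adjacency_at_min} (mean fraction of post-burn-in samples on
#'   branches adjacent to the truth at the smallest level).
#' @export
experiment_single_source <- function(seed, levels = c(500, 250, 75, 50, 10),
                                     replicates = 10, n_taxa = 7,
                                     identity = 0.93, ref_length = 16500,
                                     iterations = 1e5,
                                     profile = default_damage_profile()) {
  levels <- sort(levels, decreasing = TRUE)
  correct <- matrix(FALSE, replicates, length(levels),
                    dimnames = list(NULL, levels))
  adjacency <- numeric(replicates)
  mean_len <- numeric(replicates)
  for (r in seq_len(replicates)) {
    rs <- seed + 97L * r
    refs <- make_reference_set(n_taxa, identity, rs, length = ref_length)
    db <- build_reference_db(refs)
    src <- pick_internal_source(db$tree)
    sim <- simulate_fragments(refs, stats::setNames(1, src), max(levels),
                              profile = profile, seed = rs + 1L)
    aln_all <- align_fragments(sim$reads, db$graph)
    mean_len[r] <- mean(sim$truth$length)
    truth_adj <- adjacent_branch_set(db$tree, src)
    for (li in seq_along(levels)) {
      ids <- sim$truth$read[seq_len(levels[li])]
      aln <- aln_all[aln_all$read %in% ids, , drop = FALSE]
      attr(aln, "summary") <- attr(aln_all, "summary")
      class(aln) <- class(aln_all)
      cfg <- mcmc_config(iterations = iterations, seed = rs + 10L + li,
                         init = "signature")
      fit <- suppressWarnings(
        mitoplace(aln, db$graph, db$tree, model = db$model,
                  profile = profile, config = cfg)
      )
      d <- fit$diagnostics[[fit$k_selected]]
      hit <- placement_nearest_node(db$tree$branches, d$map$branch[1],
                                    d$map$beta[1])
      correct[r, li] <- identical(hit, src)
      if (levels[li] == min(levels)) {
        tr <- fit$traces[[fit$k_selected]][[1]]
        n <- nrow(tr)
        post <- tr[(floor(attr(tr, "config")$burnin * n) + 1L):n, ]
        adjacency[r] <- mean(post$branch.1 %in% truth_adj)
      }
    }
  }
  majority <- colSums(correct) > replicates / 2
  run_ok <- cumprod(majority) == 1
  smallest <- if (any(run_ok)) min(levels[run_ok]) else NA_integer_
  list(
    per_level = data.frame(level = levels,
                           n_correct = colSums(correct),
                           majority = majority,
                           coverage = levels * mean(mean_len) / ref_length),
    smallest_recovered = smallest,
    adjacency_at_min = mean(adjacency),
    mean_fragment_length = mean(mean_len)
  )
}

#' Two-source mixture experiment
#'
#' Two synthetic references at a chosen pairwise identity, mixed at the
#' given ratios; the sampler is run with k = 2 and asked to recover
#' both branches and the mixing proportions.
#'
#' @param seed Integer seed.
#' @param ratios List of length-2 proportion vectors (majority first);
#'   defaults to the four study ratios 95:5, 85:15, 75:25, 55:45.
#' @param n Fragments per mixture (default 1000).
#' @param identity Pairwise reference identity (default 0.931).
#' @param ref_length Reference length (default 16500).
#' @param iterations MCMC iterations (default 1e5).
#' @param profile Damage profile.
#' @return A data.frame with one row per ratio: the true and estimated
#'   majority proportion (percent), and whether both true branches were
#'   recovered by the MAP placements.
#' @export
experiment_two_source <- function(seed,
                                  ratios = list(c(0.95, 0.05),
                                                c(0.85, 0.15),
                                                c(0.75, 0.25),
                                                c(0.55, 0.45)),
                                  n = 1000, identity = 0.931,
                                  ref_length = 16500, iterations = 1e5,
                                  profile = default_damage_profile()) {
  refs <- make_reference_set(2, identity, seed, length = ref_length)
  db <- build_reference_db(refs)
  truth_nodes <- tree_leaf_labels(db$tree)
  out <- do.call(rbind, lapply(seq_along(ratios), function(i) {
    ratio <- ratios[[i]]
    sim <- simulate_fragments(refs,
                              stats::setNames(ratio, truth_nodes),
                              n, profile = profile, seed = seed + 13L * i)
    aln <- align_fragments(sim$reads, db$graph)
    cfg <- mcmc_config(iterations = iterations, seed = seed + 29L * i,
                       init = "signature")
    fit <- suppressWarnings(
      mitoplace(aln, db$graph, db$tree, model = db$model, profile = profile,
                force_k = 2, config = cfg)
    )
    d <- fit$diagnostics[[2]]
    hits <- placement_nearest_node(db$tree$branches, d$map$branch,
                                   d$map$beta)
    data.frame(
      majority_true = 100 * max(ratio),
      majority_est = 100 * d$summary$theta_mean[1],
      both_recovered = setequal(hits, truth_nodes)
    )
  }))
  out
}

#' Three-source mixture experiment
#'
#' Two sister leaves (a cherry) plus one ancestral-node source mixed at
#' the given proportions; the sampler is run with k = 3 and asked to
#' recover all three branches and the proportions.
#'
#' @param seed Integer seed.
#' @param props Three-way proportions, decreasing (default
#'   \code{c(0.47, 0.33, 0.20)}: the two leaves carry the two larger
#'   shares, the ancestral node the smallest).
#' @param n Fragments (default 1500).
#' @param n_taxa,identity,ref_length Reference-set conditions.
#' @param iterations MCMC iterations (default 1e5).
#' @param profile Damage profile.
#' @return A list: \code{largest_est} (posterior mean percent of the
#'   largest component), \code{largest_true}, \code{all_recovered},
#'   \code{sources} (true source labels), \code{map_nodes}.
#' @export
experiment_three_source <- function(seed, props = c(0.47, 0.33, 0.20),
                                    n = 1500, n_taxa = 6, identity = 0.93,
                                    ref_length = 16500, iterations = 1e5,
                                    profile = default_damage_profile()) {
  refs <- make_reference_set(n_taxa, identity, seed, length = ref_length)
  db <- build_reference_db(refs)
  cherry <- pick_cherry(db$tree)
  anc_pool <- setdiff(tree_internal_labels(db$tree),
                      c(tree_root_label(db$tree), cherry$parent))
  anc <- if (length(anc_pool)) {
    plen <- db$tree$branches$length[vapply(anc_pool, parent_branch,
                                           integer(1), tree = db$tree)]
    anc_pool[which.max(plen)]
  } else cherry$parent
  sources <- stats::setNames(props, c(cherry$leaves, anc))
  sim <- simulate_fragments(refs, sources, n, profile = profile,
                            seed = seed + 3L)
  aln <- align_fragments(sim$reads, db$graph)
  cfg <- mcmc_config(iterations = iterations, seed = seed + 7L,
                     init = "signature")
  fit <- suppressWarnings(
    mitoplace(aln, db$graph, db$tree, model = db$model, profile = profile,
              force_k = 3, config = cfg)
  )
  d <- fit$diagnostics[[3]]
  hits <- placement_nearest_node(db$tree$branches, d$map$branch, d$map$beta)
  list(largest_est = 100 * d$summary$theta_mean[1],
       largest_true = 100 * max(props),
       all_recovered = setequal(hits, names(sources)),
       sources = names(sources),
       map_nodes = hits,
       fit = fit)
}

#' Truth-vs-estimate recovery harness
#'
#' One-command reproduction of the simulation studies: runs the
#' requested experiment with its default study conditions and returns
#' a truth-vs-estimate report. Seed-reproducible.
#'
#' @param type \code{"single"} (downsampling grid),
#'   \code{"two"} (two-source mixtures) or \code{"three"}
#'   (three-source mixture).
#' @param seed Integer seed.
#' @param ... Passed to the underlying experiment function.
#' @return The experiment report (see the respective experiment
#'   function).
#' @export
recovery_harness <- function(type = c("single", "two", "three"), seed, ...) {
  type <- match.arg(type)
  switch(type,
         single = experiment_single_source(seed, ...),
         two = experiment_two_source(seed, ...),
         three = experiment_three_source(seed, ...))
}
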