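#' MCMC configuration
#'
#' @param iterations Number of Metropolis-Hastings iterations.
#' @param burnin Burn-in fraction in \code{[0, 1)} (default 0.1).
#' @param seed Integer seed controlling all randomness of a run.
#' @param sigma_beta Standard deviation of the reflected Gaussian
#'   random walk on branch positions (default 0.1).
#' @param sigma_theta Standard deviation of the logistic-normal random
#'   walk on mixture proportions (default 0.3).
#' @param p_hop Probability of proposing a branch hop to an adjacent
#'   branch instead of a within-branch move (default 0.2).
#' @param init Initialization mode: \code{"signature"} (start sources
#'   on the branches suggested by the most-hit signature node sets) or
#'   \code{"random"}.
#' @param chains Number of independent chains run by
#'   \code{\link{mitoplace}} (default 1).
#' @return A list of class \code{mcmc_config}.
#' @export
mcmc_config <- function(iterations = 1e5, burnin = 0.1, seed = NULL,
                        sigma_beta = 0.1, sigma_theta = 0.3, p_hop = 0.2,
                        init = c("signature", "random"), chains = 1L) {
  init <- match.arg(init)
  stopifnot(iterations >= 1, burnin >= 0, burnin < 1,
            sigma_beta > 0, sigma_theta > 0, p_hop >= 0, p_hop <= 1,
            chains >= 1)
  if (iterations * (1 - burnin) < 1) stop("iterations must exceed burn-in")
  structure(list(iterations = as.integer(iterations), burnin = burnin,
                 seed = seed, sigma_beta = sigma_beta,
                 sigma_theta = sigma_theta, p_hop = p_hop, init = init,
                 chains = as.integer(chains)),
            class = "mcmc_config")
}

## ---- likelihood precompute for the C++ sampler -------------------------

## Flattens a fragment_alignments table into the per-base arrays the
## sampler consumes: damage/error factors W, unsupported probabilities,
## constant event probabilities and per-path support flags.
prepare_likelihood_data <- function(aln, graph, tree, model, profile,
                                    indel_prob = 0.02) {
  ids <- unique(aln$read)
  if (length(ids) == 0L) stop("no aligned fragments")
  ord <- order(match(aln$read, ids))
  aln <- aln[ord, , drop = FALSE]
  nb <- nrow(aln)
  frag_ptr <- c(0L, cumsum(as.integer(table(factor(aln$read, levels = ids)))))

  is_hky <- aln$event %in% c("match", "mismatch")
  kind <- ifelse(is_hky, 0L, 1L)
  cprob <- numeric(nb)
  cprob[aln$event %in% c("insertion", "deletion")] <- indel_prob
  sc <- aln$event %in% c("softclip", "unresolved")
  cprob[sc] <- aln$eps[sc] / 3

  bgc <- rep(-1L, nb)
  bg_chr <- row_graph_bases(aln, graph)
  bgc[is_hky] <- encode_bases(bg_chr[is_hky])

  W <- matrix(0, 4, nb)
  u <- numeric(nb)
  if (any(is_hky)) {
    i <- which(is_hky)
    eps <- aln$eps[i]
    b <- encode_bases(aln$base[i])
    d5 <- delta5_at(profile, aln$pos5[i])
    d3 <- delta3_at(profile, aln$pos3[i])
    eb <- function(bd) ifelse(b == bd, 1 - eps, eps / 3)
    EA <- eb(0L); EC <- eb(1L); EG <- eb(2L); ET <- eb(3L)
    W[1, i] <- EA
    W[2, i] <- (1 - d5) * EC + d5 * ET
    W[3, i] <- (1 - d3) * EG + d3 * EA
    W[4, i] <- ET
    u[i] <- base_prob_unsupported(eps)
  }

  path_names <- names(graph$paths)
  npath <- length(path_names)
  maxnode <- nrow(graph$nodes)
  node_in_path <- matrix(0L, maxnode, npath)
  for (p in seq_len(npath)) node_in_path[graph$paths[[p]], p] <- 1L
  support <- matrix(0L, nb, npath)
  hasnode <- which(!is.na(aln$node) & is_hky)
  if (length(hasnode)) {
    support[hasnode, ] <- node_in_path[aln$node[hasnode], , drop = FALSE]
  }

  br <- tree$branches
  anc_idx <- match(br$anc, path_names) - 1L
  dec_idx <- match(br$dec, path_names) - 1L
  if (anyNA(anc_idx) || anyNA(dec_idx)) {
    stop("tree nodes without a reference path in the graph")
  }
  nbs <- branch_neighbors(tree)
  list(
    lik = list(frag_ptr = as.integer(frag_ptr), kind = kind,
               bg = bgc, W = W, u = u, cprob = cprob, support = support),
    treec = list(anc = anc_idx, dec = dec_idx, length = br$length,
                 neighbors = lapply(nbs, function(v) as.integer(v - 1L))),
    ids = ids, pi = as.numeric(model$pi), kappa = model$kappa
  )
}

## ---- initial number of sources -----------------------------------------

#' Initial estimate of the number of sources
#'
#' Counts, for every signature node set, the aligned fragments touching
#' at least one of its nodes. A set counts as evidence for a distinct
#' source when its fragments exceed 1\% of all aligned fragments; the
#' estimate is floored at 1.
#'
#' @param aln A \code{fragment_alignments} table.
#' @param sig A \code{\link{compute_signature_sets}} result.
#' @return Integer \code{k0} with attribute \code{counts} (per-set
#'   fragment counts) and \code{frequency} (counts / total fragments).
#' @export
estimate_initial_k <- function(aln, sig) {
  n <- n_aligned_fragments(aln)
  if (n == 0L) stop("zero aligned fragments")
  counts <- vapply(sig, function(set) {
    if (length(set) == 0L) return(0L)
    length(unique(aln$read[!is.na(aln$node) & aln$node %in% set]))
  }, integer(1))
  k0 <- max(1L, sum(counts > 0.01 * n))
  structure(k0, counts = counts, frequency = counts / n)
}

#' Initialize the MCMC state
#'
#' Signature mode starts the k sources on the parent branches of the
#' tree nodes owning the k most-hit signature sets (position
#' \eqn{\beta = 0.5}, uniform proportions); random mode draws branches
#' uniformly without replacement and \eqn{\beta \sim U(0,1)}.
#' Deterministic given \code{seed}.
#'
#' @param k Number of sources.
#' @param mode \code{"signature"} or \code{"random"}.
#' @param tree A \code{taxon_tree}.
#' @param sig_counts Named per-path hit counts (attribute
#'   \code{counts} of \code{\link{estimate_initial_k}}); required for
#'   signature mode.
#' @param seed Integer seed.
#' @return A \code{\link{mixture_model}}.
#' @export
init_state <- function(k, mode = c("signature", "random"), tree,
                       sig_counts = NULL, seed = NULL) {
  mode <- match.arg(mode)
  nb <- nrow(tree$branches)
  if (k > nb) stop("k exceeds the number of branches")
  if (!is.null(seed)) set.seed(seed)
  root <- tree_root_label(tree)
  if (mode == "signature") {
    if (is.null(sig_counts)) stop("signature mode needs sig_counts")
    ranked <- names(sort(sig_counts[sig_counts > 0], decreasing = TRUE))
    owners <- utils::head(ranked, k)
    branches <- vapply(owners, function(lab) {
      if (lab == root) which(tree$branches$anc == root)[1] else {
        parent_branch(tree, lab)
      }
    }, integer(1))
    branches <- unique(branches)
    if (length(branches) < k) {
      pool <- setdiff(seq_len(nb), branches)
      branches <- c(branches,
                    sample(pool, k - length(branches)))
    }
    beta <- rep(0.5, k)
  } else {
    branches <- sample.int(nb, k)
    beta <- stats::runif(k)
  }
  mixture_model(rep(1 / k, k),
                lapply(seq_len(k), function(i) {
                  placement(tree, branches[i], beta[i])
                }))
}

## Reflect a proposal into [0, 1].
reflect01 <- function(x) {
  while (x < 0 || x > 1) {
    if (x < 0) x <- -x
    if (x > 1) x <- 2 - x
  }
  x
}

#' Propose a Metropolis-Hastings move (reference implementation)
#'
#' Mirrors the sampler's proposal kernel at R level, mainly for
#' inspection and testing: with probability \code{p_hop} one source
#' hops to a uniformly chosen adjacent branch (parent, sibling or
#' child) with a fresh \eqn{\beta \sim U(0,1)} and Hastings ratio
#' \eqn{|nbr(cur)| / |nbr(new)|}; otherwise either a reflected Gaussian
#' step on one \eqn{\beta} (symmetric) or a logistic-normal step on
#' \eqn{\theta} with exact Jacobian correction.
#'
#' @param state A \code{\link{mixture_model}}.
#' @param config An \code{\link{mcmc_config}}.
#' @param tree A \code{taxon_tree}.
#' @param force_type Optional move type (\code{"hop"}, \code{"beta"},
#'   \code{"theta"}) instead of the random mix.
#' @return List with the proposed \code{state}, the
#'   \code{log_hastings} correction (including the Jacobian term for
#'   theta moves) and the move \code{type}.
#' @export
propose_move <- function(state, config, tree, force_type = NULL) {
  stopifnot(inherits(state, "mixture_model"))
  k <- state$k
  type <- force_type %||% {
    if (stats::runif(1) < config$p_hop) "hop"
    else if (k > 1 && stats::runif(1) < 0.5) "theta"
    else "beta"
  }
  nbs <- branch_neighbors(tree)
  if (type == "hop") {
    j <- sample.int(k, 1)
    cur <- state$placements[[j]]$branch
    cand <- nbs[[cur]]
    nb <- cand[sample.int(length(cand), 1)]
    newp <- placement(tree, nb, stats::runif(1))
    state$placements[[j]] <- newp
    lh <- log(length(cand)) - log(length(nbs[[nb]]))
  } else if (type == "theta") {
    y <- log(state$theta[-k] / state$theta[k]) +
      stats::rnorm(k - 1, 0, config$sigma_theta)
    ey <- exp(c(y, 0) - max(c(y, 0)))
    ntheta <- ey / sum(ey)
    lh <- sum(log(ntheta)) - sum(log(state$theta))
    state <- mixture_model(ntheta, state$placements)
  } else {
    j <- sample.int(k, 1)
    p <- state$placements[[j]]
    nb <- reflect01(p$beta + stats::rnorm(1, 0, config$sigma_beta))
    state$placements[[j]] <- placement(tree, p$branch, nb)
    lh <- 0
  }
  list(state = state, log_hastings = lh, type = type)
}

## ---- sampler driver ----------------------------------------------------

#' Run the Metropolis-Hastings sampler for a fixed number of sources
#'
#' Samples branch placements and mixture proportions for \code{k}
#' sources with the target proportional to the mixture likelihood
#' (flat priors). Reproducible under a fixed seed. If the likelihood is
#' non-finite at the initial state, initialization is retried (randomly)
#' up to 20 times before failing.
#'
#' @param aln A \code{fragment_alignments} table.
#' @param graph,tree The pangenome graph and taxon tree.
#' @param model An \code{\link{hky_model}}.
#' @param profile A \code{\link{damage_profile}} (default: no damage).
#' @param k Number of sources.
#' @param config An \code{\link{mcmc_config}}.
#' @param sig_counts Signature hit counts for signature initialization
#'   (computed from \code{aln} when omitted).
#' @param indel_prob Insertion/deletion probability (default 0.02).
#' @param prep Precomputed likelihood arrays (internal reuse).
#' @return A \code{mitoplace_trace}: data.frame with per-iteration
#'   columns \code{logl}, \code{proposed_logl}, \code{accepted},
#'   \code{move}, \code{branch.i}, \code{beta.i}, \code{theta.i}.
#' @export
run_mcmc <- function(aln, graph, tree, model, profile = uniform_profile(0),
                     k = 1L, config = mcmc_config(), sig_counts = NULL,
                     indel_prob = 0.02, prep = NULL) {
  if (is.null(prep)) {
    prep <- prepare_likelihood_data(aln, graph, tree, model, profile,
                                    indel_prob)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$init == "signature" && is.null(sig_counts)) {
    sig_counts <- attr(estimate_initial_k(aln, compute_signature_sets(graph)),
                       "counts")
  }
  state <- init_state(k, config$init, tree, sig_counts = sig_counts)
  ll0 <- .state_loglik(prep, state)
  tries <- 0L
  while (!is.finite(ll0) && tries < 20L) {
    state <- init_state(k, "random", tree)
    ll0 <- .state_loglik(prep, state)
    tries <- tries + 1L
  }
  if (!is.finite(ll0)) stop("non-finite likelihood at initialization")
  res <- .run_mcmc_cpp(
    prep$lik, prep$treec, prep$pi, prep$kappa, config$iterations,
    vapply(state$placements, function(p) p$branch - 1L, integer(1)),
    vapply(state$placements, function(p) p$beta, numeric(1)),
    state$theta, config$p_hop, config$sigma_beta, config$sigma_theta
  )
  tr <- as.data.frame(res$trace)
  names(tr) <- c("logl", "proposed_logl", "accepted", "move",
                 paste0("branch.", seq_len(k)),
                 paste0("beta.", seq_len(k)),
                 paste0("theta.", seq_len(k)))
  structure(tr, k = k, config = config, branches = tree$branches,
            class = c("mitoplace_trace", "data.frame"))
}

## Mixture log-likelihood of a state via the C++ per-fragment kernels.
.state_loglik <- function(prep, state) {
  lvs <- lapply(state$placements, function(p) {
    .frag_logliks_cpp(prep$lik, prep$treec, prep$pi, prep$kappa,
                      p$branch - 1L, p$beta)
  })
  lth <- log(state$theta)
  sum(apply(mapply(function(lv, lt) lv + lt, lvs, lth), 1, logsumexp))
}

## ---- diagnostics -------------------------------------------------------

#' Effective sample size of an MCMC series
#'
#' \code{N / (1 + 2 sum(rho_k))} with Geyer's initial-positive-sequence
#' truncation of the empirical autocorrelations: lags are summed while
#' consecutive pairs \code{rho(2m-1) + rho(2m)} remain positive. A
#' constant series is reported as ESS = N (with a note attribute),
#' since it carries no sampling noise to correct for.
#'
#' @param x Numeric series of length >= 10.
#' @return The effective sample size (capped at N).
#' @export
compute_ess <- function(x) {
  n <- length(x)
  if (n < 10L) stop("series too short for an ESS estimate")
  if (stats::var(x) == 0) {
    return(structure(as.numeric(n), note = "constant series"))
  }
  lm <- min(n - 1L, 2000L)
  rho <- as.numeric(stats::acf(x, lag.max = lm, plot = FALSE,
                               demean = TRUE)$acf)[-1]
  s <- 0
  m <- 1L
  while (m + 1L <= length(rho)) {
    g <- rho[m] + rho[m + 1L]
    if (g <= 0) break
    s <- s + g
    m <- m + 2L
  }
  min(n / (1 + 2 * s), n)
}

#' Choose the number of sources from a k-curve
#'
#' The paper-style visual criterion (no significant likelihood gain for
#' higher k) is made explicit with a BIC-flavoured threshold: the
#' smallest k whose gain to k+1 falls below
#' \code{tau = 2 * log(n_fragments) / 2} (two parameters, branch and
#' proportion, per added source) is selected; the full curve is always
#' reported so users can override.
#'
#' @param kcurve Data frame with columns \code{k} and \code{best_logl}.
#' @param n_frags Number of aligned fragments (sets the default
#'   threshold).
#' @param tau Threshold on the log-likelihood gain (default
#'   \code{log(n_frags)}).
#' @return The k-curve with a logical \code{selected} column; the
#'   chosen k in attribute \code{k_selected}.
#' @export
select_k <- function(kcurve, n_frags, tau = NULL) {
  stopifnot(all(c("k", "best_logl") %in% names(kcurve)))
  kcurve <- kcurve[order(kcurve$k), , drop = FALSE]
  tau <- tau %||% log(n_frags)
  ks <- kcurve$k
  sel <- ks[length(ks)]
  for (i in seq_len(length(ks) - 1L)) {
    if (kcurve$best_logl[i + 1L] - kcurve$best_logl[i] < tau) {
      sel <- ks[i]
      break
    }
  }
  kcurve$selected <- kcurve$k == sel
  structure(kcurve, k_selected = sel, tau = tau)
}

#' Posterior summaries and diagnostics of a trace
#'
#' Discards the burn-in, relabels sources by decreasing posterior mean
#' proportion (label switching), and reports 5/50/95\% quantiles for
#' every proportion and branch position, per-branch visit frequencies,
#' the maximum-a-posteriori state, and per-parameter effective sample
#' sizes. A warning is raised when any ESS falls below 200.
#'
#' @param trace A \code{mitoplace_trace}.
#' @param burnin Burn-in fraction (default: the trace's config value).
#' @return A list of class \code{mitoplace_diagnostics}.
#' @export
summarize_posterior <- function(trace, burnin = NULL) {
  k <- attr(trace, "k")
  cfg <- attr(trace, "config")
  burnin <- burnin %||% (if (!is.null(cfg)) cfg$burnin else 0.1)
  n <- nrow(trace)
  if (n < 1L || floor(burnin * n) + 1L > n) {
    stop("empty post-burn-in trace")
  }
  post <- trace[(floor(burnin * n) + 1L):n, , drop = FALSE]
  theta_means <- vapply(seq_len(k), function(i) {
    mean(post[[paste0("theta.", i)]])
  }, numeric(1))
  ord <- order(theta_means, decreasing = TRUE)
  qs <- c(0.05, 0.5, 0.95)
  quantiles <- do.call(rbind, lapply(seq_along(ord), function(rank) {
    i <- ord[rank]
    th <- stats::quantile(post[[paste0("theta.", i)]], qs, names = FALSE)
    be <- stats::quantile(post[[paste0("beta.", i)]], qs, names = FALSE)
    data.frame(source = rank,
               theta_mean = theta_means[i],
               theta_q5 = th[1], theta_q50 = th[2], theta_q95 = th[3],
               beta_q5 = be[1], beta_q50 = be[2], beta_q95 = be[3])
  }))
  branches <- attr(trace, "branches")
  visit <- lapply(seq_along(ord), function(rank) {
    i <- ord[rank]
    tab <- table(factor(post[[paste0("branch.", i)]],
                        levels = seq_len(nrow(branches))))
    data.frame(branch = seq_len(nrow(branches)),
               anc = branches$anc, dec = branches$dec,
               freq = as.numeric(tab) / nrow(post))
  })
  imax <- which.max(post$logl)
  map <- list(
    logl = post$logl[imax],
    branch = vapply(ord, function(i) post[[paste0("branch.", i)]][imax],
                    numeric(1)),
    beta = vapply(ord, function(i) post[[paste0("beta.", i)]][imax],
                  numeric(1)),
    theta = vapply(ord, function(i) post[[paste0("theta.", i)]][imax],
                   numeric(1))
  )
  map$branch_dec <- branches$dec[map$branch]
  ess <- c(logl = compute_ess(post$logl),
           stats::setNames(vapply(seq_along(ord), function(rank) {
             compute_ess(post[[paste0("theta.", ord[rank])]])
           }, numeric(1)), paste0("theta.", seq_along(ord))),
           stats::setNames(vapply(seq_along(ord), function(rank) {
             compute_ess(post[[paste0("beta.", ord[rank])]])
           }, numeric(1)), paste0("beta.", seq_along(ord))))
  low_ess <- any(ess < 200)
  if (low_ess) {
    warning("effective sample size below 200 for at least one parameter; ",
            "posterior quantiles (especially the 5%/95% tails) may be ",
            "poorly estimated -- consider more iterations")
  }
  structure(list(k = k, summary = quantiles, visit_freq = visit, map = map,
                 ess = ess, low_ess_warning = low_ess,
                 source_order = ord, n_post = nrow(post)),
            class = "mitoplace_diagnostics")
}

#' @export
print.mitoplace_diagnostics <- function(x, ...) {
  cat(sprintf("mitoplace diagnostics: k = %d (%d post-burn-in samples)\n",
              x$k, x$n_post))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  source %d: theta %.3f [%.3f, %.3f], MAP branch -> %s (beta %.2f)\n",
      i, s$theta_mean[i], s$theta_q5[i], s$theta_q95[i],
      x$map$branch_dec[i], x$map$beta[i]))
  }
  if (x$low_ess_warning) cat("  WARNING: ESS < 200 for some parameter\n")
  invisible(x)
}

## Nearest tree node of a placement: the derived node when beta >= 0.5,
## else the ancestral node.
placement_nearest_node <- function(branches, branch, beta) {
  ifelse(beta >= 0.5, branches$dec[branch], branches$anc[branch])
}
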