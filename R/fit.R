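#' Fit branch placements and mixture proportions to aligned fragments
#'
#' The main modelling interface. Starting from fragment alignments on a
#' pangenome graph, it (i) estimates an initial number of sources k0
#' from signature-node frequencies, (ii) runs the Metropolis-Hastings
#' sampler for every k in 1..k_max under the damage-aware HKY mixture
#' likelihood, (iii) selects k from the k-curve of best log-likelihoods
#' and (iv) returns posterior summaries and diagnostics as a classed
#' model object.
#'
#' @param aln A \code{\link{align_fragments}} result, or a
#'   \code{\link{read_set}} / FASTQ path (aligned on the fly).
#' @param graph A \code{pangenome_graph} (with ancestral paths).
#' @param tree The matching \code{taxon_tree}.
#' @param model An \code{\link{hky_model}}; by default kappa 2 with
#'   base frequencies estimated from the reference path sequences.
#' @param profile A \code{\link{damage_profile}} (default: no damage).
#' @param k Run k = 1..\code{k} instead of 1..k0.
#' @param force_k Like \code{k} but explicitly allowed to exceed k0
#'   (mirrors forcing a higher source count on sparse data).
#' @param config An \code{\link{mcmc_config}}; its seed drives every
#'   stochastic step, with per-k, per-chain derived seeds.
#' @param indel_prob Per-base insertion/deletion probability
#'   (default 0.02).
#' @param tau Model-selection threshold passed to
#'   \code{\link{select_k}}.
#' @return An object of class \code{mitoplace_fit} with components
#'   \code{kcurve}, \code{k_selected}, \code{k0}, \code{traces} (per k,
#'   a list of chains), \code{diagnostics} (per k, computed on the
#'   best chain), \code{sig_counts}, \code{model}, \code{config} and
#'   \code{n_fragments}. Methods: \code{print}, \code{summary},
#'   \code{coef} (posterior mean proportions), \code{logLik},
#'   \code{plot}.
#' @export
mitoplace <- function(aln, graph, tree, model = NULL,
                      profile = uniform_profile(0), k = NULL,
                      force_k = NULL, config = mcmc_config(),
                      indel_prob = 0.02, tau = NULL) {
  if (inherits(aln, "read_set") || (is.character(aln) && length(aln) == 1L)) {
    aln <- align_fragments(aln, graph)
  }
  stopifnot(inherits(aln, "fragment_alignments"))
  if (is.null(model)) {
    allseq <- paste(vapply(names(graph$paths), function(p) {
      path_sequence(graph, p)
    }, character(1)), collapse = "")
    counts <- vapply(BASES, function(b) {
      sum(charToRaw(allseq) == charToRaw(b))
    }, numeric(1))
    model <- hky_model(2, counts / sum(counts))
  }
  sig <- compute_signature_sets(graph)
  k0 <- estimate_initial_k(aln, sig)
  sig_counts <- attr(k0, "counts")
  k_max <- force_k %||% k %||% as.integer(k0)
  n_frags <- n_aligned_fragments(aln)
  prep <- prepare_likelihood_data(aln, graph, tree, model, profile,
                                  indel_prob)
  base_seed <- config$seed %||% 1L
  traces <- vector("list", k_max)
  diagnostics <- vector("list", k_max)
  kcurve <- data.frame(k = seq_len(k_max), best_logl = NA_real_)
  for (kk in seq_len(k_max)) {
    chains <- vector("list", config$chains)
    for (ch in seq_len(config$chains)) {
      cfg <- config
      cfg$seed <- base_seed + 101L * kk + ch - 1L
      chains[[ch]] <- run_mcmc(aln, graph, tree, model, profile, k = kk,
                               config = cfg, sig_counts = sig_counts,
                               indel_prob = indel_prob, prep = prep)
    }
    traces[[kk]] <- chains
    best_chain <- which.max(vapply(chains, function(tr) max(tr$logl),
                                   numeric(1)))
    kcurve$best_logl[kk] <- max(chains[[best_chain]]$logl)
    diagnostics[[kk]] <- suppressWarnings(
      summarize_posterior(chains[[best_chain]])
    )
  }
  kcurve <- select_k(kcurve, n_frags, tau = tau)
  k_sel <- attr(kcurve, "k_selected")
  if (diagnostics[[k_sel]]$low_ess_warning) {
    warning("effective sample size below 200 for the selected k; ",
            "consider more iterations")
  }
  structure(list(kcurve = kcurve, k_selected = k_sel, k0 = as.integer(k0),
                 traces = traces, diagnostics = diagnostics,
                 sig_counts = sig_counts, model = model, config = config,
                 profile = profile, n_fragments = n_frags,
                 tree = tree),
            class = "mitoplace_fit")
}

#' @export
print.mitoplace_fit <- function(x, ...) {
  cat(sprintf(
    "mitoplace fit: %d aligned fragments, k0 = %d, selected k = %d\n",
    x$n_fragments, x$k0, x$k_selected))
  print(x$diagnostics[[x$k_selected]])
  invisible(x)
}

#' @export
summary.mitoplace_fit <- function(object, ...) {
  cat("k-curve (best log-likelihood per number of sources):\n")
  print(as.data.frame(object$kcurve), row.names = FALSE)
  cat("\n")
  print(object$diagnostics[[object$k_selected]])
  invisible(object$diagnostics[[object$k_selected]])
}

#' @export
coef.mitoplace_fit <- function(object, ...) {
  d <- object$diagnostics[[object$k_selected]]
  stats::setNames(d$summary$theta_mean,
                  paste0("theta.", seq_len(object$k_selected)))
}

#' @export
logLik.mitoplace_fit <- function(object, ...) {
  k <- object$k_selected
  val <- object$kcurve$best_logl[object$kcurve$k == k]
  structure(val, df = 3 * k - 1, nobs = object$n_fragments,
            class = "logLik")
}

#' @export
plot.mitoplace_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$kcurve$k, x$kcurve$best_logl, type = "b", pch = 19,
                 xlab = "number of sources k",
                 ylab = "best log-likelihood", main = "k-curve")
  tr <- x$traces[[x$k_selected]][[1]]
  idx <- seq(1, nrow(tr), length.out = min(5000, nrow(tr)))
  graphics::plot(idx, tr$proposed_logl[idx], pch = ".", col = "grey50",
                 xlab = "iteration", ylab = "log-likelihood",
                 main = sprintf("trace (k = %d)", x$k_selected))
  graphics::lines(idx, tr$logl[idx], col = "firebrick")
  invisible(x)
}

#' Per-branch accepted-move table
#'
#' Data behind branch-placement plots: for every branch, the number of
#' accepted post-burn-in samples per source and their mean
#' log-likelihood.
#'
#' @param fit A \code{mitoplace_fit}.
#' @param k Which k to report (default: the selected one).
#' @return A data.frame with columns \code{source}, \code{branch},
#'   \code{anc}, \code{dec}, \code{n}, \code{freq}, \code{mean_logl}.
#' @export
branch_placement_table <- function(fit, k = NULL) {
  k <- k %||% fit$k_selected
  tr <- fit$traces[[k]][[1]]
  cfg <- attr(tr, "config")
  n <- nrow(tr)
  post <- tr[(floor(cfg$burnin * n) + 1L):n, , drop = FALSE]
  branches <- attr(tr, "branches")
  out <- do.call(rbind, lapply(seq_len(k), function(i) {
    b <- post[[paste0("branch.", i)]]
    agg <- stats::aggregate(post$logl, list(branch = b), mean)
    cnt <- table(b)
    data.frame(source = i, branch = as.integer(names(cnt)),
               n = as.integer(cnt),
               freq = as.integer(cnt) / nrow(post),
               mean_logl = agg$x[match(as.integer(names(cnt)),
                                       agg$branch)])
  }))
  out$anc <- branches$anc[out$branch]
  out$dec <- branches$dec[out$branch]
  out[, c("source", "branch", "anc", "dec", "n", "freq", "mean_logl")]
}
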