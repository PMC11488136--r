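## Damage-aware, placement-conditional likelihood.
##
## Observation chain per aligned base (fragment frame):
##   graph base b_g --HKY(t)--> source base b_s --damage--> b_d --error--> b
## All 16 intermediate (b_s, b_d) combinations are marginalized; no
## shortcut formulas, so a mutation later reverted by deamination is
## counted correctly.

PROB_FLOOR <- 1e-12

error_matrix <- function(eps) {
  E <- matrix(eps / 3, 4, 4, dimnames = list(BASES, BASES))
  diag(E) <- 1 - eps
  E
}

#' Probability of a base on an unsupported graph node
#'
#' When a fragment base sits on a graph node that the evaluated
#' reference path does not traverse, the path carries no aligned base
#' to compare against. Such bases are scored by a fixed mixture: 6/7 of
#' them as a sequencing error with probability \eqn{\epsilon/3} and 1/7
#' as a match with probability \eqn{1-\epsilon}.
#'
#' @param eps Per-base error probability from the quality score,
#'   in \code{(0, 1]}.
#' @return \code{(6/7) * (eps/3) + (1/7) * (1 - eps)}.
#' @export
base_prob_unsupported <- function(eps) {
  (6 / 7) * (eps / 3) + (1 / 7) * (1 - eps)
}

#' Probability of an aligned base given a reference path and distance
#'
#' For a match or mismatch the full marginalization
#' \deqn{P(b | b_g, t) = \sum_{b_s}\sum_{b_d} P_{HKY}(b_s|b_g, t)\,
#'   P_{dam}(b_d|b_s; pos5, pos3)\, P_{err}(b|b_d, \epsilon)}
#' is evaluated; insertions and deletions have fixed probability
#' \code{indel_prob}; unresolved bases and softclips are sequencing
#' errors with probability \eqn{\epsilon/3}.
#'
#' @param model An \code{\link{hky_model}}.
#' @param profile A \code{\link{damage_profile}}.
#' @param t Distance (expected substitutions/site) from the placement to
#'   the tree node owning the reference path.
#' @param aligned_base A list with fields \code{event}, \code{base}
#'   (observed, fragment strand), \code{bg} (graph base in the fragment
#'   frame; required for match/mismatch/deletion), \code{eps},
#'   \code{pos5}, \code{pos3}.
#' @param indel_prob Per-base insertion/deletion probability
#'   (default 0.02).
#' @return A probability.
#' @export
base_prob_aligned <- function(model, profile, t, aligned_base,
                              indel_prob = 0.02) {
  ev <- aligned_base$event
  if (ev %in% c("insertion", "deletion")) return(indel_prob)
  if (ev %in% c("softclip", "unresolved")) return(aligned_base$eps / 3)
  if (is.null(aligned_base$bg) || is.na(aligned_base$bg)) {
    stop("graph base b_g required for a ", ev, " event")
  }
  P <- hky_transition_matrix(model, t)
  D <- damage_matrix(profile, aligned_base$pos5, aligned_base$pos3)
  E <- error_matrix(aligned_base$eps)
  (P %*% D %*% E)[aligned_base$bg, aligned_base$base]
}

#' Continuous branch placement
#'
#' A placement lives on the branch between an ancestral tree node
#' \eqn{N_A} and its derived (child) node \eqn{N_D}, at relative
#' position \eqn{\beta \in [0,1]}: \eqn{\beta = 1} means the source is
#' \eqn{N_D} itself. The distance from the source to \eqn{N_D} is
#' \eqn{t_D = (1-\beta) t} and to \eqn{N_A} is \eqn{t_A = \beta t}.
#'
#' @param tree A \code{taxon_tree}.
#' @param branch Branch id (row of \code{tree$branches}) or the label of
#'   the branch's derived node.
#' @param beta Relative position in \code{[0, 1]}.
#' @return A list of class \code{placement} with \code{branch},
#'   \code{anc}, \code{dec}, \code{beta}, \code{t}, \code{t_A},
#'   \code{t_D}.
#' @export
placement <- function(tree, branch, beta) {
  stopifnot(inherits(tree, "taxon_tree"))
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta < 0 || beta > 1) {
    stop("beta must lie in [0, 1]")
  }
  br <- tree$branches
  id <- if (is.character(branch)) match(branch, br$dec) else as.integer(branch)
  if (is.na(id) || id < 1L || id > nrow(br)) {
    stop("placement branch not in tree: ", branch)
  }
  t <- br$length[id]
  structure(list(branch = id, anc = br$anc[id], dec = br$dec[id],
                 beta = beta, t = t, t_A = beta * t,
                 t_D = (1 - beta) * t),
            class = "placement")
}

## Per-base probabilities of one fragment against one reference path at
## distance t. `rows` is the fragment's slice of a fragment_alignments
## table; bg_frag and supported are precomputed per row.
fragment_side_loglik <- function(rows, bg_frag, supported, t, model, profile,
                                 indel_prob) {
  P <- hky_transition_matrix(model, t)
  p <- numeric(nrow(rows))
  for (q in seq_len(nrow(rows))) {
    ev <- rows$event[q]
    if (ev %in% c("insertion", "deletion")) {
      p[q] <- indel_prob
    } else if (ev %in% c("softclip", "unresolved")) {
      p[q] <- rows$eps[q] / 3
    } else if (!supported[q]) {
      p[q] <- base_prob_unsupported(rows$eps[q])
    } else {
      D <- damage_matrix(profile, rows$pos5[q], rows$pos3[q])
      E <- error_matrix(rows$eps[q])
      p[q] <- (P %*% D %*% E)[bg_frag[q], rows$base[q]]
    }
  }
  sum(log(pmax(p, PROB_FLOOR)))
}

## Graph base (fragment frame) for each row of an alignment slice.
row_graph_bases <- function(rows, graph) {
  bg <- rep(NA_character_, nrow(rows))
  has <- !is.na(rows$node)
  if (any(has)) {
    bg[has] <- substring(graph$nodes$seq[rows$node[has]],
                         rows$offset[has] + 1L, rows$offset[has] + 1L)
    rc <- has & rows$orientation == "reverse-complement"
    bg[rc] <- decode_bases(3L - encode_bases(bg[rc]))
  }
  bg
}

#' Log-likelihood of one fragment given a branch placement
#'
#' Evaluates the affine combination
#' \deqn{P(fr|\beta) = (1-\beta) \prod_b P(b|N_A, t_A) +
#'   \beta \prod_b P(b|N_D, t_D)}
#' where bases on nodes traversed by a node's reference path use the
#' damage-aware HKY channel with the path's graph base, and bases on
#' untraversed nodes use the unsupported-base mixture. Computed in log
#' space with a stable log-sum-exp combine; per-base probabilities are
#' floored at 1e-12.
#'
#' @param aln A \code{fragment_alignments} table (rows of one read, or
#'   a table from which the read is selected via \code{read_id}).
#' @param plc A \code{\link{placement}}.
#' @param graph The \code{pangenome_graph} the read was aligned to.
#' @param model An \code{\link{hky_model}}.
#' @param profile A \code{\link{damage_profile}}.
#' @param read_id Optional read id to select from \code{aln}.
#' @param indel_prob Insertion/deletion probability (default 0.02).
#' @return The log-probability of the fragment.
#' @export
fragment_loglik <- function(aln, plc, graph, model, profile,
                            read_id = NULL, indel_prob = 0.02) {
  stopifnot(inherits(plc, "placement"))
  rows <- if (is.null(read_id)) aln else aln[aln$read == read_id, ,
                                             drop = FALSE]
  if (nrow(rows) == 0L) stop("empty alignment")
  bg <- row_graph_bases(rows, graph)
  sup_of <- function(label) {
    nodeset <- graph$paths[[label]]
    if (is.null(nodeset)) stop("path missing for tree node ", label)
    !is.na(rows$node) & rows$node %in% nodeset
  }
  la <- fragment_side_loglik(rows, bg, sup_of(plc$anc), plc$t_A, model,
                             profile, indel_prob)
  ld <- fragment_side_loglik(rows, bg, sup_of(plc$dec), plc$t_D, model,
                             profile, indel_prob)
  if (plc$beta <= 0) return(la)
  if (plc$beta >= 1) return(ld)
  logsumexp(c(log1p(-plc$beta) + la, log(plc$beta) + ld))
}

#' Mixture model over k sources
#'
#' @param theta Mixture proportions (non-negative, summing to 1 within
#'   1e-12).
#' @param placements List of \code{\link{placement}} objects, one per
#'   source.
#' @return An object of class \code{mixture_model}.
#' @export
mixture_model <- function(theta, placements) {
  k <- length(theta)
  if (k < 1L || length(placements) != k) {
    stop("theta and placements must have equal length k >= 1")
  }
  if (any(theta < 0) || abs(sum(theta) - 1) > 1e-12) {
    stop("theta must be non-negative and sum to 1 (tolerance 1e-12)")
  }
  stopifnot(all(vapply(placements, inherits, logical(1), "placement")))
  structure(list(k = k, theta = as.numeric(theta), placements = placements),
            class = "mixture_model")
}

#' Mixture log-likelihood of all fragments
#'
#' Marginalizes each fragment over the k sources,
#' \eqn{\sum_{fr} \log \sum_i \theta_i P(fr|\beta_i)}, with log-sum-exp
#' stabilization. This is the quantity the MCMC targets (flat priors on
#' placements and proportions make the posterior proportional to it).
#'
#' @param aln A \code{fragment_alignments} table.
#' @param mixture A \code{\link{mixture_model}}.
#' @param graph,model,profile As in \code{\link{fragment_loglik}}.
#' @param indel_prob Insertion/deletion probability (default 0.02).
#' @return The total log-likelihood.
#' @export
mixture_loglik <- function(aln, mixture, graph, model, profile,
                           indel_prob = 0.02) {
  stopifnot(inherits(mixture, "mixture_model"))
  ids <- unique(aln$read)
  total <- 0
  for (id in ids) {
    terms <- vapply(seq_len(mixture$k), function(i) {
      if (mixture$theta[i] == 0) return(-Inf)
      log(mixture$theta[i]) +
        fragment_loglik(aln, mixture$placements[[i]], graph, model,
                        profile, read_id = id, indel_prob = indel_prob)
    }, numeric(1))
    total <- total + logsumexp(terms)
  }
  total
}
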