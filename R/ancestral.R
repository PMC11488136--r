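#' Reconstruct ancestral reference paths
#'
#' Extends a reference alignment with one aligned sequence per internal
#' tree node, so that every tree node (leaf and ancestral) owns a
#' reference path in the pangenome graph. Per column, the base of an
#' internal node is the marginal maximum-likelihood state under the
#' given HKY85 model (Felsenstein pruning over the whole tree, root at
#' stationarity), with exact likelihood ties broken toward the
#' alphabetically first base. Gap/non-gap states are reconstructed
#' separately by Fitch parsimony on the gap indicator, with ties
#' resolved toward non-gap. Leaves with \code{N} or \code{-} contribute
#' no information to the base reconstruction at that column.
#'
#' @param msa A \code{\link{reference_msa}} containing one record per
#'   tree leaf (extra records are ignored).
#' @param tree A \code{\link{load_tree}} result whose leaf labels all
#'   appear among the MSA record names.
#' @param model An \code{\link{hky_model}}.
#' @return A \code{reference_msa} holding the leaf records followed by
#'   one aligned record per internal node, named by the internal-node
#'   labels (\code{N1..Nm} by default). Deterministic given inputs.
#' @export
reconstruct_ancestral_paths <- function(msa, tree, model) {
  stopifnot(inherits(msa, "reference_msa"), inherits(tree, "taxon_tree"),
            inherits(model, "hky_model"))
  leaves <- tree_leaf_labels(tree)
  if (!all(leaves %in% rownames(msa))) {
    stop("unresolvable leaf-to-record mapping; missing record(s): ",
         paste(setdiff(leaves, rownames(msa)), collapse = ", "))
  }
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  ncols <- ncol(msa)
  m <- unclass(msa)

  post <- rev(preorder_nodes(phy))          # children before parents
  pre <- preorder_nodes(phy)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  elen <- numeric(ntip + nnode)
  elen[phy$edge[, 2]] <- phy$edge.length
  Pmat <- vector("list", ntip + nnode)      # P(t) of each node's parent branch
  for (v in phy$edge[, 2]) Pmat[[v]] <- hky_transition_matrix(model, elen[v])

  ## ---- gap indicator by Fitch parsimony (bit1 = base, bit2 = gap) ----
  gsets <- matrix(0L, ntip + nnode, ncols)
  for (v in seq_len(ntip)) {
    gsets[v, ] <- ifelse(m[tree$labels[v], ] == "-", 2L, 1L)
  }
  for (v in post) {
    if (v <= ntip) next
    ch <- kids[[as.character(v)]]
    s <- gsets[ch[1], ]
    for (c2 in ch[-1]) {
      inter <- bitwAnd(s, gsets[c2, ])
      uni <- bitwOr(s, gsets[c2, ])
      s <- ifelse(inter > 0L, inter, uni)
    }
    gsets[v, ] <- s
  }
  gstate <- matrix(FALSE, ntip + nnode, ncols)   # TRUE = gap
  root <- ntip + 1L
  gstate[root, ] <- gsets[root, ] == 2L          # tie {base,gap} -> non-gap
  for (v in pre[-1]) {
    if (v <= ntip) { gstate[v, ] <- gsets[v, ] == 2L; next }
    par <- phy$edge[match(v, phy$edge[, 2]), 1]
    pg <- gstate[par, ] + 1L                      # 1 = base, 2 = gap
    keep <- bitwAnd(gsets[v, ], pg) > 0L          # parent state attainable
    gstate[v, ] <- ifelse(keep, pg == 2L, gsets[v, ] == 2L)
  }

  ## ---- marginal base reconstruction by pruning (4 x ncols per node) ----
  L <- vector("list", ntip + nnode)
  for (v in seq_len(ntip)) {
    obs <- m[tree$labels[v], ]
    Lv <- matrix(1, 4, ncols)
    for (b in 1:4) Lv[b, ] <- ifelse(obs %in% c("N", "-"), 1, obs == BASES[b])
    L[[v]] <- Lv
  }
  down_msg <- vector("list", ntip + nnode)   # P_v %*% L_v, message to parent
  for (v in post) {
    if (v > ntip) {
      ch <- kids[[as.character(v)]]
      Lv <- matrix(1, 4, ncols)
      for (c2 in ch) Lv <- Lv * down_msg[[c2]]
      L[[v]] <- Lv
    }
    if (v != root) down_msg[[v]] <- Pmat[[v]] %*% L[[v]]
  }
  U <- vector("list", ntip + nnode)
  U[[root]] <- matrix(model$pi, 4, ncols)
  for (v in pre) {
    if (v <= ntip) next
    ch <- kids[[as.character(v)]]
    for (ci in seq_along(ch)) {
      excl <- U[[v]]
      for (cj in seq_along(ch)) {
        if (cj != ci) excl <- excl * down_msg[[ch[cj]]]
      }
      U[[ch[ci]]] <- crossprod(Pmat[[ch[ci]]], excl)
    }
  }

  internal <- root - 1L + seq_len(nnode)
  out <- m
  for (v in internal) {
    marg <- U[[v]] * L[[v]]
    tot <- colSums(marg)
    if (any(tot == 0)) stop("zero marginal likelihood at some column")
    best <- apply(marg, 2, which.max)   # first max = alphabetical tie-break
    seqv <- BASES[best]
    seqv[gstate[v, ]] <- "-"
    out <- rbind(out, seqv)
    rownames(out)[nrow(out)] <- tree$labels[v]
  }
  structure(out, class = "reference_msa")
}
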