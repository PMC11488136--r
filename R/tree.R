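#' Read a rooted taxon tree with branch lengths
#'
#' Parses a Newick tree (string or file path) into the coordinate system
#' used for branch placements. Every branch is identified by its derived
#' (child) node; a placement on a branch interpolates between the
#' ancestral node \eqn{N_A} (parent) and the derived node \eqn{N_D}
#' (child). Internal nodes without labels are auto-labelled
#' \code{N1..Nm} in pre-order; existing labels are preserved.
#'
#' @param newick A Newick string, or the path of a file containing one.
#' @return An object of class \code{taxon_tree}: a list with the
#'   underlying \code{ape::phylo} tree (\code{$phy}), a per-node label
#'   vector (\code{$labels}, indexed by ape node number), and a branch
#'   table (\code{$branches}) with columns \code{branch} (id),
#'   \code{anc}, \code{dec} (node labels) and \code{length}.
#' @examples
#' tr <- load_tree("((A:0.1,B:0.1):0.05,C:0.2);")
#' tr$branches
#' @export
load_tree <- function(newick) {
  if (length(newick) != 1L || !is.character(newick)) {
    stop("newick must be a single string or file path")
  }
  txt <- if (file.exists(newick)) {
    paste(readLines(newick, warn = FALSE), collapse = "")
  } else {
    newick
  }
  check_newick_syntax(txt)
  phy <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop("malformed Newick: ", conditionMessage(e))
  )
  if (is.null(phy)) stop("malformed Newick: parser returned no tree")
  if (is.null(phy$edge.length) || anyNA(phy$edge.length)) {
    stop("every branch must carry a branch length (no silent defaults)")
  }
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative")
  }
  if (nrow(phy$edge) != phy$Nnode + length(phy$tip.label) - 1L) {
    stop("tree must have exactly one root")
  }
  if (anyDuplicated(phy$tip.label)) stop("duplicate leaf names")
  taxon_tree_from_phylo(phy)
}

## Quick balanced-parenthesis scan so syntax errors name a position.
check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed Newick: unbalanced ')' at position %d", i))
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf("malformed Newick: %d unclosed '(' at end of input", depth))
  }
  if (!grepl(";\\s*$", txt)) stop("malformed Newick: missing terminal ';'")
  invisible(TRUE)
}

taxon_tree_from_phylo <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  labels <- character(ntip + nnode)
  labels[seq_len(ntip)] <- phy$tip.label
  internal <- ntip + seq_len(nnode)
  have <- !is.null(phy$node.label) && all(nzchar(phy$node.label))
  if (have) {
    labels[internal] <- phy$node.label
  } else {
    ## pre-order numbering of internal nodes: N1 = root, then depth-first
    ord <- preorder_nodes(phy)
    ints <- ord[ord > ntip]
    labels[ints] <- paste0("N", seq_along(ints))
    phy$node.label <- labels[internal]
  }
  if (anyDuplicated(labels)) stop("node labels not unique")
  br <- data.frame(
    branch = seq_len(nrow(phy$edge)),
    anc = labels[phy$edge[, 1]],
    dec = labels[phy$edge[, 2]],
    length = phy$edge.length,
    stringsAsFactors = FALSE
  )
  structure(
    list(phy = phy, labels = labels, branches = br),
    class = "taxon_tree"
  )
}

## Node numbers in pre-order (root first, depth-first down the edge table).
preorder_nodes <- function(phy) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    out <- c(out, v)
    ch <- kids[[as.character(v)]]
    if (!is.null(ch)) stack <- c(ch, stack)
  }
  out
}

#' @export
print.taxon_tree <- function(x, ...) {
  cat(sprintf(
    "taxon_tree: %d leaves, %d internal nodes, %d branches\n",
    length(x$phy$tip.label), x$phy$Nnode, nrow(x$branches)
  ))
  invisible(x)
}

#' Serialize a taxon tree back to Newick
#'
#' @param tree A \code{taxon_tree}.
#' @return A Newick string (with internal-node labels and branch lengths).
#' @export
write_tree_newick <- function(tree) {
  stopifnot(inherits(tree, "taxon_tree"))
  ape::write.tree(tree$phy)
}

## ---- internal tree accessors -------------------------------------------

tree_node_id <- function(tree, label) {
  id <- match(label, tree$labels)
  if (anyNA(id)) stop("unknown tree node label(s): ",
                      paste(label[is.na(id)], collapse = ", "))
  id
}

tree_root_label <- function(tree) {
  tree$labels[length(tree$phy$tip.label) + 1L]
}

tree_node_labels <- function(tree, preorder = FALSE) {
  if (preorder) tree$labels[preorder_nodes(tree$phy)] else tree$labels
}

tree_leaf_labels <- function(tree) tree$phy$tip.label

tree_internal_labels <- function(tree) {
  tree$labels[length(tree$phy$tip.label) + seq_len(tree$phy$Nnode)]
}

## Branch id of the parent branch of a node label (NA for the root).
parent_branch <- function(tree, label) {
  hit <- match(label, tree$branches$dec)
  hit
}

## Branches adjacent to a branch: the parent edge of anc, the other child
## edges of anc (siblings) and the child edges of dec.
branch_neighbors <- function(tree) {
  br <- tree$branches
  lapply(seq_len(nrow(br)), function(i) {
    anc <- br$anc[i]
    dec <- br$dec[i]
    nb <- c(
      which(br$dec == anc),                       # parent branch of anc
      which(br$anc == anc & br$dec != dec),       # sibling branches
      which(br$anc == dec)                        # child branches
    )
    sort(unique(nb))
  })
}

## Nodes incident to the parent branch of `label` plus its parent, sibling
## and child branches; used for the adjacency check at very low coverage.
adjacent_branch_set <- function(tree, label) {
  pb <- parent_branch(tree, label)
  nb <- branch_neighbors(tree)
  if (is.na(pb)) {
    which(tree$branches$anc == label)
  } else {
    sort(unique(c(pb, nb[[pb]])))
  }
}
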