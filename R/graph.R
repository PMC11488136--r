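#' Build a pangenome graph from a reference alignment
#'
#' Column-wise graph construction: maximal runs of consecutive columns
#' that induce the same partition of records (by residue, with gapped
#' records forming their own group) collapse into one node per distinct
#' non-gap allele. Edges follow the adjacency of consecutive non-gap
#' characters in each record, and each record becomes one path. By
#' construction, concatenating the node sequences along a path spells
#' the record's degapped sequence exactly.
#'
#' @param msa A \code{\link{reference_msa}} holding one record per tree
#'   node (leaves and internal nodes, e.g. the output of
#'   \code{\link{reconstruct_ancestral_paths}}). Ambiguous bases
#'   (\code{N}) are not allowed in graph records.
#' @param tree A \code{taxon_tree}; paths are stored in tree pre-order,
#'   which fixes the deterministic tie-break order used downstream.
#' @return An object of class \code{pangenome_graph}: list with
#'   \code{nodes} (data.frame: \code{node}, \code{seq}),
#'   \code{edges} (data.frame: \code{from}, \code{to}),
#'   \code{paths} (named list of node-id vectors, one per tree node, in
#'   tree pre-order), and \code{support} (list: per node, the character
#'   vector of path names traversing it).
#' @export
build_graph_from_msa <- function(msa, tree) {
  stopifnot(inherits(msa, "reference_msa"), inherits(tree, "taxon_tree"))
  if (nrow(msa) == 0L) stop("empty MSA")
  if (anyDuplicated(rownames(msa))) stop("duplicate record names")
  wanted <- tree_node_labels(tree, preorder = TRUE)
  missing <- setdiff(wanted, rownames(msa))
  if (length(missing)) {
    stop("MSA must contain one record per tree node; missing: ",
         paste(missing, collapse = ", "))
  }
  m <- unclass(msa)[wanted, , drop = FALSE]
  if (any(m == "N")) stop("ambiguous base N not allowed in graph records")
  nrec <- nrow(m)
  ncols <- ncol(m)

  ## canonical partition key per column: records grouped by residue,
  ## gapped records marked so gap patterns never merge across
  part_key <- character(ncols)
  for (j in seq_len(ncols)) {
    col <- m[, j]
    grp <- match(col, unique(col[col != "-"]))
    grp[col == "-"] <- 0L
    part_key[j] <- paste(grp, collapse = ",")
  }
  run_id <- cumsum(c(TRUE, part_key[-1] != part_key[-ncols]))

  node_seq <- character(0)
  path_nodes <- vector("list", nrec)
  for (r in seq_len(nrec)) path_nodes[[r]] <- integer(0)
  for (run in unique(run_id)) {
    cols <- which(run_id == run)
    sub <- m[, cols, drop = FALSE]
    alleles <- apply(sub, 1, paste, collapse = "")
    nong <- !grepl("-", alleles, fixed = TRUE)
    ## within a run the partition is constant, so a record is either
    ## gapped at every column of the run or at none
    if (any(grepl("-", alleles[!nong], fixed = TRUE) !=
            grepl("^-+$", alleles[!nong]))) {
      stop("internal error: inconsistent gap pattern within a run")
    }
    uniq <- unique(alleles[nong])
    ids <- length(node_seq) + seq_along(uniq)
    node_seq <- c(node_seq, uniq)
    hit <- match(alleles, uniq)
    for (r in which(nong)) {
      path_nodes[[r]] <- c(path_nodes[[r]], ids[hit[r]])
    }
  }
  names(path_nodes) <- rownames(m)

  edges <- unique(do.call(rbind, lapply(path_nodes, function(p) {
    if (length(p) < 2L) return(NULL)
    cbind(from = p[-length(p)], to = p[-1])
  })))
  if (is.null(edges)) edges <- cbind(from = integer(0), to = integer(0))
  edges <- as.data.frame(edges)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  support <- vector("list", length(node_seq))
  for (r in seq_len(nrec)) {
    for (nd in path_nodes[[r]]) {
      support[[nd]] <- c(support[[nd]], rownames(m)[r])
    }
  }
  structure(
    list(
      nodes = data.frame(node = seq_along(node_seq), seq = node_seq,
                         stringsAsFactors = FALSE),
      edges = edges,
      paths = path_nodes,
      support = support
    ),
    class = "pangenome_graph"
  )
}

#' @export
print.pangenome_graph <- function(x, ...) {
  cat(sprintf("pangenome_graph: %d nodes, %d edges, %d paths\n",
              nrow(x$nodes), nrow(x$edges), length(x$paths)))
  invisible(x)
}

#' Sequence spelled by a path
#'
#' @param graph A \code{pangenome_graph}.
#' @param name Path name (tree node label).
#' @return The concatenated node sequences along the path.
#' @export
path_sequence <- function(graph, name) {
  p <- graph$paths[[name]]
  if (is.null(p)) stop("unknown path: ", name)
  paste(graph$nodes$seq[p], collapse = "")
}

## Cumulative start offset (0-based) of each node within a path sequence.
path_node_offsets <- function(graph, name) {
  p <- graph$paths[[name]]
  lens <- nchar(graph$nodes$seq[p])
  list(nodes = p, start = cumsum(c(0L, lens[-length(lens)])), len = lens)
}

#' Signature node sets
#'
#' For every reference path, the set of graph nodes supported by that
#' path alone. In analogy with signature genes in metagenomics, reads
#' touching these nodes are evidence for the presence of that specific
#' reference; their alignment frequencies drive the initial estimate of
#' the number of sources.
#'
#' @param graph A \code{pangenome_graph}.
#' @return An object of class \code{signature_index}: named list (per
#'   path) of integer node-id vectors; sets are pairwise disjoint, and
#'   every member node has path-support cardinality 1.
#' @export
compute_signature_sets <- function(graph) {
  stopifnot(inherits(graph, "pangenome_graph"))
  card <- lengths(graph$support)
  sets <- lapply(names(graph$paths), function(p) {
    which(card == 1L & vapply(graph$support, function(s) s[1] == p,
                              logical(1)))
  })
  names(sets) <- names(graph$paths)
  structure(sets, class = "signature_index")
}

#' @export
print.signature_index <- function(x, ...) {
  cat("signature_index:\n")
  for (p in names(x)) cat(sprintf("  %s: %d node(s)\n", p, length(x[[p]])))
  invisible(x)
}

#' Write the signature-node table
#'
#' @param sig A \code{signature_index}.
#' @param path Output TSV path.
#' @export
write_signature_table <- function(sig, path) {
  df <- data.frame(
    path = names(sig),
    set_size = lengths(sig),
    node_ids = vapply(sig, function(s) paste(s, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- GFA1 export / import ----------------------------------------------

#' Export a pangenome graph as GFA1
#'
#' Emits S-lines (nodes), L-lines (edges, 0M overlap) and P-lines
#' (paths). \code{import_gfa(export_gfa(g))} reproduces the graph.
#'
#' @param graph A \code{pangenome_graph}.
#' @param path Optional file path; if omitted the GFA text is returned.
#' @return The GFA text (invisibly when written to a file).
#' @export
export_gfa <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "pangenome_graph"))
  if (any(lengths(graph$paths) == 0L)) stop("empty path cannot be exported")
  lines <- c(
    "H\tVN:Z:1.0",
    sprintf("S\t%d\t%s", graph$nodes$node, graph$nodes$seq),
    if (nrow(graph$edges)) {
      sprintf("L\t%d\t+\t%d\t+\t0M", graph$edges$from, graph$edges$to)
    },
    sprintf("P\t%s\t%s\t*", names(graph$paths),
            vapply(graph$paths, function(p) paste0(p, "+", collapse = ","),
                   character(1)))
  )
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(paste(lines, collapse = "\n"))
}

#' Import a GFA1 graph
#'
#' @param x GFA text or the path of a GFA file.
#' @return A \code{pangenome_graph}.
#' @export
import_gfa <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(fields, `[`, character(1), 1)
  s <- fields[tag == "S"]
  nodes <- data.frame(
    node = as.integer(vapply(s, `[`, character(1), 2)),
    seq = vapply(s, `[`, character(1), 3),
    stringsAsFactors = FALSE
  )
  nodes <- nodes[order(nodes$node), , drop = FALSE]
  rownames(nodes) <- NULL
  l <- fields[tag == "L"]
  edges <- data.frame(
    from = as.integer(vapply(l, `[`, character(1), 2)),
    to = as.integer(vapply(l, `[`, character(1), 4))
  )
  p <- fields[tag == "P"]
  paths <- lapply(p, function(f) {
    as.integer(sub("[+-]$", "", strsplit(f[3], ",", fixed = TRUE)[[1]]))
  })
  names(paths) <- vapply(p, `[`, character(1), 2)
  if (any(lengths(paths) == 0L)) stop("empty path in GFA input")
  support <- vector("list", nrow(nodes))
  for (nm in names(paths)) {
    for (nd in paths[[nm]]) support[[nd]] <- c(support[[nd]], nm)
  }
  structure(list(nodes = nodes, edges = edges, paths = paths,
                 support = support),
            class = "pangenome_graph")
}
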