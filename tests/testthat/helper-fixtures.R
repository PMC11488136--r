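## Shared small fixtures, built in code.

## The worked toy alignment: shared prefix "AC", a G/T allele column
## (one record gapped there), shared suffix "T". Mapped onto a 2-leaf
## tree so the three records are exactly the three reference paths
## (leaves A, B and root N1).
toy_msa <- function() {
  structure(rbind(A = c("A", "C", "G", "T"),
                  B = c("A", "C", "-", "T"),
                  N1 = c("A", "C", "T", "T")),
            class = "reference_msa")
}

toy_tree <- function() {
  load_tree("(A:0.1,B:0.2);")
}

toy_graph <- function() {
  build_graph_from_msa(toy_msa(), toy_tree())
}

## Random gapless MSA over a star of n records.
random_msa <- function(n, len, gap_prob = 0, seed = 1) {
  set.seed(seed)
  rows <- t(replicate(n, sample(c("A", "C", "G", "T"), len, TRUE)))
  if (gap_prob > 0) {
    mask <- matrix(stats::runif(n * len) < gap_prob, n, len)
    ## keep at least one non-gap per column
    for (j in seq_len(len)) if (all(mask[, j])) mask[1, j] <- FALSE
    rows[mask] <- "-"
  }
  rownames(rows) <- paste0("r", seq_len(n))
  reference_msa(stats::setNames(apply(rows, 1, paste, collapse = ""),
                                rownames(rows)))
}

## A small reference database (refs + ancestral graph) reused by
## several alignment/likelihood tests.
.fix <- new.env(parent = emptyenv())

small_db <- function() {
  if (is.null(.fix$small_db)) {
    refs <- make_reference_set(4, 0.93, seed = 7, length = 1200)
    .fix$small_db <- c(list(refs = refs),
                       mitoplace:::build_reference_db(refs))
  }
  .fix$small_db
}
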