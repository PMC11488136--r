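#' Default ancient-DNA damage profile for simulations
#'
#' A Briggs-style geometric decay of terminal deamination: rate 0.25 at
#' the fragment end, halving per position over 10 positions, with a
#' residual rate of 0.01 further inside the fragment — the magnitude
#' commonly estimated from well-preserved ancient samples. Used as the
#' study condition for the simulation experiments.
#'
#' @return A \code{\link{damage_profile}}.
#' @export
default_damage_profile <- function() {
  d <- pmax(0.25 * 0.5^(0:9), 0.01)
  damage_profile(d, d, residual5 = 0.01, residual3 = 0.01)
}

#' Simulate a reference set at a target pairwise identity
#'
#' Draws a random coalescent-shaped rooted tree, rescales its branch
#' lengths so the expected mean pairwise sequence identity under the
#' HKY model matches \code{target_identity}, and simulates aligned
#' sequences (without indels) down the tree, including the true
#' ancestral sequence at every internal node. Mirrors reference sets of
#' closely related mitogenomes at a chosen divergence without any
#' download.
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param target_identity Mean pairwise identity in (0.5, 1).
#' @param seed Integer seed.
#' @param length Sequence length in bp (default 16500, a typical
#'   vertebrate mitogenome).
#' @param kappa,pi HKY parameters for the simulation (defaults:
#'   kappa 2; mitochondrial-like base composition A 0.31, C 0.25,
#'   G 0.13, T 0.31).
#' @param tol Acceptable deviation of the realized mean identity
#'   (default 0.01); simulation is retried with fresh trees up to 5
#'   times before failing.
#' @return A list of class \code{reference_set}: \code{msa} (leaf
#'   records), \code{truth_msa} (leaves + true ancestral sequences,
#'   named by the tree's node labels), \code{tree} (a
#'   \code{taxon_tree} with the rescaled branch lengths),
#'   \code{model} (the generating \code{hky_model}) and
#'   \code{realized_identity}.
#' @export
make_reference_set <- function(n_taxa, target_identity, seed,
                               length = 16500,
                               kappa = 2,
                               pi = c(0.31, 0.25, 0.13, 0.31),
                               tol = 0.01) {
  stopifnot(n_taxa >= 2)
  model <- hky_model(kappa, pi)
  floor_id <- sum(model$pi^2)
  if (target_identity <= max(0.5, floor_id) || target_identity >= 1) {
    stop("unattainable identity target: must lie in (",
         sprintf("%.2f", max(0.5, floor_id)), ", 1)")
  }
  expected_identity <- function(d) {
    vapply(d, function(di) {
      sum(model$pi * diag(hky_transition_matrix(model, di)))
    }, numeric(1))
  }
  for (attempt in 0:4) {
    set.seed(seed + attempt)
    phy <- ape::rcoal(n_taxa, tip.label = paste0("T", seq_len(n_taxa)))
    dmat <- ape::cophenetic.phylo(phy)
    pair_d <- dmat[upper.tri(dmat)]
    f <- function(s) mean(expected_identity(s * pair_d)) - target_identity
    scale <- stats::uniroot(f, c(1e-8, 200), tol = 1e-10)$root
    phy$edge.length <- phy$edge.length * scale
    tree <- taxon_tree_from_phylo(phy)
    dat <- phangorn::simSeq(phy, l = length,
                            Q = c(1, kappa, 1, 1, kappa, 1),
                            bf = model$pi, type = "DNA", ancestral = TRUE)
    chrmat <- as.character(dat)
    chr <- toupper(apply(chrmat, 1, paste, collapse = ""))
    names(chr) <- rownames(chrmat)
    ntip <- length(phy$tip.label)
    node_nums <- ntip + seq_len(phy$Nnode)
    names(chr)[match(as.character(node_nums), names(chr))] <-
      tree$labels[node_nums]
    truth <- reference_msa(chr)
    leaf <- reference_msa(chr[phy$tip.label])
    m <- unclass(leaf)
    pairs <- utils::combn(nrow(m), 2)
    ident <- mean(apply(pairs, 2, function(pr) mean(m[pr[1], ] == m[pr[2], ])))
    if (abs(ident - target_identity) <= tol) {
      return(structure(list(msa = leaf, truth_msa = truth, tree = tree,
                            model = model, realized_identity = ident),
                       class = "reference_set"))
    }
  }
  stop("could not realize the identity target within +/-", tol,
       " after 5 attempts")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf(
    "reference_set: %d leaves, %d columns, realized identity %.3f\n",
    nrow(x$msa), ncol(x$msa), x$realized_identity))
  invisible(x)
}

#' Simulate ancient DNA fragments with known truth
#'
#' Samples fragments from the chosen source sequences (mixing
#' proportions \code{sources}), with log-normal lengths, uniform start
#' positions and strands, position-dependent terminal deamination
#' (C->T by distance from the 5' end, G->A by distance from the 3'
#' end, applied on the fragment's own strand) and quality-derived
#' sequencing errors. Deterministic under \code{seed}.
#'
#' @param refs A \code{\link{make_reference_set}} result, or any list
#'   with a \code{truth_msa} \code{reference_msa}.
#' @param sources Named numeric vector of true mixture proportions;
#'   names are tree node labels (leaf or ancestral) present in
#'   \code{truth_msa}.
#' @param n Number of fragments.
#' @param profile A \code{\link{damage_profile}} (default:
#'   \code{\link{default_damage_profile}}).
#' @param seed Integer seed.
#' @param mu_len,sigma_len Log-normal fragment length parameters
#'   (defaults 3.7344 and 0.35, typical of ancient DNA).
#' @param min_len Shortest emitted fragment (default 20 bp); lengths
#'   are resampled (bounded retries) when outside
#'   \code{[min_len, reference length]}.
#' @param quality Constant Phred quality assigned to every base
#'   (default 30, i.e. error rate 0.001).
#' @return A list of class \code{sim_fragments}: \code{reads} (a
#'   \code{\link{read_set}}) and \code{truth} (data.frame with per-read
#'   source, start, length, strand, damaged- and error-base counts).
#' @export
simulate_fragments <- function(refs, sources, n,
                               profile = default_damage_profile(),
                               seed = 1, mu_len = 3.7344, sigma_len = 0.35,
                               min_len = 20, quality = 30L) {
  truth_msa <- if (inherits(refs, "reference_set")) refs$truth_msa else {
    refs$truth_msa %||% refs
  }
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    stop("sources must be a named proportion vector")
  }
  if (abs(sum(sources) - 1) > 1e-8 || any(sources < 0)) {
    stop("source proportions must be non-negative and sum to 1")
  }
  missing <- setdiff(names(sources), rownames(truth_msa))
  if (length(missing)) stop("unknown source node(s): ",
                            paste(missing, collapse = ", "))
  seqs <- lapply(names(sources), function(nm) {
    seq_to_codes(msa_record_sequence(truth_msa, nm))
  })
  names(seqs) <- names(sources)
  set.seed(seed)
  eps <- min(10^(-quality / 10), 1)
  qchar <- rawToChar(as.raw(33L + quality))
  src <- sample(names(sources), n, replace = TRUE, prob = sources)
  out_seq <- character(n)
  truth <- data.frame(read = sprintf("frag%05d", seq_len(n)), source = src,
                      start = NA_integer_, length = NA_integer_,
                      strand = NA_character_, n_damaged = NA_integer_,
                      n_errors = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ref <- seqs[[src[i]]]
    L <- length(ref)
    len <- NA
    for (try in 1:100) {
      cand <- round(stats::rlnorm(1, mu_len, sigma_len))
      if (cand >= min_len && cand <= L) { len <- cand; break }
    }
    if (is.na(len)) stop("could not draw an admissible fragment length")
    start <- sample.int(L - len + 1L, 1) - 1L
    frag <- ref[(start + 1L):(start + len)]
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    if (strand == "-") frag <- revcomp_codes(frag)
    pos <- seq_len(len) - 1L
    isC <- frag == 1L
    isG <- frag == 2L
    dam <- (isC & stats::runif(len) < delta5_at(profile, pos)) |
      (isG & stats::runif(len) < delta3_at(profile, len - 1L - pos))
    frag[dam & isC] <- 3L   # C -> T
    frag[dam & isG] <- 0L   # G -> A
    err <- stats::runif(len) < eps
    if (any(err)) {
      for (j in which(err)) {
        frag[j] <- sample(setdiff(0:3, frag[j]), 1)
      }
    }
    out_seq[i] <- codes_to_seq(frag)
    truth$start[i] <- start
    truth$length[i] <- len
    truth$strand[i] <- strand
    truth$n_damaged[i] <- sum(dam)
    truth$n_errors[i] <- sum(err)
  }
  reads <- read_set(truth$read, out_seq,
                    vapply(truth$length, function(l) {
                      strrep(qchar, l)
                    }, character(1)))
  structure(list(reads = reads, truth = truth), class = "sim_fragments")
}

#' Write a read set as FASTQ
#'
#' @param reads A \code{\link{read_set}}.
#' @param path Output path; gzip when it ends in \code{.gz}.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
             con)
  invisible(path)
}
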