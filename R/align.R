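ALIGN_EVENTS <- c("match", "mismatch", "insertion", "deletion", "softclip",
                  "unresolved")
ALIGN_FORMAT_VERSION <- "v1"

#' Read ancient DNA fragments from FASTQ
#'
#' Reads single-end (or interleaved, pre-merged) FASTQ, plain or gzip.
#' Per-base error probabilities are derived from the Phred+33 qualities
#' as \eqn{\epsilon = 10^{-Q/10}} (capped at 1).
#'
#' @param path FASTQ file path.
#' @return A list of class \code{read_set}: \code{id}, \code{seq},
#'   \code{qual} (character vectors of equal length).
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  ids <- names(ss)
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "/")
  read_set(ids, as.character(ss),
           as.character(S4Vectors::mcols(ss)$qualities))
}

#' Construct a read set from vectors
#'
#' @param id,seq,qual Equal-length character vectors (Phred+33
#'   qualities, same width as the sequences).
#' @return A \code{read_set}.
#' @export
read_set <- function(id, seq, qual) {
  id <- unname(id)
  seq <- toupper(unname(seq))
  qual <- unname(qual)
  if (length(unique(c(length(id), length(seq), length(qual)))) != 1L) {
    stop("id, seq and qual must have equal length")
  }
  if (any(nchar(seq) != nchar(qual))) {
    stop("sequence and quality strings must have equal width")
  }
  if (any(nchar(seq) < 1L)) stop("empty read")
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("read(s) with characters outside {A,C,G,T,N}: ",
         paste(utils::head(id[bad], 3), collapse = ", "))
  }
  structure(list(id = id, seq = seq, qual = qual), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads, mean length %.1f\n", length(x$id),
              mean(nchar(x$seq))))
  invisible(x)
}

#' Align fragments to the pangenome graph
#'
#' Aligns every read, in both orientations, against every reference
#' path with affine-gap local alignment (a gap of length L costs
#' \code{gap_open + L * gap_ext}), keeps the single best hit, and
#' projects it onto graph nodes and offsets. Ties between paths are
#' broken by tree pre-order (the order paths are stored in the graph);
#' orientation ties prefer forward. Per-base events are classified as
#' match, mismatch, insertion, deletion, softclip (unaligned flanks) or
#' unresolved (\code{N}). Reads whose best score falls below
#' \code{min_score_frac * read length * match} are reported unmapped.
#'
#' Damage is deliberately not modelled at the alignment stage (no
#' C/T, G/A half-matches); deamination enters only through the
#' likelihood.
#'
#' @param reads A \code{\link{read_set}} (or FASTQ path).
#' @param graph A \code{pangenome_graph}.
#' @param min_score_frac Minimum score fraction (default 0.8).
#' @param match,mismatch,gap_open,gap_ext Scoring parameters
#'   (defaults +1, -1, 2, 1).
#' @return An object of class \code{fragment_alignments}: a data.frame
#'   with one row per aligned base (columns \code{read},
#'   \code{orientation}, \code{score}, \code{event}, \code{node},
#'   \code{offset}, \code{base}, \code{eps}, \code{pos5}, \code{pos3})
#'   and attributes \code{summary} (per-read table incl. unmapped
#'   reads) and \code{scoring}.
#' @export
align_fragments <- function(reads, graph, min_score_frac = 0.8,
                            match = 1, mismatch = -1, gap_open = 2,
                            gap_ext = 1) {
  if (is.character(reads)) reads <- read_fastq(reads)
  stopifnot(inherits(reads, "read_set"), inherits(graph, "pangenome_graph"))
  if (nrow(graph$nodes) == 0L || length(graph$paths) == 0L) {
    stop("empty graph")
  }
  path_names <- names(graph$paths)
  path_codes <- lapply(path_names, function(p) {
    seq_to_codes(path_sequence(graph, p))
  })
  read_codes <- lapply(reads$seq, seq_to_codes)
  hits <- .align_reads_cpp(read_codes, path_codes, match, mismatch,
                           gap_open, gap_ext, min_score_frac)

  offmaps <- lapply(path_names, function(p) path_node_offsets(graph, p))
  rows <- vector("list", length(hits))
  summ <- data.frame(
    read = reads$id,
    mapped = vapply(hits, function(h) isTRUE(h$mapped), logical(1)),
    path = NA_character_, orientation = NA_character_, score = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(hits)) {
    h <- hits[[i]]
    if (!isTRUE(h$mapped)) next
    ev <- h$events
    L <- nchar(reads$seq[i])
    orient <- if (h$orient == 1L) "forward" else "reverse-complement"
    summ$path[i] <- path_names[h$path]
    summ$orientation[i] <- orient
    summ$score[i] <- h$score
    om <- offmaps[[h$path]]
    refp <- ev[, 2]
    nidx <- findInterval(pmax(refp, 0L), om$start)
    node <- ifelse(refp >= 0, om$nodes[nidx], NA_integer_)
    offset <- ifelse(refp >= 0, refp - om$start[nidx], NA_integer_)
    code <- ev[, 3]
    keepref <- code %in% c(0L, 1L, 3L)   # match, mismatch, deletion
    node[!keepref] <- NA_integer_
    offset[!keepref] <- NA_integer_
    rp <- ev[, 1]
    base <- rep(NA_character_, nrow(ev))
    eps <- rep(NA_real_, nrow(ev))
    hasb <- rp >= 0
    if (any(hasb)) {
      chars <- strsplit(reads$seq[i], "", fixed = TRUE)[[1]]
      base[hasb] <- chars[rp[hasb] + 1L]
      eps[hasb] <- phred_to_eps(reads$qual[i])[rp[hasb] + 1L]
    }
    rows[[i]] <- data.frame(
      read = reads$id[i],
      orientation = orient,
      score = h$score,
      event = ALIGN_EVENTS[code + 1L],
      node = node,
      offset = offset,
      base = base,
      eps = eps,
      pos5 = ifelse(rp >= 0, rp, NA_integer_),
      pos3 = ifelse(rp >= 0, L - 1L - rp, NA_integer_),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab)) {
    tab <- data.frame(read = character(), orientation = character(),
                      score = numeric(), event = character(),
                      node = integer(), offset = integer(),
                      base = character(), eps = numeric(),
                      pos5 = integer(), pos3 = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(tab) <- NULL
  structure(tab,
            summary = summ,
            scoring = list(match = match, mismatch = mismatch,
                           gap_open = gap_open, gap_ext = gap_ext,
                           min_score_frac = min_score_frac),
            class = c("fragment_alignments", "data.frame"))
}

#' @export
print.fragment_alignments <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("fragment_alignments: %d/%d reads mapped, %d aligned bases\n",
              sum(s$mapped), nrow(s), nrow(x)))
  invisible(x)
}

alignment_read_ids <- function(aln) unique(aln$read)

n_aligned_fragments <- function(aln) length(unique(aln$read))

#' Serialize alignments to a TSV table
#'
#' Lossless, versioned text representation of a
#' \code{fragment_alignments} object; the inverse of
#' \code{\link{read_alignments}}.
#'
#' @param aln A \code{fragment_alignments} object.
#' @param path Output file path.
#' @export
serialize_alignments <- function(aln, path) {
  stopifnot(inherits(aln, "fragment_alignments"))
  s <- attr(aln, "summary")
  unmapped <- s$read[!s$mapped]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#mitoplace-alignments\t", ALIGN_FORMAT_VERSION),
    paste0("#unmapped\t", paste(unmapped, collapse = ",")),
    paste(names(aln), collapse = "\t")
  ), con)
  if (nrow(aln)) {
    utils::write.table(aln, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, na = ".")
  }
  invisible(path)
}

#' Read a serialized alignment table
#'
#' @param path TSV written by \code{\link{serialize_alignments}}.
#' @return A \code{fragment_alignments} object.
#' @export
read_alignments <- function(path) {
  hdr <- readLines(path, n = 3)
  if (length(hdr) < 3 || !startsWith(hdr[1], "#mitoplace-alignments")) {
    stop("not a mitoplace alignment file")
  }
  ver <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]][2]
  if (!identical(ver, ALIGN_FORMAT_VERSION)) {
    stop("alignment file version mismatch: found ", ver,
         ", expected ", ALIGN_FORMAT_VERSION)
  }
  cols <- strsplit(hdr[3], "\t", fixed = TRUE)[[1]]
  body <- readLines(path)[-(1:3)]
  if (length(body)) {
    nf <- lengths(strsplit(body, "\t", fixed = TRUE))
    if (any(nf != length(cols))) {
      stop("truncated or malformed row(s) at line(s): ",
           paste(utils::head(which(nf != length(cols)) + 3L, 5),
                 collapse = ", "))
    }
  }
  tab <- if (length(body)) {
    utils::read.table(text = body, sep = "\t", col.names = cols,
                      na.strings = ".", stringsAsFactors = FALSE,
                      colClasses = c(read = "character",
                                     orientation = "character",
                                     score = "numeric", event = "character",
                                     node = "integer", offset = "integer",
                                     base = "character", eps = "numeric",
                                     pos5 = "integer", pos3 = "integer"))
  } else {
    data.frame(read = character(), orientation = character(),
               score = numeric(), event = character(), node = integer(),
               offset = integer(), base = character(), eps = numeric(),
               pos5 = integer(), pos3 = integer(), stringsAsFactors = FALSE)
  }
  unmapped <- strsplit(hdr[2], "\t", fixed = TRUE)[[1]][2]
  unmapped <- if (is.na(unmapped) || !nzchar(unmapped)) character(0) else {
    strsplit(unmapped, ",", fixed = TRUE)[[1]]
  }
  per_read <- unique(tab[c("read", "orientation", "score")])
  mapped_ids <- per_read$read
  ntot <- length(mapped_ids) + length(unmapped)
  summ <- data.frame(
    read = c(mapped_ids, unmapped),
    mapped = c(rep(TRUE, length(mapped_ids)), rep(FALSE, length(unmapped))),
    path = rep(NA_character_, ntot),
    orientation = c(per_read$orientation, rep(NA, length(unmapped))),
    score = c(per_read$score, rep(NA_real_, length(unmapped))),
    stringsAsFactors = FALSE
  )
  structure(tab, summary = summ, scoring = NULL,
            class = c("fragment_alignments", "data.frame"))
}
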