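#' Reference multiple sequence alignment
#'
#' Constructs the reference MSA container from named aligned sequences
#' over the alphabet \code{A,C,G,T,N,-}. All records must have equal
#' length, names must be unique, and every column must contain at least
#' one non-gap character.
#'
#' @param seqs Named character vector of aligned sequences, or the path
#'   of an aligned FASTA file.
#' @return An object of class \code{reference_msa}: a character matrix
#'   (records x columns) with record names as rownames.
#' @export
reference_msa <- function(seqs) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs)) {
    ss <- Biostrings::readDNAStringSet(seqs)
    seqs <- stats::setNames(as.character(ss), names(ss))
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all records must be named")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate record names")
  if (length(seqs) < 2L) stop("an alignment needs at least 2 records")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  bad <- setdiff(unique(as.vector(mat)), c(BASES, "N", "-"))
  if (length(bad)) stop("invalid characters in alignment: ",
                        paste(bad, collapse = ", "))
  if (any(colSums(mat != "-") == 0L)) {
    stop("every column must contain at least one non-gap character")
  }
  structure(mat, class = "reference_msa")
}

#' @export
print.reference_msa <- function(x, ...) {
  cat(sprintf("reference_msa: %d records x %d columns\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Write a reference MSA as aligned FASTA
#'
#' @param msa A \code{reference_msa}.
#' @param path Output file path.
#' @export
write_msa <- function(msa, path) {
  stopifnot(inherits(msa, "reference_msa"))
  seqs <- apply(unclass(msa), 1, paste, collapse = "")
  writeLines(paste0(">", rownames(msa), "\n", seqs), path)
  invisible(path)
}

#' Stationary base frequencies from alignment counts
#'
#' Empirical A, C, G, T frequencies across all records (gaps and
#' \code{N} ignored); the usual plug-in estimate for the HKY model's
#' stationary distribution.
#'
#' @param msa A \code{reference_msa}.
#' @return A length-4 named frequency vector summing to 1.
#' @export
msa_base_freq <- function(msa) {
  counts <- vapply(BASES, function(b) sum(msa == b), numeric(1))
  if (sum(counts) == 0) stop("alignment contains no unambiguous bases")
  counts / sum(counts)
}

## Degapped sequence of one record.
msa_record_sequence <- function(msa, name) {
  row <- unclass(msa)[name, ]
  paste(row[row != "-"], collapse = "")
}
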