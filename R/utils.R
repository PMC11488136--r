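## Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

## Integer coding used throughout: A=0, C=1, G=2, T=3, N=4.
## Complement of a 0..3 code is 3 - code.
encode_bases <- function(x) {
  stopifnot(is.character(x))
  codes <- match(x, c(BASES, "N")) - 1L
  if (anyNA(codes)) {
    bad <- unique(x[is.na(codes)])
    stop("invalid base character(s): ", paste(bad, collapse = ", "))
  }
  codes
}

decode_bases <- function(codes) c(BASES, "N")[codes + 1L]

seq_to_codes <- function(s) encode_bases(strsplit(s, "", fixed = TRUE)[[1]])

codes_to_seq <- function(codes) paste(decode_bases(codes), collapse = "")

revcomp_codes <- function(codes) {
  out <- rev(codes)
  acgt <- out < 4L
  out[acgt] <- 3L - out[acgt]
  out
}

revcomp_seq <- function(s) codes_to_seq(revcomp_codes(seq_to_codes(s)))

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

phred_to_eps <- function(qual_string) {
  q <- as.integer(charToRaw(qual_string)) - 33L
  pmin(10^(-q / 10), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
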