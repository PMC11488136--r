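#' Position-dependent deamination profile
#'
#' Post-mortem cytosine deamination is read as C->T substitutions near
#' the 5' end of a fragment and G->A substitutions near the 3' end (on
#' the opposite strand), with rates decaying with distance from the
#' fragment end. A profile stores per-position rates for the two
#' modelled channels: \code{d5[p]} is the C->T rate at distance
#' \code{p} (0-based) from the 5' end, \code{d3[p]} the G->A rate at
#' distance \code{p} from the 3' end. Positions beyond the profile
#' length use the flat residual rates.
#'
#' @param d5 Numeric vector of 5'-anchored C->T rates in \code{[0,1]}.
#' @param d3 Numeric vector of 3'-anchored G->A rates in \code{[0,1]}.
#' @param residual5,residual3 Flat rates beyond the profiled positions;
#'   default to the last profiled value of the respective channel.
#' @return An object of class \code{damage_profile}.
#' @examples
#' no_damage <- uniform_profile(0)
#' briggs_like <- damage_profile(d5 = 0.25 * 0.5^(0:9),
#'                               d3 = 0.25 * 0.5^(0:9))
#' @export
damage_profile <- function(d5, d3,
                           residual5 = d5[length(d5)],
                           residual3 = d3[length(d3)]) {
  rates <- c(d5, d3, residual5, residual3)
  if (length(d5) < 1L || length(d3) < 1L) stop("profiles need >= 1 position")
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("damage rates must lie in [0, 1]")
  }
  structure(list(d5 = as.numeric(d5), d3 = as.numeric(d3),
                 residual5 = as.numeric(residual5),
                 residual3 = as.numeric(residual3)),
            class = "damage_profile")
}

#' @export
print.damage_profile <- function(x, ...) {
  cat(sprintf(
    "damage_profile: %d positions 5' (C->T %.3f..%.3f, residual %.3f), %d positions 3' (G->A %.3f..%.3f, residual %.3f)\n",
    length(x$d5), x$d5[1], x$d5[length(x$d5)], x$residual5,
    length(x$d3), x$d3[1], x$d3[length(x$d3)], x$residual3))
  invisible(x)
}

#' Constant-rate damage profile
#'
#' Mostly a convenience for tests and sensitivity analyses: the same
#' deamination rate at every position (and as residual) on both ends.
#' \code{uniform_profile(0)} is the no-damage model.
#'
#' @param delta Deamination rate in \code{[0,1]}.
#' @param positions Number of profiled positions (default 1).
#' @return A \code{damage_profile}.
#' @export
uniform_profile <- function(delta, positions = 1L) {
  damage_profile(rep(delta, positions), rep(delta, positions),
                 residual5 = delta, residual3 = delta)
}

## Vectorized rate lookups (0-based distances from the respective end).
delta5_at <- function(profile, pos5) {
  ifelse(pos5 < length(profile$d5), profile$d5[pmin(pos5, length(profile$d5) - 1L) + 1L],
         profile$residual5)
}

delta3_at <- function(profile, pos3) {
  ifelse(pos3 < length(profile$d3), profile$d3[pmin(pos3, length(profile$d3) - 1L) + 1L],
         profile$residual3)
}

#' Per-base damage probability
#'
#' The probability that a source base \code{source_base} is observed
#' (pre-sequencing-error) as \code{observed_base} given the fragment
#' position: \code{delta} for C->T at distance \code{pos5} from the 5'
#' end and for G->A at distance \code{pos3} from the 3' end;
#' \code{1 - delta} for C->C and G->G; 1 for A->A and T->T; 0 for every
#' other base pair.
#'
#' @param profile A \code{damage_profile}.
#' @param pos5,pos3 0-based distances of the base from the fragment's
#'   5' and 3' ends.
#' @param source_base,observed_base Single characters in A,C,G,T.
#' @return A probability.
#' @export
delta_at <- function(profile, pos5, pos3, source_base, observed_base) {
  stopifnot(inherits(profile, "damage_profile"), pos5 >= 0, pos3 >= 0)
  damage_matrix(profile, pos5, pos3)[source_base, observed_base]
}

## Row-stochastic 4x4 damage matrix (rows = source, cols = observed).
damage_matrix <- function(profile, pos5, pos3) {
  d5 <- delta5_at(profile, pos5)
  d3 <- delta3_at(profile, pos3)
  D <- diag(4)
  dimnames(D) <- list(BASES, BASES)
  D["C", "C"] <- 1 - d5
  D["C", "T"] <- d5
  D["G", "G"] <- 1 - d3
  D["G", "A"] <- d3
  D
}

#' Read a damage profile from TSV files
#'
#' Each file is a tab-separated table with a header; rows are positions
#' (row 1 = distance 0 from the respective fragment end). The 5' file
#' must contain a C->T rate column and the 3' file a G->A rate column;
#' column-name variants such as \code{C>T}, \code{C.T} or \code{CtoT}
#' are accepted, so 12-substitution tables in the style of bam2prof
#' reduce to their two modelled channels and extra columns are ignored.
#' Rates beyond the table use the last row as flat residual.
#'
#' @param path5 TSV of 5'-anchored rates (positions from the 5' end).
#' @param path3 TSV of 3'-anchored rates (positions from the 3' end);
#'   defaults to \code{path5} for single-file profiles carrying both
#'   columns.
#' @return A \code{damage_profile}.
#' @export
read_damage_profile <- function(path5, path3 = path5) {
  pick <- function(path, keys, channel) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, comment.char = "")
    norm <- toupper(gsub("[^A-Za-z]", "", names(df)))
    hit <- which(norm %in% keys)
    if (length(hit) == 0L) {
      stop("missing required column (", channel, ") in ", path)
    }
    v <- as.numeric(df[[hit[1]]])
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      stop("damage rate outside [0,1] in ", path)
    }
    v
  }
  d5 <- pick(path5, c("CT", "CTOT"), "C->T")
  d3 <- pick(path3, c("GA", "GTOA"), "G->A")
  damage_profile(d5, d3)
}

#' Write a damage profile to TSV files
#'
#' Inverse of \code{\link{read_damage_profile}}; writes one table per
#' end with columns \code{pos}, \code{C>T}, \code{G>A} (the unmodelled
#' channel is written as zero for format compatibility).
#'
#' @param profile A \code{damage_profile}.
#' @param path5,path3 Output TSV paths.
#' @export
write_damage_profile <- function(profile, path5, path3) {
  tab5 <- data.frame(pos = seq_along(profile$d5) - 1L,
                     `C>T` = profile$d5, `G>A` = 0,
                     check.names = FALSE)
  tab3 <- data.frame(pos = seq_along(profile$d3) - 1L,
                     `C>T` = 0, `G>A` = profile$d3,
                     check.names = FALSE)
  utils::write.table(tab5, path5, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tab3, path3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path5, path3))
}
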