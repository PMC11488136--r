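#' HKY85 substitution model
#'
#' Defines the nucleotide substitution model used for both ancestral
#' reconstruction and the placement likelihood: transitions
#' (A<->G, C<->T) occur at rate \code{kappa} relative to transversions,
#' with stationary base frequencies \code{pi}. The rate matrix is
#' normalized so that branch lengths are expected substitutions per site.
#'
#' @param kappa Transition/transversion rate ratio (> 0). Default 2,
#'   reflecting the strong transition bias of mitochondrial DNA.
#' @param pi Stationary base frequencies in A, C, G, T order; strictly
#'   positive, summing to 1 (renormalized if slightly off).
#' @return An object of class \code{hky_model}.
#' @examples
#' m <- hky_model(kappa = 2, pi = c(0.31, 0.25, 0.13, 0.31))
#' hky_transition_matrix(m, 0.1)
#' @export
hky_model <- function(kappa = 2, pi = rep(0.25, 4)) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa <= 0) {
    stop("kappa must be a single finite positive number")
  }
  if (length(pi) != 4L || any(!is.finite(pi)) || any(pi <= 0)) {
    stop("pi must be 4 strictly positive frequencies")
  }
  pi <- pi / sum(pi)
  names(pi) <- BASES
  structure(list(kappa = kappa, pi = pi), class = "hky_model")
}

#' @export
print.hky_model <- function(x, ...) {
  cat(sprintf("HKY85 model: kappa = %g, pi = (%s)\n", x$kappa,
              paste(sprintf("%s=%.4f", BASES, x$pi), collapse = ", ")))
  invisible(x)
}

## Normalized HKY rate matrix (rows = from, A,C,G,T order).
hky_rate_matrix <- function(model) {
  k <- model$kappa
  pi <- model$pi
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    transition <- (BASES[i] %in% c("A", "G") && BASES[j] %in% c("A", "G")) ||
      (BASES[i] %in% c("C", "T") && BASES[j] %in% c("C", "T"))
    Q[i, j] <- pi[j] * if (transition) k else 1
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))   # expected rate; normalize to 1 per unit length
  Q / mu
}

#' HKY85 transition probability matrix
#'
#' Closed-form transition probabilities \eqn{P(t)} under the normalized
#' HKY85 model (the equal-transition-rate special case of TN93), for a
#' branch of length \code{t} expected substitutions per site.
#'
#' @param model An \code{\link{hky_model}}.
#' @param t Branch length (>= 0).
#' @return A 4x4 row-stochastic matrix in A, C, G, T order; rows index
#'   the ancestral base, columns the descendant base. \code{P(0)} is the
#'   identity and rows converge to \code{pi} as \code{t} grows.
#' @export
hky_transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "hky_model"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("t must be a single finite non-negative branch length")
  }
  pi <- model$pi
  k <- model$kappa
  piR <- pi[["A"]] + pi[["G"]]
  piY <- pi[["C"]] + pi[["T"]]
  ## rate scale: mean rate of the unnormalized matrix (beta = 1)
  mu <- 2 * k * (pi[["A"]] * pi[["G"]] + pi[["C"]] * pi[["T"]]) +
    2 * piR * piY
  bt <- t / mu
  e2 <- exp(-bt)
  eR <- exp(-bt * (1 + piR * (k - 1)))
  eY <- exp(-bt * (1 + piY * (k - 1)))
  P <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (i in BASES) for (j in BASES) {
    jR <- j %in% c("A", "G")
    piC <- if (jR) piR else piY
    eC <- if (jR) eR else eY
    iR <- i %in% c("A", "G")
    if (iR == jR) {
      if (i == j) {
        P[i, j] <- pi[j] + pi[j] * (1 / piC - 1) * e2 +
          ((piC - pi[j]) / piC) * eC
      } else {
        P[i, j] <- pi[j] + pi[j] * (1 / piC - 1) * e2 - (pi[j] / piC) * eC
      }
    } else {
      P[i, j] <- pi[j] * (1 - e2)
    }
  }
  P
}
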