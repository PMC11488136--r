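random_hky <- function() {
  hky_model(runif(1, 0.5, 8), prop.table(runif(4, 0.05, 1)))
}

test_that("HKY transition matrices match the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  m0 <- hky_model(2, c(0.31, 0.25, 0.13, 0.31))
  expect_equal(hky_transition_matrix(m0, 0), diag(4),
               ignore_attr = TRUE)
  ## Jukes-Cantor specialization in closed form
  jc <- hky_model(1, rep(0.25, 4))
  for (t in c(0.01, 0.3, 1.5)) {
    P <- hky_transition_matrix(jc, t)
    expect_equal(unname(diag(P)), rep(1 / 4 + 3 / 4 * exp(-4 * t / 3), 4),
                 tolerance = 1e-12)
  }
  set.seed(61)
  for (i in 1:20) {
    m <- random_hky()
    t <- runif(1, 0, 3)
    P <- hky_transition_matrix(m, t)
    Q <- mitoplace:::hky_rate_matrix(m)
    expect_lt(max(abs(P - as.matrix(Matrix::expm(Q * t)))), 1e-10)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
    ## detailed balance and convergence to stationarity
    expect_lt(max(abs(m$pi * P - t(m$pi * P))), 1e-12)
    Pinf <- hky_transition_matrix(m, 500)
    for (r in 1:4) expect_equal(unname(Pinf[r, ]), unname(m$pi),
                                tolerance = 1e-6)
  }
  expect_error(hky_transition_matrix(m0, -0.1), "non-negative")
})

test_that("unsupported-base probability follows the 6/7 error, 1/7 match mix", {
  ## algebraic limit as the error rate vanishes
  expect_equal(base_prob_unsupported(1e-12), 1 / 7, tolerance = 1e-10)
  ## both terms equal at eps = 3/4
  expect_equal(base_prob_unsupported(3 / 4), 1 / 4)
  ## the derivative of (6/7)(eps/3) + (1/7)(1 - eps) is +1/7: the
  ## mixture rises linearly from 1/7 toward 2/7 as quality degrades
  eps <- seq(0.001, 1, length.out = 50)
  expect_true(all(abs(diff(base_prob_unsupported(eps)) /
                        diff(eps) - 1 / 7) < 1e-12))
})

test_that("aligned-base probability equals the 16-term enumeration oracle", {
  ## identity at t = 0 with no damage and no error
  m <- hky_model(2, rep(0.25, 4))
  ab <- list(event = "match", base = "C", bg = "C", eps = 0, pos5 = 3,
             pos3 = 20)
  expect_equal(base_prob_aligned(m, uniform_profile(0), 0, ab), 1)
  ## only the damage channel contributes
  prof <- damage_profile(d5 = c(0.3), d3 = c(0.0), residual5 = 0.3,
                         residual3 = 0)
  ab2 <- list(event = "mismatch", base = "T", bg = "C", eps = 0, pos5 = 0,
              pos3 = 20)
  expect_equal(base_prob_aligned(m, prof, 0, ab2), 0.3)

  ## exhaustive enumeration over the 16 (b_s, b_d) pairs
  set.seed(71)
  B <- c("A", "C", "G", "T")
  for (i in 1:25) {
    m <- random_hky()
    prof <- damage_profile(d5 = runif(4), d3 = runif(4))
    t <- runif(1, 0, 0.5)
    eps <- runif(1, 0, 0.3)
    pos5 <- sample(0:6, 1); pos3 <- sample(0:6, 1)
    bg <- sample(B, 1); b <- sample(B, 1)
    P <- hky_transition_matrix(m, t)
    D <- mitoplace:::damage_matrix(prof, pos5, pos3)
    brute <- 0
    for (bs in B) for (bd in B) {
      brute <- brute + P[bg, bs] * D[bs, bd] *
        (if (bd == b) 1 - eps else eps / 3)
    }
    ab <- list(event = "match", base = b, bg = bg, eps = eps,
               pos5 = pos5, pos3 = pos3)
    expect_equal(base_prob_aligned(m, prof, t, ab), brute,
                 tolerance = 1e-12)
  }
  ## indels and clips use their fixed probabilities
  expect_equal(base_prob_aligned(m, prof, 0.1,
                                 list(event = "insertion")), 0.02)
  expect_equal(base_prob_aligned(m, prof, 0.1,
                                 list(event = "deletion"),
                                 indel_prob = 0.05), 0.05)
  expect_equal(base_prob_aligned(m, prof, 0.1,
                                 list(event = "softclip", eps = 0.3)), 0.1)
  expect_error(base_prob_aligned(m, prof, 0.1,
                                 list(event = "match", base = "A",
                                      bg = NA, eps = 0)), "b_g")
})

test_that("observed-base distribution sums to one for match events", {
  set.seed(81)
  for (i in 1:15) {
    m <- random_hky()
    prof <- damage_profile(d5 = runif(3), d3 = runif(3))
    t <- runif(1, 0, 1)
    eps <- runif(1, 0, 0.5)
    for (bg in c("A", "C", "G", "T")) {
      tot <- sum(vapply(c("A", "C", "G", "T"), function(b) {
        base_prob_aligned(m, prof, t,
                          list(event = if (b == bg) "match" else "mismatch",
                               base = b, bg = bg, eps = eps,
                               pos5 = 1, pos3 = 2))
      }, numeric(1)))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

## small alignment fixture on the toy graph: one two-base fragment
## anchored on the shared "AC" node.
toy_aln <- function(bases = c("A", "C"), eps = 0.001) {
  structure(
    data.frame(read = "f1", orientation = "forward", score = 2,
               event = ifelse(bases == c("A", "C"), "match", "mismatch"),
               node = 1L, offset = c(0L, 1L), base = bases, eps = eps,
               pos5 = 0:1, pos3 = 1:0, stringsAsFactors = FALSE),
    class = c("fragment_alignments", "data.frame"))
}

test_that("fragment likelihood is the stated affine combination in beta", {
  g <- toy_graph()
  tr <- toy_tree()
  m <- hky_model(2, c(0.3, 0.2, 0.2, 0.3))
  prof <- damage_profile(d5 = c(0.2, 0.1), d3 = c(0.15, 0.05))
  aln <- toy_aln()
  ## beta = 1: only the derived-node product, at distance 0
  plc1 <- placement(tr, "A", 1)
  ll1 <- fragment_loglik(aln, plc1, g, m, prof)
  pd <- vapply(1:2, function(q) {
    base_prob_aligned(m, prof, 0, list(event = aln$event[q],
                                       base = aln$base[q], bg = c("A", "C")[q],
                                       eps = aln$eps[q], pos5 = aln$pos5[q],
                                       pos3 = aln$pos3[q]))
  }, numeric(1))
  expect_equal(ll1, sum(log(pd)), tolerance = 1e-12)

  ## beta = 0.5 equals the hand-built two-term average
  plc <- placement(tr, "A", 0.5)
  t <- plc$t
  pa <- vapply(1:2, function(q) {
    base_prob_aligned(m, prof, 0.5 * t,
                      list(event = aln$event[q], base = aln$base[q],
                           bg = c("A", "C")[q], eps = aln$eps[q],
                           pos5 = aln$pos5[q], pos3 = aln$pos3[q]))
  }, numeric(1))
  pdh <- vapply(1:2, function(q) {
    base_prob_aligned(m, prof, 0.5 * t,
                      list(event = aln$event[q], base = aln$base[q],
                           bg = c("A", "C")[q], eps = aln$eps[q],
                           pos5 = aln$pos5[q], pos3 = aln$pos3[q]))
  }, numeric(1))
  expect_equal(fragment_loglik(aln, plc, g, m, prof),
               log(0.5 * prod(pa) + 0.5 * prod(pdh)), tolerance = 1e-12)

  ## across a beta grid the likelihood is the affine combination of the
  ## two per-node products evaluated at the beta-dependent distances
  ## t_A = beta t and t_D = (1 - beta) t
  prod_at <- function(tt) {
    prod(vapply(1:2, function(q) {
      base_prob_aligned(m, prof, tt,
                        list(event = aln$event[q], base = aln$base[q],
                             bg = c("A", "C")[q], eps = aln$eps[q],
                             pos5 = aln$pos5[q], pos3 = aln$pos3[q]))
    }, numeric(1)))
  }
  for (b in seq(0, 1, length.out = 11)) {
    lb <- exp(fragment_loglik(aln, placement(tr, "A", b), g, m, prof))
    expect_equal(lb, (1 - b) * prod_at(b * t) + b * prod_at((1 - b) * t),
                 tolerance = 1e-9)
  }
})

test_that("beta endpoints use only one node's quantities", {
  g <- toy_graph()
  tr <- toy_tree()
  m <- hky_model(2, rep(0.25, 4))
  prof <- uniform_profile(0)
  ## a fragment touching the G allele: supported by path A only
  gnode <- which(g$nodes$seq == "G")
  aln <- structure(
    data.frame(read = "f1", orientation = "forward", score = 1,
               event = "match", node = gnode, offset = 0L, base = "G",
               eps = 0.001, pos5 = 0, pos3 = 0, stringsAsFactors = FALSE),
    class = c("fragment_alignments", "data.frame"))
  ## branch N1 -> A: beta = 1 is path A (supported, prob ~ 1 - eps);
  ## beta = 0 is the root path N1 (unsupported mixture)
  llA <- fragment_loglik(aln, placement(tr, "A", 1), g, m, prof)
  llN <- fragment_loglik(aln, placement(tr, "A", 0), g, m, prof)
  expect_equal(llA, log(1 - 0.001), tolerance = 1e-9)
  expect_equal(llN, log(base_prob_unsupported(0.001)), tolerance = 1e-9)
})

test_that("mixture likelihood marginalizes sources like the assignment oracle", {
  g <- toy_graph()
  tr <- toy_tree()
  m <- hky_model(2, rep(0.25, 4))
  prof <- uniform_profile(0.1)
  ## two fragments
  aln <- structure(
    data.frame(read = c("f1", "f1", "f2"),
               orientation = "forward", score = c(2, 2, 1),
               event = c("match", "match", "mismatch"),
               node = c(1L, 1L, 3L), offset = c(0L, 1L, 0L),
               base = c("A", "C", "T"), eps = 0.01,
               pos5 = c(0L, 1L, 0L), pos3 = c(1L, 0L, 0L),
               stringsAsFactors = FALSE),
    class = c("fragment_alignments", "data.frame"))
  p1 <- placement(tr, "A", 0.8)
  p2 <- placement(tr, "B", 0.3)
  theta <- c(0.6, 0.4)
  mix <- mixture_model(theta, list(p1, p2))
  got <- mixture_loglik(aln, mix, g, m, prof)
  ## exhaustive sum over the 4 read-to-source assignments
  f1 <- c(exp(fragment_loglik(aln, p1, g, m, prof, read_id = "f1")),
          exp(fragment_loglik(aln, p2, g, m, prof, read_id = "f1")))
  f2 <- c(exp(fragment_loglik(aln, p1, g, m, prof, read_id = "f2")),
          exp(fragment_loglik(aln, p2, g, m, prof, read_id = "f2")))
  brute <- 0
  for (a1 in 1:2) for (a2 in 1:2) {
    brute <- brute + theta[a1] * f1[a1] * theta[a2] * f2[a2]
  }
  expect_equal(got, log(brute), tolerance = 1e-12)

  ## k = 1 reduces to the sum of fragment log-likelihoods
  mix1 <- mixture_model(1, list(p1))
  expect_equal(mixture_loglik(aln, mix1, g, m, prof),
               fragment_loglik(aln, p1, g, m, prof, read_id = "f1") +
                 fragment_loglik(aln, p1, g, m, prof, read_id = "f2"))

  ## identical placements make theta irrelevant
  mixa <- mixture_model(c(0.9, 0.1), list(p1, p1))
  mixb <- mixture_model(c(0.2, 0.8), list(p1, p1))
  expect_equal(mixture_loglik(aln, mixa, g, m, prof),
               mixture_loglik(aln, mixb, g, m, prof))

  ## label switching invariance
  mix_sw <- mixture_model(rev(theta), list(p2, p1))
  expect_equal(mixture_loglik(aln, mix_sw, g, m, prof), got)

  ## a zero-weight source changes nothing
  mix0 <- mixture_model(c(theta, 0), list(p1, p2, placement(tr, "B", 0.9)))
  expect_equal(mixture_loglik(aln, mix0, g, m, prof), got)

  ## off-simplex weights are rejected
  expect_error(mixture_model(c(0.6, 0.5), list(p1, p2)), "sum to 1")
})
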