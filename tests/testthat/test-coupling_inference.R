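test_that("analytic pseudo-likelihood gradient matches central finite differences", {
  aln <- msa(paste0("s", 1:3), c("ACDE", "ACDF", "GCDE"))
  w <- c(1, 0.6, 1.3)
  npar <- 4 * 21 + choose(4, 2) * 441
  set.seed(5)
  theta <- rnorm(npar) * 0.1
  an <- plm_objective(aln, w, theta)
  idx <- sample(npar, 60)   # random subset of coordinates, h and J both hit
  idx <- c(idx, 1:5)
  h <- 1e-5
  for (k in idx) {
    e <- rep(0, npar); e[k] <- h
    fd <- (plm_objective(aln, w, theta + e)$value -
             plm_objective(aln, w, theta - e)$value) / (2 * h)
    expect_equal(an$gradient[k], fd,
                 tolerance = 1e-5 * max(1, abs(fd)))
  }
})

test_that("the fit is deterministic and its optimum is scale-consistent", {
  aln <- random_alignment(8, 6, seed = 2)
  w <- runif(8, 0.5, 1.5)
  m1 <- fit_plm(aln, w, lfactor = 0.2, lambda_single = 0.01, maxit = 200)
  m2 <- fit_plm(aln, w, lfactor = 0.2, lambda_single = 0.01, maxit = 200)
  expect_identical(m1$h, m2$h)
  expect_identical(m1$J, m2$J)
  expect_true(is.finite(m1$fit_meta$objective))
  expect_true(m1$fit_meta$converged)

  # objective homogeneity: scaling weights and both penalties by c > 0
  # rescales the objective but leaves the optimum unchanged
  cfac <- 2.5
  m3 <- fit_plm(aln, w * cfac, lfactor = 0.2 * cfac,
                lambda_single = 0.01 * cfac, maxit = 200)
  expect_equal(m3$h, m1$h, tolerance = 1e-3)
  expect_equal(max(abs(m3$J - m1$J)), 0, tolerance = 1e-3)
  expect_equal(m3$fit_meta$objective, cfac * m1$fit_meta$objective,
               tolerance = 1e-6)

  expect_error(fit_plm(aln, rep(0, 8)), "zero")
  expect_error(fit_plm(aln, runif(5)), "length")
})

test_that("coupling scores are a gauge-invariant Frobenius norm over amino-acid states", {
  L <- 4; q <- 21
  model <- structure(list(h = matrix(0, L, q), J = matrix(0, L * q, L * q),
                          L = L, q = q,
                          regularization = c(lambda_single = 0.01,
                                             lfactor = 0.2, lambda_pair = 0.6),
                          weights_method = "uniform",
                          fit_meta = list()), class = "potts_model")
  s0 <- coupling_scores(model)
  expect_equal(s0$scores, matrix(0, L, L))
  expect_equal(s0$variant, "raw")

  # a single off-diagonal block: score equals the brute-force centered norm
  set.seed(3)
  B <- matrix(rnorm(441), q, q)
  model$J[1:q, (q + 1):(2 * q)] <- B
  model$J[(q + 1):(2 * q), 1:q] <- t(B)
  s1 <- coupling_scores(model)
  B20 <- B[1:20, 1:20]
  Bc <- B20 - rowMeans(B20)[row(B20)] - colMeans(B20)[col(B20)] + mean(B20)
  expect_equal(s1$scores[1, 2], sqrt(sum(Bc^2)), tolerance = 1e-12)
  expect_equal(s1$scores, t(s1$scores))
  expect_equal(unname(diag(s1$scores)), rep(0, L))

  # additive gauge shifts g(a) + f(b) leave the score untouched
  g <- rnorm(20); f <- rnorm(20)
  B2 <- B
  B2[1:20, 1:20] <- B2[1:20, 1:20] + outer(g, rep(1, 20)) + outer(rep(1, 20), f)
  model$J[1:q, (q + 1):(2 * q)] <- B2
  model$J[(q + 1):(2 * q), 1:q] <- t(B2)
  s2 <- coupling_scores(model)
  expect_equal(s2$scores[1, 2], s1$scores[1, 2], tolerance = 1e-10)
})

test_that("APC annihilates product structure and constant matrices", {
  set.seed(7)
  L <- 30
  a <- runif(L, 0.5, 2)
  S <- outer(a, a)
  diag(S) <- 0
  corrected <- apc_correct(coupling_matrix(S, "raw"))
  expect_equal(corrected$variant, "apc")
  # APC removes rank-one structure up to O(1/L) diagonal-exclusion effects
  expect_lt(max(abs(corrected$scores)), max(S) * 5 / L)

  Sc <- matrix(1, 10, 10); diag(Sc) <- 0
  expect_equal(apc_correct(coupling_matrix(Sc, "raw"))$scores,
               matrix(0, 10, 10), tolerance = 1e-12)

  # permutation equivariance
  S2 <- abs(matrix(rnorm(64), 8, 8)); S2 <- S2 + t(S2); diag(S2) <- 0
  p <- sample(8)
  left <- apc_correct(coupling_matrix(S2[p, p], "raw"))$scores
  right <- apc_correct(coupling_matrix(S2, "raw"))$scores[p, p]
  expect_equal(left, right, tolerance = 1e-12)

  expect_error(apc_correct(corrected), "raw")
  expect_warning(z <- apc_correct(coupling_matrix(matrix(0, 4, 4), "raw")),
                 "no-op")
})

test_that("entropy correction regresses out sqrt-entropy products", {
  aln <- random_alignment(12, 8, seed = 4, gap_frac = 0.1)
  w <- uniform_weights(aln)
  ent <- column_entropies(aln, w)
  E <- sqrt(outer(ent, ent))

  # scores exactly equal to the entropy surface vanish (alpha = 1)
  S <- E; diag(S) <- 0
  ec <- entropy_correct(coupling_matrix(S, "raw"), aln, w)
  expect_equal(ec$variant, "entropy")
  expect_equal(ec$scores[upper.tri(S)], -E[upper.tri(S)] + S[upper.tri(S)],
               tolerance = 1e-10)
  expect_lt(max(abs(ec$scores[upper.tri(S)])), 1e-10)

  # alpha recovery: scores c*E + noise give residuals centered like the noise
  set.seed(11)
  noise <- matrix(rnorm(64, sd = 0.01), 8, 8); noise <- (noise + t(noise)) / 2
  S2 <- 3 * E + noise; diag(S2) <- 0
  ec2 <- entropy_correct(coupling_matrix(S2, "raw"), aln, w)
  ut <- upper.tri(S2)
  alpha_hat <- sum((S2[ut] - ec2$scores[ut]) * E[ut]) / sum(E[ut]^2)
  expect_equal(alpha_hat, 3, tolerance = 0.05)

  # constant columns: zero entropy everywhere, correction is the identity
  const <- msa(c("a", "b", "c"), rep("AAAA", 3))
  Sr <- matrix(0.5, 4, 4); diag(Sr) <- 0
  expect_warning(
    ec3 <- entropy_correct(coupling_matrix(Sr, "raw"), const,
                           uniform_weights(const)),
    "constant")
  expect_equal(ec3$scores, Sr)
})

test_that("no-covariation alignments yield no stable score signal", {
  # i.i.d. columns: after fitting, the largest Frobenius score should be of
  # the same order as scores from a column-permuted null of the same data
  aln <- random_alignment(30, 10, seed = 13)
  w <- uniform_weights(aln)
  m <- fit_plm(aln, w, maxit = 150)
  s <- coupling_scores(m)$scores

  set.seed(14)
  X <- msa_matrix(aln)
  Xp <- apply(X, 2, sample)  # permute within columns: kills residual pairing
  rows <- apply(Xp, 1, function(r)
    paste(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")[r], collapse = ""))
  alnp <- msa(aln$ids, rows)
  sp <- coupling_scores(fit_plm(alnp, w, maxit = 150))$scores

  med_null <- median(sp[upper.tri(sp)])
  expect_lt(max(s[upper.tri(s)]), 10 * med_null)
})

test_that("score matrices and tidy tables round-trip through files", {
  set.seed(21)
  S <- abs(matrix(rnorm(36), 6, 6)); S <- S + t(S); diag(S) <- 0
  cm <- coupling_matrix(S, "raw")
  f <- withr::local_tempfile(fileext = ".mat")
  write_coupling_matrix(cm, f)
  back <- read_coupling_matrix(f)
  expect_equal(back$scores, cm$scores, tolerance = 1e-6)

  apc <- apc_correct(cm)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_coupling_tsv(cm, tsv, apc = apc)
  tab <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), choose(6, 2))
  expect_true(all(tab$i < tab$j))
  k <- which(tab$i == 2 & tab$j == 5)
  expect_equal(tab$raw[k], S[2, 5], tolerance = 1e-6)
  expect_equal(tab$apc[k], apc$scores[2, 5], tolerance = 1e-6)
})
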