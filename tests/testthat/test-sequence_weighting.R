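test_that("uniform weights are all ones with effective N = n", {
  aln <- random_alignment(5, 12, seed = 1)
  w <- uniform_weights(aln)
  expect_equal(unname(w$values), rep(1, 5))
  expect_equal(effective_n(w), 5)
  expect_equal(gini(w), 0)
  expect_equal(unname(uniform_weights(random_alignment(1, 4, seed = 2))$values), 1)
})

test_that("identity-threshold weights reproduce the published two-sequence cases", {
  expect_equal(unname(identity_threshold_weights(two_seq_alignment(1), 0.8)$values),
               c(0.5, 0.5))   # 99% identity pair
  expect_equal(unname(identity_threshold_weights(two_seq_alignment(19), 0.8)$values),
               c(0.5, 0.5))   # 81% identity pair: same weight despite distance
  expect_equal(unname(identity_threshold_weights(two_seq_alignment(21), 0.8)$values),
               c(1.0, 1.0))   # 79% identity pair: below threshold, independent
  expect_error(identity_threshold_weights(two_seq_alignment(1), 0), "lambda")
})

test_that("k identical copies each get weight 1/k and effective N 1", {
  for (k in c(2, 5, 9)) {
    aln <- msa(paste0("s", 1:k), rep("ACDEFGHIKL", k))
    w <- identity_threshold_weights(aln, 0.8)
    expect_equal(unname(w$values), rep(1 / k, k))
    expect_equal(effective_n(w), 1)
  }
})

test_that("similarity-adjusted weights reproduce the published values and bounds", {
  w99 <- similarity_adjusted_weights(two_seq_alignment(1), 0.8)
  expect_equal(unname(w99$values), rep(1 / (1 + 0.95), 2), tolerance = 1e-12)
  expect_equal(round(unname(w99$values)[1], 3), 0.513)
  w81 <- similarity_adjusted_weights(two_seq_alignment(19), 0.8)
  expect_equal(unname(w81$values), rep(1 / (1 + 0.05), 2), tolerance = 1e-12)
  expect_equal(round(unname(w81$values)[1], 2), 0.95)
  # lambda = 1 makes the adjustment undefined and must be rejected
  expect_error(similarity_adjusted_weights(two_seq_alignment(1), 1), "lambda")
})

test_that("similarity-adjusted weights dominate threshold weights termwise", {
  for (seed in 1:4) {
    aln <- random_alignment(12, 25, seed = seed, gap_frac = 0.05)
    for (lam in c(0.2, 0.5, 0.8)) {
      wt <- identity_threshold_weights(aln, lam)$values
      ws <- similarity_adjusted_weights(aln, lam)$values
      expect_true(all(ws >= wt - 1e-12))
      expect_true(all(ws > 0 & ws <= 1))
    }
  }
})

test_that("the two identity methods agree when identities are only 1 or < lambda", {
  # three exact duplicates plus two unrelated sequences: I_adj is 0/1 valued
  aln <- msa(paste0("s", 1:5),
             c(rep("AAAAAAAAAA", 3), "CDEFGHIKLM", "NPQRSTVWYA"))
  wt <- identity_threshold_weights(aln, 0.8)$values
  ws <- similarity_adjusted_weights(aln, 0.8)$values
  expect_equal(ws, wt)
  expect_equal(unname(wt), c(1/3, 1/3, 1/3, 1, 1))
})

test_that("duplicating every sequence halves identity weights, preserving Neff", {
  for (seed in 1:3) {
    aln <- random_alignment(6, 30, seed = seed)
    dup <- msa(c(aln$ids, paste0(aln$ids, "_dup")), c(aln$rows, aln$rows))
    for (fun in list(identity_threshold_weights, similarity_adjusted_weights)) {
      w1 <- fun(aln, 0.8)
      w2 <- fun(dup, 0.8)
      expect_equal(unname(w2$values), rep(unname(w1$values) / 2, 2),
                   tolerance = 1e-12)
      expect_equal(effective_n(w2), effective_n(w1), tolerance = 1e-12)
    }
  }
})

test_that("weights reduce to uniform when no pair reaches the threshold", {
  aln <- random_alignment(8, 40, seed = 5)
  D <- identity_matrix(aln)
  lam <- max(D[upper.tri(D)]) + 0.01
  expect_equal(unname(identity_threshold_weights(aln, lam)$values), rep(1, 8))
  expect_equal(unname(similarity_adjusted_weights(aln, lam)$values), rep(1, 8))
})

test_that("Henikoff weights follow the position-based procedure", {
  # single column {A, A, C}: A's half-share splits over two rows
  aln <- msa(c("p", "q", "r"), c("A", "A", "C"))
  expect_equal(unname(henikoff_weights(aln)$values), c(0.25, 0.25, 0.5))

  # gap-free alignments: raw weights sum to the alignment length
  for (seed in 1:3) {
    aln <- random_alignment(7, 23, seed = seed)
    expect_equal(effective_n(henikoff_weights(aln)), aln$L, tolerance = 1e-12)
  }

  # identical gap-free sequences share weight equally
  same <- msa(paste0("s", 1:4), rep("ACDE", 4))
  expect_equal(unname(henikoff_weights(same)$values), rep(1, 4))

  # gap handling: gapped rows receive nothing from that column, and the
  # column's weight shrinks with its gap fraction
  g <- msa(c("a", "b", "c", "d"), c("A", "A", "C", "-"))
  wg <- henikoff_weights(g)$values
  expect_equal(unname(wg), c(0.75 / 2 / 2, 0.75 / 2 / 2, 0.75 / 2, 0))
  allgap <- msa(c("a", "b"), c("A-", "--"))
  expect_equal(unname(henikoff_weights(allgap)$values)[2], 0)
})

test_that("permuting sequence order permutes weights identically", {
  aln <- random_alignment(9, 20, seed = 8, gap_frac = 0.1)
  set.seed(99)
  perm <- sample(aln$n)
  paln <- msa(aln$ids[perm], aln$rows[perm])
  for (fun in list(function(a) identity_threshold_weights(a, 0.8),
                   function(a) similarity_adjusted_weights(a, 0.8),
                   henikoff_weights)) {
    expect_equal(unname(fun(paln)$values), unname(fun(aln)$values[perm]),
                 tolerance = 1e-12)
  }
})

test_that("weight files round-trip in alignment order", {
  aln <- random_alignment(6, 15, seed = 3)
  w <- identity_threshold_weights(aln, 0.8)
  f <- withr::local_tempfile(fileext = ".txt")
  write_weight_file(w, f)
  back <- read_weight_file(f, aln)
  expect_equal(back, w$values, tolerance = 1e-15)
  expect_error(read_weight_file(f, random_alignment(5, 15, seed = 1)),
               "5 sequences")
})
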