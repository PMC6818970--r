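make_pdb_lines <- function(residues) {
  # residues: list of lists(resid, resno, atoms = list(name = xyz))
  serial <- 0L
  out <- character(0)
  for (r in residues) {
    for (nm in names(r$atoms)) {
      serial <- serial + 1L
      xyz <- r$atoms[[nm]]
      out <- c(out, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm, r$resid, "A", r$resno, xyz[1], xyz[2], xyz[3], 1, 0,
        substr(nm, 1, 1)))
    }
  }
  c(out, "TER", "END")
}

test_that("side-chain centers average heavy side-chain atoms, with CA fallbacks", {
  res <- list(
    # glycine: no side-chain heavy atoms, must use CA
    list(resid = "GLY", resno = 1,
         atoms = list(N = c(0, 1, 0), CA = c(1, 2, 3), C = c(2, 1, 0),
                      O = c(3, 1, 0))),
    # alanine: CB only, center is CB itself
    list(resid = "ALA", resno = 2,
         atoms = list(N = c(5, 1, 0), CA = c(5, 0, 0), C = c(6, 1, 0),
                      O = c(7, 1, 0), CB = c(1, 1, 1))),
    # two side-chain atoms: unweighted mean
    list(resid = "SER", resno = 3,
         atoms = list(CA = c(9, 9, 9), CB = c(0, 0, 0), OG = c(2, 0, 0))))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(make_pdb_lines(res), f)
  sc <- side_chain_centers(f, chain = "A")
  expect_equal(sc$centers[1, ], c(x = 1, y = 2, z = 3))    # GLY -> CA
  expect_equal(sc$centers[2, ], c(x = 1, y = 1, z = 1))    # ALA -> CB
  expect_equal(sc$centers[3, ], c(x = 1, y = 0, z = 0))    # mean of CB, OG
  expect_equal(sc$resno, c(1, 2, 3))
  expect_error(side_chain_centers(f, chain = "B"), "chain")
})

test_that("missing side-chain atoms fall back to CA with a warning", {
  res <- list(
    list(resid = "LYS", resno = 1,   # side chain absent from the model
         atoms = list(N = c(0, 0, 0), CA = c(1, 1, 1), C = c(2, 0, 0),
                      O = c(3, 0, 0))),
    list(resid = "ALA", resno = 2,
         atoms = list(CA = c(4, 4, 4), CB = c(5, 5, 5))))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(make_pdb_lines(res), f)
  expect_warning(sc <- side_chain_centers(f), "C-alpha")
  expect_equal(sc$centers[1, ], c(x = 1, y = 1, z = 1))
})

test_that("contact threshold is boundary-inclusive at 7.5 angstroms", {
  near <- rbind(c(0, 0, 0), c(7.4, 0, 0))
  expect_true(contact_map(near)$contacts[1, 2])
  far <- rbind(c(0, 0, 0), c(7.6, 0, 0))
  expect_false(contact_map(far)$contacts[1, 2])
  exact <- rbind(c(0, 0, 0), c(7.5, 0, 0))
  expect_true(contact_map(exact)$contacts[1, 2])
})

test_that("contact maps match a brute-force distance recount and are monotone in threshold", {
  set.seed(17)
  X <- matrix(runif(3 * 25, 0, 20), 25, 3)
  cm <- contact_map(X, 7.5)
  brute <- matrix(FALSE, 25, 25)
  for (i in 1:25)
    for (j in 1:25)
      if (i != j) brute[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2)) <= 7.5
  expect_identical(cm$contacts, brute)
  expect_identical(cm$contacts, t(cm$contacts))
  expect_false(any(diag(cm$contacts)))
  wider <- contact_map(X, 9)
  expect_true(all(wider$contacts[cm$contacts]))
})

test_that("alignment-to-reference mapping indexes non-gap reference positions", {
  aln <- msa(c("ref", "o"), c("ACD", "AAA"), reference_id = "ref")
  m <- map_alignment_to_reference(aln)
  expect_equal(m$column_to_residue, 1:3)
  expect_equal(m$n_residues, 3)

  aln2 <- msa(c("ref", "o"), c("A-C", "AAA"), reference_id = "ref")
  m2 <- map_alignment_to_reference(aln2)
  expect_equal(m2$column_to_residue, c(1L, NA, 2L))
  expect_equal(m2$n_residues, 2)
  mapped <- m2$column_to_residue[!is.na(m2$column_to_residue)]
  expect_false(anyDuplicated(mapped) > 0)  # injective by construction

  expect_error(map_alignment_to_reference(aln, "missing"), "reference")
})

test_that("top-L PPV: perfect, inverted, and randomized scores", {
  set.seed(19)
  X <- matrix(runif(3 * 15, 0, 18), 15, 3)
  cm <- contact_map(X, 7.5)
  col_to_res <- 1:15
  map <- list(column_to_residue = col_to_res, coverage = 1, n_residues = 15)

  ideal <- matrix(0, 15, 15)
  ideal[cm$contacts] <- 1
  expect_equal(ppv_top_L(coupling_matrix(ideal, "raw"), map, cm, L = 5), 1)

  worst <- 1 - ideal; diag(worst) <- 0
  n_noncontact <- sum(!cm$contacts[upper.tri(cm$contacts)])
  if (n_noncontact > 15)
    expect_equal(ppv_top_L(coupling_matrix(worst, "raw"), map, cm, L = 15), 0)

  for (seed in 1:4) {
    set.seed(seed)
    S <- matrix(runif(225), 15, 15); S <- (S + t(S)) / 2; diag(S) <- 0
    got <- ppv_top_L(coupling_matrix(S, "raw"), map, cm, L = 15)
    expect_equal(got, oracle_ppv(S, col_to_res, cm$contacts, 15))
  }
})

test_that("PPV is invariant under monotone score transforms and warns when pairs run out", {
  set.seed(23)
  X <- matrix(runif(3 * 12, 0, 15), 12, 3)
  cm <- contact_map(X)
  map <- list(column_to_residue = 1:12, coverage = 1, n_residues = 12)
  S <- matrix(runif(144), 12, 12); S <- (S + t(S)) / 2; diag(S) <- 0
  p1 <- ppv_top_L(coupling_matrix(S, "raw"), map, cm, L = 12)
  p2 <- ppv_top_L(coupling_matrix(exp(3 * S), "raw"), map, cm, L = 12)
  expect_equal(p1, p2)

  # min_separation shrinks the eligible set; a huge L triggers the warning
  expect_warning(
    pw <- ppv_top_L(coupling_matrix(S, "raw"), map, cm, L = 12,
                    min_separation = 11L),
    "eligible")
  expect_equal(pw, as.numeric(cm$contacts[1, 12]))
})

test_that("expected PPV under random scores approximates the contact density", {
  set.seed(29)
  X <- matrix(runif(3 * 20, 0, 16), 20, 3)
  cm <- contact_map(X)
  map <- list(column_to_residue = 1:20, coverage = 1, n_residues = 20)
  dens <- random_ppv_expectation(map, cm)
  ppvs <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    S <- matrix(runif(400), 20, 20); S <- (S + t(S)) / 2; diag(S) <- 0
    ppv_top_L(coupling_matrix(S, "raw"), map, cm, L = 20)
  }, numeric(1))
  se <- sqrt(dens * (1 - dens) / (40 * 20))
  expect_lt(abs(mean(ppvs) - dens), 5 * se + 0.01)
})
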