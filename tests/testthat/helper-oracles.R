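# Fixture builders and independent brute-force oracles used across the suite.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_alignment <- function(n, L, seed, gap_frac = 0, ids = paste0("s", seq_len(n))) {
  set.seed(seed)
  rows <- replicate(n, {
    ch <- sample(AA20, L, replace = TRUE)
    if (gap_frac > 0) ch[runif(L) < gap_frac] <- "-"
    paste(ch, collapse = "")
  })
  msa(ids, rows)
}

random_rooted_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, rooted = TRUE)
  tr$edge.length <- runif(length(tr$edge.length), 0.1, 2)
  tr
}

# brute-force pairwise identity: explicit per-column double loop
oracle_identity_matrix <- function(aln) {
  chars <- strsplit(aln$rows, "")
  m <- matrix(0, aln$n, aln$n)
  for (i in seq_len(aln$n))
    for (j in seq_len(aln$n)) {
      eq <- 0
      for (c in seq_len(aln$L))
        if (chars[[i]][c] == chars[[j]][c]) eq <- eq + 1
      m[i, j] <- eq / aln$L
    }
  m
}

# ACL oracle: assemble and solve the full Kirchhoff node-voltage system.
# Tips are grounded at 0 V, a unit current is injected at the root, and the
# current leaving each tip is read off its pendant branch.
oracle_acl_kirchhoff <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode
  bl <- tree$edge.length
  mbl <- mean(bl)
  bl[bl <= 0] <- 1e-8 * ifelse(mbl > 0, mbl, 1)
  internal <- (ntip + 1L):nnode
  A <- matrix(0, length(internal), length(internal))
  b <- numeric(length(internal))
  b[match(root, internal)] <- 1
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    g <- 1 / bl[e]
    ip <- match(p, internal)
    A[ip, ip] <- A[ip, ip] + g
    if (ch > ntip) {
      ic <- match(ch, internal)
      A[ic, ic] <- A[ic, ic] + g
      A[ip, ic] <- A[ip, ic] - g
      A[ic, ip] <- A[ic, ip] - g
    } # tips are at 0 V: no unknown, no off-diagonal term
  }
  v <- solve(A, b)
  w <- numeric(ntip)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2L]
    if (ch <= ntip) w[ch] <- v[match(tree$edge[e, 1L], internal)] / bl[e]
  }
  names(w) <- tree$tip.label
  w
}

# GSC oracle: independent recursive apportionment of every branch among its
# descendant tips (plain recursion on subtrees, no preorder bookkeeping)
oracle_gsc <- function(tree) {
  ntip <- length(tree$tip.label)
  bl_above <- rep(0, ntip + tree$Nnode)
  bl_above[tree$edge[, 2L]] <- tree$edge.length
  rec <- function(u) {
    if (u <= ntip) {
      w <- stats::setNames(bl_above[u], tree$tip.label[u])
      return(w)
    }
    kids <- tree$edge[tree$edge[, 1L] == u, 2L]
    w <- unlist(lapply(kids, rec))
    if (u != ntip + 1L) { # non-root: share this node's branch among tips below
      tot <- sum(w)
      share <- if (tot > 0) w / tot else rep(1 / length(w), length(w))
      w <- w + bl_above[u] * share
    }
    w
  }
  w <- rec(ntip + 1L)
  w[tree$tip.label]
}

# brute-force top-L PPV: explicit sort over an eligible-pair data frame
oracle_ppv <- function(scores, col_to_res, contacts, L, min_sep = 1L) {
  df <- NULL
  n <- nrow(scores)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n) {
      ri <- col_to_res[i]; rj <- col_to_res[j]
      if (is.na(ri) || is.na(rj) || abs(ri - rj) < min_sep) next
      df <- rbind(df, data.frame(i = i, j = j, s = scores[i, j],
                                 hit = contacts[ri, rj]))
    }
  df <- df[order(-df$s, df$i, df$j), ]
  mean(df$hit[seq_len(L)])
}

two_seq_alignment <- function(n_diff, len = 100L) {
  r1 <- paste(rep("A", len), collapse = "")
  r2 <- paste(c(rep("A", len - n_diff), rep("V", n_diff)), collapse = "")
  msa(c("seq1", "seq2"), c(r1, r2))
}
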