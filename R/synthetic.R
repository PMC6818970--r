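#' Simulate a random rooted tree for benchmarking
#'
#' Two generators: `yule` draws a pure-birth ultrametric tree; `skewed_clades`
#' emulates database over-sampling of one lineage by grafting a shallow,
#' densely sampled clade (many tips, short branches) onto a deeper backbone
#' tree, with all tips contemporaneous. Optional lineage rate heterogeneity
#' multiplies branch lengths by rates that random-walk multiplicatively from
#' root to tips, making the raw tree non-ultrametric the way real
#' substitutions-per-site trees are; `rate_heterogeneity = 1` leaves branch
#' lengths untouched.
#'
#' @param n_tips number of tips (>= 2; >= 4 for `skewed_clades`).
#' @param model `yule` or `skewed_clades`.
#' @param rate_heterogeneity per-edge multiplicative rate spread factor
#'   (>= 1); each edge's rate is its parent's rate times
#'   `rate_heterogeneity^u`, u ~ Uniform(-1, 1).
#' @param seed RNG seed.
#' @param clade_fraction fraction of tips placed in the over-sampled clade
#'   (`skewed_clades` only).
#' @param clade_depth_fraction depth of the over-sampled clade relative to the
#'   backbone depth of 1.
#' @return a rooted binary [ape::phylo] tree with tip labels `t1..tn`.
#' @export
simulate_tree <- function(n_tips, model = c("yule", "skewed_clades"),
                          rate_heterogeneity = 1, seed = 1L,
                          clade_fraction = 0.4, clade_depth_fraction = 0.1) {
  model <- match.arg(model)
  stopifnot(n_tips >= 2L, rate_heterogeneity >= 1)
  old_seed <- .save_rng(seed)
  on.exit(.restore_rng(old_seed))
  if (model == "yule" || n_tips < 4L) {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tree)[seq_len(n_tips)])
    tree$edge.length <- tree$edge.length / depth
  } else {
    n_clade <- max(2L, round(clade_fraction * n_tips))
    n_main <- n_tips - n_clade
    if (n_main < 2L) stop("clade_fraction leaves fewer than 2 backbone tips")
    tree <- .graft_shallow_clade(n_main, n_clade, clade_depth_fraction)
  }
  tree$tip.label <- paste0("t", seq_len(n_tips))
  if (rate_heterogeneity > 1)
    tree <- .apply_rate_heterogeneity(tree, rate_heterogeneity)
  tree
}

.graft_shallow_clade <- function(n_main, n_clade, clade_depth) {
  rescale_to <- function(tr, target) {
    d <- max(ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)])
    tr$edge.length <- tr$edge.length * target / d
    tr
  }
  main <- rescale_to(ape::rphylo(n_main, birth = 1, death = 0), 1)
  clade <- rescale_to(ape::rphylo(n_clade, birth = 1, death = 0), clade_depth)
  main$tip.label <- paste0("m", seq_len(n_main))
  clade$tip.label <- paste0("c", seq_len(n_clade))
  stem_main <- 0.2
  stem_clade <- 1 + stem_main - clade_depth  # keeps all tips contemporaneous
  nw <- function(tr) sub(";$", "", ape::write.tree(tr))
  txt <- paste0("(", nw(main), ":", stem_main, ",",
                nw(clade), ":", stem_clade, ");")
  ape::read.tree(text = txt)
}

.apply_rate_heterogeneity <- function(tree, factor) {
  nnode <- length(tree$tip.label) + tree$Nnode
  rate <- rep(1, nnode)
  for (u in .preorder_nodes(tree)) {
    kids <- which(tree$edge[, 1L] == u)
    for (e in kids) {
      child <- tree$edge[e, 2L]
      rate[child] <- rate[u] * factor^runif(1, -1, 1)
      tree$edge.length[e] <- tree$edge.length[e] * rate[child]
    }
  }
  tree
}

#' Evolve an alignment along a tree with designated co-evolving column pairs
#'
#' Columns evolve independently along the tree under a simple uniform-exchange
#' substitution process: on each branch, each site substitutes with
#' probability `1 - exp(-branch length)` and redraws its state uniformly from
#' the 20 amino acids (no gaps or indels are generated). Each designated
#' coupled column pair instead evolves jointly over a restricted set of
#' compatible state combinations (a random bijection between `n_combos` states
#' of the two columns): a substitution event redraws a compatible combination
#' with probability `coupling_strength` and draws the two states independently
#' (breaking the constraint) otherwise. With strength 0 the pair is
#' statistically indistinguishable from independent columns; with strength 1
#' the pair is locked to the compatible set, creating strong two-site
#' covariation with weak single-site signal.
#'
#' @param tree a rooted [ape::phylo] tree with branch lengths.
#' @param n_columns alignment length L.
#' @param coupled_pairs two-column matrix (or list of length-2 vectors) of
#'   disjoint column index pairs.
#' @param coupling_strength probability in `[0, 1]` that a substitution event
#'   at a coupled pair respects the compatible set.
#' @param seed RNG seed.
#' @param n_combos number of compatible state combinations per coupled pair.
#' @return list with `aln` (an [msa], tips in tree tip order, reference set to
#'   the first tip) and `coupled_pairs` (the ground-truth pair matrix).
#' @export
evolve_alignment <- function(tree, n_columns, coupled_pairs = NULL,
                             coupling_strength = 0.9, seed = 1L,
                             n_combos = 6L) {
  validate_tree(tree)
  if (!ape::is.rooted(tree)) stop("evolve_alignment requires a rooted tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  stopifnot(n_columns >= 1L, coupling_strength >= 0, coupling_strength <= 1)
  pairs <- .as_pair_matrix(coupled_pairs, n_columns)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L

  old_seed <- .save_rng(seed)
  on.exit(.restore_rng(old_seed))

  states <- matrix(0L, nnode, n_columns)
  p_sub <- 1 - exp(-pmax(tree$edge.length, 0))
  coupled_cols <- as.vector(pairs)
  free_cols <- setdiff(seq_len(n_columns), coupled_cols)

  # independent columns
  states[root, free_cols] <- sample.int(20L, length(free_cols), replace = TRUE)
  edges_pre <- .preorder_edges(tree)
  for (e in edges_pre) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    s <- states[par, free_cols]
    hit <- runif(length(free_cols)) < p_sub[e]
    s[hit] <- sample.int(20L, sum(hit), replace = TRUE)
    states[child, free_cols] <- s
  }

  # coupled pairs: evolve over a random bijection of compatible combinations
  if (nrow(pairs) > 0L) {
    for (k in seq_len(nrow(pairs))) {
      ca <- pairs[k, 1L]; cb <- pairs[k, 2L]
      sA <- sample.int(20L, n_combos)
      sB <- sample.int(20L, n_combos)
      m0 <- sample.int(n_combos, 1L)
      states[root, c(ca, cb)] <- c(sA[m0], sB[m0])
      for (e in edges_pre) {
        par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
        ab <- states[par, c(ca, cb)]
        if (runif(1) < p_sub[e]) {
          if (runif(1) < coupling_strength) {
            m <- sample.int(n_combos, 1L)
            ab <- c(sA[m], sB[m])
          } else {
            ab <- sample.int(20L, 2L, replace = TRUE)
          }
        }
        states[child, c(ca, cb)] <- ab
      }
    }
  }

  rows <- apply(states[seq_len(ntip), , drop = FALSE], 1L, function(s)
    paste(AA_ALPHABET[s], collapse = ""))
  aln <- msa(tree$tip.label, rows, reference_id = tree$tip.label[1L])
  list(aln = aln, coupled_pairs = pairs)
}

.as_pair_matrix <- function(coupled_pairs, L) {
  if (is.null(coupled_pairs))
    return(matrix(integer(0), 0L, 2L))
  if (is.list(coupled_pairs))
    coupled_pairs <- do.call(rbind, coupled_pairs)
  pairs <- matrix(as.integer(coupled_pairs), ncol = 2L)
  pairs <- t(apply(pairs, 1L, sort))
  if (nrow(pairs) == 1L) pairs <- matrix(pairs, 1L, 2L)
  if (any(pairs < 1L) || any(pairs > L))
    stop("coupled pair indices out of range 1..", L)
  if (anyDuplicated(as.vector(pairs)))
    stop("coupled pairs must be disjoint (no column in two pairs)")
  pairs
}

# edges in preorder (parent rows before child rows)
.preorder_edges <- function(tree) {
  ord <- .preorder_nodes(tree)
  unlist(lapply(ord, function(u) which(tree$edge[, 1L] == u)))
}

#' Build a toy structure realizing a designated contact set
#'
#' Places one side-chain pseudo-atom per residue in 3D so that exactly the
#' designated coupled pairs plus sequential chain neighbors (i, i+1) fall
#' within the 7.5-angstrom contact threshold of each other's side-chain
#' centers, and emits the coordinates as a minimal valid PDB file (poly-ALA:
#' backbone N/CA/C/O placed at a fixed offset, CB at the side-chain center so
#' the side-chain geometric center reproduces the intended coordinates
#' exactly). The layout is found by a force-directed embedding (contact pairs
#' pulled to 5 A, all other pairs pushed beyond 9.5 A) and verified; if no
#' layout realizes the requested pair set the function errors, suggesting
#' fewer pairs.
#'
#' @param L number of residues (>= 2).
#' @param coupled_pairs two-column matrix or list of disjoint residue pairs
#'   that must be contacts (in addition to chain neighbors).
#' @param seed RNG seed.
#' @return list with `contact_map` (a [contact_map] derived from the emitted
#'   coordinates), `pdb_text` (character vector of PDB lines), `centers`
#'   (L x 3 matrix), `intended` (logical L x L matrix of the requested
#'   contact set).
#' @export
toy_structure <- function(L, coupled_pairs = NULL, seed = 1L) {
  stopifnot(L >= 2L)
  pairs <- .as_pair_matrix(coupled_pairs, L)
  intended <- matrix(FALSE, L, L)
  for (i in seq_len(L - 1L)) intended[i, i + 1L] <- intended[i + 1L, i] <- TRUE
  if (nrow(pairs) > 0L)
    intended[rbind(pairs, pairs[, 2:1, drop = FALSE])] <- TRUE

  old_seed <- .save_rng(seed)
  on.exit(.restore_rng(old_seed))
  X <- NULL
  for (attempt in seq_len(10L)) {
    cand <- .embed_contact_graph(intended, L)
    if (!is.null(cand)) { X <- cand; break }
  }
  if (is.null(X))
    stop("could not realize the requested contact set geometrically; ",
         "try fewer coupled pairs")
  X <- round(X, 3L)  # match the precision of the PDB text exactly
  cm <- contact_map(X, 7.5)
  if (!identical(cm$contacts, intended))
    stop("could not realize the requested contact set geometrically; ",
         "try fewer coupled pairs")
  list(contact_map = cm, pdb_text = .poly_ala_pdb(X), centers = X,
       intended = intended)
}

# force-directed 3D embedding: edges pulled to `d_edge`, non-edges pushed to
# `d_gap`; returns NULL when the margins around the 7.5 A threshold fail
.embed_contact_graph <- function(adj, L, d_edge = 5, d_gap = 9.5,
                                 n_iter = 3000L, lr = 0.05) {
  X <- matrix(rnorm(L * 3L), L, 3L) * (2 * L^(1 / 3))
  X <- X + outer(seq_len(L), c(1, 0, 0)) * 2  # mild chain-like initial spread
  for (it in seq_len(n_iter)) {
    D <- as.matrix(stats::dist(X))
    diag(D) <- Inf
    C <- matrix(0, L, L)
    C[adj] <- (1 - d_edge / D[adj])
    push <- !adj & D < d_gap
    C[push] <- 0.5 * (1 - d_gap / D[push])
    diag(C) <- 0
    G <- rowSums(C) * X - C %*% X
    X <- X - lr * G
  }
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  ok <- all(D[adj] <= 7.3) && all(D[!adj & upper.tri(D)] >= 7.7)
  if (ok) X else NULL
}

.poly_ala_pdb <- function(X) {
  L <- nrow(X)
  offsets <- list(N = c(2.0, 0.8, 0), CA = c(1.2, 0, 0),
                  C = c(2.0, -0.8, 0), O = c(2.9, -1.0, 0),
                  CB = c(0, 0, 0))
  lines <- character(0)
  serial <- 0L
  for (k in seq_len(L)) {
    for (nm in names(offsets)) {
      serial <- serial + 1L
      xyz <- X[k, ] + offsets[[nm]]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm, "ALA", "A", k, xyz[1], xyz[2], xyz[3], 1.00, 0.00,
        substr(nm, 1L, 1L)))
    }
  }
  c(lines, "TER", "END")
}

#' Generate a complete end-to-end benchmark fixture
#'
#' Writes a self-contained bundle to `dir`: a simulated tree (Newick), an
#' alignment evolved along it with known co-evolving column pairs (aligned
#' FASTA), a toy PDB structure whose contact map is exactly those pairs plus
#' chain neighbors, one weight file per weighting method, the ground-truth
#' pair list, and a manifest of byte counts and MD5 checksums for determinism
#' checks.
#'
#' Profiles: `small` is 60 tips x 40 columns with 8 coupled pairs
#' (coupling strength 0.9), sized so the full pipeline runs in well under five
#' minutes on one CPU; `paper_like` is 500 tips x 100 columns with 25 pairs.
#' Both use a skewed-clade tree (40% of tips in one shallow clade) with
#' lineage rate heterogeneity 1.5.
#'
#' @param profile `small` or `paper_like`.
#' @param seed RNG seed controlling tree, alignment, structure and pair
#'   placement.
#' @param dir output directory (created if missing).
#' @return list with the in-memory objects (`tree`, `aln`, `coupled_pairs`,
#'   `structure`, `weights`) plus `files` (paths) and `manifest` (data frame
#'   of file, bytes, md5).
#' @export
end_to_end_fixture <- function(profile = c("small", "paper_like"), seed = 1L,
                               dir = tempfile("fixture")) {
  profile <- match.arg(profile)
  prm <- switch(profile,
    small = list(n_tips = 60L, L = 40L, n_pairs = 8L, strength = 0.9),
    paper_like = list(n_tips = 500L, L = 100L, n_pairs = 25L, strength = 0.9))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  tree <- simulate_tree(prm$n_tips, "skewed_clades",
                        rate_heterogeneity = 1.5, seed = seed)
  pairs <- sample_coupled_pairs(prm$L, prm$n_pairs, seed = seed + 1L)
  sim <- evolve_alignment(tree, prm$L, pairs, coupling_strength = prm$strength,
                          seed = seed + 2L)
  struct <- toy_structure(prm$L, pairs, seed = seed + 3L)

  weights <- list(
    uniform = uniform_weights(sim$aln),
    identity_threshold = identity_threshold_weights(sim$aln, 0.8),
    similarity_adjusted = similarity_adjusted_weights(sim$aln, 0.8),
    henikoff = henikoff_weights(sim$aln),
    acl = acl_weights(tree),
    gsc = gsc_weights(tree))

  files <- c(alignment = file.path(dir, "alignment.fasta"),
             tree = file.path(dir, "tree.nwk"),
             structure = file.path(dir, "structure.pdb"),
             pairs = file.path(dir, "coupled_pairs.tsv"))
  write_fasta_alignment(sim$aln, files[["alignment"]])
  write_newick(tree, files[["tree"]])
  writeLines(struct$pdb_text, files[["structure"]])
  write.table(data.frame(i = pairs[, 1L], j = pairs[, 2L]),
              files[["pairs"]], sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(weights)) {
    p <- file.path(dir, paste0("weights_", nm, ".txt"))
    # weight files follow the alignment's sequence order
    v <- weights[[nm]]$values[sim$aln$ids]
    write_weight_file(v, p)
    files[[paste0("weights_", nm)]] <- p
  }
  manifest <- data.frame(
    file = basename(unname(files)),
    bytes = unname(file.size(files)),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.tsv")
  write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files[["manifest"]] <- manifest_path

  list(profile = profile, tree = tree, aln = sim$aln, coupled_pairs = pairs,
       structure = struct, weights = weights, files = files,
       manifest = manifest, dir = dir)
}

#' Sample disjoint co-evolving column pairs
#'
#' Pairs are drawn uniformly among column pairs with sequence separation of at
#' least 3 and no shared columns.
#'
#' @param L alignment length.
#' @param n_pairs number of pairs.
#' @param seed RNG seed.
#' @return integer matrix with `n_pairs` rows and 2 columns (i < j).
#' @export
sample_coupled_pairs <- function(L, n_pairs, seed = 1L) {
  stopifnot(n_pairs >= 0, 2 * n_pairs <= L)
  old_seed <- .save_rng(seed)
  on.exit(.restore_rng(old_seed))
  available <- seq_len(L)
  out <- matrix(0L, n_pairs, 2L)
  for (k in seq_len(n_pairs)) {
    for (tries in seq_len(1000L)) {
      ij <- sort(sample(available, 2L))
      if (ij[2L] - ij[1L] >= 3L) break
    }
    if (ij[2L] - ij[1L] < 3L)
      stop("could not place ", n_pairs, " disjoint pairs with separation >= 3")
    out[k, ] <- ij
    available <- setdiff(available, ij)
  }
  out
}
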