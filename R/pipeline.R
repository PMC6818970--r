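#' Compute sequence weights by any supported method
#'
#' Dispatcher over the package's weighting schemes. Sequence-based methods
#' need only the alignment; `acl` and `gsc` need a rooted tree whose tip
#' labels match the alignment ids exactly (mismatches are a hard error), with
#' optional RelTime rescaling of the tree first.
#'
#' @param aln an [msa] object.
#' @param method one of `uniform`, `identity_threshold`,
#'   `similarity_adjusted`, `henikoff`, `acl`, `gsc`.
#' @param tree rooted [ape::phylo] (tree-based methods only).
#' @param lambda_threshold identity cutoff for the identity-based methods.
#' @param scaling `raw`, `mean` or `max`.
#' @param reltime if TRUE, rescale the tree with [reltime_rescale()] before
#'   computing tree-based weights.
#' @return a [weight_vector] whose values follow the alignment's id order.
#' @export
compute_weights <- function(aln, method, tree = NULL, lambda_threshold = 0.8,
                            scaling = c("raw", "mean", "max"),
                            reltime = FALSE) {
  stopifnot(inherits(aln, "msa"))
  scaling <- match.arg(scaling)
  method <- match.arg(method, c("uniform", "identity_threshold",
                                "similarity_adjusted", "henikoff",
                                "acl", "gsc"))
  if (method %in% c("acl", "gsc")) {
    if (is.null(tree))
      stop("method '", method, "' requires a rooted tree")
    check_tree_alignment(tree, aln)
    if (reltime) tree <- reltime_rescale(tree)
    w <- switch(method, acl = acl_weights(tree), gsc = gsc_weights(tree))
    # reorder tip weights into alignment order
    w <- weight_vector(w$values[aln$ids], method, ids = aln$ids)
  } else {
    w <- switch(method,
      uniform = uniform_weights(aln),
      identity_threshold = identity_threshold_weights(aln, lambda_threshold),
      similarity_adjusted = similarity_adjusted_weights(aln, lambda_threshold),
      henikoff = henikoff_weights(aln))
  }
  switch(scaling, raw = w, mean = mean_scale(w), max = max_scale(w))
}

#' Run the full contact-prediction pipeline
#'
#' Weights an alignment, fits the weighted pseudo-likelihood Potts model,
#' extracts raw / APC / entropy-corrected coupling scores, and evaluates each
#' variant's top-L positive predictive value against a structure-derived
#' contact map.
#'
#' @inheritParams compute_weights
#' @param contacts a [contact_map], or a path to a PDB file (contacts are then
#'   derived from side-chain geometric centers at 7.5 angstroms).
#' @param weights optionally a precomputed [weight_vector] or numeric vector,
#'   overriding `method`.
#' @param chain chain identifier when `contacts` is a PDB path.
#' @param lfactor,lambda_single,maxit passed to [fit_plm()].
#' @param min_separation minimum residue separation for PPV eligibility.
#' @param reference_id structure-bearing sequence id (defaults to the
#'   alignment's).
#' @return list with `weights`, `model`, `scores` (list of raw/apc/entropy
#'   `coupling_matrix`), `map`, `contacts`, and `ppv` (named vector over the
#'   three variants).
#' @export
run_contact_pipeline <- function(aln, contacts, method = "uniform",
                                 weights = NULL, tree = NULL,
                                 lambda_threshold = 0.8, scaling = "raw",
                                 reltime = FALSE, chain = NULL, lfactor = 0.2,
                                 lambda_single = 0.01, maxit = 500L,
                                 min_separation = 1L,
                                 reference_id = aln$reference_id) {
  stopifnot(inherits(aln, "msa"))
  if (is.character(contacts))
    contacts <- contact_map(side_chain_centers(contacts, chain = chain))
  stopifnot(inherits(contacts, "contact_map"))
  if (is.null(weights))
    weights <- compute_weights(aln, method, tree = tree,
                               lambda_threshold = lambda_threshold,
                               scaling = scaling, reltime = reltime)
  model <- fit_plm(aln, weights, lfactor = lfactor,
                   lambda_single = lambda_single, maxit = maxit)
  raw <- coupling_scores(model)
  apc <- apc_correct(raw)
  entropy <- entropy_correct(raw, aln, weights)
  map <- map_alignment_to_reference(aln, reference_id)
  ppv <- vapply(list(raw = raw, apc = apc, entropy = entropy), function(cm)
    ppv_top_L(cm, map, contacts, min_separation = min_separation), numeric(1))
  list(weights = weights, model = model,
       scores = list(raw = raw, apc = apc, entropy = entropy),
       map = map, contacts = contacts, ppv = ppv)
}

#' Expected PPV of a random ranking
#'
#' Under random coupling scores, the expected top-L PPV equals the contact
#' density among the eligible column pairs; this is the baseline that any
#' genuine co-evolutionary signal must beat.
#'
#' @param map column-to-residue map from [map_alignment_to_reference()].
#' @param contacts a [contact_map].
#' @param min_separation minimum residue separation for eligibility.
#' @return expected PPV fraction.
#' @export
random_ppv_expectation <- function(map, contacts, min_separation = 1L) {
  stopifnot(inherits(contacts, "contact_map"))
  L_aln <- length(map$column_to_residue)
  idx <- which(upper.tri(matrix(0, L_aln, L_aln)), arr.ind = TRUE)
  ri <- map$column_to_residue[idx[, 1L]]
  rj <- map$column_to_residue[idx[, 2L]]
  ok <- !is.na(ri) & !is.na(rj) & abs(ri - rj) >= min_separation
  mean(contacts$contacts[cbind(ri[ok], rj[ok])])
}
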