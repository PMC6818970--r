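#' Mean-scale a weight vector
#'
#' Divides every weight by the mean weight, so the scaled weights sum exactly
#' to the number of sequences n while preserving all relative ratios. This
#' puts tree- and position-based weights (whose raw scales are arbitrary) on
#' the same absolute footing as identity-threshold weights, which matters
#' because the regularization strength of the coupling fit is tied to the
#' effective N.
#'
#' @param w a [weight_vector].
#' @return a [weight_vector] with `scaling = "mean"`.
#' @export
mean_scale <- function(w) {
  stopifnot(inherits(w, "weight_vector"))
  m <- mean(w$values)
  if (m <= 0) stop("cannot mean-scale an all-zero weight vector")
  weight_vector(w$values / m, w$method, ids = names(w$values),
                lambda_threshold = w$lambda_threshold, scaling = "mean")
}

#' Max-scale a weight vector
#'
#' Divides every weight by the maximum weight, so the largest weight becomes 1
#' and all others a fraction of it; the scaled weights sum to at most n.
#'
#' @param w a [weight_vector].
#' @return a [weight_vector] with `scaling = "max"`.
#' @export
max_scale <- function(w) {
  stopifnot(inherits(w, "weight_vector"))
  m <- max(w$values)
  if (m <= 0) stop("cannot max-scale an all-zero weight vector")
  weight_vector(w$values / m, w$method, ids = names(w$values),
                lambda_threshold = w$lambda_threshold, scaling = "max")
}

#' GINI coefficient of a weight distribution
#'
#' Standard Gini: the mean absolute difference between all weight pairs
#' divided by twice the mean weight. Zero for uniform weights; approaching 1
#' when a few sequences hold almost all the weight. Invariant under positive
#' rescaling, so raw, mean- and max-scaled versions of the same weights share
#' one Gini.
#'
#' @param w a [weight_vector] or numeric vector of non-negative weights.
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini <- function(w) {
  v <- .wvals(w)
  n <- length(v)
  stopifnot(n >= 1, sum(v) > 0)
  # O(n log n) form of the pairwise mean absolute difference
  v <- sort(v)
  g <- sum((2 * seq_len(n) - n - 1) * v) / (n^2 * mean(v))
  max(g, 0)
}

#' Lorenz curve of a weight distribution
#'
#' Points of the cumulative weight share (y) against the cumulative sequence
#' share (x), with sequences sorted from lowest to highest weight. The curve
#' runs from (0,0) to (1,1), lies on the diagonal for uniform weights and
#' sags below it in proportion to the Gini coefficient.
#'
#' @param w a [weight_vector] or numeric vector.
#' @return data.frame with columns `seq_fraction`, `weight_fraction`
#'   (n + 1 rows including the origin).
#' @export
lorenz_curve <- function(w) {
  v <- sort(.wvals(w))
  n <- length(v)
  stopifnot(sum(v) > 0)
  data.frame(seq_fraction = (0:n) / n,
             weight_fraction = c(0, cumsum(v)) / sum(v))
}

#' Spearman correlation between two weight vectors
#'
#' Rank-based correlation with average ranks for ties (identity-threshold
#' weights are heavily tied). If either vector is constant the correlation is
#' undefined and `NA` is returned.
#'
#' @param w1,w2 [weight_vector]s or numeric vectors over the same sequences in
#'   the same order.
#' @return Spearman's rho in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
weight_correlation <- function(w1, w2) {
  v1 <- .wvals(w1)
  v2 <- .wvals(w2)
  if (length(v1) != length(v2))
    stop("weight vectors have different lengths")
  if (length(unique(v1)) < 2L || length(unique(v2)) < 2L)
    return(NA_real_)
  cor(v1, v2, method = "spearman")
}

#' Bootstrap stability of a weighting method
#'
#' Resamples alignment columns with replacement (the standard phylogenetic
#' bootstrap applied to sites), recomputes the weights on each replicate, and
#' correlates them with the weights from the original alignment. For the
#' tree-based methods (`acl`, `gsc`) tree inference is an external step, so a
#' precomputed tree per replicate must be supplied; the column resampling is
#' then implicit in how those trees were built.
#'
#' @param aln an [msa] object.
#' @param method one of `identity_threshold`, `similarity_adjusted`,
#'   `henikoff`, `acl`, `gsc`.
#' @param n_replicates number of bootstrap replicates.
#' @param seed RNG seed for the column resampling.
#' @param lambda_threshold identity cutoff for the identity-based methods.
#' @param trees_per_replicate for tree-based methods, a list of
#'   `n_replicates` precomputed replicate trees; `original_tree` must also be
#'   given.
#' @param original_tree the tree the reference weights are computed from
#'   (tree-based methods only).
#' @return list with `rho` (per-replicate Spearman correlations versus the
#'   original weights) and `median_rho`.
#' @export
bootstrap_weight_stability <- function(aln, method, n_replicates, seed = 1L,
                                       lambda_threshold = 0.8,
                                       trees_per_replicate = NULL,
                                       original_tree = NULL) {
  stopifnot(inherits(aln, "msa"), n_replicates >= 0)
  method <- match.arg(method, c("identity_threshold", "similarity_adjusted",
                                "henikoff", "acl", "gsc"))
  tree_based <- method %in% c("acl", "gsc")
  if (tree_based) {
    if (is.null(trees_per_replicate) || is.null(original_tree))
      stop("tree-based bootstrap needs `original_tree` and one precomputed ",
           "tree per replicate in `trees_per_replicate`: tree inference on ",
           "resampled columns is an external step this package does not run")
    if (length(trees_per_replicate) < n_replicates)
      stop("need at least n_replicates trees in `trees_per_replicate`")
  }
  weight_fun <- switch(method,
    identity_threshold = function(a) identity_threshold_weights(a, lambda_threshold),
    similarity_adjusted = function(a) similarity_adjusted_weights(a, lambda_threshold),
    henikoff = henikoff_weights)
  tree_fun <- switch(method, acl = acl_weights, gsc = gsc_weights, NULL)
  original <- if (tree_based) tree_fun(original_tree) else weight_fun(aln)
  if (n_replicates == 0L)
    return(list(rho = numeric(0), median_rho = NA_real_))
  old_seed <- .save_rng(seed)
  on.exit(.restore_rng(old_seed))
  rho <- vapply(seq_len(n_replicates), function(b) {
    if (tree_based) {
      rep_w <- tree_fun(trees_per_replicate[[b]])
      rep_v <- rep_w$values[names(original$values)]
    } else {
      cols <- sample.int(aln$L, aln$L, replace = TRUE)
      rows <- vapply(strsplit(aln$rows, ""), function(ch)
        paste(ch[cols], collapse = ""), character(1))
      rep_w <- weight_fun(msa(aln$ids, rows))
      rep_v <- rep_w$values
    }
    weight_correlation(original$values, rep_v)
  }, numeric(1))
  list(rho = rho, median_rho = median(rho))
}

#' Write a per-method weight diagnostics table
#'
#' @param aln an [msa] object the weights belong to.
#' @param weights named list of [weight_vector]s (raw).
#' @param path output TSV path; columns are id, then one raw and one
#'   mean-scaled column per method.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(aln, weights, path) {
  stopifnot(inherits(aln, "msa"), is.list(weights))
  df <- data.frame(id = aln$ids, stringsAsFactors = FALSE)
  for (nm in names(weights)) {
    w <- weights[[nm]]
    df[[paste0(nm, "_raw")]] <- unname(w$values[aln$ids])
    df[[paste0(nm, "_mean_scaled")]] <- unname(mean_scale(w)$values[aln$ids])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
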