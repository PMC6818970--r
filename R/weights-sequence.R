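#' Construct a per-sequence weight vector
#'
#' A `weight_vector` carries one non-negative weight per sequence of a source
#' alignment (or per tip of a tree), together with provenance: the weighting
#' method, the identity threshold lambda where applicable, and the scaling
#' applied (`raw`, `mean` or `max`). The effective number of sequences is
#' always the current sum of the weights, recomputed by [effective_n()].
#'
#' @param values numeric vector of non-negative weights.
#' @param method one of `uniform`, `identity_threshold`, `similarity_adjusted`,
#'   `henikoff`, `acl`, `gsc`.
#' @param ids sequence/tip identifiers the weights are aligned to.
#' @param lambda_threshold identity threshold used (identity methods only).
#' @param scaling `raw`, `mean` or `max`.
#' @return an object of class `weight_vector`.
#' @export
weight_vector <- function(values, method, ids = names(values),
                          lambda_threshold = NULL, scaling = "raw") {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("weights must be finite and non-negative")
  method <- match.arg(method, c("uniform", "identity_threshold",
                                "similarity_adjusted", "henikoff",
                                "acl", "gsc"))
  scaling <- match.arg(scaling, c("raw", "mean", "max"))
  if (!is.null(ids)) {
    if (length(ids) != length(values))
      stop("ids and values length mismatch")
    names(values) <- ids
  }
  structure(list(values = values, method = method,
                 lambda_threshold = lambda_threshold, scaling = scaling),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("Sequence weights [", x$method,
      if (!is.null(x$lambda_threshold))
        paste0(", lambda=", format(x$lambda_threshold)) else "",
      ", scaling=", x$scaling, "]\n", sep = "")
  cat("  n = ", length(x$values), ", effective N = ",
      format(effective_n(x), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Effective number of sequences
#'
#' The effective N of a weighting is simply the sum of the weights; it governs
#' the balance between the data term and the regularization prior in the
#' Potts-model fit.
#'
#' @param w a [weight_vector] or bare numeric vector.
#' @return scalar sum of weights.
#' @export
effective_n <- function(w) {
  sum(.wvals(w))
}

.wvals <- function(w) {
  if (inherits(w, "weight_vector")) w$values else as.numeric(w)
}

#' Uniform sequence weights
#'
#' Every sequence is given weight 1; the effective N equals the number of
#' sequences. This is the phylogenetically agnostic baseline.
#'
#' @param aln an [msa] object.
#' @return a [weight_vector] with method `uniform`.
#' @export
uniform_weights <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  weight_vector(rep(1, aln$n), "uniform", ids = aln$ids)
}

#' Identity-threshold sequence weights
#'
#' The standard DCA down-weighting: the weight of sequence i is the inverse of
#' the number of sequences j (including i itself) whose pairwise identity
#' d(i,j) is at least `lambda_threshold`. Sequences with no neighbor above the
#' threshold keep weight 1; members of a cluster of k mutually similar
#' sequences get roughly 1/k.
#'
#' @param aln an [msa] object.
#' @param lambda_threshold identity cutoff in `(0, 1]`; the field standard is
#'   0.8.
#' @param id_matrix optional precomputed [identity_matrix()] (avoids
#'   recomputation when several lambdas are tried).
#' @return a [weight_vector] with method `identity_threshold`.
#' @export
identity_threshold_weights <- function(aln, lambda_threshold = 0.8,
                                       id_matrix = NULL) {
  stopifnot(inherits(aln, "msa"))
  if (lambda_threshold <= 0 || lambda_threshold > 1)
    stop("lambda_threshold must be in (0, 1]")
  D <- if (is.null(id_matrix)) identity_matrix(aln) else id_matrix
  counts <- rowSums(D >= lambda_threshold)  # includes the self term d(i,i)=1
  weight_vector(1 / counts, "identity_threshold", ids = aln$ids,
                lambda_threshold = lambda_threshold)
}

#' Similarity-adjusted identity weights
#'
#' A continuous variant of the identity-threshold scheme: instead of counting
#' each above-threshold neighbor as a full unit, neighbor j contributes
#' `(d(i,j) - lambda) / (1 - lambda)`, a value that grows linearly from 0 at
#' the threshold to 1 for identical sequences. The self term contributes
#' exactly 1, so weights stay in `(0, 1]`, and near-threshold neighbors
#' barely reduce a sequence's weight.
#'
#' @inheritParams identity_threshold_weights
#' @param lambda_threshold identity cutoff in `(0, 1)`; `lambda = 1` would
#'   make the adjustment undefined and is rejected.
#' @return a [weight_vector] with method `similarity_adjusted`.
#' @export
similarity_adjusted_weights <- function(aln, lambda_threshold = 0.8,
                                        id_matrix = NULL) {
  stopifnot(inherits(aln, "msa"))
  if (lambda_threshold <= 0 || lambda_threshold >= 1)
    stop("lambda_threshold must be in (0, 1) for similarity-adjusted weights")
  D <- if (is.null(id_matrix)) identity_matrix(aln) else id_matrix
  I_adj <- pmax(D - lambda_threshold, 0) / (1 - lambda_threshold)
  I_adj[D < lambda_threshold] <- 0
  denom <- rowSums(I_adj)  # self term contributes (1 - lambda)/(1 - lambda) = 1
  weight_vector(1 / denom, "similarity_adjusted", ids = aln$ids,
                lambda_threshold = lambda_threshold)
}

#' Henikoff-Henikoff position-based weights
#'
#' Each alignment column carries a weight equal to its fraction of non-gap
#' rows; that column weight is shared equally among the distinct amino acids
#' observed in the column, and each residue's share is divided equally among
#' the rows carrying it. Rows gapped at a column receive nothing from it.
#' A sequence's raw weight is the sum of its shares over all columns; on a
#' gap-free alignment the raw weights sum to the alignment length. Scaling to
#' a usable absolute level is deliberately left to [mean_scale()] /
#' [max_scale()].
#'
#' @param aln an [msa] object.
#' @return a raw (unscaled) [weight_vector] with method `henikoff`.
#' @export
henikoff_weights <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  X <- msa_matrix(aln)
  w <- numeric(aln$n)
  for (c in seq_len(aln$L)) {
    col <- X[, c]
    nongap <- col != GAP_STATE
    if (!any(nongap)) next  # all-gap column contributes nothing
    f_c <- mean(nongap)     # column weight: fraction of non-gapped rows
    tab <- tabulate(col[nongap], nbins = 20L)
    k <- sum(tab > 0L)      # distinct residues, gaps never counted
    share <- numeric(aln$n)
    share[nongap] <- f_c / (k * tab[col[nongap]])
    w <- w + share
  }
  weight_vector(w, "henikoff", ids = aln$ids)
}

#' Write a per-sequence weight file
#'
#' Plain-text dialect consumed by modified coupling engines: one weight per
#' line, line order matching the input sequence order of the alignment.
#'
#' @param w a [weight_vector].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weight_file <- function(w, path) {
  writeLines(format(.wvals(w), digits = 17, scientific = FALSE, trim = TRUE),
             path)
  invisible(path)
}

#' Read a per-sequence weight file
#'
#' @param path path to a plain-text file with one weight per line.
#' @param aln optional [msa]; when supplied, the number of weights must match
#'   the number of sequences and ids are attached.
#' @return numeric vector of weights (named when `aln` is given).
#' @export
read_weight_file <- function(path, aln = NULL) {
  v <- as.numeric(readLines(path))
  if (any(is.na(v)))
    stop("non-numeric line in weight file: ", path)
  if (!is.null(aln)) {
    stopifnot(inherits(aln, "msa"))
    if (length(v) != aln$n)
      stop("weight file has ", length(v), " entries but alignment has ",
           aln$n, " sequences")
    names(v) <- aln$ids
  }
  v
}
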