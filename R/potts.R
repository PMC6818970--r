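#' Fit a weighted pseudo-likelihood Potts model
#'
#' Fits the 21-state Potts model (20 amino acids + gap) that underlies direct
#' coupling analysis by maximizing the sequence-weighted log-pseudo-likelihood
#'
#' \deqn{\sum_s w_s \sum_i \log P(x_{si} \mid x_{s,-i}; h, J)
#'   - \lambda_h \|h\|^2 - \lambda_J \|J\|^2}
#'
#' where the conditional of column i is a softmax over its 21 states with
#' logits \eqn{h_i(a) + \sum_{j \ne i} J_{ij}(a, x_{sj})}. The pair coupling
#' tensor J is symmetric (\eqn{J_{ij}(a,b) = J_{ji}(b,a)}) with zero diagonal
#' blocks and the pair penalty follows the common coupling-engine convention
#' \eqn{\lambda_J = \mathrm{lfactor} \cdot (L - 1)} with each unordered pair
#' penalized once. Optimization is deterministic: zero initialization and
#' L-BFGS-B with a gradient tolerance, so repeated fits are identical.
#'
#' @param aln an [msa] object with `L >= 2` columns.
#' @param w a [weight_vector] or numeric vector of per-sequence weights
#'   (positive sum required). The effective N, i.e. `sum(w)`, sets the balance
#'   between data and regularization.
#' @param lfactor pair regularization strength factor; `lambda_pair =
#'   lfactor * (L - 1)`. The field-standard value is 0.2.
#' @param lambda_single L2 penalty on the single-site fields (default 0.01).
#' @param maxit iteration cap for L-BFGS-B.
#' @param pgtol projected-gradient stopping tolerance.
#' @return an object of class `potts_model` with elements `h` (L x 21 field
#'   matrix), `J` (full symmetric (L*21) x (L*21) coupling matrix with zero
#'   diagonal blocks), `L`, `regularization`, and `fit_meta` (objective,
#'   iterations, honest `converged` flag).
#' @export
fit_plm <- function(aln, w, lfactor = 0.2, lambda_single = 0.01,
                    maxit = 500L, pgtol = 1e-4) {
  stopifnot(inherits(aln, "msa"), aln$L >= 2L)
  wv <- .wvals(w)
  if (length(wv) != aln$n)
    stop("weight vector length (", length(wv), ") != number of sequences (",
         aln$n, ")")
  if (sum(wv) <= 0) stop("weights sum to zero")
  if (lfactor <= 0 || lambda_single <= 0)
    stop("regularization parameters must be positive")

  L <- aln$L
  q <- 21L
  n <- aln$n
  X <- msa_matrix(aln)
  X1 <- .one_hot(X, q)
  lambda_pair <- lfactor * (L - 1)

  layout <- .plm_layout(L, q)
  npar <- L * q + nrow(layout$pairs) * q * q
  obscol <- (col(X) - 1L) * q + X  # linear column of the observed state
  obs_idx <- cbind(rep(seq_len(n), L), as.vector(obscol))

  env <- new.env(parent = emptyenv())  # cache fn/gr at the same theta
  env$theta <- NULL

  compute <- function(theta) {
    h <- theta[seq_len(L * q)]
    Jvec <- theta[-seq_len(L * q)]
    Jfull <- matrix(0, L * q, L * q)
    Jfull[layout$upper] <- Jvec
    Jfull[layout$lower] <- Jvec
    Z <- X1 %*% Jfull
    Z <- sweep(Z, 2L, h, "+")
    # per-(sequence, column) log-normalizer over the 21 states
    Z3 <- array(Z, c(n, q, L))
    Zmax <- Z3[, 1L, , drop = TRUE]
    if (is.null(dim(Zmax))) Zmax <- matrix(Zmax, n, L)
    for (a in 2:q) Zmax <- pmax(Zmax, Z3[, a, ])
    Esum <- matrix(0, n, L)
    for (a in seq_len(q)) Esum <- Esum + exp(Z3[, a, ] - Zmax)
    logz <- Zmax + log(Esum)
    zobs <- matrix(Z[obs_idx], n, L)
    nll <- -sum(wv * rowSums(zobs - logz)) +
      lambda_single * sum(h^2) + lambda_pair * sum(Jvec^2)
    # gradient
    P <- Z
    for (a in seq_len(q)) P[, (seq_len(L) - 1L) * q + a] <-
      exp(Z3[, a, ] - logz)
    D <- P
    D[obs_idx] <- D[obs_idx] - 1
    D <- D * wv
    grad_h <- colSums(D) + 2 * lambda_single * h
    M <- crossprod(D, X1)  # t(D) %*% X1
    grad_J <- M[layout$upper] + M[layout$lower] + 2 * lambda_pair * Jvec
    env$theta <- theta
    env$fn <- nll
    env$gr <- c(grad_h, grad_J)
    invisible(NULL)
  }
  fn <- function(theta) {
    if (is.null(env$theta) || !identical(env$theta, theta)) compute(theta)
    env$fn
  }
  gr <- function(theta) {
    if (is.null(env$theta) || !identical(env$theta, theta)) compute(theta)
    env$gr
  }

  fit <- optim(rep(0, npar), fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, pgtol = pgtol, factr = 1e7))
  if (!is.finite(fit$value)) stop("pseudo-likelihood fit diverged")

  h <- matrix(fit$par[seq_len(L * q)], nrow = L, ncol = q, byrow = TRUE)
  Jfull <- matrix(0, L * q, L * q)
  Jfull[layout$upper] <- fit$par[-seq_len(L * q)]
  Jfull[layout$lower] <- fit$par[-seq_len(L * q)]
  structure(list(
    h = h, J = Jfull, L = L, q = q, ids = aln$ids,
    regularization = c(lambda_single = lambda_single, lfactor = lfactor,
                       lambda_pair = lambda_pair),
    weights_method = if (inherits(w, "weight_vector")) w$method else "custom",
    fit_meta = list(objective = fit$value,
                    iterations = unname(fit$counts["function"]),
                    converged = fit$convergence == 0L,
                    message = fit$message)),
    class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  cat("Potts model: L = ", x$L, ", q = ", x$q, "\n", sep = "")
  cat("  objective = ", format(x$fit_meta$objective),
      ", converged = ", x$fit_meta$converged, "\n", sep = "")
  cat("  lambda_single = ", x$regularization[["lambda_single"]],
      ", lambda_pair = ", x$regularization[["lambda_pair"]],
      " (lfactor = ", x$regularization[["lfactor"]], ")\n", sep = "")
  invisible(x)
}

# One-hot encoding of an n x L state matrix into n x (L*q)
.one_hot <- function(X, q) {
  n <- nrow(X)
  L <- ncol(X)
  X1 <- matrix(0, n, L * q)
  X1[cbind(rep(seq_len(n), L), as.vector((col(X) - 1L) * q + X))] <- 1
  X1
}

# index layout of upper (i<j) coupling blocks in the full (L*q) x (L*q) matrix
.plm_layout <- function(L, q) {
  pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  a <- rep(seq_len(q), times = q)   # row state within block (varies fastest)
  b <- rep(seq_len(q), each = q)
  nblk <- nrow(pairs)
  rows <- rep((pairs[, 1L] - 1L) * q, each = q * q) + rep(a, nblk)
  cols <- rep((pairs[, 2L] - 1L) * q, each = q * q) + rep(b, nblk)
  list(pairs = pairs,
       upper = cbind(rows, cols),
       lower = cbind(cols, rows))
}

# internal: objective/gradient at a given parameter vector (for testing the
# analytic gradient against finite differences without running the optimizer)
plm_objective <- function(aln, w, theta, lfactor = 0.2, lambda_single = 0.01) {
  stopifnot(inherits(aln, "msa"))
  wv <- .wvals(w)
  L <- aln$L; q <- 21L; n <- aln$n
  X <- msa_matrix(aln)
  X1 <- .one_hot(X, q)
  lambda_pair <- lfactor * (L - 1)
  layout <- .plm_layout(L, q)
  h <- theta[seq_len(L * q)]
  Jvec <- theta[-seq_len(L * q)]
  Jfull <- matrix(0, L * q, L * q)
  Jfull[layout$upper] <- Jvec
  Jfull[layout$lower] <- Jvec
  Z <- sweep(X1 %*% Jfull, 2L, h, "+")
  Z3 <- array(Z, c(n, q, L))
  Zmax <- matrix(Z3[, 1L, ], n, L)
  for (a in 2:q) Zmax <- pmax(Zmax, Z3[, a, ])
  Esum <- matrix(0, n, L)
  for (a in seq_len(q)) Esum <- Esum + exp(Z3[, a, ] - Zmax)
  logz <- Zmax + log(Esum)
  obs_idx <- cbind(rep(seq_len(n), L), as.vector((col(X) - 1L) * q + X))
  zobs <- matrix(Z[obs_idx], n, L)
  nll <- -sum(wv * rowSums(zobs - logz)) +
    lambda_single * sum(h^2) + lambda_pair * sum(Jvec^2)
  P <- Z
  for (a in seq_len(q)) P[, (seq_len(L) - 1L) * q + a] <- exp(Z3[, a, ] - logz)
  D <- P
  D[obs_idx] <- D[obs_idx] - 1
  D <- D * wv
  M <- crossprod(D, X1)
  list(value = nll,
       gradient = c(colSums(D) + 2 * lambda_single * h,
                    M[layout$upper] + M[layout$lower] + 2 * lambda_pair * Jvec))
}

#' Extract raw coupling scores from a fitted Potts model
#'
#' The score of a column pair (i, j) is the Frobenius norm of the
#' zero-sum-gauge transform of the 20x20 amino-acid part of the coupling
#' block \eqn{J_{ij}} (the gap state is excluded). The zero-sum gauge removes
#' the additive row/column freedoms of the Potts parameterization, so scores
#' are invariant under gauge shifts of J.
#'
#' @param model a fitted `potts_model`.
#' @return a `coupling_matrix` (variant `raw`): symmetric L x L non-negative
#'   score matrix with zero diagonal.
#' @export
coupling_scores <- function(model) {
  stopifnot(inherits(model, "potts_model"))
  L <- model$L
  q <- model$q
  S <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    ri <- (i - 1L) * q + seq_len(20L)
    for (j in (i + 1L):L) {
      B <- model$J[ri, (j - 1L) * q + seq_len(20L)]
      B <- B - rowMeans(B)[row(B)] - colMeans(B)[col(B)] + mean(B)
      S[i, j] <- S[j, i] <- sqrt(sum(B^2))
    }
  }
  coupling_matrix(S, "raw",
                  source = list(weights_method = model$weights_method,
                                lfactor = model$regularization[["lfactor"]]))
}

#' Construct a coupling-score matrix object
#'
#' @param scores symmetric L x L numeric matrix with zero diagonal.
#' @param variant `raw`, `apc` or `entropy`.
#' @param source optional provenance list (weights method, lfactor).
#' @return an object of class `coupling_matrix`.
#' @export
coupling_matrix <- function(scores, variant = c("raw", "apc", "entropy"),
                            source = NULL) {
  variant <- match.arg(variant)
  scores <- as.matrix(scores)
  if (nrow(scores) != ncol(scores))
    stop("coupling score matrix must be square")
  if (max(abs(scores - t(scores))) > 1e-8)
    stop("coupling score matrix must be symmetric")
  diag(scores) <- 0
  structure(list(scores = scores, variant = variant, source = source),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat("Coupling scores [", x$variant, "]: ", nrow(x$scores), " x ",
      ncol(x$scores), " columns\n", sep = "")
  invisible(x)
}

#' Average product correction (APC)
#'
#' Subtracts the product of the row means divided by the grand mean (all
#' computed over off-diagonal entries) from each score. APC removes the
#' rank-one background component of coupling matrices, which absorbs much of
#' the shared phylogenetic and entropic signal, and is the single largest
#' accuracy improvement in coupling-based contact prediction.
#'
#' @param cm a `coupling_matrix` with variant `raw`.
#' @return a `coupling_matrix` with variant `apc`.
#' @export
apc_correct <- function(cm) {
  stopifnot(inherits(cm, "coupling_matrix"))
  if (cm$variant != "raw")
    stop("APC must be applied to a raw coupling matrix")
  S <- cm$scores
  L <- nrow(S)
  if (L < 2L) stop("need at least 2 columns")
  rmean <- rowSums(S) / (L - 1L)  # diagonal is zero, so this excludes it
  gmean <- sum(S) / (L * (L - 1L))
  if (gmean == 0) {
    warning("grand mean of coupling scores is zero; APC is a no-op")
    return(cm)
  }
  corrected <- S - outer(rmean, rmean) / gmean
  diag(corrected) <- 0
  coupling_matrix(corrected, "apc", source = cm$source)
}

#' Entropy correction of coupling scores
#'
#' Subtracts a fitted multiple of \eqn{\sqrt{S_i S_j}} from each score, where
#' \eqn{S_i} is the weighted Shannon entropy of column i over the 21 states
#' (frequencies from the same sequence weights as the fit, no pseudocounts)
#' and the coefficient is the least-squares slope of the scores against
#' \eqn{\sqrt{S_i S_j}} over all column pairs. Columns with high entropy
#' attract inflated raw couplings; this correction removes that trend.
#'
#' @param cm a `coupling_matrix` with variant `raw`.
#' @param aln the [msa] the model was fitted to.
#' @param w the [weight_vector] (or numeric weights) used in the fit.
#' @return a `coupling_matrix` with variant `entropy`.
#' @export
entropy_correct <- function(cm, aln, w) {
  stopifnot(inherits(cm, "coupling_matrix"), inherits(aln, "msa"))
  if (cm$variant != "raw")
    stop("entropy correction must be applied to a raw coupling matrix")
  S <- cm$scores
  L <- nrow(S)
  if (L != aln$L) stop("coupling matrix / alignment size mismatch")
  ent <- column_entropies(aln, w)
  if (all(ent == 0)) {
    warning("all columns are constant (zero entropy); correction is identity")
    return(coupling_matrix(S, "entropy", source = cm$source))
  }
  E <- sqrt(outer(ent, ent))
  ut <- upper.tri(S)
  alpha <- sum(S[ut] * E[ut]) / sum(E[ut]^2)
  corrected <- S - alpha * E
  diag(corrected) <- 0
  coupling_matrix(corrected, "entropy", source = cm$source)
}

#' Weighted per-column Shannon entropies
#'
#' @param aln an [msa] object.
#' @param w a [weight_vector] or numeric weights (default uniform).
#' @return numeric vector of length L: entropy (nats) of the weighted state
#'   frequencies over the 21-letter alphabet.
#' @export
column_entropies <- function(aln, w = NULL) {
  stopifnot(inherits(aln, "msa"))
  wv <- if (is.null(w)) rep(1, aln$n) else .wvals(w)
  X <- msa_matrix(aln)
  vapply(seq_len(aln$L), function(c) {
    f <- vapply(seq_len(21L), function(s) sum(wv[X[, c] == s]), numeric(1))
    f <- f / sum(f)
    f <- f[f > 0]
    -sum(f * log(f))
  }, numeric(1))
}

#' Write a dense coupling-score matrix
#'
#' Whitespace-delimited L x L text matrix, the dialect of common coupling
#' engines.
#'
#' @param cm a `coupling_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coupling_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "coupling_matrix"))
  write.table(format(cm$scores, digits = 8, trim = TRUE), path,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a dense coupling-score matrix
#'
#' @param path path to a whitespace-delimited square matrix.
#' @param variant variant tag to attach.
#' @return a `coupling_matrix`.
#' @export
read_coupling_matrix <- function(path, variant = "raw") {
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  m <- (m + t(m)) / 2  # printed precision can break exact symmetry
  coupling_matrix(m, variant)
}

#' Write a tidy pair-score table
#'
#' TSV with 1-based column indices i < j and one column per score variant.
#'
#' @param raw,apc,entropy `coupling_matrix` objects of matching size (only
#'   `raw` is required).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coupling_tsv <- function(raw, path, apc = NULL, entropy = NULL) {
  stopifnot(inherits(raw, "coupling_matrix"))
  L <- nrow(raw$scores)
  idx <- which(upper.tri(raw$scores), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(i = idx[, 1L], j = idx[, 2L],
                   raw = raw$scores[idx])
  if (!is.null(apc)) df$apc <- apc$scores[idx]
  if (!is.null(entropy)) df$entropy <- entropy$scores[idx]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
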