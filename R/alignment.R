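#' @importFrom stats optim cor runif rnorm setNames quantile median
#' @importFrom utils write.table read.table head
NULL

# 21-letter alphabet: 20 amino acids + gap, in fixed order. Index 21 is the gap.
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
GAP_STATE <- 21L

#' Construct a protein multiple sequence alignment object
#'
#' An `msa` is the container every weighting scheme attaches to: a set of
#' equal-length aligned amino-acid strings over the 21-symbol alphabet
#' (20 amino acids plus the gap `-`). Characters are case-normalized and any
#' symbol outside the alphabet (`X`, `B`, `Z`, `U`, `O`, `.`, etc.) is mapped
#' to the gap, so that downstream frequency and Potts-model code only ever
#' sees 21 states.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param rows character vector of aligned sequences, same length as `ids`.
#' @param reference_id optional id of the structure-bearing reference sequence.
#' @return An object of class `msa` with fields `ids`, `rows`, `n`, `L`,
#'   `reference_id`.
#' @export
msa <- function(ids, rows, reference_id = NULL) {
  ids <- as.character(ids)
  rows <- toupper(as.character(rows))
  if (length(ids) != length(rows))
    stop("`ids` and `rows` must have the same length")
  if (length(rows) == 0L)
    stop("empty alignment: no sequences")
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  L <- unique(nchar(rows))
  if (length(L) != 1L)
    stop("alignment rows have unequal lengths: ",
         paste(sort(unique(nchar(rows))), collapse = ", "))
  # normalize: anything outside the 21-letter alphabet becomes a gap
  rows <- vapply(rows, .normalize_row, character(1), USE.NAMES = FALSE)
  if (!is.null(reference_id) && !reference_id %in% ids)
    stop("reference_id '", reference_id, "' not found among sequence ids")
  structure(
    list(ids = ids, rows = rows, n = length(ids), L = as.integer(L),
         reference_id = reference_id),
    class = "msa"
  )
}

.normalize_row <- function(row) {
  ch <- strsplit(row, "")[[1]]
  ch[!ch %in% AA_ALPHABET] <- "-"
  paste(ch, collapse = "")
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple sequence alignment: ", x$n, " sequences x ", x$L,
      " columns\n", sep = "")
  if (!is.null(x$reference_id))
    cat("Reference sequence: ", x$reference_id, "\n", sep = "")
  shown <- head(seq_len(x$n), 5L)
  for (i in shown)
    cat(sprintf("  %-12s %s\n", x$ids[i],
                if (x$L > 50) paste0(substr(x$rows[i], 1, 50), "...") else x$rows[i]))
  if (x$n > 5L) cat("  ... (", x$n - 5L, " more)\n", sep = "")
  invisible(x)
}

#' Encode an alignment as an integer state matrix
#'
#' States are 1..20 for amino acids in the order `ACDEFGHIKLMNPQRSTVWY` and
#' 21 for the gap.
#'
#' @param aln an [msa] object.
#' @return integer matrix of dimension n x L with rownames `aln$ids`.
#' @export
msa_matrix <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  m <- matrix(match(unlist(strsplit(aln$rows, "")), AA_ALPHABET),
              nrow = aln$n, ncol = aln$L, byrow = TRUE)
  rownames(m) <- aln$ids
  storage.mode(m) <- "integer"
  m
}

#' Read an aligned FASTA file
#'
#' The first whitespace-delimited token of each FASTA header is used as the
#' sequence identifier. All records must have equal (aligned) length.
#'
#' @param path path to an aligned FASTA file.
#' @param reference_id optional id of the reference sequence.
#' @return an [msa] object, preserving input record order.
#' @export
read_fasta_alignment <- function(path, reference_id = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  msa(ids = ids, rows = as.character(set), reference_id = reference_id)
}

#' Write an alignment to FASTA
#'
#' @param aln an [msa] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "msa"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", aln$ids, "\n", aln$rows), con, sep = "\n")
  invisible(path)
}

#' Pairwise sequence identity
#'
#' Fraction of alignment columns at which two rows carry the identical symbol,
#' divided by the full alignment length. Gap--gap columns count as identical
#' (see the package vignette for the rationale).
#'
#' @param aln an [msa] object.
#' @param i,j sequence indices (1-based).
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(aln, i, j) {
  stopifnot(inherits(aln, "msa"))
  if (any(c(i, j) < 1L) || any(c(i, j) > aln$n))
    stop("sequence index out of range")
  a <- strsplit(aln$rows[i], "")[[1]]
  b <- strsplit(aln$rows[j], "")[[1]]
  sum(a == b) / aln$L
}

#' All-against-all identity matrix
#'
#' @param aln an [msa] object.
#' @return symmetric n x n matrix of identity fractions with unit diagonal.
#' @export
identity_matrix <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  X <- msa_matrix(aln)
  counts <- matrix(0, aln$n, aln$n)
  # sum of per-state match indicators; BLAS-level outer products per symbol
  for (s in seq_along(AA_ALPHABET)) {
    M <- (X == s) * 1
    counts <- counts + tcrossprod(M)
  }
  m <- counts / aln$L
  dimnames(m) <- list(aln$ids, aln$ids)
  m
}

#' Randomly down-sample an alignment to a maximum size
#'
#' If the alignment has more than `max_n` sequences, a uniform random subset
#' of size `max_n` is retained (mandatorily including `keep_id` when given,
#' e.g. the structure-bearing reference). Retained rows keep their original
#' relative order. With `n <= max_n` the input is returned unchanged.
#'
#' @param aln an [msa] object.
#' @param max_n maximum number of sequences to keep.
#' @param seed integer RNG seed for reproducibility.
#' @param keep_id optional id that must be retained.
#' @return an [msa] object with at most `max_n` sequences.
#' @export
downsample <- function(aln, max_n, seed = 1L, keep_id = aln$reference_id) {
  stopifnot(inherits(aln, "msa"), max_n >= 1L)
  if (!is.null(keep_id) && !keep_id %in% aln$ids)
    stop("keep_id '", keep_id, "' not present in the alignment")
  if (aln$n <= max_n) return(aln)
  idx <- seq_len(aln$n)
  keep <- integer(0)
  if (!is.null(keep_id)) {
    keep <- match(keep_id, aln$ids)
    idx <- setdiff(idx, keep)
  }
  old_seed <- .save_rng(seed)
  on.exit(.restore_rng(old_seed))
  chosen <- sort(c(keep, sample(idx, max_n - length(keep))))
  msa(aln$ids[chosen], aln$rows[chosen], reference_id = aln$reference_id)
}

# Seed hygiene: use a local RNG stream so package functions do not clobber the
# caller's random state.
.save_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
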