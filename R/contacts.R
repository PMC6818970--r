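BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Side-chain geometric centers from a PDB structure
#'
#' For each residue of the selected chain, the unweighted mean coordinate of
#' its side-chain heavy atoms: everything except hydrogens and the backbone
#' N/CA/C/O(/OXT), with the C-beta atom included. Glycine has no side-chain
#' heavy atoms and uses its C-alpha coordinate instead; any other residue
#' whose side-chain atoms are entirely missing from the model also falls back
#' to C-alpha, with a warning. Residues with neither side-chain atoms nor a
#' C-alpha are dropped (they become unresolved/unmapped).
#'
#' @param pdb a structure from [bio3d::read.pdb()], or a path to a PDB file.
#' @param chain chain identifier (default: first chain in the file).
#' @return list with `centers` (L x 3 coordinate matrix), `resno` (PDB residue
#'   numbers), `resid` (residue names); rows follow the chain's residue order,
#'   so row k is residue ordinal k.
#' @export
side_chain_centers <- function(pdb, chain = NULL) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' not found in structure")
  at <- at[is.na(at$elesy) | toupper(at$elesy) != "H", , drop = FALSE]
  at <- at[!grepl("^H", trimws(at$elety)) | !is.na(at$elesy), , drop = FALSE]
  resnos <- unique(at$resno)
  centers <- matrix(NA_real_, length(resnos), 3L,
                    dimnames = list(NULL, c("x", "y", "z")))
  resid <- character(length(resnos))
  fallback <- character(0)
  for (k in seq_along(resnos)) {
    r <- at[at$resno == resnos[k], , drop = FALSE]
    resid[k] <- r$resid[1L]
    side <- r[!trimws(r$elety) %in% BACKBONE_ATOMS, , drop = FALSE]
    if (nrow(side) > 0L) {
      centers[k, ] <- colMeans(cbind(side$x, side$y, side$z))
    } else {
      ca <- r[trimws(r$elety) == "CA", , drop = FALSE]
      if (nrow(ca) > 0L) {
        centers[k, ] <- c(ca$x[1L], ca$y[1L], ca$z[1L])
        if (resid[k] != "GLY") fallback <- c(fallback, as.character(resnos[k]))
      }
    }
  }
  ok <- !is.na(centers[, 1L])
  if (!any(ok)) stop("no residues with resolvable coordinates in chain ", chain)
  if (length(fallback))
    warning("side-chain atoms missing for residue(s) ",
            paste(fallback, collapse = ", "), "; C-alpha used instead")
  list(centers = centers[ok, , drop = FALSE], resno = resnos[ok],
       resid = resid[ok])
}

#' Residue-residue contact map from side-chain centers
#'
#' Two residues are in contact when the Euclidean distance between their
#' side-chain geometric centers is at most `threshold` angstroms (boundary
#' inclusive).
#'
#' @param centers L x 3 coordinate matrix (e.g. from [side_chain_centers()]),
#'   or the list returned by that function.
#' @param threshold contact distance in angstroms (default 7.5).
#' @return an object of class `contact_map`: list with `contacts` (symmetric
#'   logical matrix, FALSE diagonal), `distances`, `threshold`, `n_residues`.
#' @export
contact_map <- function(centers, threshold = 7.5) {
  if (is.list(centers) && !is.null(centers$centers)) centers <- centers$centers
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3L, nrow(centers) >= 2L, threshold > 0)
  d <- as.matrix(stats::dist(centers))
  contacts <- d <= threshold
  diag(contacts) <- FALSE
  dimnames(contacts) <- NULL
  dimnames(d) <- NULL
  structure(list(contacts = contacts, distances = d, threshold = threshold,
                 n_residues = nrow(centers)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("Contact map: ", x$n_residues, " residues, threshold ", x$threshold,
      " A, ", sum(x$contacts[upper.tri(x$contacts)]), " contacts\n", sep = "")
  invisible(x)
}

#' Write a contact map as a TSV edge list
#'
#' @param cm a `contact_map`.
#' @param path output path; columns res_i, res_j, distance for each contact
#'   pair i < j.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(cm, path) {
  stopifnot(inherits(cm, "contact_map"))
  idx <- which(cm$contacts & upper.tri(cm$contacts), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(res_i = idx[, 1L], res_j = idx[, 2L],
                   distance = cm$distances[idx])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map alignment columns to reference residue ordinals
#'
#' The k-th non-gap character of the reference row maps its alignment column
#' to residue ordinal k (1-based) of the reference chain; reference-gap
#' columns are unmapped and excluded from contact scoring.
#'
#' @param aln an [msa] object.
#' @param reference_id id of the structure-bearing reference row (defaults to
#'   `aln$reference_id`).
#' @return list with `column_to_residue` (integer vector of length L,
#'   `NA` where unmapped), `coverage` (fraction of reference residues mapped),
#'   `n_residues` (reference length).
#' @export
map_alignment_to_reference <- function(aln, reference_id = aln$reference_id) {
  stopifnot(inherits(aln, "msa"))
  if (is.null(reference_id) || !reference_id %in% aln$ids)
    stop("reference_id absent from the alignment")
  ref <- strsplit(aln$rows[match(reference_id, aln$ids)], "")[[1]]
  nongap <- ref != "-"
  col_to_res <- rep(NA_integer_, aln$L)
  col_to_res[nongap] <- seq_len(sum(nongap))
  list(column_to_residue = col_to_res,
       coverage = 1,  # every reference residue appears in exactly one column
       n_residues = sum(nongap))
}

#' Top-L positive predictive value of coupling scores
#'
#' Ranks all eligible column pairs (both columns mapped to reference residues,
#' residue separation at least `min_separation`) by coupling score in
#' descending order, with deterministic tie-breaking by smaller i then
#' smaller j, and reports the fraction of the top L pairs that are contacts
#' in the reference structure. L is the reference length by convention.
#'
#' @param cm a `coupling_matrix`.
#' @param map column-to-residue map from [map_alignment_to_reference()].
#' @param contacts a `contact_map` over the reference residues.
#' @param L number of top pairs to evaluate (default: the reference length).
#' @param min_separation minimum residue separation |res_i - res_j| for a pair
#'   to be eligible; the default 1 excludes only self-pairs.
#' @return PPV fraction in `[0, 1]`.
#' @export
ppv_top_L <- function(cm, map, contacts, L = map$n_residues,
                      min_separation = 1L) {
  stopifnot(inherits(cm, "coupling_matrix"), inherits(contacts, "contact_map"))
  if (map$n_residues != contacts$n_residues)
    stop("map covers ", map$n_residues, " residues but contact map has ",
         contacts$n_residues)
  S <- cm$scores
  if (nrow(S) != length(map$column_to_residue))
    stop("coupling matrix size does not match the alignment length of the map")
  idx <- which(upper.tri(S), arr.ind = TRUE)
  ri <- map$column_to_residue[idx[, 1L]]
  rj <- map$column_to_residue[idx[, 2L]]
  ok <- !is.na(ri) & !is.na(rj) & abs(ri - rj) >= min_separation
  idx <- idx[ok, , drop = FALSE]
  ri <- ri[ok]; rj <- rj[ok]
  if (nrow(idx) == 0L) stop("no eligible column pairs")
  if (nrow(idx) < L) {
    warning("only ", nrow(idx), " eligible pairs for top-", L,
            " evaluation; PPV computed over all eligible pairs")
    L <- nrow(idx)
  }
  ord <- order(-S[idx], idx[, 1L], idx[, 2L])
  top <- ord[seq_len(L)]
  hits <- contacts$contacts[cbind(ri[top], rj[top])]
  sum(hits) / L
}
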