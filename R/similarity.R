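#' Identity-by-state and mismatch distances between profiles
#'
#' IBS between two diploid-representable profiles is, per locus, the size of
#' the multiset intersection of the two called allele sets (0-2), summed
#' over loci; missing calls simply contribute no matches, so 21 complete
#' loci give a maximum IBS of 42. The mismatch distance used for MDS is the
#' slot-wise mismatch count normalized by the number of compared slots.
#'
#' @name similarity
NULL

# coerce a profile-like object to a 2L slot vector (diploid representation)
as_slot_vector <- function(x) {
  if (inherits(x, "consensus_profile")) return(x$calls)
  if (inherits(x, "genotype_profile")) return(as.vector(t(unclass(x))))
  if (is.numeric(x)) return(x)
  stop("cannot interpret object as an allele-slot profile")
}

# multiset intersection size of two sorted allele pairs (NAs = absent)
locus_ibs <- function(x1, x2, y1, y2) {
  m11 <- !is.na(x1) & !is.na(y1) & x1 == y1
  m12 <- !is.na(x1) & !is.na(y2) & x1 == y2
  m21 <- !is.na(x2) & !is.na(y1) & x2 == y1
  m22 <- !is.na(x2) & !is.na(y2) & x2 == y2
  two <- (m11 & m22) | (m12 & m21)
  ifelse(two, 2L, (m11 | m12 | m21 | m22) * 1L)
}

#' Count identity-by-state allele sharing
#'
#' @param a,b profiles over the same panel: [genotype_profile],
#'   [consensus_profile], or a diploid slot vector (length 2L).
#' @return integer IBS count (0 to 2L).
#' @export
ibs_count <- function(a, b) {
  va <- as_slot_vector(a)
  vb <- as_slot_vector(b)
  if (length(va) != length(vb)) stop("profiles cover different panels")
  L <- length(va) / 2
  i1 <- 2 * seq_len(L) - 1
  sum(locus_ibs(va[i1], va[i1 + 1], vb[i1], vb[i1 + 1]))
}

#' Pairwise IBS matrix over all cells of a mixture
#'
#' Vectorized per locus; haploid datasets are compared on their single slot
#' per locus (IBS 0-1 per locus).
#' @param dataset a `mixture_dataset`.
#' @return symmetric integer matrix of pairwise IBS counts.
#' @export
ibs_matrix <- function(dataset) {
  X <- dataset$profiles
  n <- nrow(X)
  out <- matrix(0L, n, n)
  L <- n_loci(dataset$panel)
  eqo <- function(u, v) {
    r <- outer(u, v, "==")
    r[is.na(r)] <- FALSE
    r
  }
  if (dataset$ploidy == "haploid") {
    for (i in seq_len(L)) out <- out + eqo(X[, i], X[, i])
  } else {
    for (i in seq_len(L)) {
      a1 <- X[, 2 * i - 1]; a2 <- X[, 2 * i]
      m11 <- eqo(a1, a1); m12 <- eqo(a1, a2)
      m21 <- eqo(a2, a1); m22 <- eqo(a2, a2)
      two <- (m11 & m22) | (m12 & m21)
      out <- out + ifelse(two, 2L, (m11 | m12 | m21 | m22) * 1L)
    }
  }
  dimnames(out) <- list(rownames(X), rownames(X))
  out
}

#' Normalized slot-mismatch distance
#'
#' A slot mismatches when exactly one profile is missing there or both are
#' called but unequal; slots missing in both profiles are excluded from
#' numerator and denominator. Two profiles with no comparable slot are
#' assigned distance 0 (no evidence of difference).
#'
#' @param a,b profiles of the same ploidy and panel (slot vectors or
#'   profile objects).
#' @return distance in `[0, 1]`.
#' @export
mismatch_distance <- function(a, b) {
  va <- as_slot_vector(a)
  vb <- as_slot_vector(b)
  if (length(va) != length(vb)) stop("profiles differ in ploidy or panel")
  both_na <- is.na(va) & is.na(vb)
  compared <- sum(!both_na)
  if (compared == 0L) return(0)
  mism <- xor(is.na(va), is.na(vb)) | (!is.na(va) & !is.na(vb) & va != vb)
  sum(mism) / compared
}

#' Pairwise mismatch-distance matrix
#'
#' @param X profile matrix (cells x slots, NA = missing).
#' @return symmetric matrix of [mismatch_distance()] values.
#' @export
mismatch_matrix <- function(X) {
  n <- nrow(X)
  S <- ncol(X)
  mism <- matrix(0, n, n)
  comp <- matrix(0, n, n)
  na <- is.na(X)
  for (s in seq_len(S)) {
    xs <- X[, s]
    nas <- na[, s]
    one_na <- outer(nas, nas, xor)
    neq <- outer(xs, xs, "!=")
    neq[is.na(neq)] <- FALSE
    mism <- mism + (one_na | neq)
    comp <- comp + !outer(nas, nas, "&")
  }
  out <- matrix(0, n, n)
  pos <- comp > 0
  out[pos] <- mism[pos] / comp[pos]
  dimnames(out) <- list(rownames(X), rownames(X))
  out
}

#' Embed single-cell profiles in low dimensions by classical MDS
#'
#' Classical (Torgerson) scaling of the pairwise mismatch-distance matrix —
#' double-centered squared distances, top eigenvectors scaled by root
#' eigenvalues — as implemented by [stats::cmdscale()]. Deterministic up to
#' axis sign; degenerate all-zero distance matrices yield all-zero
#' coordinates.
#'
#' @param dataset a `mixture_dataset` (needs at least `dims + 1` cells).
#' @param dims embedding dimension (default 3).
#' @return cells x dims coordinate matrix.
#' @export
mds_embed <- function(dataset, dims = 3L) {
  X <- dataset$profiles
  if (nrow(X) < dims + 1L) stop("need at least dims + 1 cells")
  D <- mismatch_matrix(X)
  if (all(D == 0)) {
    coords <- matrix(0, nrow(X), dims)
  } else {
    coords <- stats::cmdscale(D, k = dims)
    if (ncol(coords) < dims)  # rank-deficient configurations
      coords <- cbind(coords, matrix(0, nrow(coords), dims - ncol(coords)))
  }
  rownames(coords) <- rownames(X)
  colnames(coords) <- c("x", "y", "z", paste0("d", seq_len(max(0, dims - 3))))[seq_len(dims)]
  coords
}

#' Write MDS coordinates as CSV
#'
#' Columns: cell_id, x, y, z, optional cluster and truth_label.
#' @param dataset a `mixture_dataset`.
#' @param coords output of [mds_embed()].
#' @param path output path.
#' @param cluster optional integer cluster labels.
#' @export
write_coords_csv <- function(dataset, coords, path, cluster = NULL) {
  df <- data.frame(cell_id = rownames(dataset$profiles), coords)
  if (!is.null(cluster)) df$cluster <- cluster
  if (!is.null(dataset$truth)) df$truth_label <- dataset$truth
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average classification error of an IBS threshold
#'
#' Classification rule: "same source iff IBS > threshold". Returns the
#' average of the false-positive rate (different-source pairs above the
#' threshold) and the false-negative rate (same-source pairs at or below
#' it).
#'
#' @param same_source_ibs integer IBS sample for truly same-source pairs.
#' @param different_source_ibs integer IBS sample for different-source pairs.
#' @param threshold integer IBS threshold.
#' @return average error rate in `[0, 1]`.
#' @export
threshold_error_rate <- function(same_source_ibs, different_source_ibs,
                                 threshold) {
  if (!length(same_source_ibs) || !length(different_source_ibs))
    stop("both samples must be non-empty")
  fpr <- mean(different_source_ibs > threshold)
  fnr <- mean(same_source_ibs <= threshold)
  (fpr + fnr) / 2
}
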