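#' Consensus profiles from clustered single cells
#'
#' The consensus allele at each slot is the most frequent observed allele at
#' that slot among the cells of the cluster; missing calls (drop-outs) are
#' ignored during voting, and modal-vote ties break toward the smaller
#' allele designation. Haploid clusters are expanded to a diploid consensus:
#' per locus the two most frequent distinct observed alleles fill slots 1-2
#' ascending; a single observed distinct allele is duplicated (homozygous),
#' so a consensus built on one haploid cell is homozygous at every called
#' locus.
#'
#' @param cells matrix of cell profiles (rows = cells of one cluster;
#'   2L columns diploid, L columns haploid, NA = missing).
#' @param ploidy ploidy of the input cells.
#' @param table the panel (used for slot naming).
#' @return object of class `consensus_profile`: list with `calls` (2L slot
#'   vector, NA where no votes), `support` (cells voting for the winner per
#'   slot) and `cluster_size`.
#' @export
consensus_profile <- function(cells, table,
                              ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1)
  if (nrow(cells) == 0L) stop("empty cluster")
  L <- n_loci(table)
  calls <- rep(NA_real_, 2 * L)
  support <- integer(2 * L)
  names(calls) <- names(support) <- slot_names(table)
  if (ploidy == "diploid") {
    stopifnot(ncol(cells) == 2 * L)
    for (s in seq_len(2 * L)) {
      v <- cells[, s]
      v <- v[!is.na(v)]
      if (!length(v)) next
      tab <- base::table(v)
      win <- as.numeric(names(tab))[tab == max(tab)]
      calls[s] <- min(win)  # tie -> smaller designation
      support[s] <- max(tab)
    }
  } else {
    stopifnot(ncol(cells) == L)
    for (i in seq_len(L)) {
      v <- cells[, i]
      v <- v[!is.na(v)]
      if (!length(v)) next
      tab <- sort(base::table(v), decreasing = TRUE)
      vals <- as.numeric(names(tab))
      # deterministic: among equal counts prefer the smaller allele
      ord <- order(-as.integer(tab), vals)
      vals <- vals[ord]; cnt <- as.integer(tab)[ord]
      if (length(vals) == 1L) {
        calls[2 * i - 1] <- calls[2 * i] <- vals[1L]
        support[2 * i - 1] <- support[2 * i] <- cnt[1L]
      } else {
        top <- sort(vals[1:2])
        calls[2 * i - 1] <- top[1L]
        calls[2 * i] <- top[2L]
        support[c(2 * i - 1, 2 * i)] <- cnt[match(top, vals)]
      }
    }
  }
  structure(list(calls = calls, support = support,
                 cluster_size = nrow(cells)),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("consensus profile from %d cell(s): %d/%d slots called\n",
              x$cluster_size, sum(!is.na(x$calls)), length(x$calls)))
  invisible(x)
}

#' Consensus accuracy against the true genotype
#'
#' Fraction of the 2L truth allele slots (truth pairs sorted ascending)
#' whose consensus call equals the truth allele; missing consensus slots
#' count as incorrect.
#'
#' @param consensus a [consensus_profile] (or a 2L slot vector).
#' @param truth a [genotype_profile].
#' @return accuracy in `[0, 1]`.
#' @export
consensus_accuracy <- function(consensus, truth) {
  calls <- if (inherits(consensus, "consensus_profile")) consensus$calls
           else consensus
  tr <- as.vector(t(unclass(truth)))  # slot order a1, a2 per locus
  if (length(calls) != length(tr))
    stop("consensus and truth cover different numbers of slots")
  mean(!is.na(calls) & calls == tr)
}

#' Optimally match consensus profiles to true contributors
#'
#' Finds the one-to-one assignment maximizing total IBS between matched
#' pairs by exhaustive search over permutations (the workflow caps the NOC
#' at 6, so at most 720 candidates); ties break toward the
#' lexicographically first permutation.
#'
#' @param consensus_list list of [consensus_profile]s.
#' @param truths list of [genotype_profile]s, same length.
#' @return integer vector `m`: consensus i is matched to `truths[[m[i]]]`.
#' @export
match_clusters_to_truth <- function(consensus_list, truths) {
  k <- length(consensus_list)
  if (k != length(truths)) stop("lists must have equal length")
  score <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    score[i, j] <- ibs_count(consensus_list[[i]], truths[[j]])
  perms <- permutations(k)
  best <- NULL
  best_total <- -Inf
  for (r in seq_len(nrow(perms))) {
    tot <- sum(score[cbind(seq_len(k), perms[r, ])])
    if (tot > best_total) {
      best_total <- tot
      best <- perms[r, ]
    }
  }
  best
}

# all permutations of 1..k in lexicographic order
permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (first in seq_len(k)) {
    rest <- matrix(setdiff(seq_len(k), first)[sub], nrow(sub), k - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

#' Write a consensus profile as CSV
#'
#' Same long-format dialect as [write_profiles_csv()] plus support columns.
#' @param consensus a [consensus_profile].
#' @param table the panel.
#' @param path output path.
#' @export
write_consensus_csv <- function(consensus, table, path) {
  L <- n_loci(table)
  df <- data.frame(locus = table$loci,
                   allele1 = consensus$calls[2 * seq_len(L) - 1],
                   allele2 = consensus$calls[2 * seq_len(L)],
                   support1 = consensus$support[2 * seq_len(L) - 1],
                   support2 = consensus$support[2 * seq_len(L)])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
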