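#' Allele drop-out / drop-in model
#'
#' `D` is the per-allele drop-out probability at a heterozygous locus, `D2`
#' the whole-locus drop-out probability at a homozygous locus (default
#' D2 = D^2 / 2), and `e` the per-called-allele drop-in (miscall)
#' probability: a surviving call is replaced by a uniformly random *other*
#' allele of the locus. Drop-out is decided first; miscall applies only to
#' surviving calls, so a heterozygous locus showing a drop-in necessarily
#' lost the true allele it replaced.
#'
#' @param D per-allele drop-out probability at heterozygous loci.
#' @param D2 whole-locus drop-out probability at homozygous loci.
#' @param e per-called-allele drop-in probability.
#' @return object of class `drop_model`.
#' @export
drop_model <- function(D = 0.2, D2 = D^2 / 2, e = 0.01) {
  stopifnot(D >= 0, D <= 1, D2 >= 0, D2 <= 1, e >= 0, e <= 1)
  structure(list(D = D, D2 = D2, e = e), class = "drop_model")
}

# apply independent uniform miscalls to a vector of called alleles (NA kept)
miscall <- function(x, locus_alleles, e) {
  if (e <= 0) return(x)
  called <- which(!is.na(x))
  if (!length(called)) return(x)
  flip <- called[stats::runif(length(called)) < e]
  if (length(flip)) {
    A <- length(locus_alleles)
    j <- match(x[flip], locus_alleles)
    r <- sample.int(A - 1L, length(flip), replace = TRUE)
    x[flip] <- locus_alleles[r + (r >= j)]
  }
  x
}

# Vectorized simulation of n single-cell profiles from one genotype.
# Returns an n x 2L (diploid) or n x L (haploid) matrix, NA = missing,
# diploid slots sorted ascending and left-packed per locus.
sim_cells <- function(genotype, n, table, model = drop_model(),
                      ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  G <- unclass(genotype)
  L <- nrow(G)
  if (ploidy == "haploid") {
    out <- matrix(NA_real_, n, L, dimnames = list(NULL, table$loci))
    for (i in seq_len(L)) {
      al <- G[i, 1L + (stats::runif(n) < 0.5)]
      al[stats::runif(n) < model$D] <- NA
      out[, i] <- miscall(al, table$alleles[[i]], model$e)
    }
    return(out)
  }
  out <- matrix(NA_real_, n, 2 * L,
                dimnames = list(NULL, slot_names(table)))
  for (i in seq_len(L)) {
    het <- G[i, 1] != G[i, 2]
    a1 <- rep(G[i, 1], n)
    a2 <- rep(G[i, 2], n)
    if (het) {
      a1[stats::runif(n) < model$D] <- NA
      a2[stats::runif(n) < model$D] <- NA
    } else {
      gone <- stats::runif(n) < model$D2
      a1[gone] <- NA
      a2[gone] <- NA
    }
    al <- table$alleles[[i]]
    a1 <- miscall(a1, al, model$e)
    a2 <- miscall(a2, al, model$e)
    s1 <- pmin(a1, a2)
    s1[is.na(s1)] <- ifelse(is.na(a1[is.na(s1)]), a2[is.na(s1)], a1[is.na(s1)])
    s2 <- pmax(a1, a2)  # NA unless both called
    out[, 2 * i - 1] <- s1
    out[, 2 * i] <- s2
  }
  out
}

slot_names <- function(table) {
  as.vector(rbind(paste0(table$loci, "_1"), paste0(table$loci, "_2")))
}

#' Simulate one diploid single-cell profile
#'
#' Heterozygous loci lose each allele independently with probability `D`;
#' homozygous loci drop entirely with probability `D2` (otherwise the allele
#' fills both slots); surviving calls are miscalled with probability `e`.
#' Surviving calls are re-sorted ascending and left-packed (a lone survivor
#' occupies slot 1).
#'
#' @param genotype a [genotype_profile].
#' @param table the panel.
#' @param model a [drop_model].
#' @return numeric slot vector of length 2L with NA for missing.
#' @export
simulate_diploid_cell <- function(genotype, table, model = drop_model()) {
  drop(sim_cells(genotype, 1L, table, model, "diploid"))
}

#' Simulate one haploid single-cell profile
#'
#' One of the genotype's two alleles is selected per locus with probability
#' 1/2 each; it drops with probability `D` and, if called, is miscalled with
#' probability `e`.
#'
#' @inheritParams simulate_diploid_cell
#' @return numeric vector of length L with NA for missing.
#' @export
simulate_haploid_cell <- function(genotype, table, model = drop_model()) {
  drop(sim_cells(genotype, 1L, table, model, "haploid"))
}

#' Assemble a single-cell mixture from contributor genotypes
#'
#' Generates the stated number of cells per contributor, pools and shuffles
#' them, and keeps the hidden truth labels for evaluation.
#'
#' @param contributors list of [genotype_profile]s.
#' @param cell_counts integer vector, same length, of cells per contributor.
#' @param table the panel.
#' @param model a [drop_model].
#' @param ploidy `"diploid"` or `"haploid"`.
#' @return object of class `mixture_dataset`: list with `profiles` (cells x
#'   slots matrix, NA = missing), `ploidy`, `panel`, `truth` (contributor id
#'   per cell) and `genotypes` (the true profiles).
#' @export
assemble_mixture <- function(contributors, cell_counts, table,
                             model = drop_model(),
                             ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  if (length(contributors) != length(cell_counts))
    stop("cell_counts must match contributors in length")
  if (any(cell_counts < 0)) stop("cell counts must be >= 0")
  mats <- mapply(function(g, n) sim_cells(g, n, table, model, ploidy),
                 contributors, cell_counts, SIMPLIFY = FALSE)
  profiles <- do.call(rbind, mats)
  truth <- rep(vapply(contributors, attr, character(1), "contributor_id"),
               cell_counts)
  ord <- sample.int(nrow(profiles))
  profiles <- profiles[ord, , drop = FALSE]
  truth <- truth[ord]
  rownames(profiles) <- sprintf("cell%03d", seq_len(nrow(profiles)))
  structure(list(profiles = profiles, ploidy = ploidy, panel = table,
                 truth = truth, genotypes = contributors),
            class = "mixture_dataset")
}

#' @export
print.mixture_dataset <- function(x, ...) {
  cat(sprintf("single-cell mixture: %d %s cells, %d loci\n",
              nrow(x$profiles), x$ploidy, n_loci(x$panel)))
  if (!is.null(x$truth))
    print(table(contributor = x$truth))
  invisible(x)
}

#' Write / read a mixture in ARFF
#'
#' One numeric attribute per allele slot (`<locus>_1`, `<locus>_2` for
#' diploid; `<locus>_1` for haploid), missing values encoded as `?` —
#' the WEKA-compatible representation of single-cell profiles.
#'
#' @param dataset a `mixture_dataset`.
#' @param path output path.
#' @export
write_arff <- function(dataset, path) {
  df <- as.data.frame(dataset$profiles)
  foreign::write.arff(df, path, relation = "single_cell_mixture")
  invisible(path)
}

#' @rdname write_arff
#' @param table the panel the profiles must conform to.
#' @return `read_arff` returns a `mixture_dataset` (truth labels unknown).
#' @export
read_arff <- function(path, table) {
  df <- foreign::read.arff(path)
  L <- n_loci(table)
  if (ncol(df) == 2 * L) {
    ploidy <- "diploid"
    expected <- slot_names(table)
  } else if (ncol(df) == L) {
    ploidy <- "haploid"
    expected <- paste0(table$loci, "_1")
  } else {
    stop(sprintf("ARFF has %d attributes; panel implies %d (diploid) or %d (haploid)",
                 ncol(df), 2 * L, L))
  }
  if (!identical(names(df), expected))
    stop("ARFF attribute names do not match the panel slot order")
  profiles <- as.matrix(df)
  if (ploidy == "haploid") colnames(profiles) <- table$loci
  for (i in seq_len(L)) {
    loc <- table$loci[i]
    cols <- if (ploidy == "diploid") c(2 * i - 1, 2 * i) else i
    vals <- profiles[, cols]
    if (!all(vals[!is.na(vals)] %in% table$alleles[[loc]]))
      stop(sprintf("locus %s: ARFF contains alleles absent from the panel", loc))
  }
  rownames(profiles) <- sprintf("cell%03d", seq_len(nrow(profiles)))
  structure(list(profiles = profiles, ploidy = ploidy, panel = table,
                 truth = NULL, genotypes = NULL),
            class = "mixture_dataset")
}

#' Filter low-quality cells
#'
#' Keeps cells whose fraction of non-missing allele slots is at least
#' `min_call_fraction`; order and truth labels are preserved.
#'
#' @param dataset a `mixture_dataset`.
#' @param min_call_fraction required call fraction in `[0, 1]`.
#' @export
filter_cells <- function(dataset, min_call_fraction) {
  stopifnot(min_call_fraction >= 0, min_call_fraction <= 1)
  frac <- rowMeans(!is.na(dataset$profiles))
  keep <- frac >= min_call_fraction
  dataset$profiles <- dataset$profiles[keep, , drop = FALSE]
  if (!is.null(dataset$truth)) dataset$truth <- dataset$truth[keep]
  dataset
}

#' Write / read single-cell profiles as CSV
#'
#' Long-format dialect: cell_id, locus, allele1, allele2 (allele2 empty for
#' haploid profiles; empty = missing).
#' @param dataset a `mixture_dataset`.
#' @param path file path.
#' @export
write_profiles_csv <- function(dataset, path) {
  L <- n_loci(dataset$panel)
  n <- nrow(dataset$profiles)
  if (dataset$ploidy == "diploid") {
    a1 <- dataset$profiles[, 2 * seq_len(L) - 1, drop = FALSE]
    a2 <- dataset$profiles[, 2 * seq_len(L), drop = FALSE]
  } else {
    a1 <- dataset$profiles
    a2 <- matrix(NA_real_, n, L)
  }
  df <- data.frame(cell_id = rep(rownames(dataset$profiles), each = L),
                   locus = rep(dataset$panel$loci, times = n),
                   allele1 = as.vector(t(a1)), allele2 = as.vector(t(a2)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_profiles_csv
#' @param table the panel.
#' @param ploidy ploidy of the stored profiles.
#' @export
read_profiles_csv <- function(path, table, ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cells <- unique(df$cell_id)
  L <- n_loci(table)
  ns <- if (ploidy == "diploid") slot_names(table) else table$loci
  profiles <- matrix(NA_real_, length(cells), length(ns),
                     dimnames = list(cells, ns))
  for (ci in seq_along(cells)) {
    sub <- df[df$cell_id == cells[ci], ]
    idx <- match(sub$locus, table$loci)
    if (ploidy == "diploid") {
      profiles[ci, 2 * idx - 1] <- sub$allele1
      profiles[ci, 2 * idx] <- sub$allele2
    } else {
      profiles[ci, idx] <- sub$allele1
    }
  }
  structure(list(profiles = profiles, ploidy = ploidy, panel = table,
                 truth = NULL, genotypes = NULL),
            class = "mixture_dataset")
}
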