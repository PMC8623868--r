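#' Allele-frequency panel
#'
#' An `freq_table` holds, for a panel of autosomal STR loci, the allele
#' designations (repeat numbers, possibly with partial repeats such as 12.3)
#' and their population frequencies. It is the sampling prior for genotype
#' simulation and the denominator of likelihood ratios.
#'
#' @param loci character vector of locus names.
#' @param alleles named list (one entry per locus) of numeric allele
#'   designations.
#' @param freqs named list of numeric frequencies aligned to `alleles`.
#'   Per-locus frequencies whose raw sum lies in `[0.98, 1.02]` are
#'   renormalized to sum to 1; sums outside that band are rejected.
#' @return an object of class `freq_table` with fields `loci`, `alleles`,
#'   `freqs`.
#' @export
freq_table <- function(loci, alleles, freqs) {
  loci <- as.character(loci)
  if (length(loci) < 1L) stop("panel must contain at least one locus")
  if (anyDuplicated(loci)) stop("duplicate locus names in panel")
  if (!setequal(names(alleles), loci) || !setequal(names(freqs), loci))
    stop("alleles/freqs must be named by locus")
  alleles <- alleles[loci]
  freqs <- freqs[loci]
  for (i in seq_along(loci)) {
    loc <- loci[i]
    a <- alleles[[i]]
    f <- freqs[[i]]
    if (length(a) < 2L)
      stop(sprintf("locus %s: needs at least 2 alleles", loc))
    if (anyDuplicated(a))
      stop(sprintf("locus %s: duplicate allele designations", loc))
    if (length(a) != length(f))
      stop(sprintf("locus %s: alleles and frequencies differ in length", loc))
    if (any(!is.finite(f)) || any(f <= 0))
      stop(sprintf("locus %s: non-positive frequency", loc))
    s <- sum(f)
    if (s < 0.98 || s > 1.02)
      stop(sprintf("locus %s: frequencies sum to %.4f, outside [0.98, 1.02]",
                   loc, s))
    ord <- order(a)
    alleles[[i]] <- a[ord]
    freqs[[i]] <- f[ord] / s
  }
  structure(list(loci = loci, alleles = alleles, freqs = freqs),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("STR allele-frequency panel: %d loci\n", length(x$loci)))
  na <- vapply(x$alleles, length, integer(1))
  cat(sprintf("  alleles per locus: %d-%d (median %g)\n",
              min(na), max(na), stats::median(na)))
  het <- mean(vapply(x$freqs, function(p) 1 - sum(p^2), numeric(1)))
  cat(sprintf("  mean expected heterozygosity: %.3f\n", het))
  invisible(x)
}

#' Load an allele-frequency panel from a tab-separated file
#'
#' The dialect is a 3-column TSV with header `locus`, `allele`, `frequency`;
#' lines starting with `#` are comments. Frequencies per locus are
#' renormalized when their raw sum is within 2% of 1 (published tables are
#' rounded); anything further off is rejected as a likely format error.
#'
#' @param path path to the TSV file.
#' @return a validated [freq_table].
#' @export
load_frequency_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = c("character", "numeric", "numeric"),
                          stringsAsFactors = FALSE)
  if (!all(c("locus", "allele", "frequency") %in% names(df)))
    stop("frequency file must have columns locus, allele, frequency")
  if (anyDuplicated(df[c("locus", "allele")]))
    stop("duplicate (locus, allele) row in frequency file")
  loci <- unique(df$locus)
  freq_table(loci,
             alleles = split(df$allele, factor(df$locus, levels = loci)),
             freqs = split(df$frequency, factor(df$locus, levels = loci)))
}

#' Write an allele-frequency panel
#'
#' Emits the same 3-column TSV dialect that [load_frequency_table()] reads,
#' so load -> save -> load round-trips to an identical table.
#'
#' @param table a [freq_table].
#' @param path output path.
#' @export
write_frequency_table <- function(table, path) {
  df <- data.frame(
    locus = rep(table$loci, vapply(table$alleles, length, integer(1))),
    allele = unlist(table$alleles, use.names = FALSE),
    frequency = unlist(table$freqs, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthesize a random allele-frequency panel
#'
#' Draws per-locus frequencies from a symmetric Dirichlet distribution. The
#' synthetic panel stands in for published population tables so that every
#' analysis runs offline; allele designations are consecutive integers from
#' 8 (no microvariants), although [load_frequency_table()] accepts decimal
#' designations such as 12.3.
#'
#' @param n_loci number of loci (default 21, a GlobalFiler-sized autosomal
#'   panel).
#' @param alleles_per_locus alleles per locus (default 8).
#' @param concentration symmetric Dirichlet concentration (default 1; larger
#'   values give more even frequencies).
#' @param seed integer seed; the same seed always yields the same panel.
#' @return a [freq_table].
#' @export
synthesize_frequency_table <- function(n_loci = 21, alleles_per_locus = 8,
                                       concentration = 1, seed = NULL) {
  if (n_loci < 1 || alleles_per_locus < 2 || concentration <= 0)
    stop("need n_loci >= 1, alleles_per_locus >= 2, concentration > 0")
  if (!is.null(seed)) set.seed(seed)
  loci <- sprintf("L%02d", seq_len(n_loci))
  des <- seq(8, length.out = alleles_per_locus)
  freqs <- lapply(loci, function(loc) {
    g <- stats::rgamma(alleles_per_locus, shape = concentration)
    # guard against zero draws at tiny concentrations
    g <- pmax(g, 1e-12)
    g / sum(g)
  })
  names(freqs) <- loci
  alleles <- stats::setNames(rep(list(des), n_loci), loci)
  freq_table(loci, alleles, freqs)
}

n_loci <- function(table) length(table$loci)
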