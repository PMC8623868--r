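#' True-genotype simulation under population substructure and pedigrees
#'
#' Contributor genotypes are drawn locus by locus from the panel frequencies
#' with the Balding-Nichols subpopulation correction: having already seen m
#' alleles of which x equal allele A, the next draw is A with probability
#' (x*theta + (1-theta)*p_A) / (1 + (m-1)*theta), theta being the
#' coancestry coefficient Fst. Loci are independent; the two draws of an
#' individual are exchangeable. Related individuals are built from Mendelian
#' transmissions with an optional two-phase mutation model.
#'
#' @name genotype_sim
NULL

#' Construct a genotype profile
#'
#' @param mat numeric L x 2 matrix of allele designations, rownames = loci;
#'   each row is stored ascending (smaller allele first).
#' @param table the [freq_table] the alleles belong to.
#' @param id contributor label.
#' @return object of class `genotype_profile`: the sorted L x 2 matrix with
#'   attributes `contributor_id` and `loci`.
#' @export
genotype_profile <- function(mat, table, id = "ind") {
  if (!is.matrix(mat) || ncol(mat) != 2L) stop("genotype must be an L x 2 matrix")
  if (nrow(mat) != n_loci(table)) stop("genotype has wrong number of loci")
  rownames(mat) <- table$loci
  for (i in seq_len(nrow(mat))) {
    if (!all(mat[i, ] %in% table$alleles[[i]]))
      stop(sprintf("locus %s: allele not present in panel", table$loci[i]))
  }
  mat <- cbind(a1 = pmin(mat[, 1], mat[, 2]), a2 = pmax(mat[, 1], mat[, 2]))
  rownames(mat) <- table$loci
  structure(mat, contributor_id = id, class = c("genotype_profile", "matrix"))
}

#' @export
print.genotype_profile <- function(x, ...) {
  cat(sprintf("genotype profile '%s' (%d loci)\n",
              attr(x, "contributor_id"), nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE])
  if (nrow(x) > 6L) cat(sprintf("  ... %d more loci\n", nrow(x) - 6L))
  invisible(x)
}

#' Two-phase STR mutation model
#'
#' Per parent-child transmission a mutation occurs with `rate_per_locus`;
#' it is a +/-1 repeat step with probability `p_single_step`, otherwise a
#' +/-k step with k >= 2 geometric(`geometric_p`); direction is equiprobable.
#' Designations outside the panel allele list are clamped to the nearest
#' panel allele so every simulated allele keeps a frequency.
#'
#' @param rate_per_locus mutation probability per transmission (default 1.5e-3).
#' @param p_single_step probability of a single-repeat step (default 0.9).
#' @param geometric_p step-size parameter for multi-step mutations (default 0.5).
#' @return object of class `mutation_model`.
#' @export
mutation_model <- function(rate_per_locus = 1.5e-3, p_single_step = 0.9,
                           geometric_p = 0.5) {
  stopifnot(rate_per_locus >= 0, rate_per_locus <= 1,
            p_single_step >= 0, p_single_step <= 1,
            geometric_p > 0, geometric_p <= 1)
  structure(list(rate_per_locus = rate_per_locus,
                 p_single_step = p_single_step,
                 geometric_p = geometric_p),
            class = "mutation_model")
}

#' Relationship specification for a set of contributors
#'
#' @param kind one of `"unrelated"`, `"parent-child"`, `"full-siblings"`,
#'   `"trio"` (father, mother, child).
#' @param n_contributors contributor count; forced to 2 for parent-child /
#'   full-siblings and 3 for a trio.
#' @export
relationship_spec <- function(kind = c("unrelated", "parent-child",
                                       "full-siblings", "trio"),
                              n_contributors = 2L) {
  kind <- match.arg(kind)
  n_contributors <- as.integer(n_contributors)
  if (kind %in% c("parent-child", "full-siblings") && n_contributors != 2L)
    stop(kind, " implies exactly 2 contributors")
  if (kind == "trio" && n_contributors != 3L)
    stop("trio implies exactly 3 contributors")
  if (n_contributors < 1L) stop("need at least one contributor")
  structure(list(kind = kind, n_contributors = n_contributors),
            class = "relationship_spec")
}

# Vectorized Balding-Nichols genotype draws at one locus: n two-allele draws.
# Mixture form of the sampling formula: the second draw copies the first with
# probability theta, otherwise it is a fresh draw from the panel frequencies.
sample_genotypes_locus <- function(alleles, freqs, n, fst) {
  a1 <- sample(alleles, n, replace = TRUE, prob = freqs)
  fresh <- sample(alleles, n, replace = TRUE, prob = freqs)
  copy <- stats::runif(n) < fst
  a2 <- ifelse(copy, a1, fresh)
  cbind(pmin(a1, a2), pmax(a1, a2))
}

# One additional BN draw given `seen` (list-free: matrix n x m of already
# observed alleles per individual) -- used for kinship conditionals and the
# non-transmitted allele of a child.
sample_allele_conditional <- function(alleles, freqs, seen, fst) {
  n <- nrow(seen)
  m <- ncol(seen)
  denom <- 1 + (m - 1) * fst
  copy <- stats::runif(n) < (m * fst) / denom
  which_prev <- sample.int(m, n, replace = TRUE)
  copied <- seen[cbind(seq_len(n), which_prev)]
  fresh <- sample(alleles, n, replace = TRUE, prob = freqs)
  ifelse(copy, copied, fresh)
}

#' Sample one genotype profile with the Fst correction
#'
#' @param table a [freq_table].
#' @param fst coancestry coefficient in `[0, 1)`; `fst = 0` reduces to
#'   Hardy-Weinberg sampling from the panel frequencies.
#' @param id contributor label.
#' @return a [genotype_profile].
#' @export
sample_genotype_fst <- function(table, fst = 0.01, id = "ind") {
  stopifnot(fst >= 0, fst < 1)
  L <- n_loci(table)
  mat <- matrix(NA_real_, L, 2)
  for (i in seq_len(L)) {
    mat[i, ] <- sample_genotypes_locus(table$alleles[[i]],
                                       table$freqs[[i]], 1L, fst)
  }
  genotype_profile(mat, table, id)
}

# clamp designations to the nearest panel allele (tie -> smaller)
clamp_to_panel <- function(x, alleles) {
  vapply(x, function(v) {
    d <- abs(alleles - v)
    alleles[which.min(d)]  # which.min takes the first (smaller) on ties
  }, numeric(1))
}

# One full gamete: one transmitted allele per locus, mutations applied.
transmit_gamete <- function(parent, table, model) {
  L <- nrow(parent)
  pick <- sample.int(2L, L, replace = TRUE)
  allele <- parent[cbind(seq_len(L), pick)]
  mut <- stats::runif(L) < model$rate_per_locus
  if (any(mut)) {
    nm <- sum(mut)
    single <- stats::runif(nm) < model$p_single_step
    step <- ifelse(single, 1, 2 + stats::rgeom(nm, model$geometric_p))
    dir <- sample(c(-1, 1), nm, replace = TRUE)
    allele[mut] <- allele[mut] + dir * step
    for (i in which(mut))
      allele[i] <- clamp_to_panel(allele[i], table$alleles[[i]])
  }
  allele
}

#' Transmit one allele from a parent at one locus
#'
#' One of the parent's two alleles is chosen with probability 1/2 each; with
#' probability `rate_per_locus` it mutates under the two-phase model.
#'
#' @param parent a [genotype_profile].
#' @param locus locus name.
#' @param table the panel.
#' @param model a [mutation_model].
#' @return a single allele designation.
#' @export
transmit_allele <- function(parent, locus, table, model = mutation_model()) {
  i <- match(locus, table$loci)
  if (is.na(i)) stop("unknown locus: ", locus)
  sub <- unclass(parent)[i, , drop = FALSE]
  gam <- transmit_gamete(sub,
                         list(loci = locus,
                              alleles = table$alleles[locus],
                              freqs = table$freqs[locus]),
                         model)
  unname(gam)
}

#' Simulate a set of related or unrelated contributor genotypes
#'
#' * `unrelated`: independent draws.
#' * `parent-child`: parent drawn; each child locus is one transmitted allele
#'   plus one population allele (the latter conditioned on the child's own
#'   transmitted draw under the Fst recursion).
#' * `full-siblings`: two unobserved parents drawn; two children by
#'   independent transmissions.
#' * `trio`: father and mother drawn; child transmitted from each.
#'
#' @param spec a [relationship_spec].
#' @param table a [freq_table].
#' @param fst coancestry coefficient.
#' @param model a [mutation_model].
#' @return list of [genotype_profile]s (trio order: father, mother, child).
#' @export
simulate_contributors <- function(spec, table, fst = 0.01,
                                  model = mutation_model()) {
  stopifnot(inherits(spec, "relationship_spec"))
  L <- n_loci(table)
  draw <- function(id) sample_genotype_fst(table, fst, id)
  child_from <- function(parent, id) {
    trans <- transmit_gamete(unclass(parent), table, model)
    other <- numeric(L)
    for (i in seq_len(L)) {
      other[i] <- sample_allele_conditional(
        table$alleles[[i]], table$freqs[[i]],
        matrix(trans[i], 1, 1), fst)
    }
    genotype_profile(cbind(trans, other), table, id)
  }
  switch(spec$kind,
    "unrelated" = lapply(seq_len(spec$n_contributors),
                         function(i) draw(sprintf("C%d", i))),
    "parent-child" = {
      parent <- draw("parent")
      list(parent, child_from(parent, "child"))
    },
    "full-siblings" = {
      f <- draw("father"); m <- draw("mother")
      sib <- function(id)
        genotype_profile(cbind(transmit_gamete(unclass(f), table, model),
                               transmit_gamete(unclass(m), table, model)),
                         table, id)
      list(sib("sib1"), sib("sib2"))
    },
    "trio" = {
      f <- draw("father"); m <- draw("mother")
      child <- genotype_profile(
        cbind(transmit_gamete(unclass(f), table, model),
              transmit_gamete(unclass(m), table, model)),
        table, "child")
      list(f, m, child)
    })
}

#' Write genotype profiles as CSV
#'
#' Columns: contributor_id, locus, allele1, allele2.
#' @param profiles list of [genotype_profile]s.
#' @param path output path.
#' @export
write_genotypes_csv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(g) {
    data.frame(contributor_id = attr(g, "contributor_id"),
               locus = rownames(g),
               allele1 = unclass(g)[, 1], allele2 = unclass(g)[, 2],
               row.names = NULL)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
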