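#' Analytic probabilities and likelihood ratios
#'
#' Closed-form counterparts of the simulator: binomial contributor-detection
#' probability, Balding-Nichols genotype probabilities with substructure,
#' exact observation (transition) probabilities under the drop-out/drop-in
#' generative model, and likelihood ratios comparing source and kinship
#' hypotheses. The transition probabilities are derived from this package's
#' own generative model by exhaustive enumeration of drop/miscall outcomes,
#' so the LR exactly inverts the simulator.
#'
#' @name inference
NULL

#' Probability that a contributor is missed during cell sampling
#'
#' Under binomial sampling of a large cell population, the probability that
#' none of the cells of a contributor with mixture proportion `p` appears
#' among `n` sampled cells is `(1 - p)^n`.
#'
#' @param p mixture proportion of the contributor, in `(0, 1)`.
#' @param n number of cells sampled (>= 0).
#' @return the probability, vectorized over `p` and `n`.
#' @export
prob_missing_contributor <- function(p, n) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly between 0 and 1")
  if (any(n < 0)) stop("n must be >= 0")
  (1 - p)^n
}

#' Kinship hypothesis with IBD coefficients
#'
#' @param kind `"same-source"`, `"unrelated"` (k = (1,0,0)),
#'   `"parent-child"` (0,1,0) or `"full-siblings"` (1/4,1/2,1/4).
#' @export
relationship_hypothesis <- function(kind = c("unrelated", "parent-child",
                                             "full-siblings", "same-source")) {
  kind <- match.arg(kind)
  k <- switch(kind,
              "unrelated" = c(1, 0, 0),
              "parent-child" = c(0, 1, 0),
              "full-siblings" = c(0.25, 0.5, 0.25),
              "same-source" = c(0, 0, 1))
  structure(list(kind = kind, ibd = k), class = "relationship_hypothesis")
}

# Balding-Nichols conditional probability of drawing allele `a` after having
# seen the alleles in `seen` (m = length(seen)).
bn_next_prob <- function(a, seen, p, fst) {
  m <- length(seen)
  x <- sum(seen == a)
  (x * fst + (1 - fst) * p) / (1 + (m - 1) * fst)
}

#' Single-locus genotype probability with substructure
#'
#' Two sequential Balding-Nichols draws: hom AA has probability
#' p (theta + (1-theta) p); het AB has probability 2 p q (1-theta).
#'
#' @param pair numeric length-2 allele pair (unordered).
#' @param locus locus name.
#' @param table a [freq_table].
#' @param fst coancestry coefficient.
#' @return the genotype probability.
#' @export
genotype_probability <- function(pair, locus, table, fst = 0) {
  al <- table$alleles[[locus]]
  fr <- table$freqs[[locus]]
  if (is.null(al)) stop("unknown locus: ", locus)
  i <- match(pair, al)
  if (anyNA(i)) stop(sprintf("locus %s: allele not in panel", locus))
  p1 <- fr[i[1]]
  if (pair[1] == pair[2]) p1 * (fst + (1 - fst) * p1)
  else 2 * p1 * fr[i[2]] * (1 - fst)
}

#' Profile-level genotype probability (random match probability)
#'
#' Product of [genotype_probability()] over loci.
#' @param genotype a [genotype_profile] or L x 2 matrix with locus rownames.
#' @inheritParams genotype_probability
#' @export
genotype_probability_profile <- function(genotype, table, fst = 0) {
  g <- unclass(genotype)
  prod(vapply(seq_len(nrow(g)), function(i)
    genotype_probability(g[i, ], rownames(g)[i], table, fst), numeric(1)))
}

# probability that a called allele `from` is reported as `to` under uniform
# miscall with rate e among A panel alleles
miscall_prob <- function(from, to, e, A) {
  ifelse(to == from, 1 - e, e / (A - 1))
}

#' Exact observation probability of a single-locus call set
#'
#' Probability of observing the call multiset `observed` (length 0, 1 or 2)
#' from a diploid true genotype under the generative model of
#' [simulate_diploid_cell()]: drop-out first (per-allele `D` at heterozygous
#' loci, whole-locus `D2` at homozygous loci), then independent uniform
#' miscalls at rate `e` on surviving calls. Computed by enumerating every
#' drop/miscall outcome, so the distribution over all call sets sums to 1.
#'
#' @param observed numeric vector of observed alleles (0-2 values, multiset).
#' @param true_pair the true allele pair.
#' @param model a [drop_model].
#' @param locus_alleles allele designations available at the locus.
#' @return the probability.
#' @export
observation_probability <- function(observed, true_pair, model,
                                    locus_alleles) {
  A <- length(locus_alleles)
  observed <- sort(observed[!is.na(observed)])
  D <- model$D; D2 <- model$D2; e <- model$e
  het <- true_pair[1] != true_pair[2]
  # survivor branches: list(prob, surviving true alleles)
  branches <- if (het) list(
    list(p = D^2, s = numeric(0)),
    list(p = D * (1 - D), s = true_pair[1]),
    list(p = D * (1 - D), s = true_pair[2]),
    list(p = (1 - D)^2, s = true_pair)
  ) else list(
    list(p = D2, s = numeric(0)),
    list(p = 1 - D2, s = true_pair)
  )
  total <- 0
  for (b in branches) {
    ns <- length(b$s)
    if (ns != length(observed)) next
    pr <- if (ns == 0L) 1
    else if (ns == 1L) miscall_prob(b$s, observed, e, A)
    else {
      u <- b$s[1]; v <- b$s[2]; c1 <- observed[1]; c2 <- observed[2]
      if (c1 == c2) miscall_prob(u, c1, e, A) * miscall_prob(v, c1, e, A)
      else miscall_prob(u, c1, e, A) * miscall_prob(v, c2, e, A) +
           miscall_prob(u, c2, e, A) * miscall_prob(v, c1, e, A)
    }
    total <- total + b$p * pr
  }
  total
}

# all unordered genotypes at a locus (rows: a1 <= a2)
locus_genotypes <- function(alleles) {
  idx <- which(upper.tri(matrix(0, length(alleles), length(alleles)), diag = TRUE),
               arr.ind = TRUE)
  cbind(alleles[idx[, 1]], alleles[idx[, 2]])
}

# P(G | B, IBD coefficients, theta): kinship conditional genotype
# distribution at one locus, theta-corrected by continuing the BN recursion
# over B's observed alleles. k0 branch uses the unconditional genotype
# probability so identical hypotheses cancel exactly in LRs.
kinship_genotype_prob <- function(G, B, ibd, locus, table, fst) {
  al <- table$alleles[[locus]]
  fr <- table$freqs[[locus]]
  pfun <- function(a, seen) bn_next_prob(a, seen, fr[match(a, al)], fst)
  p <- 0
  # k2: identical genotype
  if (ibd[3] > 0 && all(sort(G) == sort(B)))
    p <- p + ibd[3]
  # k1: one IBD allele shared; the shared allele is one of B's two (1/2
  # each), the other is a fresh conditional draw
  if (ibd[2] > 0) {
    p1 <- 0
    for (shared_i in 1:2) {
      s <- B[shared_i]
      # G must contain s; the companion allele t completes the multiset
      if (s == G[1]) t <- G[2]
      else if (s == G[2]) t <- G[1]
      else next
      p1 <- p1 + 0.5 * pfun(t, B)
      # heterozygous G containing s twice over is handled by both branches
    }
    p <- p + ibd[2] * p1
  }
  # k0: unrelated draw
  if (ibd[1] > 0)
    p <- p + ibd[1] * genotype_probability(G, locus, table, fst)
  p
}

#' Likelihood ratio: consensus profile vs. reference, same source
#'
#' LR = Pr(A, B | same source) / Pr(A, B | unrelated) for a consensus
#' profile A and a reference genotype B. Per locus the numerator is the
#' genotype probability of B times the observation probability of A's calls
#' given B; the denominator is the product of the genotype probabilities of
#' A (read as a genotype) and B. Loci where A is fully missing contribute a
#' factor 1; loci where A has a single call are not representable as a
#' genotype in the denominator and are skipped with a warning. With D = e =
#' 0 and A identical to B the LR reduces to the inverse of the random match
#' probability of A.
#'
#' @param A a [consensus_profile] (or 2L slot vector).
#' @param B a [genotype_profile].
#' @param model a [drop_model] carrying consensus-level effective rates
#'   (see [consensus_error_rates()]).
#' @param table the panel.
#' @param fst coancestry coefficient.
#' @return the LR, with attribute `per_locus` of per-locus factors.
#' @export
lr_same_source <- function(A, B, model, table, fst = 0) {
  va <- as_slot_vector(A)
  g <- unclass(B)
  L <- n_loci(table)
  factors <- stats::setNames(rep(1, L), table$loci)
  for (i in seq_len(L)) {
    loc <- table$loci[i]
    obs <- va[c(2 * i - 1, 2 * i)]
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0L) next
    if (length(obs) == 1L) {
      warning(sprintf("locus %s: single called allele, treated as missing", loc))
      next
    }
    num <- observation_probability(obs, g[i, ], model, table$alleles[[loc]])
    den <- genotype_probability(obs, loc, table, fst)
    factors[i] <- num / den
  }
  structure(prod(factors), per_locus = factors)
}

#' Likelihood ratio: consensus profile vs. reference under a kinship
#' hypothesis
#'
#' LR = Pr(A, B | related as specified) / Pr(A, B | unrelated). Per locus
#' the numerator sums, over candidate true genotypes G of A's donor, the
#' kinship-conditional genotype probability of G given B times the
#' observation probability of A's calls given G; the denominator is the
#' same sum under the unrelated hypothesis. Identical hypotheses therefore
#' give LR = 1 exactly, and partially missing consensus loci remain usable.
#' Mutation is ignored in the kinship transition.
#'
#' @inheritParams lr_same_source
#' @param hypothesis a [relationship_hypothesis].
#' @return the LR, with attribute `per_locus`.
#' @export
lr_related <- function(A, B, hypothesis, model, table, fst = 0) {
  va <- as_slot_vector(A)
  g <- unclass(B)
  L <- n_loci(table)
  factors <- stats::setNames(rep(1, L), table$loci)
  for (i in seq_len(L)) {
    loc <- table$loci[i]
    obs <- va[c(2 * i - 1, 2 * i)]
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0L) next
    gs <- locus_genotypes(table$alleles[[loc]])
    num <- den <- 0
    for (r in seq_len(nrow(gs))) {
      G <- gs[r, ]
      obsp <- observation_probability(obs, G, model, table$alleles[[loc]])
      if (obsp == 0) next
      num <- num + obsp *
        kinship_genotype_prob(G, g[i, ], hypothesis$ibd, loc, table, fst)
      den <- den + obsp * genotype_probability(G, loc, table, fst)
    }
    factors[i] <- if (den > 0) num / den else 1
  }
  structure(prod(factors), per_locus = factors)
}

#' Estimate consensus-level effective drop-out and drop-in rates
#'
#' The error rates of a consensus profile differ from single-cell rates.
#' This helper simulates clusters of `n_cells` cells from random genotypes,
#' builds their consensus, and measures the empirical per-allele drop-out
#' rate at heterozygous loci, the whole-locus drop rate at homozygous loci,
#' and the fraction of called consensus alleles that are not true alleles.
#'
#' @param n_cells cells per simulated cluster.
#' @param model single-cell [drop_model].
#' @param table the panel.
#' @param fst coancestry coefficient for the simulated genotypes.
#' @param replicates number of simulated clusters.
#' @param seed integer seed.
#' @return a [drop_model] with the effective `D`, `D2`, `e`.
#' @export
consensus_error_rates <- function(n_cells, model, table, fst = 0.01,
                                  replicates = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  het_drop <- het_tot <- hom_drop <- hom_tot <- bad <- called <- 0
  L <- n_loci(table)
  for (r in seq_len(replicates)) {
    g <- sample_genotype_fst(table, fst)
    cons <- consensus_profile(sim_cells(g, n_cells, table, model), table)
    gm <- unclass(g)
    for (i in seq_len(L)) {
      truth <- gm[i, ]
      obs <- cons$calls[c(2 * i - 1, 2 * i)]
      obs_called <- obs[!is.na(obs)]
      called <- called + length(obs_called)
      bad <- bad + sum(!(obs_called %in% truth))
      if (truth[1] != truth[2]) {
        het_tot <- het_tot + 2
        het_drop <- het_drop + sum(!(truth %in% obs_called))
      } else {
        hom_tot <- hom_tot + 1
        hom_drop <- hom_drop + all(is.na(obs))
      }
    }
  }
  drop_model(D = if (het_tot) het_drop / het_tot else 0,
             D2 = if (hom_tot) hom_drop / hom_tot else 0,
             e = if (called) bad / called else 0)
}
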