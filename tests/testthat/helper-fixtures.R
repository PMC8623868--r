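# Shared fixtures and independent brute-force oracles.

# small panel with explicit frequencies; n_loci copies of the same locus model
toy_panel <- function(n_loci = 2, alleles = c(8, 9, 10),
                      freqs = c(0.2, 0.3, 0.5)) {
  loci <- sprintf("T%02d", seq_len(n_loci))
  freq_table(loci,
             alleles = setNames(rep(list(alleles), n_loci), loci),
             freqs = setNames(rep(list(freqs), n_loci), loci))
}

# a complete diploid slot vector from per-locus pairs (a1, a2 interleaved)
slots_from_pairs <- function(pairs) {
  as.vector(rbind(pmin(pairs[, 1], pairs[, 2]),
                  pmax(pairs[, 1], pairs[, 2])))
}

# ---- oracles -------------------------------------------------------------

# silhouette by direct definition from a distance matrix
oracle_silhouette <- function(D, assignment) {
  n <- length(assignment)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assignment == assignment[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(assignment), assignment[i]),
                    function(cl) mean(D[i, assignment == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# IBS by naive per-locus multiset counting over slot vectors
oracle_ibs <- function(va, vb) {
  L <- length(va) / 2
  total <- 0L
  for (i in seq_len(L)) {
    x <- va[c(2 * i - 1, 2 * i)]; x <- x[!is.na(x)]
    y <- vb[c(2 * i - 1, 2 * i)]; y <- y[!is.na(y)]
    for (al in unique(c(x, y)))
      total <- total + min(sum(x == al), sum(y == al))
  }
  total
}

# modal vote per slot, ties toward the smaller allele
oracle_consensus_diploid <- function(cells) {
  apply(cells, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    counts <- vapply(sort(unique(v)), function(a) sum(v == a), numeric(1))
    sort(unique(v))[which.max(counts)]
  })
}

# best cluster-truth matching by scoring every permutation independently
oracle_matching <- function(cons_list, truths) {
  k <- length(cons_list)
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == k), ,
                 drop = FALSE]
  scores <- apply(perms, 1, function(p)
    sum(vapply(seq_len(k), function(i)
      ibs_count(cons_list[[i]], truths[[p[i]]]), numeric(1))))
  unname(perms[which.max(scores), ])
}

# observation probability by exhaustive enumeration over ordered
# (drop pattern, reported value) outcomes -- a different decomposition from
# the implementation's survivor-branch form
oracle_obs_prob <- function(observed, true_pair, model, alleles) {
  A <- length(alleles)
  D <- model$D; D2 <- model$D2; e <- model$e
  observed <- sort(observed[!is.na(observed)])
  het <- true_pair[1] != true_pair[2]
  report_p <- function(from, to) if (to == from) 1 - e else e / (A - 1)
  total <- 0
  if (het) {
    for (d1 in 0:1) for (d2 in 0:1) {
      pdrop <- (if (d1) D else 1 - D) * (if (d2) D else 1 - D)
      survivors <- true_pair[c(d1 == 0, d2 == 0)]
      if (length(survivors) != length(observed)) next
      if (length(survivors) == 0L) total <- total + pdrop
      else if (length(survivors) == 1L)
        total <- total + pdrop * report_p(survivors, observed)
      else for (r1 in alleles) for (r2 in alleles) {
        if (!identical(sort(c(r1, r2)), observed)) next
        total <- total + pdrop * report_p(survivors[1], r1) *
          report_p(survivors[2], r2)
      }
    }
  } else {
    if (length(observed) == 0L) total <- total + D2
    if (length(observed) == 2L)
      for (r1 in alleles) for (r2 in alleles) {
        if (!identical(sort(c(r1, r2)), observed)) next
        total <- total + (1 - D2) * report_p(true_pair[1], r1) *
          report_p(true_pair[2], r2)
      }
  }
  total
}

# all distinct observed call multisets at a locus: empty, singles, pairs
all_call_sets <- function(alleles) {
  out <- list(numeric(0))
  for (a in alleles) out <- c(out, list(a))
  for (i in seq_along(alleles)) for (j in i:length(alleles))
    out <- c(out, list(c(alleles[i], alleles[j])))
  out
}

# kinship single-locus LR oracle: brute force over IBD states and ordered
# conditional draws (independent of kinship_genotype_prob's shortcuts)
oracle_lr_related_locus <- function(obs, B, ibd, model, alleles, freqs, fst) {
  bn_p <- function(a, seen) {
    m <- length(seen)
    (sum(seen == a) * fst + (1 - fst) * freqs[match(a, alleles)]) /
      (1 + (m - 1) * fst)
  }
  hwe_p <- function(g) {
    p <- bn_p(g[1], numeric(0)) * bn_p(g[2], g[1])
    if (g[1] != g[2]) p <- 2 * p  # hom counted once, het both orders
    p
  }
  num <- den <- 0
  for (i in seq_along(alleles)) for (j in i:length(alleles)) {
    G <- c(alleles[i], alleles[j])
    op <- oracle_obs_prob(obs, G, model, alleles)
    # k2
    pg <- ibd[3] * as.numeric(all(sort(G) == sort(B)))
    # k1: enumerate (which of B's alleles is IBD) x (every possible fresh
    # draw) and keep combinations whose multiset equals G
    p1 <- 0
    for (bi in 1:2) for (t in alleles) {
      if (!identical(sort(c(B[bi], t)), sort(G))) next
      p1 <- p1 + 0.5 * bn_p(t, B)
    }
    pg <- pg + ibd[2] * p1
    # k0
    pg <- pg + ibd[1] * hwe_p(G)
    num <- num + pg * op
    den <- den + hwe_p(G) * op
  }
  num / den
}
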