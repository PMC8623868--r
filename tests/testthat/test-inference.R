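test_that("missed-contributor probability follows the binomial form", {
  expect_equal(prob_missing_contributor(0.5, 1), 0.5)
  expect_equal(prob_missing_contributor(0.3, 0), 1)
  expect_equal(prob_missing_contributor(0.01, 80), 0.99^80)
  expect_error(prob_missing_contributor(0, 5), "strictly")
  expect_error(prob_missing_contributor(0.5, -1), ">= 0")
})

test_that("genotype probabilities respect substructure and sum to one", {
  tab <- toy_panel(1, alleles = c(8, 9, 10), freqs = c(0.2, 0.3, 0.5))
  loc <- tab$loci[1]
  # theta = 0: Hardy-Weinberg
  expect_equal(genotype_probability(c(9, 9), loc, tab, 0), 0.09)
  expect_equal(genotype_probability(c(8, 9), loc, tab, 0), 2 * 0.2 * 0.3)
  # theta-corrected homozygote
  expect_equal(genotype_probability(c(9, 9), loc, tab, 0.01),
               0.3 * (0.01 + 0.99 * 0.3))
  # total probability over all genotypes is 1 for any theta
  for (fst in c(0, 0.01, 0.05)) {
    gs <- scmixstr:::locus_genotypes(tab$alleles[[loc]])
    tot <- sum(vapply(seq_len(nrow(gs)), function(r)
      genotype_probability(gs[r, ], loc, tab, fst), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
  expect_error(genotype_probability(c(7, 9), loc, tab, 0), "not in panel")
})

test_that("observation probabilities are exact and normalized", {
  tab <- toy_panel(1, alleles = c(8, 9, 10), freqs = c(0.2, 0.3, 0.5))
  al <- tab$alleles[[1]]
  m0 <- drop_model(D = 0, e = 0)
  expect_equal(observation_probability(c(8, 9), c(8, 9), m0, al), 1)
  expect_equal(observation_probability(c(8, 8), c(8, 9), m0, al), 0)

  grid <- expand.grid(D = c(0, 0.05, 0.2, 0.7), e = c(0, 0.01, 0.3))
  for (r in seq_len(nrow(grid))) {
    model <- drop_model(D = grid$D[r], e = grid$e[r])
    for (truth in list(c(8, 9), c(9, 9))) {
      probs <- vapply(all_call_sets(al), function(obs)
        observation_probability(obs, truth, model, al), numeric(1))
      expect_true(all(probs >= 0))
      expect_equal(sum(probs), 1, tolerance = 1e-12)
      # every call set agrees with the independent enumeration oracle
      oracle <- vapply(all_call_sets(al), function(obs)
        oracle_obs_prob(obs, truth, model, al), numeric(1))
      expect_equal(probs, oracle, tolerance = 1e-12)
    }
  }
})

test_that("same-source LR reduces to 1/RMP without noise and 0 on mismatch", {
  tab <- synthesize_frequency_table(21, 8, 1, seed = 23)
  set.seed(23)
  g <- sample_genotype_fst(tab, 0.01)
  m0 <- drop_model(D = 0, e = 0)
  A <- consensus_profile(matrix(slots_from_pairs(unclass(g)), 1), tab)
  lr <- lr_same_source(A, g, m0, tab, fst = 0.01)
  expect_equal(as.numeric(lr),
               1 / genotype_probability_profile(g, tab, 0.01),
               tolerance = 1e-9)
  # a mismatching locus makes the noiseless LR vanish
  g2mat <- unclass(g)
  loc1 <- tab$loci[1]
  g2mat[1, ] <- setdiff(tab$alleles[[loc1]], g2mat[1, ])[1:2]
  g2 <- genotype_profile(g2mat, tab, "other")
  expect_equal(as.numeric(lr_same_source(A, g2, m0, tab, 0.01)), 0)
})

test_that("single-locus same-source LR matches hand enumeration with noise", {
  tab <- toy_panel(1, alleles = c(8, 9, 10), freqs = c(0.2, 0.3, 0.5))
  model <- drop_model(D = 0.2, e = 0.01)
  B <- genotype_profile(matrix(c(8, 9), 1, 2), tab, "B")
  A <- consensus_profile(matrix(c(8, 9), 1, 2), tab)
  lr <- lr_same_source(A, B, model, tab, fst = 0)
  expected <- oracle_obs_prob(c(8, 9), c(8, 9), model, c(8, 9, 10)) /
    (2 * 0.2 * 0.3)
  expect_equal(as.numeric(lr), expected, tolerance = 1e-12)
  # fully missing locus contributes factor 1
  A_missing <- consensus_profile(matrix(NA_real_, 1, 2), tab)
  expect_equal(as.numeric(lr_same_source(A_missing, B, model, tab, 0)), 1)
  # half-called locus is skipped with a warning
  A_half <- consensus_profile(matrix(c(8, NA), 1, 2), tab)
  expect_warning(out <- lr_same_source(A_half, B, model, tab, 0), "single")
  expect_equal(as.numeric(out), 1)
})

test_that("kinship LRs: identity hypothesis, exclusion, sibling oracle", {
  tab <- toy_panel(1, alleles = c(8, 9, 10), freqs = c(0.2, 0.3, 0.5))
  model <- drop_model(D = 0.2, e = 0.01)
  B <- genotype_profile(matrix(c(8, 9), 1, 2), tab, "B")
  # unrelated vs unrelated cancels exactly, even with noise
  for (obs in list(c(8, 9), c(9, 10), c(10, 10))) {
    A <- consensus_profile(matrix(obs, 1, 2), tab)
    lr <- lr_related(A, B, relationship_hypothesis("unrelated"), model, tab,
                     fst = 0.01)
    expect_equal(as.numeric(lr), 1, tolerance = 1e-12)
  }
  # parent-child without noise forbids zero sharing
  m0 <- drop_model(D = 0, e = 0)
  A_disjoint <- consensus_profile(matrix(c(10, 10), 1, 2), tab)
  lr <- lr_related(A_disjoint, B, relationship_hypothesis("parent-child"),
                   m0, tab, fst = 0)
  expect_equal(as.numeric(lr), 0)
  # full siblings against the exhaustive IBD-state enumeration oracle
  for (fst in c(0, 0.02)) {
    for (obs in list(c(8, 9), c(8, 8), c(9, 10), c(8, NA))) {
      A <- consensus_profile(matrix(obs, 1, 2), tab)
      lr <- lr_related(A, B, relationship_hypothesis("full-siblings"),
                       model, tab, fst)
      oracle <- oracle_lr_related_locus(obs[!is.na(obs)], c(8, 9),
                                        c(0.25, 0.5, 0.25), model,
                                        c(8, 9, 10), c(0.2, 0.3, 0.5), fst)
      expect_equal(as.numeric(lr), oracle, tolerance = 1e-12)
    }
  }
})

test_that("same-source beats kinship hypotheses when profiles are identical", {
  tab <- synthesize_frequency_table(10, 6, 1, seed = 29)
  set.seed(29)
  g <- sample_genotype_fst(tab, 0.01)
  m0 <- drop_model(D = 0, e = 0)
  A <- consensus_profile(matrix(slots_from_pairs(unclass(g)), 1), tab)
  lr_ss <- as.numeric(lr_same_source(A, g, m0, tab, 0.01))
  for (kind in c("parent-child", "full-siblings")) {
    lr_k <- as.numeric(lr_related(A, g, relationship_hypothesis(kind),
                                  m0, tab, 0.01))
    expect_gte(lr_ss, lr_k)
  }
})

test_that("consensus-level error rates shrink with more cells", {
  tab <- synthesize_frequency_table(10, 6, 1, seed = 31)
  model <- drop_model(0.2, e = 0.01)
  r1 <- consensus_error_rates(1, model, tab, replicates = 150, seed = 1)
  r5 <- consensus_error_rates(5, model, tab, replicates = 150, seed = 1)
  expect_lt(r5$D, r1$D)
  expect_lte(r5$e, r1$e + 0.005)
  expect_lt(abs(r1$D - 0.2), 0.03)  # one cell: effective D is the raw D
})
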