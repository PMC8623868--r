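test_that("IBS counting matches the multiset definition", {
  tab <- synthesize_frequency_table(21, 8, 1, seed = 1)
  set.seed(1)
  g <- sample_genotype_fst(tab, 0.01)
  expect_equal(ibs_count(g, g), 42)

  # locus-level cases
  p1 <- toy_panel(1, alleles = 8:15, freqs = rep(1 / 8, 8))
  pair <- function(a, b) genotype_profile(matrix(c(a, b), 1, 2), p1, "x")
  expect_equal(ibs_count(pair(10, 11), pair(11, 11)), 1)
  expect_equal(ibs_count(pair(10, 11), pair(11, 12)), 1)
  expect_equal(ibs_count(pair(10, 10), pair(10, 10)), 2)
  expect_equal(ibs_count(pair(8, 9), pair(10, 11)), 0)

  # random profiles with missing data against the brute-force oracle
  set.seed(2)
  for (r in 1:25) {
    va <- sample(c(8:12, NA), 10, replace = TRUE)
    vb <- sample(c(8:12, NA), 10, replace = TRUE)
    expect_equal(ibs_count(va, vb), oracle_ibs(va, vb))
    expect_equal(ibs_count(va, vb), ibs_count(vb, va))  # symmetry
  }
  # self-IBS equals the number of called slots
  va <- c(10, 11, NA, NA, 9, 9, 12, NA)
  expect_equal(ibs_count(va, va), sum(!is.na(va)))
})

test_that("pairwise IBS matrix agrees with cell-by-cell counting", {
  tab <- synthesize_frequency_table(6, 6, 1, seed = 3)
  set.seed(3)
  gs <- simulate_contributors(relationship_spec("unrelated", 2), tab)
  mix <- assemble_mixture(gs, c(4, 4), tab, drop_model(0.3, e = 0.05))
  M <- ibs_matrix(mix)
  for (i in 1:8) for (j in 1:8)
    expect_equal(M[i, j], oracle_ibs(mix$profiles[i, ], mix$profiles[j, ]))
})

test_that("mismatch distance normalizes over compared slots", {
  full <- c(10, 11, 12, 13, 14, 15)
  expect_equal(mismatch_distance(full, full), 0)
  expect_equal(mismatch_distance(full, full + 1), 1)
  # 42-slot pair with exactly 7 mismatching compared slots
  a <- rep(10, 42)
  b <- rep(10, 42)
  b[1:4] <- 11      # called-but-unequal
  b[5:7] <- NA      # one-sided missing
  expect_equal(mismatch_distance(a, b), 7 / 42)
  # both-missing slots drop from numerator and denominator
  a[8:10] <- NA; b[8:10] <- NA
  expect_equal(mismatch_distance(a, b), 7 / 39)
  expect_error(mismatch_distance(full, full[1:4]), "ploidy")
})

test_that("mismatch distance is a metric on complete 2-locus profiles", {
  combos <- expand.grid(a1 = 8:9, a2 = 8:9, b1 = 8:9, b2 = 8:9)
  profs <- unique(as.matrix(combos))
  n <- nrow(profs)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D[i, j] <- mismatch_distance(profs[i, ], profs[j, ])
  expect_equal(D, t(D))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
})

test_that("classical MDS reproduces embeddable configurations", {
  tab <- toy_panel(6, alleles = 8:15, freqs = rep(1 / 8, 8))
  # four pairwise fully mismatching profiles: a regular tetrahedron
  prof <- matrix(c(rep(8, 12), rep(10, 12), rep(12, 12), rep(14, 12)),
                 4, 12, byrow = TRUE,
                 dimnames = list(sprintf("c%d", 1:4),
                                 scmixstr:::slot_names(tab)))
  mix <- structure(list(profiles = prof, ploidy = "diploid", panel = tab,
                        truth = NULL, genotypes = NULL),
                   class = "mixture_dataset")
  coords <- mds_embed(mix, 3)
  D_in <- mismatch_matrix(prof)
  D_out <- as.matrix(dist(coords))
  expect_equal(unname(D_out), unname(D_in), tolerance = 1e-9)

  # duplicated profiles land on identical coordinates
  prof2 <- prof[c(1, 1, 2, 3, 4), ]
  mix2 <- mix; mix2$profiles <- prof2
  c2 <- mds_embed(mix2, 3)
  expect_equal(c2[1, ], c2[2, ], tolerance = 1e-9, ignore_attr = TRUE)

  # degenerate all-identical input: all-zero coordinates
  prof3 <- prof[c(1, 1, 1, 1), ]
  mix3 <- mix; mix3$profiles <- prof3
  expect_true(all(mds_embed(mix3, 3) == 0))
})

test_that("MDS stress beats random layouts on noisy fixtures", {
  tab <- synthesize_frequency_table(10, 6, 1, seed = 9)
  set.seed(9)
  gs <- simulate_contributors(relationship_spec("unrelated", 3), tab)
  mix <- assemble_mixture(gs, c(4, 4, 4), tab, drop_model(0.2, e = 0.01))
  coords <- mds_embed(mix, 3)
  D_in <- mismatch_matrix(mix$profiles)
  stress <- function(xy) sum((as.matrix(dist(xy)) - D_in)^2)
  s0 <- stress(coords)
  for (r in 1:100) {
    rand <- matrix(runif(length(coords), -1, 1), nrow(coords))
    expect_lte(s0, stress(rand))
  }
})

test_that("threshold error rate averages the two error arms", {
  expect_equal(threshold_error_rate(30:40, 5:15, 20), 0)
  expect_equal(threshold_error_rate(1:10, 1:10, 5), 0.5)
  # 10 + 10 values, 2 misclassified on each side of threshold 24
  same <- c(26, 27, 28, 29, 30, 31, 32, 33, 23, 24)
  diff <- c(10, 12, 14, 16, 18, 20, 22, 24, 25, 26)
  expect_equal(threshold_error_rate(same, diff, 24), 0.2)
  expect_error(threshold_error_rate(numeric(0), 1:3, 5), "non-empty")
})

test_that("single-cell and unrelated IBS distributions separate at 24", {
  tab <- synthesize_frequency_table(21, 8, 1, seed = 11)
  model <- drop_model(0.2, e = 0.01)
  set.seed(11)
  n <- 800
  gs <- lapply(seq_len(n), function(i) sample_genotype_fst(tab, 0.01))
  cells <- t(vapply(gs, function(g) sim_cells(g, 1, tab, model)[1, ],
                    numeric(42)))
  same <- vapply(seq_len(n), function(i)
    ibs_count(cells[i, ], slots_from_pairs(unclass(gs[[i]]))), numeric(1))
  mixlike <- structure(list(profiles = cells, ploidy = "diploid", panel = tab,
                            truth = NULL, genotypes = NULL),
                       class = "mixture_dataset")
  M <- ibs_matrix(mixlike)
  unrel <- M[upper.tri(M)]  # ~320k unrelated cell pairs
  expect_lt(threshold_error_rate(same, unrel, 24), 0.005)
})
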