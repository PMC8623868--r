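test_that("noiseless cells reproduce the genotype exactly", {
  tab <- synthesize_frequency_table(21, 8, 1, seed = 1)
  set.seed(1)
  g <- sample_genotype_fst(tab, 0.01)
  m0 <- drop_model(D = 0, e = 0)
  cell <- simulate_diploid_cell(g, tab, m0)
  expect_equal(unname(cell), slots_from_pairs(unclass(g)))
  hap <- simulate_haploid_cell(g, tab, m0)
  for (i in 1:21) expect_true(hap[i] %in% unclass(g)[i, ])
})

test_that("drop-out and drop-in rates are recovered empirically", {
  # all-heterozygous genotype, drop-out only
  L <- 50
  tab <- toy_panel(L, alleles = 8:15, freqs = rep(1 / 8, 8))
  g <- genotype_profile(matrix(c(10, 12), L, 2, byrow = TRUE), tab, "g")
  set.seed(21)
  n <- 1000
  cells <- sim_cells(g, n, tab, drop_model(D = 0.2, e = 0))
  called <- rowSums(!is.na(cells))  # per cell, out of 2L slots
  drop_rate <- 1 - sum(called) / (n * 2 * L)
  se <- sqrt(0.2 * 0.8 / (n * 2 * L))
  expect_lt(abs(drop_rate - 0.2), 3 * se)

  # homozygous genotype: whole-locus drop at D2 = 0.02
  gh <- genotype_profile(matrix(10, L, 2), tab, "g")
  cells <- sim_cells(gh, n, tab, drop_model(D = 0.2, e = 0))
  locus_missing <- is.na(cells[, 2 * seq_len(L) - 1])
  se <- sqrt(0.02 * 0.98 / (n * L))
  expect_lt(abs(mean(locus_missing) - 0.02), 3 * se)

  # drop-in only: fraction of called alleles not matching the truth
  cells <- sim_cells(g, n, tab, drop_model(D = 0, e = 0.01))
  wrong <- sum(vapply(seq_len(n), function(r) {
    2 * L - oracle_ibs(cells[r, ], slots_from_pairs(unclass(g)))
  }, numeric(1)))
  se <- sqrt(0.01 * 0.99 / (n * 2 * L))
  expect_lt(abs(wrong / (n * 2 * L) - 0.01), 3.5 * se)
})

test_that("miscalls stay within the panel and respect packing", {
  tab <- toy_panel(10, alleles = 8:15, freqs = rep(1 / 8, 8))
  set.seed(23)
  g <- sample_genotype_fst(tab, 0)
  cells <- sim_cells(g, 500, tab, drop_model(D = 0.5, e = 0.3))
  for (i in 1:10) {
    s1 <- cells[, 2 * i - 1]; s2 <- cells[, 2 * i]
    vals <- c(s1, s2)
    expect_true(all(vals[!is.na(vals)] %in% 8:15))
    # left-packed: slot 2 called implies slot 1 called; sorted when both
    expect_false(any(is.na(s1) & !is.na(s2)))
    both <- !is.na(s1) & !is.na(s2)
    expect_true(all(s1[both] <= s2[both]))
  }
  # a homozygous locus with drop-in can show a second, different allele
  gh <- genotype_profile(matrix(10, 10, 2), tab, "g")
  cells <- sim_cells(gh, 2000, tab, drop_model(D = 0, e = 0.2))
  expect_true(any(cells[, 1] != cells[, 2], na.rm = TRUE))
})

test_that("haploid simulation picks alleles evenly and hits boundaries", {
  L <- 50
  tab <- toy_panel(L, alleles = 8:15, freqs = rep(1 / 8, 8))
  g <- genotype_profile(matrix(c(10, 12), L, 2, byrow = TRUE), tab, "g")
  set.seed(29)
  cells <- sim_cells(g, 1000, tab, drop_model(D = 0, e = 0), "haploid")
  frac10 <- mean(cells == 10)
  se <- sqrt(0.25 / (1000 * L))
  expect_lt(abs(frac10 - 0.5), 3 * se)
  expect_true(all(is.na(sim_cells(g, 5, tab, drop_model(D = 1, e = 0),
                                  "haploid"))))
})

test_that("mixtures conserve cell counts and truth labels", {
  tab <- synthesize_frequency_table(8, 6, 1, seed = 31)
  set.seed(31)
  gs <- simulate_contributors(relationship_spec("unrelated", 3), tab)
  mix <- assemble_mixture(gs, c(2, 6, 12), tab, drop_model(0.2))
  expect_equal(nrow(mix$profiles), 20)
  expect_equal(unname(table(mix$truth)[c("C1", "C2", "C3")]),
               c(2L, 6L, 12L), ignore_attr = TRUE)

  mix0 <- assemble_mixture(gs[1:2], c(0, 5), tab, drop_model(0.2))
  expect_equal(nrow(mix0$profiles), 5)
  expect_true(all(mix0$truth == "C2"))

  # noiseless: every cell equals its own contributor's genotype
  mixn <- assemble_mixture(gs, c(3, 3, 3), tab, drop_model(D = 0, e = 0))
  for (r in seq_len(9)) {
    truth <- gs[[match(mixn$truth[r], c("C1", "C2", "C3"))]]
    expect_equal(unname(mixn$profiles[r, ]), slots_from_pairs(unclass(truth)))
  }
  expect_error(assemble_mixture(gs, c(1, 2), tab), "length")
})

test_that("ARFF round-trips profiles with ? for missing calls", {
  tab <- synthesize_frequency_table(21, 8, 1, seed = 37)
  set.seed(37)
  gs <- simulate_contributors(relationship_spec("unrelated", 2), tab)
  mix <- assemble_mixture(gs, c(5, 5), tab, drop_model(D = 0.3, e = 0.01))
  path <- withr::local_tempfile(fileext = ".arff")
  write_arff(mix, path)
  txt <- readLines(path)
  expect_length(grep("^@attribute", txt), 42)
  expect_true(any(grepl("\\?", txt)))  # dropped alleles serialize as ?
  back <- read_arff(path, tab)
  expect_equal(back$profiles, mix$profiles)
  expect_equal(back$ploidy, "diploid")

  wrong <- synthesize_frequency_table(20, 8, 1, seed = 38)
  expect_error(read_arff(path, wrong), "attributes")
})

test_that("cell filtering keeps cells above the call-fraction threshold", {
  tab <- toy_panel(5, alleles = 8:11, freqs = rep(0.25, 4))
  # constructed call fractions 1.0, 0.9, 0.5, 0.2, 0.0 over 10 slots
  prof <- matrix(8, 5, 10)
  prof[2, 1] <- NA
  prof[3, 1:5] <- NA
  prof[4, 1:8] <- NA
  prof[5, ] <- NA
  colnames(prof) <- scmixstr:::slot_names(tab)
  mix <- structure(list(profiles = prof, ploidy = "diploid", panel = tab,
                        truth = letters[1:5], genotypes = NULL),
                   class = "mixture_dataset")
  expect_equal(nrow(filter_cells(mix, 0)$profiles), 5)
  kept <- filter_cells(mix, 0.6)
  expect_equal(nrow(kept$profiles), 2)
  expect_equal(kept$truth, c("a", "b"))
  expect_equal(nrow(filter_cells(mix, 1e-9)$profiles), 4)  # all-missing removed
})

test_that("profile CSV round-trips diploid and haploid datasets", {
  tab <- synthesize_frequency_table(6, 5, 1, seed = 41)
  set.seed(41)
  gs <- simulate_contributors(relationship_spec("unrelated", 2), tab)
  for (pl in c("diploid", "haploid")) {
    mix <- assemble_mixture(gs, c(3, 3), tab, drop_model(0.3), pl)
    path <- withr::local_tempfile(fileext = ".csv")
    write_profiles_csv(mix, path)
    back <- read_profiles_csv(path, tab, pl)
    expect_equal(back$profiles, mix$profiles)
  }
})
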