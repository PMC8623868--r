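#' Scenario configuration for simulation studies
#'
#' Bundles everything one replicated mixture experiment needs: the
#' relationship among contributors, cells per contributor, ploidy, the
#' drop-out/drop-in model, substructure, the panel (a [freq_table] or NULL
#' for a synthetic default panel), the NOC algorithm and candidate k range,
#' the replicate count and the seed. Defaults mirror the reference study
#' conditions: D = 0.2, e = 0.01, Fst = 0.01, 21 loci.
#'
#' @param relationship a [relationship_spec] (or its kind as a string).
#' @param cell_counts integer cells per contributor.
#' @param ploidy `"diploid"` or `"haploid"`.
#' @param model a [drop_model].
#' @param fst coancestry coefficient.
#' @param panel a [freq_table], or NULL to synthesize a 21-locus, 8-allele
#'   panel from the seed.
#' @param replicates number of simulation replicates.
#' @param seed integer seed; the full run is reproducible from it.
#' @param noc_algorithm `"em"`, `"kmeans"` or `"ibs"`.
#' @param k_min,k_max candidate cluster range for silhouette selection.
#' @param ibs_threshold same-source IBS threshold for the `"ibs"` algorithm.
#' @param mutation a [mutation_model] for related contributors.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(relationship = "unrelated",
                            cell_counts = c(20, 20),
                            ploidy = c("diploid", "haploid"),
                            model = drop_model(),
                            fst = 0.01,
                            panel = NULL,
                            replicates = 100L,
                            seed = 1L,
                            noc_algorithm = c("em", "kmeans", "ibs"),
                            k_min = 2L, k_max = 6L,
                            ibs_threshold = 24L,
                            mutation = mutation_model()) {
  ploidy <- match.arg(ploidy)
  noc_algorithm <- match.arg(noc_algorithm)
  if (is.character(relationship))
    relationship <- relationship_spec(relationship,
                                      n_contributors = length(cell_counts))
  if (relationship$n_contributors != length(cell_counts))
    stop("cell_counts length must equal the number of contributors")
  if (replicates < 1L) stop("replicates must be >= 1")
  structure(list(relationship = relationship, cell_counts = cell_counts,
                 ploidy = ploidy, model = model, fst = fst, panel = panel,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 noc_algorithm = noc_algorithm, k_min = k_min, k_max = k_max,
                 ibs_threshold = ibs_threshold, mutation = mutation),
            class = "scenario_config")
}

# 95% Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ph <- x / n
  den <- 1 + z^2 / n
  centre <- (ph + z^2 / (2 * n)) / den
  half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Run a replicated mixture scenario
#'
#' Per replicate: simulate contributor genotypes, generate and pool cells,
#' estimate the NOC; when the estimate equals the true contributor count,
#' build one consensus profile per cluster of the winning partition,
#' optimally match clusters to true contributors, and score consensus
#' accuracy. NOC accuracy aggregates over all replicates; consensus
#' statistics aggregate only over correct-NOC replicates (per-replicate
#' value = mean accuracy over contributors). Fully reproducible from the
#' config seed.
#'
#' @param config a [scenario_config].
#' @return object of class `scenario_result`: list with `noc_accuracy`,
#'   `noc_ci` (95% Wilson), `consensus_accuracy`, `consensus_ci`,
#'   `per_contributor_accuracy`, `noc_estimates`, `replicates`,
#'   `n_correct_noc` and the `config`.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  panel <- config$panel
  if (is.null(panel))
    panel <- synthesize_frequency_table(21, 8, 1, seed = config$seed)
  ncontrib <- config$relationship$n_contributors
  if (sum(config$cell_counts > 0) < config$k_min &&
      config$noc_algorithm != "ibs")
    stop("fewer contributing cells than k_min: infeasible config")
  set.seed(config$seed)  # panel synthesis consumed draws; restart the stream
  noc_hat <- integer(config$replicates)
  cons_mean <- rep(NA_real_, config$replicates)
  per_contrib <- matrix(NA_real_, config$replicates, ncontrib)
  for (r in seq_len(config$replicates)) {
    contribs <- simulate_contributors(config$relationship, panel,
                                      config$fst, config$mutation)
    mix <- assemble_mixture(contribs, config$cell_counts, panel,
                            config$model, config$ploidy)
    est <- switch(config$noc_algorithm,
                  "ibs" = suppressWarnings(
                    estimate_noc_ibs(mix, config$ibs_threshold)),
                  estimate_noc(mix, config$noc_algorithm,
                               config$k_min, config$k_max))
    noc_hat[r] <- est$noc
    if (est$noc == ncontrib) {
      assign <- est$best_clustering$assignment
      cons <- lapply(seq_len(ncontrib), function(j)
        consensus_profile(mix$profiles[assign == j, , drop = FALSE],
                          panel, config$ploidy))
      matching <- match_clusters_to_truth(cons, contribs)
      acc <- vapply(seq_len(ncontrib), function(j)
        consensus_accuracy(cons[[j]], contribs[[matching[j]]]), numeric(1))
      # report per true contributor, in contributor order
      per_contrib[r, matching] <- acc
      cons_mean[r] <- mean(acc)
    }
  }
  correct <- noc_hat == ncontrib
  res <- list(
    noc_accuracy = mean(correct),
    noc_ci = wilson_ci(sum(correct), config$replicates),
    consensus_accuracy = if (any(correct)) mean(cons_mean[correct]) else NA_real_,
    consensus_ci = if (sum(correct) > 1) {
      v <- cons_mean[correct]
      mean(v) + c(-1, 1) * stats::qt(0.975, length(v) - 1) *
        stats::sd(v) / sqrt(length(v))
    } else c(NA_real_, NA_real_),
    per_contributor_accuracy = colMeans(per_contrib[correct, , drop = FALSE]),
    noc_estimates = noc_hat,
    replicates = config$replicates,
    n_correct_noc = sum(correct),
    config = config)
  class(res) <- "scenario_result"
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("scenario: %s, cells (%s), %s, D=%g e=%g, %d replicates\n",
              cfg$relationship$kind,
              paste(cfg$cell_counts, collapse = ","),
              cfg$ploidy, cfg$model$D, cfg$model$e, x$replicates))
  cat(sprintf("  NOC accuracy: %.2f%% [%.2f%%, %.2f%%]\n",
              100 * x$noc_accuracy, 100 * x$noc_ci[1], 100 * x$noc_ci[2]))
  if (!is.na(x$consensus_accuracy))
    cat(sprintf("  consensus accuracy (correct-NOC replicates, n=%d): %.2f%%\n",
                x$n_correct_noc, 100 * x$consensus_accuracy))
  invisible(x)
}

#' Contributor-detection probability table
#'
#' Grid of [prob_missing_contributor()] values over sampled-cell counts and
#' mixture proportions, with DNA-mass columns at 6.6 pg per diploid and
#' 3.3 pg per haploid cell.
#'
#' @param proportions mixture proportions (defaults 1%, 5%, 10%, 20%, 50%).
#' @param cell_counts sampled-cell counts (defaults 1-500).
#' @return data.frame: n_cells, dna_pg_diploid, dna_pg_haploid, then one
#'   probability column per proportion (as fractions, not percent).
#' @export
detection_table <- function(proportions = c(0.01, 0.05, 0.10, 0.20, 0.50),
                            cell_counts = c(1, 5, 10, 15, 20, 40, 80, 160, 500)) {
  out <- data.frame(n_cells = cell_counts,
                    dna_pg_diploid = 6.6 * cell_counts,
                    dna_pg_haploid = 3.3 * cell_counts)
  for (p in proportions)
    out[[sprintf("p%g", 100 * p)]] <- prob_missing_contributor(p, cell_counts)
  out
}

#' IBS distributions of related pairs and consensus-vs-truth pairs
#'
#' Generates (i) IBS between the true genotypes of pairs of individuals
#' under each requested relationship and (ii) IBS between a contributor's
#' true genotype and the consensus of n of that contributor's cells, for
#' each requested n (missing consensus calls contribute no matches).
#'
#' @param kinds relationship kinds for true-genotype pairs (subset of
#'   `"unrelated"`, `"parent-child"`, `"full-siblings"`).
#' @param cells_per_consensus integer vector of cluster sizes n.
#' @param model a [drop_model].
#' @param table a [freq_table] (NULL = synthetic default panel).
#' @param ploidy cell ploidy for the consensus arm.
#' @param fst coancestry coefficient.
#' @param replicates pairs simulated per distribution.
#' @param seed integer seed.
#' @return named list of integer IBS samples (`UR`, `PC`, `FS`,
#'   `cons1`, `cons2`, ... per requested n), plus a `histogram` data.frame
#'   of counts per IBS value per sample.
#' @export
ibs_distribution_study <- function(kinds = c("unrelated", "parent-child",
                                             "full-siblings"),
                                   cells_per_consensus = c(1, 2, 5, 10),
                                   model = drop_model(),
                                   table = NULL,
                                   ploidy = c("diploid", "haploid"),
                                   fst = 0.01,
                                   replicates = 1000L,
                                   seed = 1L) {
  ploidy <- match.arg(ploidy)
  set.seed(seed)
  if (is.null(table)) table <- synthesize_frequency_table(21, 8, 1, seed = seed)
  set.seed(seed)
  short <- c("unrelated" = "UR", "parent-child" = "PC",
             "full-siblings" = "FS")
  samples <- list()
  for (kind in kinds) {
    spec <- relationship_spec(kind, 2L)
    samples[[short[[kind]]]] <- vapply(seq_len(replicates), function(r) {
      pair <- simulate_contributors(spec, table, fst)
      ibs_count(pair[[1]], pair[[2]])
    }, numeric(1))
  }
  for (ncell in cells_per_consensus) {
    samples[[sprintf("cons%d", ncell)]] <- vapply(seq_len(replicates),
      function(r) {
        g <- sample_genotype_fst(table, fst)
        cons <- consensus_profile(sim_cells(g, ncell, table, model, ploidy),
                                  table, ploidy)
        ibs_count(cons, g)
      }, numeric(1))
  }
  hist <- do.call(rbind, lapply(names(samples), function(nm) {
    tab <- base::table(factor(samples[[nm]], levels = 0:(2 * n_loci(table))))
    data.frame(sample = nm, ibs = as.integer(names(tab)),
               count = as.integer(tab))
  }))
  c(samples, list(histogram = hist))
}

#' Run a scenario described by a YAML or JSON config file
#'
#' Recognized keys mirror the [scenario_config()] arguments (`relationship`,
#' `cell_counts`, `ploidy`, `D`, `D2`, `e`, `fst`, `panel_file`,
#' `replicates`, `seed`, `noc_algorithm`, `k_min`, `k_max`,
#' `ibs_threshold`); omitted keys take the defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `scenario_result`.
#' @export
run_scenario_file <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path)
  model <- drop_model(D = cfg$D %||% 0.2,
                      D2 = cfg$D2 %||% ((cfg$D %||% 0.2)^2 / 2),
                      e = cfg$e %||% 0.01)
  panel <- if (!is.null(cfg$panel_file)) load_frequency_table(cfg$panel_file)
  run_scenario(scenario_config(
    relationship = cfg$relationship %||% "unrelated",
    cell_counts = cfg$cell_counts %||% c(20, 20),
    ploidy = cfg$ploidy %||% "diploid",
    model = model,
    fst = cfg$fst %||% 0.01,
    panel = panel,
    replicates = cfg$replicates %||% 100L,
    seed = cfg$seed %||% 1L,
    noc_algorithm = cfg$noc_algorithm %||% "em",
    k_min = cfg$k_min %||% 2L,
    k_max = cfg$k_max %||% 6L,
    ibs_threshold = cfg$ibs_threshold %||% 24L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
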