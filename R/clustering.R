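#' Feature encoding and contributor clustering
#'
#' Single-cell profiles are clustered on their raw allele designations: the
#' feature matrix has one numeric column per allele slot (2L diploid, L
#' haploid) in panel locus order, missing calls as NA. Two algorithms are
#' provided: diagonal-covariance Gaussian mixture EM (missing entries enter
#' via the marginal likelihood over a cell's observed slots) and Lloyd
#' k-means with k-means++ seeding (distances over observed slots, rescaled
#' by total/observed slot counts). The number of contributors (NOC) is the
#' candidate k with the highest average silhouette.
#'
#' @name clustering
NULL

#' Encode a mixture as a numeric feature matrix
#'
#' @param dataset a `mixture_dataset`.
#' @return cells x slots numeric matrix with NA for missing calls; slot
#'   order is panel locus order x (slot1, slot2).
#' @export
encode_profiles <- function(dataset) {
  dataset$profiles
}

#' Pairwise missing-rescaled Euclidean distances
#'
#' d(i,j) = sqrt((S / m_ij) * sum of squared differences over the m_ij slots
#' observed in both cells), S = total slots. Pairs with no commonly observed
#' slot get the largest representable separation, sqrt(S) * allele range.
#'
#' @param X feature matrix with NA for missing.
#' @return symmetric distance matrix.
#' @export
profile_dist <- function(X) {
  S <- ncol(X)
  M <- (!is.na(X)) * 1
  X0 <- X
  X0[is.na(X0)] <- 0
  sq <- X0^2
  cross <- tcrossprod(X0)
  s2 <- tcrossprod(sq, M)
  d2 <- s2 + t(s2) - 2 * cross
  d2[d2 < 0] <- 0  # numerical noise
  m <- tcrossprod(M)
  out <- matrix(0, nrow(X), nrow(X))
  pos <- m > 0
  out[pos] <- sqrt(S * d2[pos] / m[pos])
  if (any(!pos)) {
    rng <- diff(range(X, na.rm = TRUE))
    out[!pos] <- sqrt(S) * max(rng, 1)
  }
  diag(out) <- 0
  dimnames(out) <- list(rownames(X), rownames(X))
  out
}

# distances from each cell to each complete centroid, rescaled by the
# cell's observed-slot count
cell_centroid_dist2 <- function(X, centers) {
  S <- ncol(X)
  M <- (!is.na(X)) * 1
  X0 <- X
  X0[is.na(X0)] <- 0
  m <- rowSums(M)
  # sum_s m_is (x_is - c_ks)^2
  d2 <- matrix(0, nrow(X), nrow(centers))
  for (k in seq_len(nrow(centers))) {
    diff <- sweep(X0, 2, centers[k, ])
    d2[, k] <- rowSums(M * diff^2)
  }
  sweep(d2, 1, S / pmax(m, 1), "*")
}

#' K-means clustering of single-cell profiles
#'
#' Lloyd iterations from k-means++-style seeding. Centroid slots are updated
#' as means over the cells observing that slot, weighted by each cell's
#' rescaling factor so the objective (sum of rescaled squared distances) is
#' non-increasing; empty clusters are repaired by splitting off the cell
#' farthest from its centroid.
#'
#' @param X feature matrix (NA = missing).
#' @param k number of clusters, `1 <= k <= nrow(X)`.
#' @param seed integer seed (NULL leaves the RNG stream untouched).
#' @param max_iter iteration cap.
#' @param nstart number of independent seedings; the run with the lowest
#'   final objective is kept.
#' @return object of class `clustering_result`: list with `k`, `assignment`,
#'   `objective` (final within-cluster sum of rescaled squared distances),
#'   `objective_trace`, `centers`, `silhouette` (NA until computed).
#' @export
cluster_kmeans <- function(X, k, seed = NULL, max_iter = 100L, nstart = 10L) {
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (s in seq_len(nstart)) {
    fit <- kmeans_once(X, k, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best
}

kmeans_once <- function(X, k, max_iter = 100L) {
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of cells")
  S <- ncol(X)
  M <- (!is.na(X)) * 1
  X0 <- X
  X0[is.na(X0)] <- 0
  w <- S / pmax(rowSums(M), 1)

  # k-means++ seeding on the cell-cell rescaled distances
  centers <- matrix(NA_real_, k, S)
  first <- sample.int(n, 1L)
  centers[1L, ] <- impute_row(X, first)
  if (k > 1L) {
    d2 <- cell_centroid_dist2(X, centers[1L, , drop = FALSE])[, 1]
    for (j in 2:k) {
      probs <- d2 / sum(d2)
      if (!all(is.finite(probs)) || sum(d2) == 0)
        probs <- rep(1 / n, n)
      pick <- sample.int(n, 1L, prob = probs)
      centers[j, ] <- impute_row(X, pick)
      d2 <- pmin(d2, cell_centroid_dist2(X, centers[j, , drop = FALSE])[, 1])
    }
  }

  assignment <- rep(1L, n)
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    d2 <- cell_centroid_dist2(X, centers)
    assignment <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: split off the farthest cell
    for (j in which(tabulate(assignment, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(n), assignment)])
      assignment[far] <- j
      d2[far, ] <- 0
    }
    obj <- sum(d2[cbind(seq_len(n), assignment)])
    trace <- c(trace, obj)
    new_centers <- centers
    for (j in seq_len(k)) {
      idx <- which(assignment == j)
      Wj <- M[idx, , drop = FALSE] * w[idx]
      tot <- colSums(Wj)
      num <- colSums(X0[idx, , drop = FALSE] * w[idx] * M[idx, , drop = FALSE])
      upd <- tot > 0
      new_centers[j, upd] <- num[upd] / tot[upd]
    }
    if (max(abs(new_centers - centers)) < 1e-10 && iter > 1L) break
    centers <- new_centers
  }
  structure(list(k = k, assignment = assignment, objective = trace[length(trace)],
                 objective_trace = trace, centers = centers, silhouette = NA_real_),
            class = "clustering_result")
}

# fill a cell's missing slots with the column means (for seeding centroids)
impute_row <- function(X, i) {
  r <- X[i, ]
  if (anyNA(r)) {
    mu <- colMeans(X, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    r[is.na(r)] <- mu[is.na(r)]
  }
  r
}

#' EM clustering with diagonal-covariance Gaussian mixture components
#'
#' Initialized from [cluster_kmeans()] (means, per-slot variances and weights
#' taken from its partition). Missing entries contribute through the marginal
#' likelihood: each cell's component density is evaluated over its observed
#' slots only. The observed-data log-likelihood is non-decreasing across
#' iterations; convergence when the improvement drops below `tol`. Variances
#' are floored at 1e-4.
#'
#' @inheritParams cluster_kmeans
#' @param tol log-likelihood convergence tolerance.
#' @param nstart number of independent initializations; the run with the
#'   highest final log-likelihood is kept.
#' @return a `clustering_result` with `objective` = final log-likelihood and
#'   `objective_trace` the per-iteration log-likelihood sequence.
#' @export
cluster_em <- function(X, k, seed = NULL, max_iter = 200L, tol = 1e-6,
                       nstart = 3L) {
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (s in seq_len(nstart)) {
    fit <- em_once(X, k, max_iter, tol)
    if (is.null(best) || fit$objective > best$objective) best <- fit
  }
  best
}

em_once <- function(X, k, max_iter = 200L, tol = 1e-6) {
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of cells")
  S <- ncol(X)
  M <- (!is.na(X)) * 1
  X0 <- X
  X0[is.na(X0)] <- 0

  km <- cluster_kmeans(X, k)
  mu <- km$centers
  var_floor <- 1e-4
  sig2 <- matrix(var_floor, k, S)
  for (j in seq_len(k)) {
    idx <- which(km$assignment == j)
    if (length(idx)) {
      diff <- sweep(X0[idx, , drop = FALSE], 2, mu[j, ])
      cnt <- colSums(M[idx, , drop = FALSE])
      v <- colSums(M[idx, , drop = FALSE] * diff^2) / pmax(cnt, 1)
      sig2[j, ] <- pmax(v, var_floor)
    }
  }
  wts <- pmax(tabulate(km$assignment, k), 0.5)
  wts <- wts / sum(wts)

  loglik_component <- function() {
    ll <- matrix(0, n, k)
    for (j in seq_len(k)) {
      lognorm <- -0.5 * log(2 * pi * sig2[j, ])
      diff2 <- sweep(X0, 2, mu[j, ])^2
      quad <- sweep(diff2, 2, 2 * sig2[j, ], "/")
      ll[, j] <- M %*% lognorm - rowSums(M * quad) + log(wts[j])
    }
    ll
  }

  trace <- numeric(0)
  resp <- NULL
  for (iter in seq_len(max_iter)) {
    ll <- loglik_component()
    mx <- apply(ll, 1, max)
    lse <- mx + log(rowSums(exp(ll - mx)))
    trace <- c(trace, sum(lse))
    resp <- exp(ll - lse)
    if (iter > 1L && trace[iter] - trace[iter - 1L] < tol) break
    for (j in seq_len(k)) {
      wj <- resp[, j]
      denom <- colSums(wj * M)
      upd <- denom > 1e-12
      mu[j, upd] <- colSums(wj * M * X0)[upd] / denom[upd]
      diff2 <- sweep(X0, 2, mu[j, ])^2
      sig2[j, upd] <- pmax(colSums(wj * M * diff2)[upd] / denom[upd], var_floor)
    }
    wts <- pmax(colMeans(resp), 1e-12)
    wts <- wts / sum(wts)
  }
  assignment <- max.col(resp, ties.method = "first")
  # EM may empty a component; relabel to keep clusters non-empty
  used <- sort(unique(assignment))
  assignment <- match(assignment, used)
  structure(list(k = length(used), assignment = assignment,
                 objective = trace[length(trace)], objective_trace = trace,
                 centers = mu[used, , drop = FALSE], silhouette = NA_real_),
            class = "clustering_result")
}

#' Average silhouette coefficient
#'
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)) with a(i) the mean distance to the
#' cell's own cluster and b(i) the smallest mean distance to another cluster,
#' averaged over cells; singletons contribute 0. Distances are the
#' missing-rescaled Euclidean distances of [profile_dist()].
#'
#' @param X feature matrix (ignored when `dist` is supplied).
#' @param assignment integer cluster labels covering >= 2 non-empty clusters.
#' @param dist optional precomputed distance matrix.
#' @return average silhouette in `[-1, 1]`.
#' @export
silhouette_coefficient <- function(X, assignment, dist = NULL) {
  ks <- unique(assignment)
  if (length(ks) < 2L) stop("silhouette needs at least 2 non-empty clusters")
  if (is.null(dist)) dist <- profile_dist(X)
  n <- length(assignment)
  sizes <- table(factor(assignment, levels = ks))
  s <- numeric(n)
  # mean distance from each cell to each cluster
  agg <- vapply(ks, function(j) rowSums(dist[, assignment == j, drop = FALSE]),
                numeric(n))
  for (i in seq_len(n)) {
    own <- match(assignment[i], ks)
    ni <- sizes[own]
    if (ni == 1L) { s[i] <- 0; next }
    a <- agg[i, own] / (ni - 1L)
    b <- min(agg[i, -own] / sizes[-own])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Estimate the number of contributors by clustering + silhouette
#'
#' Runs the chosen algorithm for each candidate k in `[k_min, min(k_max, n)]`
#' and returns the k with the highest average silhouette (ties broken toward
#' smaller k). k = 1 is outside the silhouette's domain, so the estimate is
#' never 1; single-source detection is delegated to [estimate_noc_ibs()].
#'
#' @param X feature matrix or a `mixture_dataset`.
#' @param algorithm `"em"` or `"kmeans"`.
#' @param k_min,k_max candidate range (defaults 2..6).
#' @param seed integer seed.
#' @return object of class `noc_estimate`: list with `noc`, `per_k_scores`
#'   (named silhouettes per candidate k) and `best_clustering`.
#' @export
estimate_noc <- function(X, algorithm = c("em", "kmeans"),
                         k_min = 2L, k_max = 6L, seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (inherits(X, "mixture_dataset")) X <- encode_profiles(X)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  if (n < k_min) stop("too few cells for the requested k range")
  kmax <- min(k_max, n)
  D <- profile_dist(X)
  ks <- seq.int(k_min, kmax)
  scores <- rep(NA_real_, length(ks))
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    fit <- if (algorithm == "em") cluster_em(X, ks[i]) else cluster_kmeans(X, ks[i])
    fit$silhouette <- if (length(unique(fit$assignment)) >= 2L)
      silhouette_coefficient(X, fit$assignment, dist = D) else -Inf
    scores[i] <- fit$silhouette
    fits[[i]] <- fit
  }
  best <- which.max(scores)  # first max -> smaller k on ties
  structure(list(noc = ks[best],
                 per_k_scores = stats::setNames(scores, ks),
                 best_clustering = fits[[best]]),
            class = "noc_estimate")
}

#' @export
print.noc_estimate <- function(x, ...) {
  cat(sprintf("estimated NOC: %d\n", x$noc))
  cat("silhouette per k:\n")
  print(round(x$per_k_scores, 4))
  invisible(x)
}

#' Estimate the NOC by pairwise IBS thresholding
#'
#' Builds a graph with an edge between two cells whenever their pairwise IBS
#' exceeds `min_same_source_ibs`; the NOC is the number of connected
#' components. Intended for diploid profiles of unrelated contributors; a
#' single consensus haploid cell is homozygous everywhere, so the method
#' warns on haploid input.
#'
#' @param dataset a `mixture_dataset`.
#' @param min_same_source_ibs edge threshold: same source iff IBS strictly
#'   greater (default 24, calibrated for D = 0.2, e = 0.01 on a 21-locus
#'   panel).
#' @return a `noc_estimate` whose `best_clustering$assignment` holds the
#'   component labels.
#' @export
estimate_noc_ibs <- function(dataset, min_same_source_ibs = 24L) {
  if (dataset$ploidy == "haploid")
    warning("IBS thresholding is unreliable for haploid cell profiles")
  ibs <- ibs_matrix(dataset)
  adj <- ibs > min_same_source_ibs
  comp <- connected_components(adj)
  fit <- structure(list(k = max(comp), assignment = comp,
                        objective = NA_real_, objective_trace = numeric(0),
                        centers = NULL, silhouette = NA_real_),
                   class = "clustering_result")
  structure(list(noc = max(comp),
                 per_k_scores = stats::setNames(numeric(0), character(0)),
                 best_clustering = fit),
            class = "noc_estimate")
}

# connected components of a logical adjacency matrix (BFS)
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start]) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Write cluster assignments as CSV
#'
#' Columns cell_id, cluster (and truth when available).
#' @param dataset a `mixture_dataset`.
#' @param result a `clustering_result`.
#' @param path output path.
#' @export
write_assignments_csv <- function(dataset, result, path) {
  df <- data.frame(cell_id = rownames(dataset$profiles),
                   cluster = result$assignment)
  if (!is.null(dataset$truth)) df$truth <- dataset$truth
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
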