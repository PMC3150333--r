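#' Euclidean distance between two reactivity profiles
#'
#' The similarity metric used throughout the clustering stage: the square root
#' of the sum of squared coordinate differences.
#'
#' @param u,v numeric vectors of equal length.
#' @return Non-negative scalar; zero iff `u == v`.
#' @export
#' @examples
#' euclidean_distance(c(0, 3), c(4, 0)) # 5
euclidean_distance <- function(u, v) {
  if (length(u) != length(v)) abort("input error: profile length mismatch")
  sqrt(sum((u - v)^2))
}

#' Clustering configuration
#'
#' @param k_candidates integer vector of candidate cluster counts (all >= 2:
#'   the validity indices are undefined at k = 1).
#' @param max_iterations Lloyd iteration cap per restart (default 10,000).
#' @param n_restarts independent random initializations; the solution with the
#'   lowest within-cluster sum of squares is kept.
#' @param seed integer seed making the whole procedure deterministic.
#' @export
clustering_config <- function(k_candidates = 2:6, max_iterations = 10000L,
                              n_restarts = 25L, seed = 1L) {
  if (any(k_candidates < 2)) abort("all k candidates must be >= 2")
  if (max_iterations < 1) abort("max_iterations must be >= 1")
  structure(list(k_candidates = as.integer(k_candidates),
                 max_iterations = as.integer(max_iterations),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "clustering_config")
}

as_profile_matrix <- function(x) {
  if (inherits(x, "ige_reactivity")) reactivity_values(x) else as.matrix(x)
}

# One Lloyd run from given initial centroids. Returns 0-based labels.
lloyd_run <- function(m, centroids, max_iterations) {
  n <- nrow(m); k <- nrow(centroids)
  rs_m <- rowSums(m^2)
  assign_old <- rep(-1L, n)
  reseeds <- 0L
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    d2 <- outer(rs_m, rowSums(centroids^2), "+") - 2 * tcrossprod(m, centroids)
    assign <- max.col(-d2, ties.method = "first")
    # Empty-cluster rule: reseed the centroid at the point farthest from its
    # current centroid, then reassign.
    empty <- setdiff(seq_len(k), unique(assign))
    tries <- 0L
    while (length(empty) && tries < 10L * k) {
      far <- which.max(d2[cbind(seq_len(n), assign)])
      centroids[empty[1], ] <- m[far, ]
      reseeds <- reseeds + 1L
      tries <- tries + 1L
      d2 <- outer(rs_m, rowSums(centroids^2), "+") - 2 * tcrossprod(m, centroids)
      assign <- max.col(-d2, ties.method = "first")
      empty <- setdiff(seq_len(k), unique(assign))
    }
    if (length(empty)) {
      abort("k-means could not fill all clusters (fewer distinct profiles than k?)")
    }
    if (identical(assign, assign_old)) { converged <- TRUE; break }
    if (iter >= max_iterations) break
    assign_old <- assign
    centroids <- rowsum(m, assign) / as.vector(table(factor(assign, seq_len(k))))
  }
  wcss <- sum((m - centroids[assign, , drop = FALSE])^2)
  list(assignments = assign - 1L, centroids = centroids, wcss = wcss,
       converged = converged, iterations = iter, reseeds = reseeds)
}

#' K-means clustering of reactivity profiles
#'
#' Lloyd's algorithm (assign each profile to the nearest centroid by Euclidean
#' distance, recompute centroids as means) iterated until assignments stop
#' changing or `max_iterations` is reached, repeated over `n_restarts` random
#' initializations (k distinct subjects drawn uniformly as seeds) keeping the
#' lowest-WCSS solution. An empty-cluster event re-seeds that centroid at the
#' point farthest from its assigned centroid, and is recorded.
#'
#' @param x reactivity table or numeric matrix (subjects x features).
#' @param k number of clusters (2 <= k <= n).
#' @param config a [clustering_config()]; its `k_candidates` is ignored here.
#' @return An object of class `ige_kmeans`: list with `k`, `assignments`
#'   (0-based labels, named by subject when available), `centroids`, `wcss`,
#'   `converged`, `iterations_used`, `n_reseeds`.
#' @export
#' @examples
#' m <- rbind(matrix(0, 4, 2), matrix(5, 4, 2))
#' profile_kmeans(m, k = 2)$wcss # 0
profile_kmeans <- function(x, k, config = clustering_config()) {
  m <- as_profile_matrix(x)
  n <- nrow(m)
  if (k > n) abort("input error: k exceeds the number of subjects")
  if (k < 1) abort("input error: k must be >= 1")
  withr::local_seed(config$seed)
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    init <- m[sample.int(n, k), , drop = FALSE]
    run <- lloyd_run(m, init, config$max_iterations)
    if (is.null(best) || run$wcss < best$wcss - 1e-12) best <- run
  }
  names(best$assignments) <- rownames(m)
  structure(list(k = as.integer(k), assignments = best$assignments,
                 centroids = best$centroids, wcss = best$wcss,
                 converged = best$converged,
                 iterations_used = best$iterations,
                 n_reseeds = best$reseeds),
            class = "ige_kmeans")
}

#' @export
print.ige_kmeans <- function(x, ...) {
  cat(sprintf("k-means profile clustering: k = %d, n = %d, WCSS = %.4g%s\n",
              x$k, length(x$assignments), x$wcss,
              if (x$converged) "" else " (not converged)"))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Cluster validity indices
#'
#' Computes the five-index validity ensemble used to choose the number of
#' clusters: silhouette, Dunn, Davies-Bouldin, C-index and an isolation
#' (neighbour-purity) index. All are based on Euclidean distances.
#'
#' * Silhouette: mean over points of (b - a) / max(a, b), with a the mean
#'   distance to the point's own cluster and b the smallest mean distance to
#'   another cluster; a singleton cluster's point contributes 0.
#' * Dunn: minimum single-linkage inter-cluster distance divided by the
#'   maximum cluster diameter.
#' * Davies-Bouldin: mean over clusters of max over other clusters of
#'   (s_i + s_j) / d(c_i, c_j), where s is the mean distance to the centroid.
#' * C-index: (S - S_min) / (S_max - S_min), S the sum of within-cluster
#'   pairwise distances and S_min/S_max the sums of the equally many smallest/
#'   largest pairwise distances overall.
#' * Isolation: mean over points of the fraction of its `q` nearest
#'   neighbours sharing its cluster.
#'
#' @param x reactivity table or numeric matrix.
#' @param result an `ige_kmeans` result (or any object with 0-based
#'   `assignments` and `centroids`).
#' @param q neighbourhood size for the isolation index (default 10).
#' @return One-row tibble with columns `k`, `silhouette`, `dunn`,
#'   `davies_bouldin`, `c_index`, `isolation`.
#' @export
validity_indices <- function(x, result, q = 10L) {
  m <- as_profile_matrix(x)
  lab <- as.integer(result$assignments) + 1L
  k <- max(lab)
  n <- nrow(m)
  if (k < 2) abort("validity indices need k >= 2")
  if (length(unique(lab)) < k) abort("empty cluster in assignments")
  D <- as.matrix(stats::dist(m))
  sizes <- tabulate(lab, k)

  # Silhouette
  clus_mean <- t(rowsum(t(D), lab)) / rep(sizes, each = n)  # n x k mean dists
  a <- numeric(n); b <- numeric(n); sil <- numeric(n)
  for (i in seq_len(n)) {
    ci <- lab[i]
    if (sizes[ci] == 1) { sil[i] <- 0; next }
    a[i] <- clus_mean[i, ci] * sizes[ci] / (sizes[ci] - 1)
    b[i] <- min(clus_mean[i, -ci])
    sil[i] <- (b[i] - a[i]) / max(a[i], b[i])
  }
  silhouette <- mean(sil)

  # Dunn
  diam <- vapply(seq_len(k), function(c) {
    pts <- which(lab == c)
    if (length(pts) < 2) 0 else max(D[pts, pts])
  }, numeric(1))
  min_between <- min(vapply(utils::combn(k, 2, simplify = FALSE), function(pr) {
    min(D[lab == pr[1], lab == pr[2]])
  }, numeric(1)))
  dunn <- if (max(diam) == 0) Inf else min_between / max(diam)

  # Davies-Bouldin
  cen <- result$centroids
  s <- vapply(seq_len(k), function(c) {
    pts <- which(lab == c)
    mean(sqrt(rowSums((m[pts, , drop = FALSE] -
                         matrix(cen[c, ], length(pts), ncol(m), byrow = TRUE))^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(cen))
  if (any(M[upper.tri(M)] == 0)) abort("index error: coincident centroids")
  R <- vapply(seq_len(k), function(i) {
    max((s[i] + s[-i]) / M[i, -i])
  }, numeric(1))
  davies_bouldin <- mean(R)

  # C-index
  ut <- upper.tri(D)
  same <- outer(lab, lab, "==") & ut
  S <- sum(D[same])
  nw <- sum(same)
  all_d <- sort(D[ut])
  s_min <- sum(all_d[seq_len(nw)])
  s_max <- sum(all_d[seq.int(length(all_d) - nw + 1L, length(all_d))])
  c_index <- if (s_max > s_min) (S - s_min) / (s_max - s_min) else 0

  # Isolation (neighbour purity)
  qq <- min(q, n - 1L)
  iso <- vapply(seq_len(n), function(i) {
    nb <- order(D[i, -i])[seq_len(qq)]
    idx <- seq_len(n)[-i][nb]
    mean(lab[idx] == lab[i])
  }, numeric(1))
  isolation <- mean(iso)

  tibble::tibble(k = k, silhouette = silhouette, dunn = dunn,
                 davies_bouldin = davies_bouldin, c_index = c_index,
                 isolation = isolation)
}

#' Choose the number of clusters with the five-index ensemble
#'
#' Runs [profile_kmeans()] for each candidate k, scores each partition with
#' [validity_indices()], and lets the indices vote: silhouette, Dunn and
#' isolation vote for their maximizing k, Davies-Bouldin and C-index for their
#' minimizing k. The plurality winner is chosen; ties are broken by the best
#' mean rank across indices, then by the smaller k.
#'
#' @inheritParams profile_kmeans
#' @param config a [clustering_config()] carrying `k_candidates`.
#' @param q isolation-index neighbourhood size.
#' @return An object of class `ige_kselect`: list with `report` (per-k index
#'   tibble + per-index rank columns), `chosen_k`, `votes` (named vector), and
#'   `results` (the `ige_kmeans` fits keyed by k).
#' @export
select_k <- function(x, config = clustering_config(), q = 10L) {
  ks <- config$k_candidates
  if (length(ks) < 1) abort("selection error: no candidate k")
  m <- as_profile_matrix(x)
  results <- list()
  rows <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    fit <- profile_kmeans(m, ks[i], cfg_i)
    results[[as.character(ks[i])]] <- fit
    rows[[i]] <- validity_indices(m, fit, q = q)
  }
  report <- dplyr::bind_rows(rows)
  higher <- c("silhouette", "dunn", "isolation")
  lower <- c("davies_bouldin", "c_index")
  ranks <- vapply(c(higher, lower), function(idx) {
    v <- report[[idx]]
    if (idx %in% higher) rank(-v, ties.method = "min") else rank(v, ties.method = "min")
  }, numeric(nrow(report)))
  ranks <- matrix(ranks, nrow = nrow(report),
                  dimnames = list(NULL, c(higher, lower)))
  votes <- table(factor(report$k[apply(ranks, 2, which.min)], levels = report$k))
  mean_rank <- rowMeans(ranks)
  top <- as.integer(names(votes)[votes == max(votes)])
  if (length(top) > 1) {
    mr <- mean_rank[report$k %in% top]
    top <- top[mr == min(mr)]
  }
  chosen_k <- min(top)
  report <- dplyr::bind_cols(report, stats::setNames(
    tibble::as_tibble(ranks), paste0("rank_", colnames(ranks))))
  structure(list(report = report, chosen_k = chosen_k,
                 votes = stats::setNames(as.integer(votes), names(votes)),
                 results = results),
            class = "ige_kselect")
}

#' @export
print.ige_kselect <- function(x, ...) {
  cat(sprintf("cluster-count selection: chosen k = %d\n", x$chosen_k))
  cat("votes:", paste(sprintf("k=%s:%d", names(x$votes), x$votes),
                      collapse = "  "), "\n")
  print(x$report[, 1:6])
  invisible(x)
}
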