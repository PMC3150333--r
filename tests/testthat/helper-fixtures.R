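# Shared fixtures built in code.

# Log-linear calibration: signal = 300 * conc^0.9 at the five reference
# standards, strictly increasing in both coordinates.
toy_curve <- function() {
  conc <- c(0.35, 1.0, 3.5, 10.0, 50.0)
  calibration_curve(conc, 300 * conc^0.9)
}

# Small cohort spec for fast tests.
small_spec <- function(seed, n_families = 60, panel_size = 40,
                       signature = default_signature(8, c(1, 1.5)), ...) {
  cohort_spec(n_families = n_families, panel_size = panel_size,
              signature = signature, seed = seed, ...)
}

# A cohort spec satisfying the Mann-Whitney independence null: no planted
# signature and no family-structured reactivity.
null_iid_spec <- function(seed, n_families = 120, panel_size = 103) {
  cohort_spec(n_families = n_families, panel_size = panel_size,
              signature = NULL, familial_correlation = 0,
              exposure_groups = 0, seed = seed)
}

# Three well-separated spherical clusters in `p` dimensions.
planted_three_clusters <- function(seed, n_per = 30, p = 5, sep = 6) {
  withr::with_seed(seed, {
    centers <- rbind(rep(0, p), c(rep(sep, p %/% 2), rep(0, p - p %/% 2)),
                     rep(-sep, p))
    m <- do.call(rbind, lapply(1:3, function(i) {
      matrix(rnorm(n_per * p, mean = 0, sd = 1), n_per, p) +
        matrix(centers[i, ], n_per, p, byrow = TRUE)
    }))
    list(m = m, truth = rep(0:2, each = n_per))
  })
}

# Exhaustive minimum-WCSS partition search over all k^n assignments with no
# empty cluster. Independent oracle for small k-means instances.
brute_force_wcss <- function(m, k) {
  n <- nrow(m)
  best <- Inf
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    if (length(unique(lab)) < k) next
    wcss <- 0
    for (c in unique(lab)) {
      pts <- m[lab == c, , drop = FALSE]
      ctr <- colMeans(pts)
      wcss <- wcss + sum(sweep(pts, 2, ctr)^2)
    }
    if (wcss < best) best <- wcss
  }
  best
}

# Direct-formula validity indices via plain loops (independent of the
# package's vectorized implementation).
direct_indices <- function(m, lab0, q = 3) {
  lab <- lab0 + 1L
  n <- nrow(m); k <- max(lab)
  d <- function(i, j) sqrt(sum((m[i, ] - m[j, ])^2))
  D <- outer(seq_len(n), seq_len(n), Vectorize(d))

  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(lab == lab[i]), i)
    if (!length(own)) { sil[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(sapply(setdiff(seq_len(k), lab[i]),
                    function(c) mean(D[i, lab == c])))
    sil[i] <- (b - a) / max(a, b)
  }

  diam <- sapply(seq_len(k), function(c) {
    pts <- which(lab == c)
    if (length(pts) < 2) 0 else max(D[pts, pts])
  })
  between <- min(apply(utils::combn(k, 2), 2, function(pr) {
    min(D[lab == pr[1], lab == pr[2]])
  }))
  dunn <- between / max(diam)

  cen <- t(sapply(seq_len(k), function(c) colMeans(m[lab == c, , drop = FALSE])))
  s <- sapply(seq_len(k), function(c) {
    mean(apply(m[lab == c, , drop = FALSE], 1,
               function(x) sqrt(sum((x - cen[c, ])^2))))
  })
  db <- mean(sapply(seq_len(k), function(i) {
    max(sapply(setdiff(seq_len(k), i), function(j) {
      (s[i] + s[j]) / sqrt(sum((cen[i, ] - cen[j, ])^2))
    }))
  }))

  ut <- D[upper.tri(D)]
  within <- D[outer(lab, lab, "==") & upper.tri(D)]
  srt <- sort(ut)
  s_min <- sum(srt[seq_along(within)])
  s_max <- sum(rev(srt)[seq_along(within)])
  cidx <- (sum(within) - s_min) / (s_max - s_min)

  qq <- min(q, n - 1)
  iso <- mean(sapply(seq_len(n), function(i) {
    nb <- setdiff(order(D[i, ]), i)[seq_len(qq)]
    mean(lab[nb] == lab[i])
  }))

  c(silhouette = mean(sil), dunn = dunn, davies_bouldin = db,
    c_index = cidx, isolation = iso)
}
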