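#' Pearson chi-square test on a cluster-by-trait contingency table
#'
#' Tests whether the frequency of a (binary or multi-level) trait differs
#' across clusters. Subjects with undefined diagnosis for the trait must be
#' excluded before tabulation. No continuity correction is applied.
#'
#' @param table integer matrix or table of counts (rows = clusters/groups,
#'   columns = trait levels).
#' @return A one-row tibble: `test`, `statistic`, `df`, `p`, plus
#'   `low_expected` flagging tables where more than 20% of cells have expected
#'   counts below 5.
#' @export
#' @examples
#' chisq_association(rbind(c(10, 20), c(20, 10)))
chisq_association <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    abort("test error: contingency table needs >= 2 rows and >= 2 columns")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("test error: zero margin in contingency table")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  low <- mean(expected < 5) > 0.2
  if (low) warn("more than 20% of cells have expected count < 5")
  ts <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble::tibble(test = "pearson_chisq",
                 statistic = unname(ts$statistic),
                 df = unname(ts$parameter),
                 p = unname(ts$p.value),
                 low_expected = low)
}

#' Compare one cluster's trait composition against the whole study sample
#'
#' Goodness-of-fit chi-square of the cluster's trait-level counts against
#' expected proportions taken from the full sample.
#'
#' @param cluster_counts named integer vector of trait-level counts within the
#'   cluster.
#' @param population_counts named integer vector of the same levels in the
#'   entire sample (the cluster must be a subset).
#' @return A one-row tibble as in [chisq_association()].
#' @export
cluster_vs_population <- function(cluster_counts, population_counts) {
  if (length(cluster_counts) != length(population_counts)) {
    abort("input error: level sets differ")
  }
  if (sum(cluster_counts) > sum(population_counts)) {
    abort("input error: cluster larger than population")
  }
  if (any(population_counts == 0)) {
    abort("test error: empty trait level in population")
  }
  p <- population_counts / sum(population_counts)
  ts <- suppressWarnings(chisq.test(cluster_counts, p = p))
  tibble::tibble(test = "goodness_of_fit_chisq",
                 statistic = unname(ts$statistic),
                 df = unname(ts$parameter),
                 p = unname(ts$p.value),
                 low_expected = mean(sum(cluster_counts) * p < 5) > 0.2)
}

#' Kruskal-Wallis test of a numeric variable across clusters
#'
#' Rank-based test with tie correction for discrete numeric variables such as
#' age of asthma onset.
#'
#' @param values numeric vector, one value per subject (NAs dropped with their
#'   group labels).
#' @param groups cluster labels, same length.
#' @return A one-row tibble: `test`, `statistic` (H), `df`, `p`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2 || any(table(groups) < 1)) {
    abort("input error: need >= 2 non-empty groups")
  }
  if (length(unique(values)) == 1L) {
    return(tibble::tibble(test = "kruskal_wallis", statistic = 0,
                          df = nlevels(groups) - 1L, p = 1))
  }
  ts <- kruskal.test(values, groups)
  tibble::tibble(test = "kruskal_wallis",
                 statistic = unname(ts$statistic),
                 df = unname(ts$parameter),
                 p = unname(ts$p.value))
}

#' Tabulate and test every trait against a clustering
#'
#' For each trait, subjects with undefined diagnosis for that trait are
#' excluded (exclusion is per trait, not per subject), the cluster x status
#' contingency table is formed, and a Pearson chi-square test is run.
#' Numeric variables (e.g. `asthma_age_onset`) are tested with
#' Kruskal-Wallis instead. A Bonferroni-adjusted column is reported alongside
#' the raw p-values for transparency; inference in the source design is on the
#' raw values.
#'
#' @param subjects subject tibble.
#' @param assignments 0-based cluster labels named by `subject_id` (as in an
#'   `ige_kmeans` fit) or an `ige_kmeans` object.
#' @param traits character vector of categorical trait columns to test.
#' @param numeric_traits numeric columns to test with Kruskal-Wallis.
#' @return A tibble with one row per trait: `trait`, `test`, `statistic`,
#'   `df`, `p`, `p_bonferroni`, `n_used`.
#' @export
trait_association_table <- function(subjects, assignments,
                                    traits = c("asthma", "rhinitis", "eczema",
                                               "conjunctivitis", "sex"),
                                    numeric_traits = intersect(
                                      "asthma_age_onset", names(subjects))) {
  if (inherits(assignments, "ige_kmeans")) assignments <- assignments$assignments
  cl <- assignments[subjects$subject_id]
  if (anyNA(cl)) abort("input error: assignments missing for some subjects")
  rows <- purrr::map_dfr(intersect(traits, names(subjects)), function(tr) {
    st <- subjects[[tr]]
    keep <- st != "undefined" & !is.na(st)
    tab <- table(cluster = cl[keep], status = st[keep])
    res <- chisq_association(tab)
    tibble::tibble(trait = tr, test = res$test, statistic = res$statistic,
                   df = res$df, p = res$p, n_used = sum(keep))
  })
  nrows <- purrr::map_dfr(numeric_traits, function(tr) {
    v <- subjects[[tr]]
    keep <- !is.na(v)
    res <- kruskal_wallis(v[keep], cl[keep])
    tibble::tibble(trait = tr, test = res$test, statistic = res$statistic,
                   df = res$df, p = res$p, n_used = sum(keep))
  })
  out <- dplyr::bind_rows(rows, nrows)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out
}

#' Permutation test of family co-segregation in clusters
#'
#' Measures whether members of the same family land in the same cluster more
#' often than chance: the statistic is the mean over multi-member families of
#' the fraction of member pairs sharing a cluster, and its null distribution
#' is obtained by permuting subject-to-cluster labels.
#'
#' @param assignments 0-based cluster labels named by subject id, or an
#'   `ige_kmeans` object.
#' @param subjects subject tibble with `subject_id` and `family_id`.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation draw.
#' @return A one-row tibble: `test`, `statistic` (observed mean pair-sharing),
#'   `null_mean`, `p` (upper-tail, with the +1 correction).
#' @export
family_cosegregation <- function(assignments, subjects, n_perm = 10000L,
                                 seed = 1L) {
  if (inherits(assignments, "ige_kmeans")) assignments <- assignments$assignments
  cl <- assignments[subjects$subject_id]
  fam <- subjects$family_id
  sizes <- table(fam)
  multi <- names(sizes)[sizes >= 2]
  if (length(multi) < 2) abort("test error: need >= 2 families with >= 2 members")
  idx_by_fam <- split(seq_along(fam), fam)[multi]
  # Precompute all within-family member pairs once; the statistic is then a
  # single vectorised comparison per permutation.
  pair_i <- integer(0); pair_j <- integer(0); pair_fam <- integer(0)
  for (f in seq_along(idx_by_fam)) {
    ix <- idx_by_fam[[f]]
    pr <- utils::combn(ix, 2)
    pair_i <- c(pair_i, pr[1, ]); pair_j <- c(pair_j, pr[2, ])
    pair_fam <- c(pair_fam, rep(f, ncol(pr)))
  }
  pairs_per_fam <- tabulate(pair_fam)
  share_stat <- function(labels) {
    eq <- labels[pair_i] == labels[pair_j]
    mean(rowsum(as.numeric(eq), pair_fam) / pairs_per_fam)
  }
  obs <- share_stat(cl)
  withr::local_seed(seed)
  null <- vapply(seq_len(n_perm), function(b) share_stat(sample(cl)), numeric(1))
  tibble::tibble(test = "family_cosegregation_permutation",
                 statistic = obs, null_mean = mean(null),
                 p = (sum(null >= obs) + 1) / (n_perm + 1))
}

#' Build an age- and sex-matched case-control subset of parents
#'
#' Greedy nearest-age matching within sex: each asthmatic parent (case) is
#' paired with the unused non-asthmatic parent (control) of the same sex whose
#' age is closest, until `n_pairs` pairs are formed.
#'
#' @param subjects subject tibble.
#' @param n_pairs number of case-control pairs requested.
#' @return A tibble of `2 * n_pairs` subjects with columns `pair_id` and
#'   `case_status` added.
#' @export
matched_case_control <- function(subjects, n_pairs) {
  parents <- subjects[subjects$role == "parent", ]
  cases <- parents[parents$asthma == "affected", ]
  controls <- parents[parents$asthma == "not_affected", ]
  if (nrow(cases) < n_pairs) {
    abort(sprintf("matching error: only %d asthmatic parents for %d pairs",
                  nrow(cases), n_pairs))
  }
  cases <- dplyr::arrange(cases, .data$age)[seq_len(n_pairs), ]
  used <- logical(nrow(controls))
  pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    cand <- which(!used & controls$sex == cases$sex[i])
    if (!length(cand)) {
      abort(sprintf(
        "matching error: no unused %s control left for case %s (deficit at pair %d)",
        cases$sex[i], cases$subject_id[i], i))
    }
    j <- cand[which.min(abs(controls$age[cand] - cases$age[i]))]
    used[j] <- TRUE
    pairs[[i]] <- dplyr::bind_rows(
      dplyr::mutate(cases[i, ], pair_id = i, case_status = "case"),
      dplyr::mutate(controls[j, ], pair_id = i, case_status = "control"))
  }
  dplyr::bind_rows(pairs)
}
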