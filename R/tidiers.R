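#' Tidy a k-means profile clustering
#'
#' @param x an `ige_kmeans` fit.
#' @param ... unused.
#' @return Tibble with `subject_id` (when available) and `cluster` (0-based).
#' @export
tidy.ige_kmeans <- function(x, ...) {
  tibble::tibble(
    subject_id = names(x$assignments) %||% as.character(seq_along(x$assignments)),
    cluster = as.integer(x$assignments))
}

#' @rdname tidy.ige_kmeans
#' @export
glance.ige_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$assignments), wcss = x$wcss,
                 converged = x$converged, iterations = x$iterations_used,
                 n_reseeds = x$n_reseeds)
}

#' Tidy a GEE fit into a coefficient table
#'
#' One row per model term with the robust-SE-based reporting columns: Wald
#' chi-square on 1 df, p, odds ratio and 95% CI (exp of coefficient +/- 1.96
#' robust SE). For a probit fit the exponentiated columns are omitted.
#'
#' @param x an `ige_gee` fit.
#' @param ... unused.
#' @export
tidy.ige_gee <- function(x, ...) {
  out <- wald_or_ci(unname(x$coefficients), unname(x$robust_se))
  out <- tibble::add_column(out, term = names(x$coefficients), .before = 1)
  if (x$link != "logit") out <- out[setdiff(names(out), c("or", "ci_low", "ci_high"))]
  out
}

#' @rdname tidy.ige_gee
#' @export
glance.ige_gee <- function(x, ...) {
  tibble::tibble(n = x$n, n_clusters = x$n_clusters, alpha = x$alpha,
                 phi = x$phi, link = x$link, iterations = x$iterations,
                 converged = x$converged, separated = x$separated %||% FALSE)
}

#' Tidy the validity-index report of a cluster-count selection
#'
#' @param x an `ige_kselect` object.
#' @param ... unused.
#' @export
tidy.ige_kselect <- function(x, ...) x$report

#' @rdname tidy.ige_kselect
#' @export
glance.ige_kselect <- function(x, ...) {
  tibble::tibble(chosen_k = x$chosen_k,
                 n_candidates = nrow(x$report),
                 max_votes = max(x$votes))
}

#' Tidy a repeated NRBF evaluation
#'
#' @param x an `ige_rbf_eval` object.
#' @param ... unused.
#' @return The per-repetition holdout metric tibble.
#' @export
tidy.ige_rbf_eval <- function(x, ...) x$per_rep

#' @rdname tidy.ige_rbf_eval
#' @export
glance.ige_rbf_eval <- function(x, ...) {
  s <- x$summary
  tibble::tibble(mean_sensitivity = s$mean[s$metric == "sensitivity"],
                 mean_specificity = s$mean[s$metric == "specificity"],
                 mean_accuracy = s$mean[s$metric == "accuracy"],
                 sd_accuracy = s$sd[s$metric == "accuracy"],
                 auc = x$auc,
                 repetitions = nrow(x$per_rep))
}
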