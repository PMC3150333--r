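#' Run the reactivity-profile analysis pipeline end to end
#'
#' Chains the analysis stages on a cohort: encode class scores, cluster the
#' full-panel profiles, test cluster-trait associations, filter
#' asthma-relevant allergens by Mann-Whitney, re-cluster on the filtered panel
#' and re-test, then (optionally) train and evaluate the NRBF classifier and
#' run the family-aware GEE screen with forward selection. Subjects with
#' undefined asthma diagnosis are excluded before filtering, classification
#' and GEE (their counts are logged in the manifest). Every artifact is
#' written as TSV/JSON under `out_dir` together with a manifest (inputs, seed,
#' package version, per-stage timings), and the whole run is reproducible for
#' a fixed seed.
#'
#' @param cohort list with `subjects` and `reactivity` (IU/ml or class-score
#'   unit), e.g. from [generate_cohort()] or the readers in [read_phenotypes()].
#' @param out_dir output directory (created if needed); `NULL` writes nothing.
#' @param k number of clusters for both clustering passes.
#' @param alpha Mann-Whitney retention threshold.
#' @param clustering a [clustering_config()] (its `k_candidates` is only used
#'   when `choose_k = TRUE`).
#' @param choose_k run the five-index ensemble ([select_k()]) to choose k
#'   instead of the fixed `k`.
#' @param protocol [training_protocol()] for the NRBF stage.
#' @param gee a [gee_config()].
#' @param run_rbf,run_gee stage toggles.
#' @param seed master seed propagated to every stochastic stage.
#' @return A list of class `ige_pipeline` with elements `class_scores`,
#'   `clustering_all`, `association_all`, `filter`, `clustering_filtered`,
#'   `association_filtered`, `rbf` (or NULL), `gee_screen`/`gee_model` (or
#'   NULL), `manifest`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, k = 3L, alpha = 0.05,
                         clustering = clustering_config(),
                         choose_k = FALSE,
                         protocol = training_protocol(),
                         gee = gee_config(),
                         run_rbf = TRUE, run_gee = TRUE, seed = 1L) {
  if (is.null(cohort$subjects) || is.null(cohort$reactivity)) {
    abort("config error: cohort must provide subjects and reactivity")
  }
  subjects <- cohort$subjects
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("igeprofiler")),
                   n_subjects = nrow(subjects),
                   stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  scores <- t_stage("quantify", {
    if (identical(reactivity_unit(cohort$reactivity), "class_score")) {
      cohort$reactivity
    } else {
      encode_class_matrix(cohort$reactivity)
    }
  })

  cl_cfg <- clustering
  cl_cfg$seed <- seed
  clustering_all <- t_stage("cluster_all", {
    if (choose_k) {
      sel <- select_k(scores, cl_cfg)
      sel$results[[as.character(sel$chosen_k)]]
    } else {
      profile_kmeans(scores, k, cl_cfg)
    }
  })
  association_all <- t_stage("associate_all",
                             trait_association_table(subjects, clustering_all))

  defined <- subjects$asthma != "undefined"
  manifest$excluded_undefined_asthma <- sum(!defined)
  message(sprintf("excluding %d subject(s) with undefined asthma diagnosis",
                  sum(!defined)))
  sub_def <- subjects[defined, ]
  scores_def <- scores[scores$subject_id %in% sub_def$subject_id, ]
  status <- sub_def$asthma[match(scores_def$subject_id, sub_def$subject_id)]

  filter <- t_stage("filter", filter_allergens(scores_def, status, alpha))
  panel <- retained_allergens(filter)
  if (length(panel) < 2) abort("stage 'filter' failed: fewer than 2 allergens retained")
  scores_filt <- scores_def[c("subject_id", panel)]

  cl_cfg2 <- clustering
  cl_cfg2$seed <- seed + 1L
  clustering_filtered <- t_stage("cluster_filtered",
                                 profile_kmeans(scores_filt, k, cl_cfg2))
  association_filtered <- t_stage("associate_filtered",
                                  trait_association_table(sub_def, clustering_filtered))

  rbf <- NULL
  if (run_rbf) {
    proto <- protocol
    proto$seed <- seed + 2L
    rbf <- t_stage("rbf", repeated_evaluation(
      scores_filt, status == "affected", proto))
  }

  gee_screen <- NULL; gee_model <- NULL
  if (run_gee) {
    covs <- tibble::tibble(age = sub_def$age, sex = sub_def$sex)
    gee_screen <- t_stage("gee_screen", gee_univariate_screen(
      scores_def, status, sub_def$family_id, covariates = covs, alpha = alpha,
      config = gee))
    cand <- gee_screen$allergen_id[gee_screen$retained]
    gee_model <- t_stage("gee_forward", gee_forward_select(
      scores_def, cand, status, sub_def$family_id, covs, config = gee))
    manifest$gee_mw_overlap <- list(
      gee_retained = length(cand),
      mw_retained = length(panel),
      shared = length(intersect(cand, panel)),
      jaccard = length(intersect(cand, panel)) /
        max(1L, length(union(cand, panel))))
  }

  out <- structure(list(class_scores = scores,
                        clustering_all = clustering_all,
                        association_all = association_all,
                        filter = filter,
                        clustering_filtered = clustering_filtered,
                        association_filtered = association_filtered,
                        rbf = rbf,
                        gee_screen = gee_screen, gee_model = gee_model,
                        manifest = manifest),
                   class = "ige_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, subjects, out_dir)
  out
}

write_pipeline <- function(res, subjects, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_reactivity_matrix(res$class_scores, p("class_scores.tsv"))
  readr::write_tsv(tidy(res$clustering_all), p("clusters_all.tsv"), progress = FALSE)
  readr::write_tsv(res$association_all, p("association_all.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(res$filter), p("allergen_filter.tsv"),
                   progress = FALSE)
  writeLines(retained_allergens(res$filter), p("retained_panel.txt"))
  readr::write_tsv(tidy(res$clustering_filtered), p("clusters_filtered.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$association_filtered, p("association_filtered.tsv"),
                   progress = FALSE)
  if (!is.null(res$rbf)) {
    readr::write_tsv(res$rbf$per_rep, p("rbf_per_repetition.tsv"), progress = FALSE)
    readr::write_tsv(res$rbf$roc, p("rbf_roc.tsv"), progress = FALSE)
    net <- res$rbf$last_net
    jsonlite::write_json(list(centers = net$centers, widths = net$widths,
                              weights = net$weights, h = net$h),
                         p("rbf_model.json"), digits = NA)
  }
  if (!is.null(res$gee_model)) {
    readr::write_tsv(res$gee_screen, p("gee_univariate.tsv"), progress = FALSE)
    readr::write_tsv(tidy(res$gee_model$fit), p("gee_final_model.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' @export
print.ige_pipeline <- function(x, ...) {
  cat("IgE reactivity-profile pipeline\n")
  cat(sprintf("  clustering (all allergens): k = %d, asthma chisq p = %.3g\n",
              x$clustering_all$k,
              x$association_all$p[x$association_all$trait == "asthma"]))
  cat(sprintf("  filter: %d allergens retained (alpha = %g)\n",
              attr(x$filter, "n_retained"), attr(x$filter, "alpha")))
  cat(sprintf("  clustering (filtered): asthma chisq p = %.3g\n",
              x$association_filtered$p[x$association_filtered$trait == "asthma"]))
  if (!is.null(x$rbf)) {
    acc <- x$rbf$summary
    cat(sprintf("  NRBF holdout accuracy: %.3f (SD %.3f)\n",
                acc$mean[acc$metric == "accuracy"],
                acc$sd[acc$metric == "accuracy"]))
  }
  if (!is.null(x$gee_model)) {
    cat(sprintf("  GEE forward selection: %d allergen(s) entered\n",
                length(x$gee_model$selected)))
  }
  invisible(x)
}
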