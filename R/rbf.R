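#' Repeated stratified split protocol for classifier evaluation
#'
#' @param train,test,holdout split fractions (must sum to 1). The training
#'   split fits the network, the test split selects the hidden-unit count, and
#'   the holdout split is reserved for performance estimation only.
#' @param repetitions number of independent repetitions, each with a fresh
#'   split and untrained network.
#' @param h_range candidate hidden-unit counts.
#' @param seed master seed.
#' @export
training_protocol <- function(train = 0.60, test = 0.10, holdout = 0.30,
                              repetitions = 10L, h_range = 2:10, seed = 1L) {
  if (abs(train + test + holdout - 1) > 1e-8) abort("split fractions must sum to 1")
  if (repetitions < 1) abort("repetitions must be >= 1")
  structure(list(train = train, test = test, holdout = holdout,
                 repetitions = as.integer(repetitions),
                 h_range = as.integer(h_range), seed = as.integer(seed)),
            class = "training_protocol")
}

#' Stratified train/test/holdout split
#'
#' Splits subjects into the protocol's three sets while preserving the class
#' proportions of the binary label in each set (largest-remainder rounding per
#' class, so each split's class ratio is within a couple of subjects of the
#' global ratio). Deterministic for a fixed seed.
#'
#' @param labels binary label per subject.
#' @param protocol a [training_protocol()].
#' @param seed integer seed (defaults to the protocol's).
#' @return List with integer index vectors `train`, `test`, `holdout`
#'   (disjoint, exhaustive).
#' @export
stratified_split <- function(labels, protocol = training_protocol(),
                             seed = protocol$seed) {
  labels <- as.logical(labels)
  if (!any(labels) || !any(!labels)) abort("split error: a class is absent")
  withr::local_seed(seed)
  lr_round <- function(x, total) {
    f <- floor(x)
    short <- total - sum(f)
    if (short > 0) {
      add <- order(x - f, decreasing = TRUE)[seq_len(short)]
      f[add] <- f[add] + 1
    }
    as.integer(f)
  }
  fr <- c(train = protocol$train, test = protocol$test,
          holdout = protocol$holdout)
  pool <- list(sample(which(labels)), sample(which(!labels)))
  n_class <- lengths(pool)
  n <- sum(n_class)
  sizes <- lr_round(n * fr, n)  # overall split totals
  remaining <- n_class
  out <- list(train = integer(0), test = integer(0), holdout = integer(0))
  for (s in 1:3) {
    if (s < 3) {
      want <- lr_round(sizes[s] * n_class / n, sizes[s])
      want <- pmin(want, remaining)
      short <- sizes[s] - sum(want)
      while (short > 0) {  # clamped classes push their share to the others
        j <- which.max(remaining - want)
        want[j] <- want[j] + 1L
        short <- short - 1L
      }
    } else {
      want <- remaining
    }
    for (cls in 1:2) {
      done <- n_class[cls] - remaining[cls]
      if (want[cls] > 0) {
        out[[s]] <- c(out[[s]], pool[[cls]][done + seq_len(want[cls])])
      }
    }
    remaining <- remaining - want
  }
  lapply(out, sort)
}

# Normalized Gaussian hidden-layer activations (rows sum to 1).
nrbf_activations <- function(m, centers, widths) {
  d2 <- outer(rowSums(m^2), rowSums(centers^2), "+") - 2 * tcrossprod(m, centers)
  d2[d2 < 0] <- 0
  # log-sum-exp normalization for numerical safety far from all centers
  loga <- -d2 / (2 * rep(widths^2, each = nrow(m)))
  loga <- loga - apply(loga, 1, max)
  a <- exp(loga)
  a / rowSums(a)
}

fit_nrbf <- function(features, labels, h, seed) {
  m <- as.matrix(features)
  if (h > nrow(m)) abort("training error: more hidden units than training subjects")
  km <- profile_kmeans(m, h, clustering_config(k_candidates = 2:3,
                                               n_restarts = 5L, seed = seed))
  centers <- km$centroids
  if (h == 1) {
    widths <- max(sd(m), 1e-6)
  } else {
    dc <- as.matrix(stats::dist(centers))
    diag(dc) <- Inf
    widths <- pmax(apply(dc, 1, min), 1e-6)
  }
  H <- nrbf_activations(m, centers, widths)
  Y <- cbind(class0 = as.numeric(!labels), class1 = as.numeric(labels))
  W <- tryCatch(qr.solve(H, Y), error = function(e) {
    solve(crossprod(H) + diag(1e-6, ncol(H)), crossprod(H, Y))
  })
  structure(list(centers = centers, widths = widths, weights = W,
                 h = as.integer(h)),
            class = "ige_rbf")
}

#' Train a normalized radial-basis-function asthma classifier
#'
#' Two-stage NRBF construction: hidden-unit centers are placed by k-means on
#' the training features, each unit's width is the distance to its nearest
#' other center (floored at a small epsilon), hidden activations are Gaussian
#' kernels normalized to sum to one per input, and the output layer is solved
#' in closed form by least squares on one-hot labels. The hidden-unit count is
#' selected from `protocol$h_range` by accuracy on the test split; the holdout
#' split never influences training or selection.
#'
#' @param features numeric matrix or reactivity table of class-score profiles
#'   (rows = subjects over the filtered allergen panel).
#' @param labels binary asthma labels.
#' @param protocol a [training_protocol()].
#' @param split optional precomputed [stratified_split()]; defaults to a fresh
#'   split under the protocol seed.
#' @param seed integer seed.
#' @return An object of class `ige_rbf` with elements `centers`, `widths`,
#'   `weights`, `h`, plus `split` and `h_selection` metadata.
#' @export
train_rbf <- function(features, labels, protocol = training_protocol(),
                      split = NULL, seed = protocol$seed) {
  m <- as_profile_matrix(features)
  labels <- as.logical(labels)
  if (is.null(split)) split <- stratified_split(labels, protocol, seed)
  tr <- split$train; te <- split$test
  n_distinct_tr <- nrow(unique(m[tr, , drop = FALSE]))
  h_cand <- protocol$h_range[protocol$h_range <= min(length(tr), n_distinct_tr)]
  if (!length(h_cand)) abort("training error: h_range exceeds training size")
  acc <- vapply(h_cand, function(h) {
    net <- fit_nrbf(m[tr, , drop = FALSE], labels[tr], h, seed)
    if (length(te)) {
      pred <- predict(net, m[te, , drop = FALSE])$label
      mean(pred == labels[te])
    } else {
      pred <- predict(net, m[tr, , drop = FALSE])$label
      mean(pred == labels[tr])
    }
  }, numeric(1))
  h_best <- h_cand[which.max(acc)]
  net <- fit_nrbf(m[tr, , drop = FALSE], labels[tr], h_best, seed)
  net$split <- split
  net$h_selection <- tibble::tibble(h = h_cand, test_accuracy = acc)
  net
}

#' Predict asthma pseudo-probabilities from an NRBF network
#'
#' Output-layer scores are passed through a softmax to yield per-class
#' pseudo-probabilities summing to one; the label is the argmax, with exact
#' ties broken deterministically to class 0 (non-asthmatic).
#'
#' @param object an `ige_rbf` network.
#' @param features matrix of profiles with the network's input width.
#' @param ... unused.
#' @return Tibble with `p_class0`, `p_class1`, `label` (logical: asthmatic).
#' @export
predict.ige_rbf <- function(object, features, ...) {
  m <- as_profile_matrix(features)
  if (ncol(m) != ncol(object$centers)) {
    abort("input error: feature width does not match the network")
  }
  H <- nrbf_activations(m, object$centers, object$widths)
  scores <- H %*% object$weights
  e <- exp(scores - apply(scores, 1, max))
  probs <- e / rowSums(e)
  tibble::tibble(p_class0 = probs[, 1], p_class1 = probs[, 2],
                 label = probs[, 2] > probs[, 1])
}

#' ROC curve and AUC from classifier scores
#'
#' Threshold sweep over the unique scores; the area under the curve is
#' computed by the trapezoid rule and equals the Mann-Whitney statistic
#' U / (n1 * n2).
#'
#' @param scores class-1 pseudo-probabilities (or any monotone score).
#' @param labels binary truth.
#' @return List with `points` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
#' @examples
#' roc_curve(c(.9, .8, .3, .2), c(TRUE, TRUE, FALSE, FALSE))$auc # 1
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || !any(!labels)) abort("both classes required for a ROC curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels); n0 <- sum(!labels)
  pts <- purrr::map_dfr(thr, function(t) {
    tibble::tibble(threshold = t,
                   fpr = sum(scores[!labels] >= t) / n0,
                   tpr = sum(scores[labels] >= t) / n1)
  })
  pts <- dplyr::bind_rows(tibble::tibble(threshold = Inf, fpr = 0, tpr = 0),
                          pts,
                          tibble::tibble(threshold = -Inf, fpr = 1, tpr = 1))
  pts <- dplyr::distinct(pts, .data$fpr, .data$tpr, .keep_all = TRUE)
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  list(points = pts, auc = auc)
}

#' Repeated randomized-split evaluation of the NRBF classifier
#'
#' Runs the protocol's repetitions, each on a fresh stratified split and a
#' newly trained network, and summarizes holdout sensitivity, specificity and
#' accuracy as means and SDs over repetitions. The ROC curve is computed on
#' the combined training and testing samples of the final repetition, and each
#' repetition's holdout agreement with the true status is tested by Pearson
#' chi-square.
#'
#' @inheritParams train_rbf
#' @return An object of class `ige_rbf_eval`: `per_rep` tibble (sensitivity,
#'   specificity, accuracy, chi-square p per repetition), `summary` tibble of
#'   means/SDs, `roc` points tibble, `auc`, and `last_net`.
#' @export
repeated_evaluation <- function(features, labels, protocol = training_protocol()) {
  m <- as_profile_matrix(features)
  labels <- as.logical(labels)
  reps <- vector("list", protocol$repetitions)
  last <- NULL
  for (r in seq_len(protocol$repetitions)) {
    seed_r <- protocol$seed + 1000L * r
    split <- stratified_split(labels, protocol, seed_r)
    res <- tryCatch({
      net <- train_rbf(m, labels, protocol, split = split, seed = seed_r)
      ho <- split$holdout
      pred <- predict(net, m[ho, , drop = FALSE])
      conf <- table(predicted = factor(pred$label, c(FALSE, TRUE)),
                    truth = factor(labels[ho], c(FALSE, TRUE)))
      chi_p <- tryCatch(suppressWarnings(chisq_association(conf)$p),
                        error = function(e) NA_real_)
      list(net = net, split = split, row = tibble::tibble(
        repetition = r,
        sensitivity = conf["TRUE", "TRUE"] / sum(conf[, "TRUE"]),
        specificity = conf["FALSE", "FALSE"] / sum(conf[, "FALSE"]),
        accuracy = sum(diag(conf)) / sum(conf),
        h = net$h, chisq_p = chi_p, failed = FALSE))
    }, error = function(e) {
      list(net = NULL, split = NULL, row = tibble::tibble(
        repetition = r, sensitivity = NA_real_,
        specificity = NA_real_, accuracy = NA_real_,
        h = NA_integer_, chisq_p = NA_real_, failed = TRUE))
    })
    if (!is.null(res$net)) last <- list(net = res$net, split = res$split)
    reps[[r]] <- res$row
  }
  per_rep <- dplyr::bind_rows(reps)
  if (all(per_rep$failed)) abort("all repetitions failed")
  ok <- !per_rep$failed
  summary <- tibble::tibble(
    metric = c("sensitivity", "specificity", "accuracy"),
    mean = c(mean(per_rep$sensitivity[ok]), mean(per_rep$specificity[ok]),
             mean(per_rep$accuracy[ok])),
    sd = c(sd(per_rep$sensitivity[ok]), sd(per_rep$specificity[ok]),
           sd(per_rep$accuracy[ok])))
  tt <- c(last$split$train, last$split$test)
  roc <- roc_curve(predict(last$net, m[tt, , drop = FALSE])$p_class1,
                   labels[tt])
  structure(list(per_rep = per_rep, summary = summary,
                 roc = roc$points, auc = roc$auc, last_net = last$net),
            class = "ige_rbf_eval")
}

#' @export
print.ige_rbf_eval <- function(x, ...) {
  cat(sprintf("NRBF repeated evaluation (%d repetitions), holdout metrics:\n",
              nrow(x$per_rep)))
  print(x$summary)
  cat(sprintf("AUC on combined train+test (last repetition): %.3f\n", x$auc))
  invisible(x)
}
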