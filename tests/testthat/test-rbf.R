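test_that("stratified splits preserve class proportions and the rounding rule", {
  labels <- rep(c(TRUE, FALSE), c(485, 342))
  sp <- stratified_split(labels, training_protocol(seed = 2))
  expect_equal(length(sp$train), 496)
  expect_equal(length(sp$test), 83)
  expect_equal(length(sp$holdout), 248)
  # disjoint and exhaustive
  expect_identical(sort(c(sp$train, sp$test, sp$holdout)), seq_along(labels))
  # class proportions within 2 subjects of the global rate in every split
  glob <- mean(labels)
  for (part in sp) {
    expect_lte(abs(sum(labels[part]) - glob * length(part)), 2)
  }
  # seed determinism
  expect_identical(sp, stratified_split(labels, training_protocol(seed = 2)))
  # 10 subjects at 0.6/0.1/0.3 split 6/1/3
  sp10 <- stratified_split(rep(c(TRUE, FALSE), 5), training_protocol(seed = 1))
  expect_equal(lengths(sp10), c(train = 6L, test = 1L, holdout = 3L))
  expect_error(stratified_split(rep(TRUE, 5), training_protocol()), "absent")
})

test_that("normalized activations form a probability simplex", {
  withr::with_seed(7, {
    m <- matrix(rnorm(60), 20, 3)
    centers <- matrix(rnorm(12), 4, 3)
  })
  H <- igeprofiler:::nrbf_activations(m, centers, rep(1.5, 4))
  expect_equal(rowSums(H), rep(1, 20), tolerance = 1e-12)
  expect_true(all(H >= 0))
  # far from every center the normalization must still hold
  H_far <- igeprofiler:::nrbf_activations(m + 100, centers, rep(0.5, 4))
  expect_equal(rowSums(H_far), rep(1, 20), tolerance = 1e-12)
})

test_that("a separable two-point problem is fit perfectly with two units", {
  m <- rbind(matrix(0, 10, 4), matrix(3, 10, 4))
  labels <- rep(c(FALSE, TRUE), each = 10)
  net <- igeprofiler:::fit_nrbf(m, labels, h = 2, seed = 1)
  pred <- predict(net, m)
  expect_identical(pred$label, labels)
  expect_equal(pred$p_class0 + pred$p_class1, rep(1, 20), tolerance = 1e-12)
})

test_that("prediction breaks exact ties toward the non-asthmatic class", {
  net <- structure(list(centers = matrix(0, 2, 3), widths = c(1, 1),
                        weights = matrix(0.5, 2, 2), h = 2L),
                   class = "ige_rbf")
  pred <- predict(net, matrix(rnorm(9), 3, 3))
  expect_true(all(!pred$label))
  expect_error(predict(net, matrix(0, 1, 5)), "feature width")
})

test_that("ROC handles the degenerate extremes and equals the rank statistic", {
  expect_equal(roc_curve(c(.9, .8, .3, .2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_curve(rep(0.5, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  # trapezoid AUC == U / (n1 n2), including ties
  scores <- c(0.1, 0.4, 0.4, 0.6, 0.8, 0.2)
  labels <- c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)
  auc <- roc_curve(scores, labels)$auc
  u <- mann_whitney_u(scores[labels], scores[!labels])$u
  expect_equal(auc, u / (3 * 3), tolerance = 1e-12)
  expect_error(roc_curve(1:3, rep(TRUE, 3)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transformations", {
  withr::with_seed(13, {
    scores <- runif(40)
    labels <- rbinom(40, 1, plogis(3 * scores - 1.5)) == 1
  })
  a1 <- roc_curve(scores, labels)$auc
  a2 <- roc_curve(plogis(5 * scores - 2), labels)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(17, {
    scores <- round(runif(60), 2)
    labels <- rbinom(60, 1, plogis(4 * scores - 2)) == 1
  })
  ours <- roc_curve(scores, labels)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                         quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("the holdout split never influences the fitted network", {
  co <- generate_cohort(small_spec(6, n_families = 80))
  keep <- co$subjects$asthma != "undefined"
  m <- reactivity_values(encode_class_matrix(co$reactivity))[keep, ]
  labels <- co$subjects$asthma[keep] == "affected"
  proto <- training_protocol(seed = 4, h_range = 2:5)
  sp <- stratified_split(labels, proto)
  net1 <- train_rbf(m, labels, proto, split = sp, seed = 4)
  m2 <- m
  m2[sp$holdout, ] <- 5 - m2[sp$holdout, ]  # corrupt holdout features
  net2 <- train_rbf(m2, labels, proto, split = sp, seed = 4)
  expect_identical(net1$centers, net2$centers)
  expect_identical(net1$weights, net2$weights)
  expect_identical(net1$h, net2$h)
})

test_that("null labels keep holdout accuracy near the majority rate", {
  co <- generate_cohort(small_spec(8, n_families = 100, signature = NULL))
  keep <- co$subjects$asthma != "undefined"
  m <- reactivity_values(encode_class_matrix(co$reactivity))[keep, ]
  n <- nrow(m)
  labels <- withr::with_seed(55, rbinom(n, 1, 0.6) == 1)  # independent of features
  ev <- repeated_evaluation(m, labels, training_protocol(repetitions = 10,
                                                         seed = 5))
  p0 <- max(mean(labels), 1 - mean(labels))
  n_ho <- round(0.3 * n)
  se <- sqrt(p0 * (1 - p0) / n_ho)
  acc <- ev$summary$mean[ev$summary$metric == "accuracy"]
  expect_lt(abs(acc - p0), 3 * se)
})

test_that("planted signatures are classified accurately on the holdout", {
  spec <- cohort_spec(n_families = 260,
                      signature = default_signature(20, c(1.5, 1.5)), seed = 11)
  co <- generate_cohort(spec)
  keep <- co$subjects$asthma != "undefined"
  cs <- encode_class_matrix(co$reactivity)[keep, ]
  labels <- co$subjects$asthma[keep] == "affected"
  feat <- cs[c("subject_id", co$signature$allergen_id)]
  ev <- repeated_evaluation(feat, labels, training_protocol(repetitions = 10,
                                                            seed = 3))
  expect_gte(sum(ev$per_rep$accuracy > 0.75, na.rm = TRUE), 8)
  expect_gt(ev$auc, 0.85)
  gl <- glance(ev)
  expect_equal(gl$repetitions, 10L)
  expect_true(all(ev$per_rep$sensitivity >= 0 & ev$per_rep$sensitivity <= 1))
})

test_that("repeated evaluation is deterministic for a fixed master seed", {
  co <- generate_cohort(small_spec(9, n_families = 50))
  keep <- co$subjects$asthma != "undefined"
  m <- reactivity_values(encode_class_matrix(co$reactivity))[keep, ]
  labels <- co$subjects$asthma[keep] == "affected"
  proto <- training_protocol(repetitions = 3, seed = 12, h_range = 2:4)
  e1 <- repeated_evaluation(m, labels, proto)
  e2 <- repeated_evaluation(m, labels, proto)
  expect_identical(e1$per_rep, e2$per_rep)
  expect_identical(e1$auc, e2$auc)
})
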