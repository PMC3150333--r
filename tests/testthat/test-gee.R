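test_that("class-factor encoding merges 5 into 4 and flags constants", {
  enc <- encode_class_factor(c(0, 1, 5, 4, 2))
  expect_equal(dim(enc), c(5, 4))
  expect_equal(enc[3, ], c(score1 = 0, score2 = 0, score3 = 0, score4 = 1))
  expect_equal(enc[4, "score4"], c(score4 = 1))
  expect_equal(unname(enc[1, ]), rep(0, 4))  # reference level 0
  # every indicator of a constant score vector is constant (score2 all ones)
  const <- encode_class_factor(rep(2, 6))
  expect_setequal(attr(const, "constant_columns"),
                  c("score1", "score2", "score3", "score4"))
  # sparse-level merging folds a thin level into the one below
  merged <- encode_class_factor(c(rep(0, 20), rep(3, 12), rep(4, 3)),
                                min_count = 5)
  expect_equal(sum(merged[, "score3"]), 15)
  expect_equal(sum(merged[, "score4"]), 0)
  expect_error(encode_class_factor(c(1, 7)), "0-5")
})

test_that("GEE with singleton clusters reproduces ordinary logistic regression", {
  withr::with_seed(1, {
    n <- 300
    x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x1 - 0.5 * x2))
  })
  fit <- gee_fit(y, cbind(x1 = x1, x2 = x2), seq_len(n))
  ref <- glm(y ~ x1 + x2, family = binomial)
  expect_lt(max(abs(fit$coefficients - stats::coef(ref))), 1e-6)
  # probit link likewise
  fitp <- gee_fit(y, cbind(x1 = x1, x2 = x2), seq_len(n),
                  gee_config(link = "probit"))
  refp <- glm(y ~ x1 + x2, family = binomial("probit"),
              control = stats::glm.control(epsilon = 1e-12))
  expect_lt(max(abs(fitp$coefficients - stats::coef(refp))), 1e-6)
})

test_that("reporting identities hold and match published GEE arithmetic", {
  out <- wald_or_ci(c(1.705, 2.171, -2.207, 0), c(0.456, 0.513, 0.541, 1))
  expect_equal(out$or, exp(out$coefficient))
  expect_equal(out$ci_low, exp(out$coefficient - 1.96 * out$se))
  expect_equal(out$wald, (out$coefficient / out$se)^2)
  expect_equal(out$or[1], 5.503, tolerance = 0.005)
  expect_equal(out$ci_low[1], 2.25, tolerance = 0.005)
  expect_equal(out$wald[1], 13.967, tolerance = 0.005)
  expect_equal(out$or[2], 8.765, tolerance = 0.005)
  expect_equal(out$or[3], 0.110, tolerance = 0.005)
  expect_equal(out$or[4], 1)
  expect_equal(out$p[4], 1)
  expect_error(wald_or_ci(1, 0), "positive")
})

sim_exchangeable <- function(seed, G = 300, rho = 0.3,
                             beta = c(-0.5, 0.8, -0.6)) {
  # Gaussian-copula exchangeable binary data with exact marginal logit model
  withr::with_seed(seed, {
    m <- sample(1:3, G, replace = TRUE)
    fam <- rep(seq_len(G), m)
    n <- length(fam)
    x1 <- rnorm(n)
    x2 <- rbinom(n, 1, 0.5)
    p <- plogis(beta[1] + beta[2] * x1 + beta[3] * x2)
    z <- sqrt(rho) * rnorm(G)[fam] + sqrt(1 - rho) * rnorm(n)
    y <- as.numeric(z < qnorm(p))
  })
  list(y = y, X = cbind(x1 = x1, x2 = x2), fam = fam)
}

test_that("GEE recovers marginal coefficients on exchangeable family data", {
  beta <- c(-0.5, 0.8, -0.6)
  est <- t(vapply(1:60, function(s) {
    d <- sim_exchangeable(s)
    f <- gee_fit(d$y, d$X, d$fam)
    lo <- f$coefficients - 1.96 * f$robust_se
    hi <- f$coefficients + 1.96 * f$robust_se
    c(f$coefficients[c("x1", "x2")],
      cover = as.numeric(beta[2:3] >= lo[c("x1", "x2")] &
                           beta[2:3] <= hi[c("x1", "x2")]),
      alpha = f$alpha)
  }, numeric(5)))
  mc_se <- apply(est[, 1:2], 2, sd) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - beta[2]), 2 * mc_se[1])
  expect_lt(abs(mean(est[, 2]) - beta[3]), 2 * mc_se[2])
  coverage <- mean(est[, 3:4])
  expect_gte(coverage, 0.92)
  expect_lte(coverage, 0.97)
  expect_gt(mean(est[, 5]), 0)  # positive estimated working correlation
})

test_that("duplicating every cluster shrinks sandwich errors by ~1/sqrt(2)", {
  d <- sim_exchangeable(5, G = 200)
  f1 <- gee_fit(d$y, d$X, d$fam)
  f2 <- gee_fit(c(d$y, d$y), rbind(d$X, d$X),
                c(d$fam, d$fam + max(d$fam)))
  expect_equal(unname(f2$coefficients), unname(f1$coefficients),
               tolerance = 1e-3)
  ratio <- f2$robust_se / f1$robust_se
  expect_equal(unname(ratio), rep(1 / sqrt(2), 3), tolerance = 0.02)
})

test_that("estimates are invariant to subject order and cluster relabeling", {
  d <- sim_exchangeable(8, G = 100)
  f1 <- gee_fit(d$y, d$X, d$fam)
  perm <- withr::with_seed(2, sample(length(d$y)))
  relab <- max(d$fam) + 1 - d$fam  # reverse the family ids
  f2 <- gee_fit(d$y[perm], d$X[perm, ], relab[perm])
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-7)
  expect_equal(f2$robust_se, f1$robust_se, tolerance = 1e-7)
})

test_that("the univariate screen holds its size on null cohorts", {
  n_rej <- 0L; n_tests <- 0L
  for (s in 1:20) {
    co <- generate_cohort(null_iid_spec(700 + s, n_families = 300,
                                        panel_size = 20))
    keep <- co$subjects$asthma != "undefined"
    sub <- co$subjects[keep, ]
    cs <- encode_class_matrix(co$reactivity)[keep, ]
    covs <- tibble::tibble(age = sub$age, sex = sub$sex)
    scr <- suppressWarnings(gee_univariate_screen(cs, sub$asthma,
                                                  sub$family_id, covs))
    n_rej <- n_rej + sum(scr$retained)
    n_tests <- n_tests + sum(scr$converged)
  }
  band <- qbinom(c(0.025, 0.975), n_tests, 0.05)
  expect_gte(n_rej, band[1])
  expect_lte(n_rej, band[2])
})

test_that("the univariate screen recovers strong planted allergens", {
  frac <- vapply(1:5, function(s) {
    spec <- cohort_spec(n_families = 283, panel_size = 30,
                        signature = default_signature(8, c(1.5, 1.5)),
                        seed = 800 + s)
    co <- generate_cohort(spec)
    keep <- co$subjects$asthma != "undefined"
    sub <- co$subjects[keep, ]
    cs <- encode_class_matrix(co$reactivity)[keep, ]
    covs <- tibble::tibble(age = sub$age, sex = sub$sex)
    scr <- suppressWarnings(gee_univariate_screen(cs, sub$asthma,
                                                  sub$family_id, covs))
    mean(scr$retained[scr$allergen_id %in% co$signature$allergen_id])
  }, numeric(1))
  expect_gte(mean(frac), 0.8)
})

test_that("forward selection enters the planted allergen first", {
  hits <- vapply(1:10, function(s) {
    spec <- cohort_spec(n_families = 120, panel_size = 10,
                        signature = tibble::tibble(allergen = 4, effect = 2),
                        exposure_groups = 0, seed = 900 + s)
    co <- generate_cohort(spec)
    keep <- co$subjects$asthma != "undefined"
    sub <- co$subjects[keep, ]
    cs <- encode_class_matrix(co$reactivity)[keep, ]
    covs <- tibble::tibble(age = sub$age, sex = sub$sex)
    fw <- suppressWarnings(gee_forward_select(
      cs, allergen_ids(cs), sub$asthma, sub$family_id, covs))
    length(fw$selected) >= 1 && fw$selected[1] == co$signature$allergen_id
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("forward selection handles empty pools and collinear candidates", {
  d <- sim_exchangeable(3, G = 80)
  scores <- matrix(withr::with_seed(4, sample(0:3, length(d$y) * 3, TRUE)),
                   ncol = 3)
  # tie column 2 to the response so it enters (shift a random subset of cases
  # so every level keeps both classes), then duplicate it exactly
  shift <- d$y == 1 & withr::with_seed(6, rbinom(length(d$y), 1, 0.6)) == 1
  scores[shift, 2] <- pmin(scores[shift, 2] + 2, 4)
  scores[, 3] <- scores[, 2]  # perfect collinearity
  x <- reactivity_tbl(scores, unit = "class_score")
  covs <- tibble::tibble(age = withr::with_seed(5, runif(length(d$y), 20, 60)),
                         sex = rep(c("M", "F"), length.out = length(d$y)))
  fw <- suppressWarnings(gee_forward_select(x, allergen_ids(x), d$y == 1,
                                            d$fam, covs))
  expect_true("A2" %in% fw$selected)
  expect_true("A3" %in% fw$excluded_collinear)
  # empty candidate list: covariates-only model with a warning
  expect_warning(
    fw0 <- gee_forward_select(x, character(0), d$y == 1, d$fam, covs),
    "covariates-only")
  expect_length(fw0$selected, 0)
  expect_s3_class(fw0$fit, "ige_gee")
})

test_that("GEE-based classification recovers planted cohorts", {
  spec <- cohort_spec(n_families = 260, panel_size = 30,
                      signature = default_signature(10, c(1.5, 1.5)),
                      seed = 77)
  co <- generate_cohort(spec)
  keep <- co$subjects$asthma != "undefined"
  sub <- co$subjects[keep, ]
  m <- reactivity_values(encode_class_matrix(co$reactivity))[keep, ]
  encs <- do.call(cbind, lapply(co$signature$allergen_id, function(a) {
    encode_class_factor(m[, a], prefix = a, min_count = 10)
  }))
  covs <- igeprofiler:::covariate_design(
    tibble::tibble(age = sub$age, sex = sub$sex))
  design <- cbind(encs, covs)
  fit <- suppressWarnings(suppressMessages(
    gee_fit(sub$asthma == "affected", design, sub$family_id)))
  cl <- classification_from_gee(fit, design, sub$asthma)
  expect_gt(cl$sensitivity, 0.8)
  expect_gt(cl$specificity, 0.8)
  # degenerate threshold: everything called positive
  cl0 <- classification_from_gee(fit, design, sub$asthma, threshold = 0)
  expect_equal(cl0$sensitivity, 1)
  expect_equal(cl0$specificity, 0)
})

test_that("tidy and glance expose the GEE reporting columns", {
  d <- sim_exchangeable(10, G = 80)
  fit <- gee_fit(d$y, d$X, d$fam)
  td <- tidy(fit)
  expect_identical(td$term, names(fit$coefficients))
  expect_equal(td$or, exp(td$coefficient))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_clusters, 80L)
})
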