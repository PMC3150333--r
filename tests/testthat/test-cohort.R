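test_that("a fixed seed reproduces the cohort exactly", {
  a <- generate_cohort(small_spec(7))
  b <- generate_cohort(small_spec(7))
  expect_identical(a, b)
  c <- generate_cohort(small_spec(8))
  expect_false(identical(a$reactivity, c$reactivity))
})

test_that("generated cohorts satisfy the structural invariants", {
  co <- generate_cohort(small_spec(3))
  s <- co$subjects
  # every offspring's family has at least one parent
  parents_by_fam <- unique(s$family_id[s$role == "parent"])
  expect_true(all(s$family_id[s$role == "offspring"] %in% parents_by_fam))
  # severity/persistency/onset defined only for asthma-affected subjects
  non_asth <- s$asthma != "affected"
  expect_true(all(s$asthma_severity[non_asth] == "undefined"))
  expect_true(all(s$asthma_persistency[non_asth] == "undefined"))
  expect_true(all(is.na(s$asthma_age_onset[non_asth])))
  expect_true(all(s$asthma_age_onset[!non_asth] <= s$age[!non_asth]))
  # reactivity within assay range, rows aligned with subjects
  m <- reactivity_values(co$reactivity)
  expect_true(all(m >= 0 & m <= 100))
  expect_identical(rownames(m), s$subject_id)
})

test_that("spec validation catches bad signatures and prevalences", {
  expect_error(cohort_spec(panel_size = 10,
                           signature = tibble::tibble(allergen = 11, effect = 1)),
               "panel error")
  bad_prev <- default_trait_prevalence()
  bad_prev$asthma$parent <- c(affected = 1.2, not_affected = 0, undefined = -0.2)
  expect_error(cohort_spec(prevalence = bad_prev), "spec error")
  expect_error(cohort_spec(familial_correlation = 1), "spec error")
})

test_that("realized prevalences approach the specified rates in large cohorts", {
  co <- generate_cohort(cohort_spec(n_families = 600, seed = 2))
  s <- co$subjects
  par <- s[s$role == "parent", ]
  off <- s[s$role == "offspring", ]
  expect_equal(mean(par$asthma == "affected"), 0.129, tolerance = 0.15)
  expect_equal(mean(off$asthma == "affected"), 0.995, tolerance = 0.01)
  expect_equal(mean(s$asthma == "undefined"),
               0.005 * nrow(off) / nrow(s) + 0.097 * nrow(par) / nrow(s),
               tolerance = 0.25)
})

test_that("the family factor induces the specified within-family correlation ordering", {
  co <- generate_cohort(cohort_spec(n_families = 150, familial_correlation = 0.6,
                                    exposure_groups = 0, negative_fraction = 0,
                                    signature = NULL, seed = 9))
  lm <- log10(pmax(reactivity_values(co$reactivity), 1e-3))
  fam <- co$subjects$family_id
  cors <- cor(t(lm))
  same_fam <- outer(fam, fam, "==") & upper.tri(cors)
  diff_fam <- !outer(fam, fam, "==") & upper.tri(cors)
  expect_gt(mean(cors[same_fam]), mean(cors[diff_fam]))
  # and the gap collapses without a family factor
  co0 <- generate_cohort(cohort_spec(n_families = 150, familial_correlation = 0,
                                     exposure_groups = 0, negative_fraction = 0,
                                     signature = NULL, seed = 9))
  lm0 <- log10(pmax(reactivity_values(co0$reactivity), 1e-3))
  cors0 <- cor(t(lm0))
  expect_lt(mean(cors0[same_fam]) - mean(cors0[diff_fam]),
            mean(cors[same_fam]) - mean(cors[diff_fam]))
})

test_that("null-signature iid cohorts give ~5% Mann-Whitney rejections per allergen", {
  # type-I error of the per-allergen test under the independence null,
  # pooled over seed replicates
  n_rej <- 0L; n_tests <- 0L
  for (s in 1:20) {
    co <- generate_cohort(null_iid_spec(s, n_families = 150, panel_size = 30))
    keep <- co$subjects$asthma != "undefined"
    status <- co$subjects$asthma[keep] == "affected"
    m <- reactivity_values(co$reactivity)[keep, ]
    p <- apply(m, 2, function(col) {
      suppressWarnings(wilcox.test(col[status], col[!status])$p.value)
    })
    n_rej <- n_rej + sum(p < 0.05)
    n_tests <- n_tests + length(p)
  }
  band <- qbinom(c(0.025, 0.975), n_tests, 0.05)
  expect_gte(n_rej, band[1])
  expect_lte(n_rej, band[2])
})

test_that("cluster-asthma chi-square p-values are uniform under a null signature", {
  pvals <- vapply(1:50, function(s) {
    co <- generate_cohort(cohort_spec(n_families = 80, panel_size = 30,
                                      signature = NULL, seed = 400 + s))
    cs <- encode_class_matrix(co$reactivity)
    km <- profile_kmeans(cs, 3, clustering_config(n_restarts = 5, seed = s))
    keep <- co$subjects$asthma != "undefined"
    tab <- table(km$assignments[keep], co$subjects$asthma[keep])
    suppressWarnings(chisq_association(tab)$p)
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("planted signatures are recovered by the Mann-Whitney filter", {
  # effect >= 1 SD, n >= 600: at least 80% of signature allergens retained,
  # averaged over seeds
  frac <- vapply(1:10, function(s) {
    spec <- cohort_spec(n_families = 200, panel_size = 60,
                        signature = default_signature(12, c(1, 1.5)),
                        seed = 500 + s)
    co <- generate_cohort(spec)
    keep <- co$subjects$asthma != "undefined"
    fl <- filter_allergens(co$reactivity[keep, ], co$subjects$asthma[keep])
    mean(co$signature$allergen_id %in% retained_allergens(fl))
  }, numeric(1))
  expect_gte(mean(frac), 0.8)
})

test_that("cohort_summary reports counts and two-decimal percentages by group", {
  co <- generate_cohort(small_spec(1))
  cs <- cohort_summary(co$subjects)
  expect_true(all(c("trait", "status", "group", "n", "pct") %in% names(cs)))
  comb <- cs[cs$group == "combined" & cs$trait == "asthma", ]
  expect_equal(sum(comb$n), nrow(co$subjects))
  expect_equal(comb$pct, round(100 * comb$n / nrow(co$subjects), 2))
  zero <- tibble::tibble(subject_id = c("a", "b"), role = "parent",
                         sex = c("M", "F"), asthma = "not_affected")
  z <- cohort_summary(zero)
  expect_equal(z$pct[z$trait == "asthma" & z$group == "combined"], 100)
  expect_error(cohort_summary(zero[0, ]), "empty")
})
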