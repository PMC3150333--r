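#' Specification of a synthetic family asthma cohort
#'
#' Describes the statistical structure of a simulated family-based atopy
#' cohort: nuclear families (one or two parents plus 1-3 offspring), per-role
#' trait prevalences, a within-family latent correlation of log-reactivity,
#' and a planted set of asthma-associated allergens whose mean log-reactivity
#' is shifted in asthma-affected subjects. The defaults emulate a cohort of
#' 283 families (~872 subjects, ~55.6% asthma prevalence, ~5% undefined
#' diagnoses) typed on a 103-allergen panel whose class-score distributions
#' are concentrated at 0.
#'
#' Reactivity is generated on the log10(IU/ml) scale as
#' per-allergen background + family factor + signature shift + noise, then
#' exponentiated and clamped to the assay range \[0, 100\]; this matches the
#' heavy right skew of IgE titres and the assay ceiling. A per-subject,
#' per-allergen dropout (`negative_fraction`) puts values below the 0.35 IU/ml
#' detection limit (stored as 0).
#'
#' @param n_families number of families.
#' @param offspring_per_family named probability vector over 1, 2, 3 offspring.
#' @param two_parent_prob probability that a family contributes both parents.
#' @param panel_size number of allergens on the panel.
#' @param prevalence nested list of per-role trait status probabilities, see
#'   [default_trait_prevalence()].
#' @param trait_or named odds ratios coupling rhinitis/eczema/conjunctivitis
#'   to asthma status (1 = independent). Marginal prevalences are preserved.
#' @param familial_correlation within-family correlation of log-reactivity
#'   (`rho_fam`), in \[0, 1).
#' @param signature tibble with columns `allergen` (panel index) and `effect`
#'   (shift of mean log-reactivity for asthma-affected subjects, in units of
#'   the residual SD). `NULL` for no planted signal.
#' @param bg_mean_mu,bg_mean_sd mean and SD of the per-allergen background
#'   location on the log10(IU/ml) scale.
#' @param bg_sd residual SD of log10 reactivity around the allergen location.
#' @param negative_fraction probability that a subject-allergen measurement
#'   falls below the detection limit regardless of the latent value.
#' @param exposure_groups number of family exposure archetypes. Families share
#'   allergen exposure: each family draws one archetype, which raises the mean
#'   log-reactivity of that archetype's background (non-signature) allergens
#'   for every member. This reproduces the structure in which full-panel
#'   clusters are partly shaped by family exposure irrespective of asthma —
#'   background reactivity that masks the asthma signature until the
#'   asthma-irrelevant allergens are filtered out. Set to 0 to disable.
#' @param exposure_allergens number of background allergens per archetype.
#' @param exposure_effect archetype shift of mean log-reactivity, in units of
#'   `bg_sd`.
#' @param seed integer seed; fixed seed gives a byte-identical cohort.
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_families = 283,
                        offspring_per_family = c("1" = 0.55, "2" = 0.38, "3" = 0.07),
                        two_parent_prob = 0.562,
                        panel_size = 103,
                        prevalence = default_trait_prevalence(),
                        trait_or = c(rhinitis = 3, eczema = 1.5, conjunctivitis = 3),
                        familial_correlation = 0.3,
                        signature = default_signature(),
                        bg_mean_mu = -1.0, bg_mean_sd = 0.5, bg_sd = 0.8,
                        negative_fraction = 0.35,
                        exposure_groups = 2L, exposure_allergens = 25L,
                        exposure_effect = 1.5,
                        seed = 1L) {
  if (!is.null(signature) && nrow(signature)) {
    if (any(signature$allergen < 1 | signature$allergen > panel_size)) {
      abort("panel error: signature allergen index outside 1..panel_size")
    }
    if (any(!is.finite(signature$effect))) abort("signature effect sizes must be finite")
  }
  for (tr in names(prevalence)) {
    for (role in names(prevalence[[tr]])) {
      p <- prevalence[[tr]][[role]]
      if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8) {
        abort(sprintf("spec error: prevalence for %s/%s must be probabilities summing to 1",
                      tr, role))
      }
    }
  }
  if (familial_correlation < 0 || familial_correlation >= 1) {
    abort("spec error: familial_correlation must lie in [0, 1)")
  }
  if (negative_fraction < 0 || negative_fraction > 1) {
    abort("spec error: negative_fraction must lie in [0, 1]")
  }
  structure(list(n_families = n_families,
                 offspring_per_family = offspring_per_family,
                 two_parent_prob = two_parent_prob,
                 panel_size = panel_size,
                 prevalence = prevalence,
                 trait_or = trait_or,
                 familial_correlation = familial_correlation,
                 signature = signature,
                 bg_mean_mu = bg_mean_mu, bg_mean_sd = bg_mean_sd,
                 bg_sd = bg_sd,
                 negative_fraction = negative_fraction,
                 exposure_groups = as.integer(exposure_groups),
                 exposure_allergens = as.integer(exposure_allergens),
                 exposure_effect = exposure_effect,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default per-role trait status probabilities
#'
#' Each trait has probabilities for `affected`, `not_affected` and `undefined`
#' status, separately for offspring and parents. Defaults follow the pattern of
#' a family asthma cohort in which essentially all offspring are asthmatic
#' while parents show community-level prevalences, with ~5% undefined asthma
#' diagnoses, and parents carrying lower atopic-trait prevalences than
#' offspring.
#'
#' @return Nested list `prevalence[[trait]][[role]]` of length-3 probability
#'   vectors.
#' @export
default_trait_prevalence <- function() {
  lv <- function(a, n, u) c(affected = a, not_affected = n, undefined = u)
  list(
    asthma = list(offspring = lv(0.995, 0.000, 0.005),
                  parent    = lv(0.129, 0.774, 0.097)),
    rhinitis = list(offspring = lv(0.7535, 0.2139, 0.0326),
                    parent    = lv(0.2353, 0.7014, 0.0633)),
    eczema = list(offspring = lv(0.3070, 0.6535, 0.0395),
                  parent    = lv(0.0905, 0.8258, 0.0837)),
    conjunctivitis = list(offspring = lv(0.4442, 0.4674, 0.0884),
                          parent    = lv(0.1674, 0.6833, 0.1493))
  )
}

#' Default planted asthma signature
#'
#' Twenty allergens (panel indices 1-20) with effect sizes spread evenly from
#' 0.5 to 1.5 residual SDs, emulating a moderate subset of asthma-relevant
#' allergens within a larger panel.
#'
#' @param n_signature number of signature allergens.
#' @param effect_range range of effect sizes (SD units), recycled evenly.
#' @export
default_signature <- function(n_signature = 20,
                              effect_range = c(0.5, 1.5)) {
  tibble::tibble(allergen = seq_len(n_signature),
                 effect = seq(effect_range[1], effect_range[2],
                              length.out = n_signature))
}

# Solve status probabilities conditional on asthma so that the defined-status
# marginal prevalence is preserved under odds-ratio coupling `or`.
coupled_probs <- function(p_marg, q_asthma, or) {
  if (or == 1 || q_asthma <= 0 || q_asthma >= 1 || p_marg <= 0 || p_marg >= 1) {
    return(c(p1 = p_marg, p0 = p_marg))
  }
  f <- function(p0) {
    p1 <- plogis(qlogis(p0) + log(or))
    q_asthma * p1 + (1 - q_asthma) * p0 - p_marg
  }
  p0 <- stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-10)$root
  c(p1 = plogis(qlogis(p0) + log(or)), p0 = p0)
}

#' Generate a synthetic family cohort with reactivity profiles
#'
#' Draws families, per-subject phenotypes and an IU/ml reactivity matrix with
#' the structure declared by the [cohort_spec()]: a per-family latent factor
#' induces within-family correlation of log-reactivity of about `rho_fam`, and
#' asthma-affected subjects have mean log-reactivity shifted by the signature
#' effect sizes on signature allergens only. Fully deterministic for a fixed
#' spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return A list with elements `subjects` (tibble, one row per subject),
#'   `reactivity` (reactivity table, unit `"iu_per_ml"`) and `signature`
#'   (the planted-truth tibble, with allergen ids attached).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_families = 20, seed = 7))
#' dplyr::count(cohort$subjects, role, asthma)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(spec$seed)

  n_fam <- spec$n_families
  n_par <- 1L + rbinom(n_fam, 1L, spec$two_parent_prob)
  n_off <- sample(as.integer(names(spec$offspring_per_family)), n_fam,
                  replace = TRUE, prob = spec$offspring_per_family)
  family_id <- sprintf("F%04d", seq_len(n_fam))

  subjects <- tibble::tibble(
    family_id = c(rep(family_id, n_par), rep(family_id, n_off)),
    role = rep(c("parent", "offspring"), c(sum(n_par), sum(n_off)))
  )
  subjects <- dplyr::arrange(subjects, .data$family_id,
                             dplyr::desc(.data$role == "parent"))
  n <- nrow(subjects)
  subjects$subject_id <- sprintf("S%04d", seq_len(n))

  is_par <- subjects$role == "parent"
  subjects$sex <- ifelse(runif(n) < ifelse(is_par, 0.455, 0.570), "M", "F")
  age <- ifelse(is_par, rnorm(n, 47.1, 10.5), rnorm(n, 21.3, 12.0))
  subjects$age <- round(pmin(pmax(age, ifelse(is_par, 25, 6)), 89), 1)

  draw_status <- function(trait) {
    pr <- spec$prevalence[[trait]]
    out <- character(n)
    for (role in c("parent", "offspring")) {
      idx <- subjects$role == role
      out[idx] <- sample(names(pr[[role]]), sum(idx), replace = TRUE,
                         prob = pr[[role]])
    }
    out
  }
  subjects$asthma <- draw_status("asthma")

  # Coupled secondary traits: undefined status independent, affected vs not
  # conditional on asthma with the configured odds ratio, marginal preserved.
  for (trait in c("rhinitis", "eczema", "conjunctivitis")) {
    or <- unname(spec$trait_or[trait])
    out <- character(n)
    for (role in c("parent", "offspring")) {
      idx <- which(subjects$role == role)
      pr <- spec$prevalence[[trait]][[role]]
      u_rate <- pr[["undefined"]]
      p_marg <- pr[["affected"]] / (1 - u_rate)
      q_asthma <- mean(subjects$asthma[idx] == "affected")
      cp <- coupled_probs(p_marg, q_asthma, or)
      undef <- runif(length(idx)) < u_rate
      p <- ifelse(subjects$asthma[idx] == "affected", cp["p1"], cp["p0"])
      aff <- runif(length(idx)) < p
      out[idx] <- ifelse(undef, "undefined",
                         ifelse(aff, "affected", "not_affected"))
    }
    subjects[[trait]] <- out
  }

  asth <- subjects$asthma == "affected"
  subjects$asthma_severity <- ifelse(
    asth, sample(c("1", "2", "3", "4"), n, replace = TRUE,
                 prob = c(0.289, 0.191, 0.188, 0.332)),
    "undefined")
  subjects$asthma_persistency <- ifelse(
    asth, sample(c("persistent", "not_persistent"), n, replace = TRUE,
                 prob = c(0.892, 0.108)),
    "undefined")
  onset <- round(pmax(rnorm(n, 10.4, 10.8), 1))
  subjects$asthma_age_onset <- ifelse(asth, pmin(onset, subjects$age), NA_real_)

  # Reactivity on the log10(IU/ml) scale.
  p <- spec$panel_size
  allergen_id <- sprintf("A%03d", seq_len(p))
  mu <- rnorm(p, spec$bg_mean_mu, spec$bg_mean_sd)
  rho <- spec$familial_correlation
  fam_factor <- matrix(rnorm(n_fam * p), n_fam, p,
                       dimnames = list(family_id, NULL))
  eps <- matrix(rnorm(n * p), n, p)
  log_iu <- rep(mu, each = n) +
    spec$bg_sd * (sqrt(rho) * fam_factor[subjects$family_id, , drop = FALSE] +
                    sqrt(1 - rho) * eps)
  if (!is.null(spec$signature) && nrow(spec$signature)) {
    shift <- numeric(p)
    shift[spec$signature$allergen] <- spec$signature$effect * spec$bg_sd
    log_iu <- log_iu + outer(as.numeric(asth), shift)
  }
  # Family exposure archetypes on background allergens: shared reactivity
  # structure unrelated to asthma, masking the signature until filtered out.
  if (spec$exposure_groups > 0 && spec$exposure_allergens > 0) {
    bg <- setdiff(seq_len(p),
                  if (is.null(spec$signature)) integer(0) else spec$signature$allergen)
    arch_sets <- lapply(seq_len(spec$exposure_groups), function(g) {
      sample(bg, min(spec$exposure_allergens, length(bg)))
    })
    fam_arch <- sample.int(spec$exposure_groups, n_fam, replace = TRUE)
    arch_shift <- matrix(0, spec$exposure_groups, p)
    for (g in seq_len(spec$exposure_groups)) {
      arch_shift[g, arch_sets[[g]]] <- spec$exposure_effect * spec$bg_sd
    }
    log_iu <- log_iu + arch_shift[fam_arch[match(subjects$family_id, family_id)], ,
                                  drop = FALSE]
  }
  iu <- pmin(10^log_iu, 100)
  iu[matrix(runif(n * p) < spec$negative_fraction, n, p)] <- 0

  signature <- spec$signature
  if (!is.null(signature) && nrow(signature)) {
    signature$allergen_id <- allergen_id[signature$allergen]
  }
  list(subjects = subjects,
       reactivity = reactivity_tbl(iu, subjects$subject_id, allergen_id,
                                   unit = "iu_per_ml"),
       signature = signature)
}

#' Encode an IU/ml reactivity table as class scores
#'
#' @param x reactivity table with unit `"iu_per_ml"`.
#' @param scale class-score bin table, see [iu_to_class()].
#' @return Reactivity table with unit `"class_score"`.
#' @export
encode_class_matrix <- function(x, scale = class_scale()) {
  if (!identical(reactivity_unit(x), "iu_per_ml")) {
    abort("`x` must be a reactivity table with unit \"iu_per_ml\"")
  }
  m <- reactivity_values(x)
  out <- matrix(iu_to_class(as.vector(m), scale), nrow(m), ncol(m))
  reactivity_tbl(out, x$subject_id, allergen_ids(x), unit = "class_score")
}

#' Summarise trait composition of a cohort
#'
#' Tabulates each trait's status counts and percentages by role and for the
#' combined sample, in the layout of a cohort description table. Percentages
#' are 100 * count / group size, reported to 2 decimals.
#'
#' @param subjects subject tibble as produced by [generate_cohort()] or
#'   [read_phenotypes()].
#' @return A tibble with columns `trait`, `status`, `group`, `n`, `pct`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_families = 30, seed = 1))
#' cohort_summary(cohort$subjects)
cohort_summary <- function(subjects) {
  if (!nrow(subjects)) abort("input error: empty cohort")
  traits <- intersect(c("sex", "asthma", "rhinitis", "eczema", "conjunctivitis"),
                      names(subjects))
  groups <- list(offspring = subjects[subjects$role == "offspring", ],
                 parent = subjects[subjects$role == "parent", ],
                 combined = subjects)
  purrr::map_dfr(traits, function(tr) {
    purrr::map_dfr(names(groups), function(g) {
      df <- groups[[g]]
      if (!nrow(df)) return(NULL)
      tab <- table(factor(df[[tr]]))
      tibble::tibble(trait = tr, status = names(tab), group = g,
                     n = as.integer(tab),
                     pct = round(100 * as.integer(tab) / nrow(df), 2))
    })
  })
}
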