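#' GEE configuration
#'
#' @param link marginal link for the binary response. `"logit"` is the
#'   default so that coefficients exponentiate to odds ratios; `"probit"` is
#'   available as a switch.
#' @param max_iterations cap on estimating-equation iterations.
#' @param tol convergence tolerance on the max absolute coefficient update.
#' @export
gee_config <- function(link = c("logit", "probit"), max_iterations = 200L,
                       tol = 1e-8) {
  link <- match.arg(link)
  if (tol <= 0) abort("tolerance must be positive")
  structure(list(link = link, max_iterations = as.integer(max_iterations),
                 tol = tol),
            class = "gee_config")
}

#' Dummy-encode a class-score column as a 4-level factor
#'
#' Class score 5 is merged into 4 (score 5 is rare), and the remaining levels
#' 1-4 are expanded into indicator columns against reference level 0.
#'
#' @param scores integer class scores in 0-5.
#' @param prefix column-name prefix (e.g. the allergen id).
#' @param min_count when positive, extend the same low-frequency principle to
#'   the remaining levels: any level (4 down to 1) carried by fewer than
#'   `min_count` subjects is merged into the next lower level before encoding.
#'   Near-empty score levels cannot support a stable robust Wald test, so the
#'   regression stages encode with `min_count = 10`; the default 0 keeps the
#'   plain 4-level encoding.
#' @return Numeric matrix with columns `<prefix>_score1` ... `<prefix>_score4`.
#'   Constant (all-zero) columns are kept but flagged via the
#'   `constant_columns` attribute; model fitting excludes them.
#' @export
#' @examples
#' encode_class_factor(c(0, 1, 5, 4))
encode_class_factor <- function(scores, prefix = "", min_count = 0) {
  if (any(!(scores %in% 0:5))) abort("input error: class scores must be 0-5")
  lv <- pmin(scores, 4L)
  if (min_count > 0) {
    for (l in 4:1) {
      n_l <- sum(lv == l)
      if (n_l > 0 && n_l < min_count) lv[lv == l] <- l - 1L
    }
  }
  out <- sapply(1:4, function(l) as.numeric(lv == l))
  colnames(out) <- paste0(prefix, if (nzchar(prefix)) "_" else "", "score", 1:4)
  structure(out, constant_columns =
              colnames(out)[apply(out, 2, function(c) length(unique(c)) == 1)])
}

# Family helpers for the two supported links.
gee_links <- list(
  logit = list(linkinv = plogis,
               mu_eta = function(eta) {
                 p <- plogis(eta); p * (1 - p)
               }),
  probit = list(linkinv = pnorm,
                mu_eta = function(eta) stats::dnorm(eta))
)

#' Fit a binary GEE with exchangeable working correlation
#'
#' Solves the generalized estimating equations for a marginal binary-response
#' model with family (cluster) dependence modelled by a single exchangeable
#' working correlation, estimated at each iteration from standardized-residual
#' moments. Standard errors are always robust (sandwich) estimates, so
#' inference stays valid if the working correlation is misspecified. The
#' exchangeable structure's closed-form inverse makes each iteration a few
#' grouped matrix products, so the fit is deterministic and fast.
#'
#' @param y binary response (0/1 or logical).
#' @param design numeric design matrix (no intercept needed; one is prepended
#'   unless a column named `(Intercept)` exists). Constant columns are dropped
#'   with a message.
#' @param cluster_ids family/cluster identifier per subject.
#' @param config a [gee_config()].
#' @return An object of class `ige_gee`: coefficients, robust SEs and
#'   covariance, the estimated exchangeable correlation `alpha`, dispersion
#'   `phi`, cluster count, convergence info.
#' @export
gee_fit <- function(y, design, cluster_ids, config = gee_config()) {
  y <- as.numeric(y)
  X <- as.matrix(design)
  if (!"(Intercept)" %in% colnames(X)) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  keep <- apply(X, 2, function(c) length(unique(c)) > 1)
  keep["(Intercept)"] <- TRUE
  dropped <- colnames(X)[!keep]
  if (length(dropped)) {
    message("dropping constant design column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  if (qr(X)$rank < ncol(X)) abort("design is rank deficient after constant-column removal")
  cl <- factor(cluster_ids)
  if (nlevels(cl) < 2) abort("need >= 2 clusters")
  n <- length(y); p <- ncol(X)
  msize <- as.vector(table(cl))
  n_pairs <- sum(msize * (msize - 1) / 2)
  fam <- gee_links[[config$link]]

  beta <- tryCatch(
    unname(stats::coef(glm(y ~ X - 1, family = binomial(config$link)))),
    error = function(e) numeric(p), warning = function(w) {
      suppressWarnings(unname(stats::coef(
        glm(y ~ X - 1, family = binomial(config$link)))))
    })
  beta[!is.finite(beta)] <- 0

  alpha <- 0; phi <- 1
  converged <- FALSE
  separated <- FALSE
  for (it in seq_len(config$max_iterations)) {
    eta <- as.vector(X %*% beta)
    mu <- fam$linkinv(eta)
    v <- pmax(mu * (1 - mu), 1e-10)
    w <- fam$mu_eta(eta)
    r <- (y - mu) / sqrt(v)
    phi <- sum(r^2) / (n - p)
    if (n_pairs > p) {
      rsum <- rowsum(r, cl)
      r2sum <- rowsum(r^2, cl)
      cross <- sum((rsum^2 - r2sum) / 2)
      alpha_new <- cross / ((n_pairs - p) * phi)
      max_m <- max(msize)
      alpha_new <- min(max(alpha_new, -1 / (max_m - 1) + 1e-6), 1 - 1e-6)
      # smooth the working-correlation update to avoid alpha/beta limit cycles
      alpha <- if (it == 1) alpha_new else (alpha + alpha_new) / 2
    }
    gam <- alpha / (1 + (msize - 1) * alpha)
    U <- X * (w / sqrt(v))
    s <- (y - mu) / sqrt(v)
    Usum <- rowsum(U, cl)
    Us <- rowsum(U * s, cl)
    ssum <- as.vector(rowsum(s, cl))
    Mstar <- crossprod(U) - crossprod(Usum * sqrt(pmax(gam, 0))) +
      (if (any(gam < 0)) crossprod(Usum * sqrt(pmax(-gam, 0))) else 0)
    Gmat <- Us - Usum * (gam * ssum)
    gstar <- colSums(Gmat)
    delta <- tryCatch(solve(Mstar, gstar), error = function(e) {
      solve(Mstar + diag(1e-6, p), gstar)
    })
    # damp oversized updates (quasi-separated factor levels oscillate otherwise)
    step_max <- max(abs(delta))
    if (step_max > 2) delta <- delta * (2 / step_max)
    beta <- beta + delta
    if (max(abs(delta)) < config$tol) { converged <- TRUE; break }
    if (any(abs(beta) > 15)) {
      # A coefficient drifting beyond 15 on the logit scale means a factor
      # level separates the response: the estimating equations have no finite
      # root in that direction. Stop with the estimate at the boundary.
      separated <- TRUE
      warn("possible separation: |coefficient| > 15; estimates truncated at the boundary")
      break
    }
  }
  if (!converged && !separated) {
    abort(sprintf("GEE did not converge in %d iterations (last max update %.3g)",
                  config$max_iterations, max(abs(delta))))
  }

  # Sandwich covariance at the solution (scalar dispersion factors cancel).
  eta <- as.vector(X %*% beta)
  mu <- fam$linkinv(eta)
  v <- pmax(mu * (1 - mu), 1e-10)
  w <- fam$mu_eta(eta)
  s <- (y - mu) / sqrt(v)
  gam <- alpha / (1 + (msize - 1) * alpha)
  U <- X * (w / sqrt(v))
  Usum <- rowsum(U, cl)
  Us <- rowsum(U * s, cl)
  ssum <- as.vector(rowsum(s, cl))
  Mstar <- crossprod(U) - crossprod(Usum * sqrt(pmax(gam, 0))) +
    (if (any(gam < 0)) crossprod(Usum * sqrt(pmax(-gam, 0))) else 0)
  Gmat <- Us - Usum * (gam * ssum)
  Minv <- solve(Mstar)
  # finite-sample cluster adjustment (the standard G/(G-1) * (n-1)/(n-p)
  # degrees-of-freedom factor for clustered sandwich covariances)
  G <- nlevels(cl)
  adj <- G / (G - 1) * (n - 1) / (n - p)
  vcov_robust <- adj * (Minv %*% crossprod(Gmat) %*% Minv)
  dimnames(vcov_robust) <- list(colnames(X), colnames(X))

  structure(list(coefficients = stats::setNames(as.vector(beta), colnames(X)),
                 robust_se = sqrt(diag(vcov_robust)),
                 vcov_robust = vcov_robust,
                 alpha = alpha, phi = phi,
                 link = config$link,
                 n = n, n_clusters = nlevels(cl),
                 iterations = it, converged = converged,
                 separated = separated,
                 dropped_columns = dropped),
            class = "ige_gee")
}

#' @export
print.ige_gee <- function(x, ...) {
  cat(sprintf(
    "GEE (%s link, exchangeable): n = %d in %d clusters, alpha = %.3f\n",
    x$link, x$n, x$n_clusters, x$alpha))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Wald statistic, odds ratio and confidence interval from a coefficient
#'
#' The reporting identities used for every emitted model term:
#' Wald chi-square = (coefficient / SE)^2 on 1 df, OR = exp(coefficient),
#' 95% CI = exp(coefficient +/- 1.96 * SE).
#'
#' @param coefficient,se numeric vectors (se > 0), recycled together.
#' @return Tibble with `coefficient`, `se`, `wald`, `df`, `p`, `or`,
#'   `ci_low`, `ci_high`.
#' @export
#' @examples
#' wald_or_ci(1.705, 0.456) # OR 5.50, CI 2.25-13.45, Wald 13.97
wald_or_ci <- function(coefficient, se) {
  if (any(se <= 0)) abort("input error: SE must be positive")
  wald <- (coefficient / se)^2
  tibble::tibble(coefficient = coefficient, se = se, wald = wald, df = 1L,
                 p = pchisq(wald, 1, lower.tail = FALSE),
                 or = exp(coefficient),
                 ci_low = exp(coefficient - 1.96 * se),
                 ci_high = exp(coefficient + 1.96 * se))
}

# Global (multi-df) robust Wald test for a set of coefficients.
global_wald <- function(fit, terms) {
  terms <- intersect(terms, names(fit$coefficients))
  if (!length(terms)) return(tibble::tibble(wald = NA_real_, df = 0L, p = NA_real_))
  b <- fit$coefficients[terms]
  V <- fit$vcov_robust[terms, terms, drop = FALSE]
  w <- as.numeric(t(b) %*% solve(V, b))
  tibble::tibble(wald = w, df = length(terms),
                 p = pchisq(w, length(terms), lower.tail = FALSE))
}

# Build the demographic covariate design (age, sex, age x sex interaction).
covariate_design <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  stopifnot(all(c("age", "sex") %in% names(covariates)))
  sexM <- as.numeric(covariates$sex == "M")
  cbind(age = covariates$age, sexM = sexM, age_x_sexM = covariates$age * sexM)
}

#' Univariate GEE screen of allergens for asthma association
#'
#' Fits one GEE per allergen: asthma status on the allergen's 4-level
#' class-score factor (plus demographic covariates when supplied), clustered
#' by family. Each allergen is summarized by the global robust Wald test over
#' its factor levels and retained when p < `alpha`. Allergens whose fit fails
#' to converge are logged and treated as not retained.
#'
#' @param x class-score reactivity table.
#' @param status binary asthma status aligned with rows (logical or
#'   `"affected"`-coded character).
#' @param cluster_ids family ids aligned with rows.
#' @param covariates optional tibble with `age` and `sex` columns.
#' @param alpha retention threshold (default 0.05).
#' @param config a [gee_config()].
#' @param min_count sparse-level merge threshold passed to
#'   [encode_class_factor()].
#' @return Tibble with one row per allergen: `allergen_id`, `wald`, `df`,
#'   `p`, `retained`, `converged`.
#' @export
gee_univariate_screen <- function(x, status, cluster_ids, covariates = NULL,
                                  alpha = 0.05, config = gee_config(),
                                  min_count = 10) {
  m <- reactivity_values(x)
  if (is.character(status) || is.factor(status)) {
    status <- as.character(status) == "affected"
  }
  cov_des <- covariate_design(covariates)
  purrr::map_dfr(colnames(m), function(a) {
    res <- tryCatch({
      ff <- fit_class_factor_gee(m[, a], a, cov_des, status, cluster_ids,
                                 config, min_count)
      if (is.null(ff$fit)) {
        tibble::tibble(allergen_id = a, wald = NA_real_, df = 0L, p = 1,
                       retained = FALSE, converged = TRUE)
      } else {
        gw <- global_wald(ff$fit, ff$terms)
        tibble::tibble(allergen_id = a, wald = gw$wald, df = gw$df, p = gw$p,
                       retained = isTRUE(gw$p < alpha),
                       converged = ff$fit$converged)
      }
    }, error = function(e) {
      tibble::tibble(allergen_id = a, wald = NA_real_, df = NA_integer_,
                     p = NA_real_, retained = FALSE, converged = FALSE)
    })
    res
  })
}

# Fit one allergen's class-score factor (plus covariates) by GEE, merging any
# level that completely separates the response into the adjacent lower level
# and refitting. A separated level has no finite coefficient, so its Wald
# contribution is uninformative (Hauck-Donner); folding it into the
# neighbouring band keeps its subjects' signal testable. Returns the fit, the
# factor's term names, and the (possibly merged) level vector.
fit_class_factor_gee <- function(scores, prefix, cov_des, status, cluster_ids,
                                 config, min_count) {
  lv <- pmin(scores, 4L)
  repeat {
    enc <- encode_class_factor(lv, prefix = prefix, min_count = min_count)
    live <- setdiff(colnames(enc), attr(enc, "constant_columns"))
    if (!length(live)) {
      return(list(fit = NULL, terms = character(0), levels = lv))
    }
    fit <- suppressMessages(withCallingHandlers(
      gee_fit(status, cbind(enc, cov_des), cluster_ids, config),
      warning = function(w) invokeRestart("muffleWarning")))
    terms <- intersect(colnames(enc), names(fit$coefficients))
    if (!isTRUE(fit$separated)) {
      return(list(fit = fit, terms = terms, levels = lv))
    }
    co <- fit$coefficients[terms]
    bad <- terms[abs(co) > 14]
    if (!length(bad)) {
      return(list(fit = fit, terms = terms, levels = lv))
    }
    lev <- max(as.integer(sub(".*score", "", bad)))
    lv[lv == lev] <- lev - 1L
  }
}

# Cramer's V between two merged class-score factors.
cramers_v <- function(a, b) {
  tab <- table(pmin(a, 4L), pmin(b, 4L))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(1)
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  sqrt(unname(chi) / (sum(tab) * (min(dim(tab)) - 1)))
}

#' Forward multivariate GEE model selection
#'
#' Starting from a covariates-only model (age, sex, age x sex, always
#' retained), candidate allergens enter one at a time: at each step the
#' candidate whose 4-level factor has the smallest global robust Wald p is
#' added if that p < `alpha_enter`; selection stops when no candidate
#' qualifies. Candidates pairwise collinear with an already-entered allergen
#' (Cramer's V > `v_max` on the merged score factors) are excluded before
#' entry.
#'
#' @inheritParams gee_univariate_screen
#' @param candidates character vector of candidate allergen ids (typically the
#'   univariate-screen retained list).
#' @param covariates tibble with `age` and `sex`.
#' @param alpha_enter entry threshold on the global factor Wald p.
#' @param v_max Cramer's V exclusion threshold.
#' @return A list of class `ige_gee_forward`: `fit` (final `ige_gee`),
#'   `selected` (allergen ids in entry order), `trace` (per-step tibble),
#'   `excluded_collinear`.
#' @export
gee_forward_select <- function(x, candidates, status, cluster_ids, covariates,
                               alpha_enter = 0.05, v_max = 0.9,
                               config = gee_config(), min_count = 10) {
  m <- reactivity_values(x)
  if (is.character(status) || is.factor(status)) {
    status <- as.character(status) == "affected"
  }
  cov_des <- covariate_design(covariates)
  selected <- character(0)
  excluded <- character(0)
  trace <- list()
  # levels actually used per selected allergen (separated levels may have
  # been merged down during candidate evaluation)
  level_map <- list()
  base_design <- function(sel) {
    encs <- lapply(sel, function(a) {
      encode_class_factor(level_map[[a]] %||% m[, a], prefix = a,
                          min_count = min_count)
    })
    do.call(cbind, c(encs, list(cov_des)))
  }
  current_fit <- suppressMessages(gee_fit(status, cov_des, cluster_ids, config))
  pool <- candidates
  repeat {
    pool <- setdiff(pool, c(selected, excluded))
    if (length(selected)) {
      coll <- vapply(pool, function(a) {
        any(vapply(selected, function(s) cramers_v(m[, a], m[, s]) > v_max,
                   logical(1)))
      }, logical(1))
      excluded <- union(excluded, pool[coll])
      pool <- pool[!coll]
    }
    if (!length(pool)) break
    base <- base_design(selected)
    step_fits <- list()
    step <- purrr::map_dfr(pool, function(a) {
      tryCatch({
        ff <- fit_class_factor_gee(m[, a], a, base, status, cluster_ids,
                                   config, min_count)
        if (is.null(ff$fit) || !length(ff$terms)) {
          return(tibble::tibble(allergen_id = a, wald = NA_real_,
                                df = NA_integer_, p = NA_real_))
        }
        step_fits[[a]] <<- ff
        gw <- global_wald(ff$fit, ff$terms)
        tibble::tibble(allergen_id = a, wald = gw$wald, df = gw$df, p = gw$p)
      }, error = function(e) tibble::tibble(allergen_id = a, wald = NA_real_,
                                            df = NA_integer_, p = NA_real_))
    })
    step <- step[!is.na(step$p), ]
    if (!nrow(step) || min(step$p) >= alpha_enter) break
    best <- step$allergen_id[which.min(step$p)]
    selected <- c(selected, best)
    level_map[[best]] <- step_fits[[best]]$levels
    trace[[length(trace) + 1L]] <-
      dplyr::mutate(step[step$allergen_id == best, ], step = length(selected))
    current_fit <- step_fits[[best]]$fit
  }
  if (!length(selected)) warn("no candidate entered; returning covariates-only model")
  structure(list(fit = current_fit, selected = selected,
                 trace = dplyr::bind_rows(trace),
                 excluded_collinear = excluded),
            class = "ige_gee_forward")
}

#' Classify subjects from a fitted GEE model
#'
#' Applies the linear predictor and inverse link to obtain asthma
#' probabilities, thresholds them, and reports the confusion matrix with
#' sensitivity and specificity.
#'
#' @param fit an `ige_gee` fit.
#' @param design design matrix matching the fit's non-intercept columns.
#' @param status true binary status.
#' @param threshold probability cutoff (default 0.5).
#' @return List with `predictions` tibble (`probability`, `predicted`),
#'   `confusion` 2x2 table, `sensitivity`, `specificity`, `accuracy`.
#' @export
classification_from_gee <- function(fit, design, status, threshold = 0.5) {
  X <- as.matrix(design)
  if (!"(Intercept)" %in% colnames(X)) X <- cbind(`(Intercept)` = 1, X)
  X <- X[, names(fit$coefficients), drop = FALSE]
  prob <- gee_links[[fit$link]]$linkinv(as.vector(X %*% fit$coefficients))
  pred <- prob > threshold
  if (is.character(status) || is.factor(status)) {
    status <- as.character(status) == "affected"
  }
  conf <- table(predicted = factor(pred, c(FALSE, TRUE)),
                truth = factor(status, c(FALSE, TRUE)))
  list(predictions = tibble::tibble(probability = prob, predicted = pred),
       confusion = conf,
       sensitivity = conf["TRUE", "TRUE"] / sum(conf[, "TRUE"]),
       specificity = conf["FALSE", "FALSE"] / sum(conf[, "FALSE"]),
       accuracy = sum(diag(conf)) / sum(conf))
}
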