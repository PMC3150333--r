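#' Mann-Whitney U test between two score groups
#'
#' U is computed from rank sums with mid-ranks for ties. The two-sided p-value
#' uses exact enumeration for small untied samples (combined n <= 20) and the
#' tie-corrected normal approximation with continuity correction otherwise.
#'
#' @param x,y numeric score vectors for the two groups (e.g. class scores of
#'   asthmatic and non-asthmatic subjects).
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration; default
#'   `NULL` applies the size/tie rule above.
#' @return A one-row tibble: `u` (number of (x, y) pairs with x > y, counting
#'   ties as 1/2), `p` (two-sided), `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.100
mann_whitney_u <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y)) abort("input error: empty group")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- (n1 + n2 <= 20) && !ties
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ts <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble::tibble(u = u, p = unname(ts$p.value),
                 method = if (isTRUE(exact)) "exact" else "normal_approx")
}

#' Filter allergens by asthmatic vs non-asthmatic reactivity differences
#'
#' Runs one Mann-Whitney U test per allergen column, comparing the score
#' distributions of asthma-affected against non-affected subjects, and retains
#' allergens with two-sided p below `alpha`. Subjects with undefined asthma
#' status must be excluded beforehand (see [run_pipeline()]). No
#' multiple-testing correction is applied to the retention rule, mirroring the
#' raw-threshold design; Benjamini-Hochberg q-values are reported as an extra
#' column only.
#'
#' @param x reactivity table (class scores by default; any numeric unit is
#'   accepted, with the unit recorded in the result).
#' @param status per-subject asthma status aligned with `x` rows: logical, or
#'   character with `"affected"` counted as case; must contain both groups.
#' @param alpha retention threshold on the raw two-sided p (default 0.05).
#' @return An object of class `ige_filter`: tibble with one row per allergen
#'   (`allergen_id`, `u`, `p`, `q`, `retained`) and attributes `alpha`,
#'   `n_retained`, `unit`.
#' @export
filter_allergens <- function(x, status, alpha = 0.05) {
  m <- reactivity_values(x)
  if (is.character(status) || is.factor(status)) {
    status <- as.character(status) == "affected"
  }
  if (length(status) != nrow(m)) abort("input error: status length mismatch")
  if (anyNA(status) || !any(status) || !any(!status)) {
    abort("input error: need both affected and non-affected subjects, no NAs")
  }
  res <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (length(unique(col)) == 1L) {
      return(tibble::tibble(u = length(col[status]) * length(col[!status]) / 2,
                            p = 1, method = "constant"))
    }
    mann_whitney_u(col[status], col[!status])
  })
  out <- tibble::tibble(allergen_id = colnames(m), u = res$u, p = res$p,
                        method = res$method,
                        q = stats::p.adjust(res$p, "BH"),
                        retained = res$p < alpha)
  structure(out, alpha = alpha, n_retained = sum(out$retained),
            unit = reactivity_unit(x),
            class = c("ige_filter", class(out)))
}

#' @export
print.ige_filter <- function(x, ...) {
  cat(sprintf("allergen filter (Mann-Whitney, alpha = %g): %d of %d retained\n",
              attr(x, "alpha"), attr(x, "n_retained"), nrow(x)))
  NextMethod()
}

#' Retained allergen panel from a filter result
#'
#' @param filter an `ige_filter` result.
#' @return Character vector of retained allergen ids, in panel order.
#' @export
retained_allergens <- function(filter) {
  filter$allergen_id[filter$retained]
}
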