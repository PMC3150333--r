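#' Build a reactivity table
#'
#' The package's canonical container for subjects-by-allergens reactivity is a
#' tibble whose first column is `subject_id` and whose remaining columns are
#' allergens, carrying a `unit` attribute that declares the measurement scale:
#' raw fluorescence (`"signal"`), calibrated concentration (`"iu_per_ml"`), or
#' the clinical 0-5 class score (`"class_score"`).
#'
#' @param values numeric matrix (subjects x allergens) or data frame of
#'   reactivity values.
#' @param subject_ids character vector of subject identifiers, one per row.
#' @param allergen_ids character vector of allergen identifiers, one per
#'   column.
#' @param unit one of `"signal"`, `"iu_per_ml"`, `"class_score"`.
#'
#' @return A tibble of class `ige_reactivity` with a `unit` attribute.
#' @export
#' @examples
#' reactivity_tbl(matrix(0:5, 2, 3), c("s1", "s2"), c("a1", "a2", "a3"),
#'                unit = "class_score")
reactivity_tbl <- function(values, subject_ids = NULL, allergen_ids = NULL,
                           unit = c("signal", "iu_per_ml", "class_score")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(subject_ids)) {
    subject_ids <- rownames(values) %||% paste0("S", seq_len(nrow(values)))
  }
  if (is.null(allergen_ids)) {
    allergen_ids <- colnames(values) %||% paste0("A", seq_len(ncol(values)))
  }
  if (length(subject_ids) != nrow(values) ||
      length(allergen_ids) != ncol(values)) {
    abort("`subject_ids`/`allergen_ids` must match the matrix dimensions.")
  }
  if (anyDuplicated(subject_ids)) abort("duplicate subject_id in reactivity table")
  check_unit_values(values, unit)
  out <- tibble::as_tibble(values, .name_repair = "minimal")
  names(out) <- as.character(allergen_ids)
  out <- tibble::add_column(out, subject_id = as.character(subject_ids),
                            .before = 1)
  new_reactivity(out, unit)
}

new_reactivity <- function(tbl, unit) {
  structure(tbl, unit = unit,
            class = c("ige_reactivity", class(tibble::as_tibble(tbl))))
}

check_unit_values <- function(values, unit) {
  if (anyNA(values)) abort("reactivity values must not contain missing cells")
  if (unit == "class_score") {
    bad <- which(!(values %in% 0:5))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(values))
      abort(sprintf(
        "class-score values must be integers 0-5; first offending cell [%d, %d] = %s",
        rc[1], rc[2], format(values[bad[1]])))
    }
  } else if (any(values < 0)) {
    abort(sprintf("%s values must be non-negative", unit))
  }
  invisible(values)
}

#' @rdname reactivity_tbl
#' @param x a reactivity table.
#' @export
reactivity_unit <- function(x) {
  attr(x, "unit") %||% abort("not a reactivity table: no unit attribute")
}

#' @rdname reactivity_tbl
#' @export
allergen_ids <- function(x) setdiff(names(x), "subject_id")

#' Extract the numeric subjects-by-allergens matrix from a reactivity table
#'
#' @param x a reactivity table created by [reactivity_tbl()].
#' @return A numeric matrix with subject ids as row names.
#' @export
reactivity_values <- function(x) {
  m <- as.matrix(x[allergen_ids(x)])
  rownames(m) <- x$subject_id
  m
}

#' @export
print.ige_reactivity <- function(x, ...) {
  cat(sprintf("# IgE reactivity: %d subjects x %d allergens [unit: %s]\n",
              nrow(x), length(allergen_ids(x)), reactivity_unit(x)))
  NextMethod()
}

# Subsetting drops to a plain tibble unless the shape is preserved; keep the
# unit attribute where the subject_id column survives.
#' @export
`[.ige_reactivity` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && "subject_id" %in% names(out)) {
    new_reactivity(tibble::as_tibble(out), attr(x, "unit"))
  } else {
    out
  }
}
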