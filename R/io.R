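#' Read and write subject phenotype tables
#'
#' Phenotype tables are TSV with one row per subject. Required columns:
#' `subject_id`, `family_id`, `role`, `age`, `sex`, `asthma`, `rhinitis`,
#' `eczema`, `conjunctivitis`; optional: `asthma_severity`,
#' `asthma_persistency`, `asthma_age_onset`. Trait statuses outside
#' `affected`/`not_affected`/`undefined` are mapped to `undefined` with a
#' logged count; invalid `role` or `sex` tokens are a format error.
#'
#' @param path file path.
#' @return `read_phenotypes()`: a subject tibble.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "family_id", "role", "age", "sex",
                "asthma", "rhinitis", "eczema", "conjunctivitis")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("format error: missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$subject_id)) {
    abort("format error: duplicate subject_id")
  }
  if (!all(df$role %in% c("parent", "offspring"))) {
    abort("format error: role must be 'parent' or 'offspring'")
  }
  if (!all(df$sex %in% c("M", "F"))) {
    abort("format error: sex must be 'M' or 'F'")
  }
  ok <- c("affected", "not_affected", "undefined")
  for (tr in c("asthma", "rhinitis", "eczema", "conjunctivitis")) {
    bad <- !(df[[tr]] %in% ok)
    if (any(bad)) {
      message(sprintf("%d unknown %s status value(s) mapped to 'undefined'",
                      sum(bad), tr))
      df[[tr]][bad] <- "undefined"
    }
  }
  tibble::as_tibble(df)
}

#' @rdname read_phenotypes
#' @param subjects subject tibble.
#' @return `write_phenotypes()`: the path, invisibly.
#' @export
write_phenotypes <- function(subjects, path) {
  readr::write_tsv(subjects, path, progress = FALSE)
  invisible(path)
}

#' Read and write reactivity matrices
#'
#' Matrix TSV layout: header row of allergen ids, first column `subject_id`,
#' dense numeric cells. Class-score matrices must contain only integers 0-5;
#' a violating cell is reported with its coordinates.
#'
#' @param path file path.
#' @param unit expected unit of the stored values.
#' @return `read_reactivity_matrix()`: a reactivity table.
#' @export
read_reactivity_matrix <- function(path,
                                   unit = c("class_score", "iu_per_ml", "signal")) {
  unit <- match.arg(unit)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "subject_id") {
    abort("format error: first column must be subject_id")
  }
  vals <- df[-1]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      abort(sprintf("format error: non-numeric cell [row %d, column %s]",
                    bad %||% 1L, names(vals)[j]))
    }
  }
  m <- as.matrix(vals)
  if (unit == "class_score" && length(bad <- which(!(m %in% 0:5)))) {
    rc <- arrayInd(bad[1], dim(m))
    abort(sprintf("format error: class-score cell [row %d, column %s] = %s outside 0-5",
                  rc[1], colnames(m)[rc[2]], format(m[bad[1]])))
  }
  reactivity_tbl(m, df$subject_id, colnames(m), unit = unit)
}

#' @rdname read_reactivity_matrix
#' @param x reactivity table.
#' @return `write_reactivity_matrix()`: the path, invisibly.
#' @export
write_reactivity_matrix <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Read a calibration curve from a two-column TSV
#'
#' @param path TSV with columns `concentration` (IU/ml) and `signal`.
#' @return An [calibration_curve()] object.
#' @export
read_calibration <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("concentration", "signal") %in% names(df))) {
    abort("format error: calibration TSV needs columns concentration, signal")
  }
  calibration_curve(df$concentration, df$signal)
}
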