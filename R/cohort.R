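#' Clinical table column specification
#'
#' The canonical clinical CSV dialect: one row per patient with the header
#' `patient_id,age,er,pr,her2,ki67,grade,size_mm,nodes,detection,chemo,
#' hormone,radio,trastuzumab,time_years,event`. Binary markers are coded
#' 0/1, missing values are empty strings (never 0 — zero positive nodes is a
#' real value), `detection` is one of `screen`, `symptomatic`, `unknown`,
#' `chemo` one of `none`, `second`, `third`, and `event` one of `bc_death`,
#' `other_death`, `censored`. Other-cause deaths are treated as censoring
#' for breast-cancer-specific survival throughout the package.
#'
#' @return A named character vector mapping column names to readr column
#'   type shorthand.
#' @export
clinical_columns <- function() {
  c(
    patient_id = "c", age = "d", er = "i", pr = "i", her2 = "i", ki67 = "i",
    grade = "i", size_mm = "d", nodes = "i", detection = "c", chemo = "c",
    hormone = "i", radio = "i", trastuzumab = "i", time_years = "d",
    event = "c"
  )
}

validate_clinical <- function(clinical) {
  cols <- names(clinical_columns())
  missing_cols <- setdiff(cols, names(clinical))
  if (length(missing_cols) > 0L) {
    abort(sprintf(
      "Clinical table is missing mandatory column(s): %s",
      paste(missing_cols, collapse = ", ")
    ), class = "predictgrs_schema_error")
  }
  if (anyDuplicated(clinical$patient_id)) {
    abort("Duplicate patient_id values in clinical table.",
      class = "predictgrs_schema_error"
    )
  }
  bad_event <- setdiff(unique(clinical$event), c("bc_death", "other_death", "censored"))
  if (length(bad_event) > 0L && !all(is.na(bad_event))) {
    abort(sprintf(
      "Invalid event value(s): %s",
      paste(stats::na.omit(bad_event), collapse = ", ")
    ), class = "predictgrs_schema_error")
  }
  with(clinical, {
    if (any(age <= 0, na.rm = TRUE)) abort("age must be positive.")
    if (any(size_mm <= 0, na.rm = TRUE)) abort("size_mm must be positive when present.")
    if (any(nodes < 0, na.rm = TRUE)) abort("nodes must be non-negative.")
    if (any(time_years < 0, na.rm = TRUE)) abort("time_years must be non-negative.")
    if (any(!grade %in% c(1L, 2L, 3L) & !is.na(grade))) {
      abort("grade must be 1, 2, 3 or missing.")
    }
  })
  invisible(clinical)
}

#' Bundle clinical records and expression into a cohort
#'
#' Links a clinical table to a genes-by-samples expression matrix by
#' patient id. Patients present in only one of the two inputs are dropped
#' with a message reporting the counts; zero overlap is an error.
#'
#' @param clinical A data frame following [clinical_columns()].
#' @param expression Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = patient ids).
#' @param er_stratum Optional filter tag, `"positive"` or `"negative"`,
#'   recording that the cohort has been restricted to one ER stratum.
#' @return An object of class `grs_cohort`: a list with elements `clinical`
#'   (tibble, one row per linked patient), `expression` (matrix restricted
#'   and ordered to the same patients) and `er_stratum`.
#' @export
grs_cohort <- function(clinical, expression, er_stratum = NULL) {
  clinical <- as_tibble(clinical)
  validate_clinical(clinical)
  if (!is.matrix(expression)) {
    abort("`expression` must be a matrix (genes x samples).")
  }
  if (anyDuplicated(rownames(expression))) abort("Duplicate gene ids in expression matrix.")
  if (anyDuplicated(colnames(expression))) abort("Duplicate sample ids in expression matrix.")

  shared <- intersect(clinical$patient_id, colnames(expression))
  if (length(shared) == 0L && (nrow(clinical) > 0L || ncol(expression) > 0L)) {
    abort("No overlapping ids between clinical table and expression matrix.",
      class = "predictgrs_linkage_error"
    )
  }
  n_drop_clin <- nrow(clinical) - length(shared)
  n_drop_expr <- ncol(expression) - length(shared)
  if (n_drop_clin > 0L || n_drop_expr > 0L) {
    inform(sprintf(
      "Linkage dropped %d clinical record(s) and %d expression sample(s) without a match.",
      n_drop_clin, n_drop_expr
    ))
  }
  clinical <- clinical[match(shared, clinical$patient_id), , drop = FALSE]
  expression <- expression[, shared, drop = FALSE]
  structure(
    list(clinical = clinical, expression = expression, er_stratum = er_stratum),
    class = "grs_cohort"
  )
}

#' @export
print.grs_cohort <- function(x, ...) {
  cat(sprintf(
    "<grs_cohort> %d patients, %d genes%s\n",
    nrow(x$clinical), nrow(x$expression),
    if (!is.null(x$er_stratum)) paste0(", ER stratum: ", x$er_stratum) else ""
  ))
  cat(sprintf(
    "  events: %d bc_death, %d other_death, %d censored\n",
    sum(x$clinical$event == "bc_death"),
    sum(x$clinical$event == "other_death"),
    sum(x$clinical$event == "censored")
  ))
  invisible(x)
}

#' Read a linked cohort from clinical CSV and expression TSV
#'
#' @param clinical_path Path to a clinical CSV (see [clinical_columns()]).
#' @param expression_path Path to a tab-delimited expression table with a
#'   `gene_id` first column and one column per sample.
#' @param transpose Set `TRUE` when the expression file is samples-in-rows.
#' @return A [grs_cohort()].
#' @export
read_cohort <- function(clinical_path, expression_path, transpose = FALSE) {
  clinical <- readr::read_csv(
    clinical_path,
    col_types = paste(clinical_columns(), collapse = ""),
    na = "", progress = FALSE
  )
  missing_cols <- setdiff(names(clinical_columns()), names(clinical))
  if (length(missing_cols) > 0L) {
    abort(sprintf(
      "Clinical file %s is missing mandatory column(s): %s",
      clinical_path, paste(missing_cols, collapse = ", ")
    ), class = "predictgrs_schema_error")
  }
  expression <- read_expression(expression_path, transpose = transpose)
  grs_cohort(clinical, expression)
}

read_expression <- function(path, transpose = FALSE) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), na = c("", "NA"), progress = FALSE)
  if (names(tab)[1] != "gene_id") {
    abort("Expression file must have `gene_id` as its first column.",
      class = "predictgrs_schema_error"
    )
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab$gene_id
  storage.mode(mat) <- "double"
  if (transpose) {
    mat <- t(mat)
    # after transposition the stored 'gene ids' were sample ids
  }
  mat
}

#' Write a cohort back to the canonical CSV/TSV dialects
#'
#' @param cohort A [grs_cohort()].
#' @param clinical_path,expression_path Output file paths.
#' @return The cohort, invisibly.
#' @export
write_cohort <- function(cohort, clinical_path, expression_path) {
  stopifnot(inherits(cohort, "grs_cohort"))
  readr::write_csv(cohort$clinical, clinical_path, na = "")
  expr <- as_tibble(cohort$expression, rownames = "gene_id")
  readr::write_tsv(expr, expression_path, na = "")
  invisible(cohort)
}

#' Per-gene z-score normalisation
#'
#' Centres and scales every gene row to mean 0, standard deviation 1
#' (sample sd, `n - 1` denominator) over non-missing entries.
#' Zero-variance genes cannot be scaled and are dropped with a message.
#' The operation is idempotent.
#'
#' @param x A genes-by-samples matrix or a [grs_cohort()].
#' @param ... Unused.
#' @return Object of the same type with normalised expression.
#' @export
zscore_normalise <- function(x, ...) UseMethod("zscore_normalise")

#' @export
zscore_normalise.matrix <- function(x, ...) {
  if (ncol(x) < 2L) abort("z-score normalisation needs at least 2 samples.")
  sds <- apply(x, 1L, function(v) sd(v[is.finite(v)]))
  zero_var <- !is.na(sds) & sds == 0
  if (any(zero_var)) {
    inform(sprintf(
      "Dropping %d zero-variance gene(s): %s",
      sum(zero_var), paste(head(rownames(x)[zero_var], 5L), collapse = ", ")
    ))
    x <- x[!zero_var, , drop = FALSE]
    sds <- sds[!zero_var]
  }
  mu <- rowMeans(x, na.rm = TRUE)
  out <- (x - mu) / sds
  out
}

#' @export
zscore_normalise.grs_cohort <- function(x, ...) {
  x$expression <- zscore_normalise(x$expression)
  x
}

#' Restrict a cohort to one ER stratum
#'
#' @param cohort A [grs_cohort()].
#' @param stratum `"positive"` or `"negative"`.
#' @return A [grs_cohort()] carrying the stratum tag.
#' @export
filter_er <- function(cohort, stratum = c("positive", "negative")) {
  stratum <- match.arg(stratum)
  keep <- if (stratum == "positive") cohort$clinical$er == 1L else cohort$clinical$er == 0L
  keep[is.na(keep)] <- FALSE
  grs_cohort(
    cohort$clinical[keep, , drop = FALSE],
    cohort$expression[, cohort$clinical$patient_id[keep], drop = FALSE],
    er_stratum = stratum
  )
}
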