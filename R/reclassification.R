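benefit_levels <- c("low", "intermediate", "high")

#' Categorise absolute chemotherapy benefit
#'
#' Maps predicted absolute 10-year survival benefit (percentage points)
#' into the three clinical action bands used to guide adjuvant
#' chemotherapy: `low` (< 3), `intermediate` (3 to 5, both endpoints
#' included — the only boundary rule under which the strict outer
#' inequalities partition the line) and `high` (> 5). Low-benefit patients
#' are usually not offered chemotherapy, high-benefit patients are
#' recommended it, and the intermediate band triggers a discussion of pros
#' and cons — which is why movement into or out of that band is the
#' clinically interesting reclassification.
#'
#' @param benefit Numeric vector of benefits in percentage points; must be
#'   finite.
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
categorize_benefit <- function(benefit) {
  if (any(!is.finite(benefit))) abort("Benefit values must be finite.")
  factor(
    ifelse(benefit < 3, "low", ifelse(benefit <= 5, "intermediate", "high")),
    levels = benefit_levels
  )
}

new_reclass_table <- function(mat) {
  stopifnot(is.matrix(mat), all(dim(mat) == c(3L, 3L)), all(mat >= 0))
  dimnames(mat) <- list(model_a = benefit_levels, model_b = benefit_levels)
  n_total <- sum(mat)
  n_reclassified <- n_total - sum(diag(mat))
  structure(
    list(
      matrix = mat,
      n_total = n_total,
      n_reclassified = n_reclassified,
      pct_reclassified = if (n_total > 0) 100 * n_reclassified / n_total else NA_real_,
      into_intermediate = sum(mat[, "intermediate"]) - mat["intermediate", "intermediate"],
      out_of_intermediate = sum(mat["intermediate", ]) - mat["intermediate", "intermediate"],
      low_to_high = mat["low", "high"],
      high_to_low = mat["high", "low"]
    ),
    class = "reclass_table"
  )
}

#' Build a reclassification table from per-patient categories
#'
#' Cross-tabulates benefit categories under a reference model (rows, e.g.
#' the clinical model alone) against an alternative model (columns, e.g.
#' clinical model plus a genomic score) and derives the movement summaries:
#' total and off-diagonal counts, moves into/out of the intermediate band,
#' and the extreme low/high swaps.
#'
#' @param categories_a,categories_b Equal-length factors or characters with
#'   levels `low`/`intermediate`/`high`; when both are named by patient id
#'   the sets must agree (the difference is reported otherwise).
#' @return An object of class `reclass_table`.
#' @export
build_reclass_table <- function(categories_a, categories_b) {
  if (!is.null(names(categories_a)) && !is.null(names(categories_b))) {
    only_a <- setdiff(names(categories_a), names(categories_b))
    only_b <- setdiff(names(categories_b), names(categories_a))
    if (length(only_a) > 0L || length(only_b) > 0L) {
      abort(sprintf(
        "Patient sets differ: %d only in A (%s...), %d only in B (%s...).",
        length(only_a), paste(head(only_a, 3L), collapse = ","),
        length(only_b), paste(head(only_b, 3L), collapse = ",")
      ))
    }
    categories_b <- categories_b[names(categories_a)]
  } else if (length(categories_a) != length(categories_b)) {
    abort("Category vectors have different lengths.")
  }
  fa <- factor(as.character(categories_a), levels = benefit_levels)
  fb <- factor(as.character(categories_b), levels = benefit_levels)
  if (anyNA(fa) || anyNA(fb)) abort("Invalid or missing category labels.")
  new_reclass_table(unclass(table(fa, fb)))
}

#' Treat a printed 3x3 matrix as a reclassification table
#'
#' Accepts a bare 3x3 count matrix (rows = reference model, columns =
#' alternative model, both ordered low/intermediate/high) so published
#' tables can be re-summarised without patient-level data.
#'
#' @param mat 3x3 non-negative count matrix.
#' @return An object of class `reclass_table`.
#' @export
as_reclass_table <- function(mat) new_reclass_table(as.matrix(mat))

#' @export
print.reclass_table <- function(x, ...) {
  cat(sprintf(
    "<reclass_table> n = %d, reclassified = %d (%.1f%%)\n",
    x$n_total, x$n_reclassified, x$pct_reclassified
  ))
  print(x$matrix)
  cat(sprintf(
    "into intermediate %d, out of intermediate %d, low->high %d, high->low %d\n",
    x$into_intermediate, x$out_of_intermediate, x$low_to_high, x$high_to_low
  ))
  invisible(x)
}

#' @export
tidy.reclass_table <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$matrix), stringsAsFactors = FALSE)) |>
    dplyr::rename(count = "Freq")
}

#' @export
glance.reclass_table <- function(x, ...) {
  tibble(
    n_total = x$n_total, n_reclassified = x$n_reclassified,
    pct_reclassified = x$pct_reclassified,
    into_intermediate = x$into_intermediate,
    out_of_intermediate = x$out_of_intermediate,
    low_to_high = x$low_to_high, high_to_low = x$high_to_low
  )
}

#' @export
autoplot.reclass_table <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$model_b,
    y = factor(.data$model_a, levels = rev(benefit_levels)),
    fill = .data$count
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      x = "category under modified model", y = "category under reference model",
      title = "Chemotherapy-benefit reclassification"
    )
}

#' Summarise reclassification tables across signatures
#'
#' One row per signature with reclassification counts, the percentage
#' reclassified (exact, plus rounded to the whole percent, half away from
#' zero, for report display) and all movement fields.
#'
#' @param tables Named list of [build_reclass_table()] /
#'   [as_reclass_table()] objects.
#' @return A tibble, one row per table.
#' @export
summarize_reclassification <- function(tables) {
  stopifnot(length(tables) >= 1L)
  purrr::imap_dfr(tables, function(tb, nm) {
    stopifnot(inherits(tb, "reclass_table"))
    dplyr::bind_cols(tibble(signature = nm), glance(tb)) |>
      mutate(pct_rounded = round_half_away(.data$pct_reclassified))
  })
}

#' Write a reclassification table as labelled CSV
#'
#' @param x A `reclass_table`.
#' @param path Output CSV path.
#' @export
write_reclass_table <- function(x, path) {
  df <- as.data.frame(x$matrix)
  df <- cbind(category = rownames(x$matrix), df)
  readr::write_csv(as_tibble(df), path)
  invisible(x)
}
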