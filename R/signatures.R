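#' Declare a genomic risk score
#'
#' A `signature_definition` describes one genomic risk score (GRS)
#' declaratively, so that pure and clinically combined variants (an
#' EPClin-like size/nodes extension, a ROR-C-like tumour-size term) are
#' configuration, not code. Three archetypes cover the published scores:
#'
#' * `linear` — weighted sum of gene expression plus an offset, optionally
#'   clipped to a scale range (recurrence-score / EndoPredict style);
#' * `centroid` — per-patient correlation with class centroids combined by
#'   class weights (risk-of-recurrence / Prosigna style);
#' * `template` — correlation with a single reference profile, higher
#'   correlation meaning better prognosis (MammaPrint style).
#'
#' @param name Signature name.
#' @param archetype One of `"linear"`, `"centroid"`, `"template"`.
#' @param gene_weights Named numeric vector, gene -> weight (linear only).
#' @param centroids Numeric matrix, genes x classes (centroid only).
#' @param class_weights Named numeric vector, class -> weight (centroid only).
#' @param template Named numeric vector, gene -> reference value (template only).
#' @param offset Scalar added to every score.
#' @param scale_bounds Optional length-2 numeric `(min, max)`; linear scores
#'   are clipped into this range.
#' @param clinical_terms Optional named numeric vector, clinical variable ->
#'   coefficient, added to every score (e.g. `c(size_mm = 0.01)`).
#' @param correlation Correlation flavour for `centroid`/`template` scoring;
#'   defaults to Spearman for centroids and Pearson for templates.
#' @param risk_cutoff Optional score threshold used to attach a two-level
#'   risk group (template archetype: correlation at or above the cutoff is
#'   labelled `"good"`).
#' @return An object of class `signature_definition`.
#' @export
signature_definition <- function(name, archetype = c("linear", "centroid", "template"),
                                 gene_weights = NULL, centroids = NULL,
                                 class_weights = NULL, template = NULL,
                                 offset = 0, scale_bounds = NULL,
                                 clinical_terms = NULL, correlation = NULL,
                                 risk_cutoff = NULL) {
  archetype <- match.arg(archetype)
  assert_scalar_number(offset, "offset")
  chk_named <- function(x, what) {
    if (is.null(x) || length(x) == 0L) abort(sprintf("%s archetype requires non-empty `%s`.", archetype, what))
    if (is.null(names(x)) || any(names(x) == "")) abort(sprintf("`%s` must be fully named.", what))
    if (anyDuplicated(names(x))) abort(sprintf("`%s` has duplicate gene names.", what))
  }
  if (archetype == "linear") {
    chk_named(gene_weights, "gene_weights")
    if (!is.null(centroids) || !is.null(template)) {
      abort("linear archetype must not carry centroids or a template.")
    }
  } else if (archetype == "centroid") {
    if (is.null(centroids) || !is.matrix(centroids) || is.null(rownames(centroids))) {
      abort("centroid archetype requires a genes x classes `centroids` matrix with gene rownames.")
    }
    if (anyDuplicated(rownames(centroids))) abort("`centroids` has duplicate gene names.")
    chk_named(class_weights, "class_weights")
    if (!setequal(names(class_weights), colnames(centroids))) {
      abort("`class_weights` names must match `centroids` columns.")
    }
    if (!is.null(gene_weights) || !is.null(template)) {
      abort("centroid archetype must not carry gene_weights or a template.")
    }
  } else {
    chk_named(template, "template")
    if (!is.null(gene_weights) || !is.null(centroids)) {
      abort("template archetype must not carry gene_weights or centroids.")
    }
  }
  if (!is.null(scale_bounds)) {
    stopifnot(length(scale_bounds) == 2L, scale_bounds[1] < scale_bounds[2])
  }
  if (is.null(correlation)) {
    correlation <- if (archetype == "centroid") "spearman" else "pearson"
  }
  correlation <- match.arg(correlation, c("spearman", "pearson"))
  structure(
    list(
      name = name, archetype = archetype, gene_weights = gene_weights,
      centroids = centroids, class_weights = class_weights,
      template = template, offset = offset, scale_bounds = scale_bounds,
      clinical_terms = clinical_terms, correlation = correlation,
      risk_cutoff = risk_cutoff
    ),
    class = "signature_definition"
  )
}

#' @export
print.signature_definition <- function(x, ...) {
  genes <- signature_genes(x)
  cat(sprintf(
    "<signature_definition> %s (%s archetype, %d genes%s)\n",
    x$name, x$archetype, length(genes),
    if (!is.null(x$clinical_terms)) {
      paste0(", clinical terms: ", paste(names(x$clinical_terms), collapse = ", "))
    } else {
      ""
    }
  ))
  invisible(x)
}

signature_genes <- function(definition) {
  switch(definition$archetype,
    linear = names(definition$gene_weights),
    centroid = rownames(definition$centroids),
    template = names(definition$template)
  )
}

#' Read or write a signature definition as YAML
#'
#' One file per signature; gene tables are stored as name/value maps so the
#' definitions are editable without touching code.
#'
#' @param path YAML file path.
#' @return `read_signature()` returns a [signature_definition()].
#' @export
read_signature <- function(path) {
  y <- yaml::read_yaml(path)
  centroids <- NULL
  if (!is.null(y$centroids)) {
    genes <- y$centroids$gene
    classes <- setdiff(names(y$centroids), "gene")
    centroids <- sapply(classes, function(k) as.numeric(y$centroids[[k]]))
    rownames(centroids) <- genes
  }
  num <- function(v) if (is.null(v)) NULL else unlist(v)
  signature_definition(
    name = y$name, archetype = y$archetype,
    gene_weights = num(y$gene_weights), centroids = centroids,
    class_weights = num(y$class_weights), template = num(y$template),
    offset = y$offset %||% 0,
    scale_bounds = if (is.null(y$scale_bounds)) NULL else as.numeric(y$scale_bounds),
    clinical_terms = num(y$clinical_terms),
    correlation = y$correlation, risk_cutoff = y$risk_cutoff
  )
}

#' @rdname read_signature
#' @param definition A [signature_definition()].
#' @export
write_signature <- function(definition, path) {
  y <- definition[!vapply(definition, is.null, logical(1))]
  if (!is.null(y$centroids)) {
    cm <- y$centroids
    y$centroids <- c(
      list(gene = rownames(cm)),
      lapply(setNames(colnames(cm), colnames(cm)), function(k) unname(cm[, k]))
    )
  }
  class(y) <- NULL
  y$gene_weights <- as.list(y$gene_weights)
  y$class_weights <- as.list(y$class_weights)
  y$template <- as.list(y$template)
  y$clinical_terms <- as.list(y$clinical_terms)
  y <- y[!vapply(y, function(v) is.list(v) && length(v) == 0L, logical(1))]
  yaml::write_yaml(y, path)
  invisible(definition)
}

clinical_term_values <- function(definition, clinical, patient_ids) {
  if (is.null(definition$clinical_terms)) {
    return(rep(0, length(patient_ids)))
  }
  if (is.null(clinical)) {
    abort(sprintf(
      "Signature %s has clinical terms (%s) but no clinical data was supplied.",
      definition$name, paste(names(definition$clinical_terms), collapse = ", ")
    ))
  }
  clinical <- clinical[match(patient_ids, clinical$patient_id), , drop = FALSE]
  out <- rep(0, length(patient_ids))
  for (v in names(definition$clinical_terms)) {
    if (!v %in% names(clinical)) abort(sprintf("Clinical term variable `%s` not found.", v))
    out <- out + definition$clinical_terms[[v]] * as.numeric(clinical[[v]])
  }
  out
}

grs_result <- function(definition, scores, coverage, risk_group = NULL) {
  tibble(
    patient_id = names(scores),
    signature = definition$name,
    score = unname(scores),
    risk_group = if (is.null(risk_group)) NA_character_ else unname(risk_group),
    coverage = coverage
  )
}

#' Score a cohort with a signature definition
#'
#' Dispatches on the signature archetype; `score_signature()` is the main
#' entry point, the per-archetype workers are exported for direct use.
#' Scores come back as a tibble with one row per patient, the fraction of
#' signature genes found in the matrix (`coverage`), and an optional risk
#' group.
#'
#' @param x A [grs_cohort()] or a genes-by-samples expression matrix
#'   (z-scored expression is assumed by the shipped definitions).
#' @param definition A [signature_definition()].
#' @param clinical Clinical table, required only when the definition carries
#'   `clinical_terms`; taken from the cohort automatically.
#' @return A tibble: `patient_id`, `signature`, `score`, `risk_group`,
#'   `coverage`.
#' @export
score_signature <- function(x, definition, clinical = NULL) {
  if (inherits(x, "grs_cohort")) {
    clinical <- clinical %||% x$clinical
    x <- x$expression
  }
  switch(definition$archetype,
    linear = score_linear(x, definition, clinical),
    centroid = score_centroid(x, definition, clinical),
    template = score_template(x, definition, clinical)
  )
}

#' @rdname score_signature
#' @export
score_linear <- function(x, definition, clinical = NULL) {
  stopifnot(definition$archetype == "linear")
  w <- definition$gene_weights
  present <- names(w)[names(w) %in% rownames(x)]
  if (length(present) == 0L) {
    abort(sprintf("No genes of signature %s present in the matrix.", definition$name),
      class = "predictgrs_coverage_error"
    )
  }
  missing_genes <- setdiff(names(w), present)
  if (length(missing_genes) > 0L) {
    inform(sprintf(
      "Signature %s: %d missing gene(s) contribute 0 (cohort mean after z-scoring): %s",
      definition$name, length(missing_genes),
      paste(head(missing_genes, 5L), collapse = ", ")
    ))
  }
  scores <- definition$offset +
    drop(crossprod(x[present, , drop = FALSE], w[present]))
  scores <- scores + clinical_term_values(definition, clinical, colnames(x))
  if (!is.null(definition$scale_bounds)) {
    scores <- pmin(pmax(scores, definition$scale_bounds[1]), definition$scale_bounds[2])
  }
  names(scores) <- colnames(x)
  grs_result(definition, scores, coverage = length(present) / length(w))
}

patient_correlations <- function(x, ref, method) {
  # ref: genes x k matrix of reference profiles; returns samples x k
  apply(ref, 2L, function(ctr) {
    apply(x, 2L, function(profile) {
      if (sd(profile) == 0 || sd(ctr) == 0) {
        return(NA_real_)
      }
      cor(profile, ctr, method = method)
    })
  })
}

#' @rdname score_signature
#' @export
score_centroid <- function(x, definition, clinical = NULL) {
  stopifnot(definition$archetype == "centroid")
  shared <- intersect(rownames(definition$centroids), rownames(x))
  if (length(shared) < 3L) {
    abort(sprintf(
      "Signature %s: only %d shared gene(s); need >= 3 for centroid correlation.",
      definition$name, length(shared)
    ), class = "predictgrs_coverage_error")
  }
  xm <- x[shared, , drop = FALSE]
  rho <- patient_correlations(xm, definition$centroids[shared, , drop = FALSE],
    method = definition$correlation
  )
  if (is.null(dim(rho))) rho <- matrix(rho, ncol = ncol(definition$centroids))
  colnames(rho) <- colnames(definition$centroids)
  undefined <- apply(rho, 1L, function(r) any(is.na(r)))
  if (any(undefined)) {
    warn(sprintf(
      "Signature %s: %d patient(s) with undefined centroid correlation (constant profile); scores set NA.",
      definition$name, sum(undefined)
    ))
  }
  w <- definition$class_weights[colnames(rho)]
  scores <- definition$offset + drop(rho %*% w)
  scores <- scores + clinical_term_values(definition, clinical, colnames(xm))
  names(scores) <- colnames(xm)
  grs_result(definition, scores,
    coverage = length(shared) / nrow(definition$centroids)
  )
}

#' @rdname score_signature
#' @export
score_template <- function(x, definition, clinical = NULL) {
  stopifnot(definition$archetype == "template")
  tpl <- definition$template
  shared <- intersect(names(tpl), rownames(x))
  if (length(shared) < 3L) {
    abort(sprintf(
      "Signature %s: only %d shared gene(s); need >= 3 for template correlation.",
      definition$name, length(shared)
    ), class = "predictgrs_coverage_error")
  }
  xm <- x[shared, , drop = FALSE]
  rho <- patient_correlations(xm, matrix(tpl[shared],
    ncol = 1,
    dimnames = list(shared, "template")
  ), method = definition$correlation)
  rho <- drop(rho)
  if (any(is.na(rho))) {
    warn(sprintf(
      "Signature %s: %d patient(s) with undefined template correlation; scores set NA.",
      definition$name, sum(is.na(rho))
    ))
  }
  scores <- definition$offset + rho +
    clinical_term_values(definition, clinical, colnames(xm))
  names(scores) <- colnames(xm)
  risk_group <- if (!is.null(definition$risk_cutoff)) {
    ifelse(is.na(rho), NA_character_,
      ifelse(rho >= definition$risk_cutoff, "good", "poor")
    )
  }
  grs_result(definition, scores,
    coverage = length(shared) / length(tpl),
    risk_group = risk_group
  )
}
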