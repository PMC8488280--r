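# Gene-pair signature models. A signature is a set of canonical gene
# pairs with real weights and a risk cutoff; the index of a sample is the
# weighted sum of its 0/1 pair indicators, i.e. a Cox linear predictor
# over pair flips. The published autophagy signature (ATGPI) for
# early-stage lung adenocarcinoma ships as a frozen instance.

new_pair_signature <- function(pairs, cutoff, provenance, meta = list()) {
  stopifnot(is.data.frame(pairs),
            all(c("gene1", "gene2", "weight") %in% colnames(pairs)))
  if (any(pairs$gene1 >= pairs$gene2)) {
    stop("pairs must be in canonical order (gene1 < gene2)")
  }
  if (anyDuplicated(pair_ids(pairs))) stop("duplicate pairs")
  structure(list(pairs = pairs[, c("gene1", "gene2", "weight")],
                 cutoff = cutoff, provenance = provenance, meta = meta),
            class = "pair_signature")
}

#' The published autophagy-related gene-pair index (ATGPI)
#'
#' The frozen 10-pair, 15-gene prognostic signature for early-stage lung
#' adenocarcinoma, with its published coefficients and risk cutoff 1.35.
#' Loaded from the JSON fixture shipped with the package.
#'
#' @return a `pair_signature` with provenance "published".
#' @export
published_atgpi <- function() {
  path <- system.file("extdata", "atgpi_published.json",
                      package = "pairsurv", mustWork = TRUE)
  read_signature(path)
}

#' The published autophagy clinical prognostic index (ACPI)
#'
#' The frozen linear combination of ATGPI, coded tumour stage (I = 1,
#' II = 2) and age in years:
#' `ACPI = 0.6657 * ATGPI + 0.4445 * stage + 0.0199 * age`,
#' with risk cutoff 1.31.
#'
#' @return an `acpi_model` with provenance "published".
#' @export
published_acpi <- function() {
  new_acpi(w_atgpi = 0.6657, w_stage = 0.4445, w_age = 0.0199,
           cutoff = 1.31, provenance = "published")
}

#' @export
print.pair_signature <- function(x, ...) {
  cat(sprintf("<pair_signature> (%s): %d pairs, %d unique genes, cutoff %g\n",
              x$provenance, nrow(x$pairs),
              length(unique(c(x$pairs$gene1, x$pairs$gene2))), x$cutoff))
  df <- x$pairs
  df$weight <- signif(df$weight, 7)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pair_signature <- function(object, ...) {
  stats::setNames(object$pairs$weight, pair_ids(object$pairs))
}

#' @export
summary.pair_signature <- function(object, ...) {
  cat(sprintf("Gene-pair prognostic signature (%s)\n", object$provenance))
  cat(sprintf("  pairs: %d   unique genes: %d   risk cutoff: %g\n",
              nrow(object$pairs),
              length(unique(c(object$pairs$gene1, object$pairs$gene2))),
              object$cutoff))
  rng <- c(sum(pmin(object$pairs$weight, 0)),
           sum(pmax(object$pairs$weight, 0)))
  cat(sprintf("  attainable score range: [%.6g, %.6g]\n", rng[1], rng[2]))
  if (length(object$meta)) {
    cat("  training metadata:\n")
    for (k in names(object$meta)) {
      v <- object$meta[[k]]
      if (is.atomic(v) && length(v) == 1L) cat(sprintf("    %s: %s\n", k, v))
    }
  }
  invisible(object)
}

signature_genes <- function(model) {
  unique(c(model$pairs$gene1, model$pairs$gene2))
}

#' Score samples with a gene-pair signature
#'
#' For each sample, the index is the weighted sum of pair indicators
#' (1 when the first gene's expression does not exceed the second's).
#' Inherits the monotone-transform invariance of [build_pair_matrix()].
#'
#' @param expr a `cohort_expr` matrix or `cohort_collection` containing
#'   every signature gene.
#' @param model a `pair_signature`.
#' @return named numeric vector of scores, one per sample.
#' @export
score_pairs <- function(expr, model) {
  stopifnot(inherits(model, "pair_signature"))
  pm <- build_pair_matrix(expr, model$pairs)
  drop(crossprod(unclass(pm), model$pairs$weight))[colnames(pm)]
}

#' Predict method for gene-pair signatures
#'
#' @param object a `pair_signature`.
#' @param newdata a `cohort_expr` matrix or `cohort_collection`.
#' @param type "score" (the continuous index, default) or "risk"
#'   (low/high classification at the model cutoff).
#' @param ... unused.
#' @return named numeric vector of scores, or factor of risk classes.
#' @export
predict.pair_signature <- function(object, newdata,
                                   type = c("score", "risk"), ...) {
  type <- match.arg(type)
  sc <- score_pairs(newdata, object)
  if (type == "score") return(sc)
  classify_risk(sc, object$cutoff)
}

#' Classify scores into low/high risk at a cutoff
#'
#' High risk means score strictly greater than the cutoff; a score equal
#' to the cutoff is low risk.
#'
#' @param score numeric scores.
#' @param cutoff risk cutoff.
#' @return factor with levels "low", "high".
#' @export
classify_risk <- function(score, cutoff) {
  stopifnot(all(is.finite(score)), is.finite(cutoff))
  factor(ifelse(score > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Combine a pair-signature score with clinical covariates (ACPI form)
#'
#' The clinical prognostic index is the linear combination
#' `w_atgpi * score + w_stage * stage + w_age * age` with stage coded
#' I = 1, II = 2.
#'
#' @param atgpi numeric signature score(s).
#' @param stage integer stage code(s) in {1, 2} (or "I"/"II").
#' @param age age(s) in years, non-negative.
#' @param model an `acpi_model`, e.g. [published_acpi()].
#' @return numeric index values.
#' @export
score_acpi <- function(atgpi, stage, age, model = published_acpi()) {
  stopifnot(inherits(model, "acpi_model"))
  stage <- code_stage(stage)
  if (any(age < 0)) stop("age must be non-negative")
  model$w_atgpi * atgpi + model$w_stage * stage + model$w_age * age
}

new_acpi <- function(w_atgpi, w_stage, w_age, cutoff, provenance,
                     meta = list()) {
  stopifnot(is.finite(w_atgpi), is.finite(w_stage), is.finite(w_age))
  structure(list(w_atgpi = w_atgpi, w_stage = w_stage, w_age = w_age,
                 cutoff = cutoff, provenance = provenance, meta = meta),
            class = "acpi_model")
}

#' @export
print.acpi_model <- function(x, ...) {
  cat(sprintf(
    "<acpi_model> (%s): index = %.4f * score + %.4f * stage + %.4f * age; cutoff %s\n",
    x$provenance, x$w_atgpi, x$w_stage, x$w_age,
    if (is.null(x$cutoff) || is.na(x$cutoff)) "none" else format(x$cutoff)))
  invisible(x)
}

#' @export
coef.acpi_model <- function(object, ...) {
  c(atgpi = object$w_atgpi, stage = object$w_stage, age = object$w_age)
}

#' Write / read a signature model as JSON
#'
#' Serialization format: `{pairs: [{gene1, gene2, weight}], cutoff,
#' provenance, config}`.
#'
#' @param model a `pair_signature`.
#' @param path file path.
#' @return `read_signature` returns a `pair_signature`.
#' @export
write_signature <- function(model, path) {
  stopifnot(inherits(model, "pair_signature"))
  obj <- list(pairs = model$pairs, cutoff = model$cutoff,
              provenance = model$provenance, config = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_signature_json(obj)
  new_pair_signature(as.data.frame(obj$pairs), cutoff = obj$cutoff,
                     provenance = obj$provenance,
                     meta = as.list(obj$config %||% list()))
}

# Minimal structural validation against the shipped schema contract.
validate_signature_json <- function(obj) {
  need <- c("pairs", "cutoff", "provenance")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    stop("signature JSON missing field(s): ", paste(miss, collapse = ", "))
  }
  pr <- as.data.frame(obj$pairs)
  if (!all(c("gene1", "gene2", "weight") %in% colnames(pr))) {
    stop("signature JSON pairs need gene1, gene2, weight")
  }
  if (!is.numeric(pr$weight) || !all(is.finite(pr$weight))) {
    stop("signature weights must be finite numbers")
  }
  if (!is.numeric(obj$cutoff)) stop("signature cutoff must be numeric")
  invisible(obj)
}
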