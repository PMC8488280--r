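#' Construct an expression matrix for one cohort
#'
#' A cohort expression matrix is a plain numeric matrix (genes in rows,
#' samples in columns) carrying a `cohort_id` attribute. No cross-sample
#' normalization is assumed: values may be on any platform scale, log or
#' linear, because downstream pair features depend only on within-sample
#' orderings.
#'
#' @param values numeric matrix, genes x samples, with unique row and
#'   column names.
#' @param cohort_id single character label for the cohort.
#' @return a numeric matrix of class `cohort_expr`.
#' @export
expression_matrix <- function(values, cohort_id) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (!all(is.finite(values))) stop("all expression values must be finite")
  if (nrow(values) < 2L) stop("need at least 2 genes")
  if (ncol(values) < 1L) stop("need at least 1 sample")
  stopifnot(is.character(cohort_id), length(cohort_id) == 1L)
  structure(values, cohort_id = cohort_id,
            class = c("cohort_expr", class(values)))
}

#' @export
print.cohort_expr <- function(x, ...) {
  cat(sprintf("<cohort_expr> cohort '%s': %d genes x %d samples\n",
              attr(x, "cohort_id"), nrow(x), ncol(x)))
  invisible(x)
}

cohort_id <- function(expr) attr(expr, "cohort_id") %||% "cohort"

#' Read a cohort expression matrix from a TSV file
#'
#' Expects tab-separated text: a header row of sample ids, first column
#' gene symbols, remaining columns numeric expression. Duplicate gene
#' symbols are collapsed by arithmetic mean (common microarray practice
#' when several probes map to one gene). Missing or non-numeric cells are
#' rejected with an error naming the offending row and column.
#'
#' @param path path to the TSV file.
#' @param cohort_id cohort label attached to the result.
#' @return a `cohort_expr` matrix.
#' @export
read_expression <- function(path, cohort_id) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression file needs a gene column plus samples")
  genes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples)) {
    stop(sprintf("duplicate sample id in '%s': %s", path,
                 samples[duplicated(samples)][1L]))
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-numeric or missing value '%s' at gene '%s', sample '%s' in '%s'",
      vals[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
      samples[bad[1L, 2L]], path))
  }
  dimnames(num) <- list(genes, samples)
  if (anyDuplicated(genes)) {
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
  }
  expression_matrix(num, cohort_id = cohort_id)
}

#' Write a cohort expression matrix to TSV
#'
#' Inverse of [read_expression()]: full-precision round trip.
#'
#' @param expr a `cohort_expr` (or plain named) matrix.
#' @param path output file path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr),
                   format(unclass(expr), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("gene_id", colnames(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' CSV with header `sample_id,time_days,event,age,stage,sex,cohort_id`.
#' Stage is accepted as "I"/"II" or 1/2 and recoded to the integer coding
#' used throughout (I = 1, II = 2); other stages are rejected because the
#' signature framework targets early-stage disease. An optional `excluded`
#' boolean column marks patients to drop (e.g. neoadjuvant/adjuvant
#' therapy) when `apply_exclusions = TRUE`.
#'
#' @param path path to the CSV file.
#' @param apply_exclusions drop rows flagged in an `excluded` column.
#' @return a data.frame with columns sample_id, time_days, event, age,
#'   stage (integer 1/2), sex, cohort_id.
#' @export
read_clinical <- function(path, apply_exclusions = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_days", "event", "age", "stage", "sex",
            "cohort_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  }
  if (apply_exclusions && "excluded" %in% colnames(df)) {
    df <- df[!as.logical(df$excluded), , drop = FALSE]
  }
  df$stage <- code_stage(df$stage)
  validate_clinical(df)
  df[, unique(c(need, setdiff(colnames(df), need))), drop = FALSE]
}

#' Recode tumour stage to the integer coding I = 1, II = 2
#'
#' @param stage vector of "I"/"II" labels or 1/2 codes.
#' @return integer vector in {1, 2}.
#' @export
code_stage <- function(stage) {
  out <- rep(NA_integer_, length(stage))
  s <- trimws(as.character(stage))
  out[s %in% c("I", "1")] <- 1L
  out[s %in% c("II", "2")] <- 2L
  if (anyNA(out)) {
    stop("invalid stage code(s): ",
         paste(unique(s[is.na(out)]), collapse = ", "),
         " (expected I/II or 1/2)")
  }
  out
}

validate_clinical <- function(df) {
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  if (!all(is.finite(df$time_days)) || any(df$time_days <= 0)) {
    stop("time_days must be finite and > 0")
  }
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
  if (!all(df$stage %in% c(1L, 2L))) stop("stage must be coded 1 or 2")
  invisible(df)
}

#' Write a clinical table to CSV
#' @param clinical data.frame as returned by [read_clinical()].
#' @param path output file path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundle expression cohorts with a clinical table
#'
#' Checks that every expression sample has exactly one clinical record and
#' (after [harmonize_genes()]) that gene sets agree across cohorts.
#'
#' @param cohorts list of `cohort_expr` matrices (one per cohort).
#' @param clinical clinical data.frame covering every expression sample.
#' @param harmonize restrict all cohorts to their common gene set first.
#' @return an object of class `cohort_collection`: list with elements
#'   `cohorts` (named list of matrices) and `clinical` (data.frame).
#' @export
cohort_collection <- function(cohorts, clinical, harmonize = TRUE) {
  if (!length(cohorts)) stop("need at least one cohort")
  if (harmonize) cohorts <- harmonize_genes(cohorts)
  ids <- vapply(cohorts, cohort_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate cohort ids")
  names(cohorts) <- ids
  genes <- rownames(cohorts[[1L]])
  for (co in cohorts) {
    if (!identical(rownames(co), genes)) {
      stop("gene sets differ across cohorts; run harmonize_genes() first")
    }
  }
  samples <- unlist(lapply(cohorts, colnames), use.names = FALSE)
  if (anyDuplicated(samples)) stop("duplicate sample ids across cohorts")
  validate_clinical(clinical)
  if (!all(samples %in% clinical$sample_id)) {
    stop("clinical record missing for sample(s): ",
         paste(utils::head(setdiff(samples, clinical$sample_id), 5L),
               collapse = ", "))
  }
  clinical <- clinical[match(samples, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  structure(list(cohorts = cohorts, clinical = clinical),
            class = "cohort_collection")
}

#' @export
print.cohort_collection <- function(x, ...) {
  cat(sprintf("<cohort_collection> %d cohort(s), %d genes, %d samples\n",
              length(x$cohorts), nrow(x$cohorts[[1L]]),
              nrow(x$clinical)))
  for (co in x$cohorts) {
    cat(sprintf("  %-12s %4d samples\n", cohort_id(co), ncol(co)))
  }
  invisible(x)
}

n_samples <- function(collection) nrow(collection$clinical)

# Pool all cohorts of a collection into one genes x samples matrix plus a
# per-sample cohort label vector (column order = clinical row order).
pool_expression <- function(collection) {
  mat <- do.call(cbind, lapply(collection$cohorts, unclass))
  labels <- rep(unname(vapply(collection$cohorts, cohort_id, character(1))),
                vapply(collection$cohorts, ncol, integer(1)))
  list(values = mat, cohort = labels)
}

#' Restrict cohorts to their common gene set
#'
#' Cross-platform analyses can only use genes measured everywhere; each
#' cohort is restricted to the intersection of all gene sets, in a common
#' (sorted) order. Idempotent.
#'
#' @param cohorts list of `cohort_expr` matrices.
#' @return list of matrices with identical gene rows.
#' @export
harmonize_genes <- function(cohorts) {
  if (!length(cohorts)) stop("need at least one cohort")
  common <- Reduce(intersect, lapply(cohorts, rownames))
  if (length(common) < 2L) {
    stop("fewer than 2 genes shared across cohorts; cannot harmonize")
  }
  common <- sort(common)
  lapply(cohorts, function(co) {
    expression_matrix(unclass(co)[common, , drop = FALSE],
                      cohort_id = cohort_id(co))
  })
}

#' Randomly split a merged collection into training and testing halves
#'
#' Samples from all cohorts are pooled and partitioned uniformly at random
#' (no stratification); each sample keeps its cohort label, which the
#' downstream constancy filter needs. Reproducible for a fixed seed.
#'
#' @param collection a `cohort_collection`.
#' @param ratio fraction of samples assigned to training, in (0, 1).
#' @param seed integer seed controlling the split.
#' @return list with `train` and `test` cohort collections.
#' @export
merge_split <- function(collection, ratio = 0.5, seed = 1L) {
  stopifnot(inherits(collection, "cohort_collection"))
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio >= 1) {
    stop("`ratio` must lie strictly between 0 and 1")
  }
  samples <- unlist(lapply(collection$cohorts, colnames), use.names = FALSE)
  n <- length(samples)
  n_train <- round(n * ratio)
  if (n_train < 1L || n_train > n - 1L) stop("split leaves an empty partition")
  idx <- with_seed(seed, sample.int(n, n_train))
  train_ids <- samples[sort(idx)]
  subset_ids <- function(ids) {
    kept <- lapply(collection$cohorts, function(co) {
      keep <- colnames(co) %in% ids
      if (!any(keep)) return(NULL)
      expression_matrix(unclass(co)[, keep, drop = FALSE],
                        cohort_id = cohort_id(co))
    })
    kept <- kept[!vapply(kept, is.null, logical(1))]
    cl <- collection$clinical[collection$clinical$sample_id %in% ids, ,
                              drop = FALSE]
    cohort_collection(kept, cl, harmonize = FALSE)
  }
  list(train = subset_ids(train_ids),
       test = subset_ids(setdiff(samples, train_ids)))
}
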