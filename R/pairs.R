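#' Enumerate all unordered gene pairs in canonical order
#'
#' Pairs are returned with `gene1 < gene2` lexicographically, listed in a
#' deterministic order (by gene1, then gene2). For G genes there are
#' G(G-1)/2 pairs.
#'
#' @param genes character vector of at least two unique gene symbols.
#' @return data.frame with columns `gene1`, `gene2`.
#' @export
enumerate_pairs <- function(genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("gene symbols must be unique")
  if (length(genes) < 2L) stop("need at least 2 genes to form pairs")
  g <- sort(genes)
  idx <- utils::combn(length(g), 2L)
  data.frame(gene1 = g[idx[1L, ]], gene2 = g[idx[2L, ]],
             stringsAsFactors = FALSE)
}

pair_ids <- function(pairs) paste(pairs$gene1, pairs$gene2, sep = "|")

parse_pair_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("pair ids must look like 'GENE1|GENE2'")
  data.frame(gene1 = vapply(parts, `[`, "", 1L),
             gene2 = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
}

#' Score one gene pair in one sample
#'
#' The pair indicator is 0 when the first gene's expression exceeds the
#' second's, and 1 otherwise — so ties score 1. The indicator depends only
#' on the within-sample ordering, never on the measurement scale.
#'
#' @param expr1,expr2 finite expression values of the two genes.
#' @return 0 or 1 (vectorized).
#' @export
pair_score <- function(expr1, expr2) {
  if (!all(is.finite(expr1)) || !all(is.finite(expr2))) {
    stop("expression values must be finite")
  }
  as.integer(expr1 <= expr2)
}

#' Build the binary pair-indicator matrix for a cohort or collection
#'
#' Applies [pair_score()] to every (pair, sample) combination. Because the
#' score only compares two values within one sample, any strictly
#' increasing per-sample transform of the expression values leaves the
#' result unchanged — the property that makes pair signatures portable
#' across platforms.
#'
#' @param expr a `cohort_expr` matrix or a `cohort_collection`.
#' @param pairs data.frame of canonical pairs (columns gene1, gene2),
#'   e.g. from [enumerate_pairs()].
#' @return integer matrix of class `pair_matrix`, pairs x samples, with
#'   rownames "GENE1|GENE2" and a `cohort` attribute giving each sample's
#'   cohort label.
#' @export
build_pair_matrix <- function(expr, pairs) {
  if (inherits(expr, "cohort_collection")) {
    pooled <- pool_expression(expr)
    values <- pooled$values
    cohort <- pooled$cohort
  } else {
    values <- unclass(expr)
    cohort <- rep(cohort_id(expr), ncol(values))
  }
  missing <- setdiff(unique(c(pairs$gene1, pairs$gene2)), rownames(values))
  if (length(missing)) {
    stop("gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  scores <- (values[pairs$gene1, , drop = FALSE] <=
               values[pairs$gene2, , drop = FALSE]) * 1L
  storage.mode(scores) <- "integer"
  rownames(scores) <- pair_ids(pairs)
  structure(scores, cohort = cohort,
            class = c("pair_matrix", class(scores)))
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("<pair_matrix> %d pairs x %d samples (%d cohort(s))\n",
              nrow(x), ncol(x), length(unique(attr(x, "cohort")))))
  invisible(x)
}

#' Drop gene pairs that are constant within any cohort
#'
#' A pair whose indicator is all-0 or all-1 inside a cohort carries no
#' within-platform information there and is likely a platform artefact;
#' the default (`scope = "any"`) excludes a pair if it is constant within
#' any single cohort. `scope = "pooled"` applies the lenient reading and
#' only drops pairs constant across the pooled sample set. An optional
#' minority-frequency threshold additionally drops pairs whose rarer
#' score occurs in less than `min_freq` of all samples (off by default).
#'
#' @param pm a `pair_matrix` with cohort labels.
#' @param scope "any" (constant in any one cohort excludes) or "pooled".
#' @param min_freq minimum pooled minority-score frequency, in [0, 0.5];
#'   0 disables the extra filter.
#' @return the retained pairs as a data.frame (gene1, gene2), in input
#'   order, with the kept row indices in attribute `index`.
#' @export
filter_informative_pairs <- function(pm, scope = c("any", "pooled"),
                                     min_freq = 0) {
  scope <- match.arg(scope)
  cohort <- attr(pm, "cohort")
  if (is.null(cohort)) stop("pair matrix lacks cohort labels")
  tab <- table(cohort)
  if (any(tab < 2L)) {
    stop("cohort(s) with fewer than 2 samples: constancy is undefined for ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  m <- unclass(pm)
  if (scope == "any") {
    keep <- rep(TRUE, nrow(m))
    for (co in names(tab)) {
      sub <- m[, cohort == co, drop = FALSE]
      p1 <- rowMeans(sub)
      keep <- keep & p1 > 0 & p1 < 1
    }
  } else {
    p1 <- rowMeans(m)
    keep <- p1 > 0 & p1 < 1
  }
  if (min_freq > 0) {
    p1 <- rowMeans(m)
    keep <- keep & pmin(p1, 1 - p1) >= min_freq
  }
  out <- parse_pair_ids(rownames(m)[keep])
  attr(out, "index") <- which(unname(keep))
  out
}

#' Write / read a pair matrix as TSV
#'
#' Rows are pair ids "GENE1|GENE2", columns samples, values 0/1; a
#' leading comment line stores the per-sample cohort labels.
#'
#' @param pm a `pair_matrix`.
#' @param path file path.
#' @return `read_pair_matrix` returns a `pair_matrix`.
#' @export
write_pair_matrix <- function(pm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#cohort\t", paste(attr(pm, "cohort"), collapse = "\t")),
             con)
  df <- data.frame(pair_id = rownames(pm), unclass(pm), check.names = FALSE)
  colnames(df) <- c("pair_id", colnames(pm))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_matrix
#' @export
read_pair_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  cohort <- strsplit(sub("^#cohort\t", "", first), "\t")[[1L]]
  df <- utils::read.delim(path, skip = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  structure(m, cohort = cohort, class = c("pair_matrix", class(m)))
}
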