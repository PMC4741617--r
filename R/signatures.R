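# Centroid signatures: a selected gene list with reference values (the
# average log2 expression in activated samples), scored against external
# datasets by per-sample correlation.

#' Derive a centroid signature from a differential-expression result
#'
#' Selects genes passing the p-value threshold (raw p by default, BH
#' adjusted when `use_adjusted = TRUE` — the adjusted route exists so a
#' stronger cutoff can equalize signature sizes across contrasts) and
#' records, per gene, the average expression over the activated-condition
#' samples only.
#'
#' @param de a `de_result`
#' @param em the `expr_matrix` the contrast was fitted on
#' @param activated_condition condition whose samples define the centroid
#'   values (e.g. `"CAF"`)
#' @param p_cut selection threshold
#' @param use_adjusted select on BH-adjusted q instead of raw p
#' @param min_genes minimum signature size (default 10)
#' @return a `centroid`: list with `label`, `genes`, `values` (named),
#'   and the thresholds used
#' @export
derive_centroid <- function(de, em, activated_condition, p_cut = 0.01,
                            use_adjusted = FALSE, min_genes = 10) {
  stopifnot(inherits(de, "de_result"), inherits(em, "expr_matrix"))
  crit <- if (use_adjusted) de$q else de$p
  genes <- de$feature[crit < p_cut]
  if (length(genes) < min_genes) {
    stop(sprintf(
      "only %d genes pass %s < %g (need >= %d): consider relaxing the threshold",
      length(genes), if (use_adjusted) "adj-p" else "p", p_cut, min_genes),
      call. = FALSE)
  }
  cols <- em$samples$sample[em$samples$condition == activated_condition]
  if (!length(cols)) stop("no samples in condition ", activated_condition,
                          call. = FALSE)
  vals <- rowMeans(em$values[genes, cols, drop = FALSE])
  structure(list(label = activated_condition, genes = genes,
                 values = vals,
                 thresholds = list(p_cut = p_cut, use_adjusted = use_adjusted)),
            class = "centroid")
}

#' @export
print.centroid <- function(x, ...) {
  cat(sprintf("centroid \"%s\": %d genes (%s < %g)\n", x$label,
              length(x$genes),
              if (x$thresholds$use_adjusted) "adj-p" else "p",
              x$thresholds$p_cut))
  invisible(x)
}

#' Match centroid genes into an external expression dataset
#'
#' Symbols are matched case-insensitively; when several external rows map
#' to one symbol their values are averaged.
#'
#' @param centroid a `centroid`
#' @param external an `expr_matrix`
#' @param min_overlap minimum number of matched genes (default 10)
#' @return a list with `values` (centroid reference values for matched
#'   genes), `external` (matched external submatrix, rows aligned), and
#'   `matched_fraction`
#' @export
match_genes <- function(centroid, external, min_overlap = 10) {
  stopifnot(inherits(centroid, "centroid"), inherits(external, "expr_matrix"))
  key_c <- toupper(centroid$genes)
  key_e <- toupper(rownames(external$values))
  ext <- rowsum(external$values, group = key_e) /
    as.vector(table(key_e)[sort(unique(key_e))])
  common <- intersect(key_c, rownames(ext))
  if (length(common) < min_overlap) {
    stop(sprintf("only %d centroid genes matched (need >= %d)",
                 length(common), min_overlap), call. = FALSE)
  }
  idx <- match(common, key_c)
  list(values = setNames(centroid$values[idx], common),
       external = ext[common, , drop = FALSE],
       matched_fraction = length(common) / length(centroid$genes))
}

#' Score external samples against a centroid by correlation
#'
#' Per external sample, the correlation between the centroid's reference
#' values and the sample's values over the matched genes. Samples with
#' zero variance over the matched genes get a missing score with a
#' warning, never a silent drop.
#'
#' @param centroid a `centroid`
#' @param external an `expr_matrix`
#' @param method `"pearson"` (default) or `"spearman"`
#' @param min_overlap minimum matched genes
#' @return named numeric vector of correlations, one per external sample,
#'   with the matched gene count as attribute `n_genes`
#' @export
score_samples <- function(centroid, external,
                          method = c("pearson", "spearman"),
                          min_overlap = 10) {
  method <- match.arg(method)
  m <- match_genes(centroid, external, min_overlap)
  scores <- vapply(seq_len(ncol(m$external)), function(j) {
    y <- m$external[, j]
    if (sd(y) == 0 || sd(m$values) == 0) return(NA_real_)
    cor(m$values, y, method = method)
  }, numeric(1))
  names(scores) <- colnames(m$external)
  if (anyNA(scores)) {
    warning("zero-variance sample(s): score recorded as missing for ",
            paste(names(scores)[is.na(scores)], collapse = ", "))
  }
  attr(scores, "n_genes") <- nrow(m$external)
  scores
}

#' Centroid-by-sample correlation score matrix
#'
#' @param centroids named list of `centroid` objects
#' @param external an `expr_matrix`
#' @param ... passed to [score_samples()]
#' @return numeric matrix, centroids x external samples
#' @export
centroid_score_matrix <- function(centroids, external, ...) {
  stopifnot(is.list(centroids), !is.null(names(centroids)))
  rows <- lapply(centroids, score_samples, external = external, ...)
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(centroids)
  mat
}
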