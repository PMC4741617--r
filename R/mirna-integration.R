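# miRNA-mRNA integration: (i) miRNA sets derived from one contrast's
# differential expression, tested for enrichment on another contrast's
# t-ranked miRNA list, with per-member coherent/divergent calls; (ii)
# genes ranked by correlation with a miRNA's expression, fed to the
# enrichment engine.

#' Define a miRNA set from a differential-expression result
#'
#' Members are the miRNAs with raw p strictly below `p_cut` whose
#' moderated t matches the requested direction.
#'
#' @param de a `de_result` computed on the miRNA matrix
#' @param direction `"up"` or `"down"`
#' @param p_cut raw p-value cutoff (default 0.05, strict)
#' @return a `mirna_set`: list with `members`, `direction`, `p_cut` and
#'   the source contrast
#' @export
define_mirna_set <- function(de, direction = c("up", "down"), p_cut = 0.05) {
  direction <- match.arg(direction)
  stopifnot(inherits(de, "de_result"))
  keep <- de$p < p_cut &
    (if (direction == "up") de$t > 0 else de$t < 0)
  members <- de$feature[keep]
  if (!length(members)) {
    stop("no miRNA passes p < ", p_cut, " in direction ", direction,
         call. = FALSE)
  }
  structure(list(members = members, direction = direction, p_cut = p_cut,
                 source = attr(de, "contrast")),
            class = "mirna_set")
}

#' @export
print.mirna_set <- function(x, ...) {
  cat(sprintf("mirna_set (%s, p < %g%s): %d members\n", x$direction, x$p_cut,
              if (!is.null(x$source)) paste0(", ", paste(x$source, collapse = " vs "))
              else "", length(x$members)))
  invisible(x)
}

#' Test a miRNA set for enrichment on a reference ranked miRNA list
#'
#' Delegates to [permutation_significance()] on the miRNA universe with a
#' single-set collection. The minimum in-universe size defaults to 3
#' because differential miRNA sets are small; members absent from the
#' universe are reported via the returned size, never silently imputed.
#'
#' @param set a `mirna_set`
#' @param reference_ranked a [ranked_list()] of miRNAs (e.g. CAF vs HPF)
#' @param B permutations
#' @param seed RNG seed
#' @param exponent weighting exponent
#' @param min_size minimum members present in the universe (default 3)
#' @return an `enrichment_result` with one row
#' @export
test_mirna_set <- function(set, reference_ranked, B = 999, seed = 1,
                           exponent = 1, min_size = 3) {
  stopifnot(inherits(set, "mirna_set"))
  in_universe <- intersect(set$members, reference_ranked$feature)
  if (length(in_universe) < min_size) {
    stop(sprintf("only %d set members in the reference universe (need >= %d)",
                 length(in_universe), min_size), call. = FALSE)
  }
  collection <- setNames(list(set$members), mirna_set_id(set))
  permutation_significance(reference_ranked, collection, B = B,
                           scheme = "set", seed = seed, exponent = exponent,
                           min_size = min_size)
}

mirna_set_id <- function(set) {
  src <- if (is.null(set$source)) "set" else paste(set$source, collapse = "v")
  paste0(src, "_", set$direction)
}

#' Coherence of miRNA-set members with a reference contrast
#'
#' A member is `coherent` when the sign of its moderated t in the
#' reference contrast agrees with the set's direction, `divergent`
#' otherwise (a t of exactly zero is labelled divergent with a warning).
#' Members absent from the reference result are reported with label
#' `missing`, never dropped.
#'
#' @param set a `mirna_set`
#' @param reference_de the reference `de_result` (e.g. CAF vs HPF)
#' @return data.frame: mirna, t (reference), label
#' @export
coherence_table <- function(set, reference_de) {
  stopifnot(inherits(set, "mirna_set"), inherits(reference_de, "de_result"))
  idx <- match(set$members, reference_de$feature)
  t_ref <- reference_de$t[idx]
  want <- if (set$direction == "up") 1 else -1
  label <- ifelse(is.na(t_ref), "missing",
                  ifelse(sign(t_ref) == want, "coherent", "divergent"))
  if (any(!is.na(t_ref) & t_ref == 0)) {
    warning("reference t of exactly 0 labelled divergent (tie)")
  }
  data.frame(mirna = set$members, t = t_ref, label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank genes by correlation with a miRNA's expression
#'
#' Correlates every gene's expression with the chosen miRNA across the
#' samples the two matrices share (all of them by default; pass `samples`
#' to restrict to a condition subset), then ranks genes by decreasing
#' correlation with ties broken by gene id.
#'
#' @param genes,mirnas `expr_matrix` objects sharing sample ids
#' @param mirna_id the miRNA whose profile drives the ranking
#' @param method `"pearson"` (default) or `"spearman"`
#' @param samples optional character vector of sample ids to use
#' @return a [ranked_list()] with the correlation as ranking metric
#' @export
correlate_genes_with_mirna <- function(genes, mirnas, mirna_id,
                                       method = c("pearson", "spearman"),
                                       samples = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(genes, "expr_matrix"), inherits(mirnas, "expr_matrix"))
  if (!mirna_id %in% rownames(mirnas$values)) {
    stop("miRNA ", mirna_id, " not found", call. = FALSE)
  }
  shared <- intersect(colnames(genes$values), colnames(mirnas$values))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  if (length(shared) < 3) stop("need >= 3 shared samples", call. = FALSE)
  m <- mirnas$values[mirna_id, shared]
  if (sd(m) == 0) stop("miRNA profile is constant across samples", call. = FALSE)
  r <- as.vector(cor(t(genes$values[, shared, drop = FALSE]), m,
                     method = method))
  names(r) <- rownames(genes$values)
  r[is.na(r)] <- 0   # constant genes carry no correlation signal
  ord <- order(-r, names(r), method = "radix")
  ranked_list(names(r)[ord], r[ord])
}

#' miRNA-correlation-guided gene set enrichment
#'
#' Runs the enrichment engine on a correlation-ranked gene list (see
#' [correlate_genes_with_mirna()]); a thin delegation kept so pipelines
#' read as the procedure they implement.
#'
#' @param ranked a correlation-ranked [ranked_list()]
#' @param collection named list of gene sets
#' @param B permutations
#' @param seed RNG seed
#' @param ... passed to [permutation_significance()]
#' @return an `enrichment_result`
#' @export
mirna_guided_enrichment <- function(ranked, collection, B = 999, seed = 1,
                                    ...) {
  permutation_significance(ranked, collection, B = B, seed = seed, ...)
}

#' Summarize miRNA-guided enrichment across miRNAs
#'
#' @param results_list named list of `enrichment_result` objects, one per
#'   miRNA
#' @param p_cut significance cutoff for set retention
#' @return numeric matrix, sets x miRNAs, of sign(ES) * -log10(p) for
#'   sets significant for at least one miRNA
#' @export
mirna_enrichment_matrix <- function(results_list, p_cut = 0.05) {
  cross_comparison_summary(results_list, p_cut = p_cut, min_contrasts = 1)
}
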