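# Detection-based filtering, probe -> feature collapsing and normalization.
#
# Gene arrays report a per-probe, per-sample detection p-value (probability
# that the signal is background); miRNA arrays report a per-probe standard
# error instead, and detection is signal > 3 x SE.

#' Filter gene probes by detection p-value
#'
#' A probe is removed if and only if its detection p-value exceeds `alpha`
#' in every sample; a single detected sample retains it. The boundary
#' `detection_p == alpha` counts as detected (the rule removes strictly
#' greater values only).
#'
#' @param detection_p numeric matrix, probes x samples, of detection
#'   p-values in \[0, 1\]
#' @param alpha detection threshold (default 0.01)
#' @return character vector of retained probe ids (rownames)
#' @export
filter_gene_probes <- function(detection_p, alpha = 0.01) {
  if (!is.matrix(detection_p) || is.null(rownames(detection_p))) {
    stop("`detection_p` must be a matrix with probe rownames", call. = FALSE)
  }
  if (anyNA(detection_p)) {
    bad <- rownames(detection_p)[which(rowSums(is.na(detection_p)) > 0)][1]
    stop("missing detection p-value for probe ", bad, call. = FALSE)
  }
  if (any(detection_p < 0 | detection_p > 1)) {
    stop("detection p-values must lie in [0, 1]", call. = FALSE)
  }
  keep <- rowSums(detection_p <= alpha) > 0
  rownames(detection_p)[keep]
}

#' Collapse probes to one representative probe per gene
#'
#' For each gene, keeps the single probe with the highest detection rate
#' (fraction of samples with detection p <= `alpha`); ties are broken by
#' the larger interquartile range of the probe's signal, remaining ties by
#' lexicographically smaller probe id. Genes whose probes were all filtered
#' out are simply absent from the output.
#'
#' @param signal numeric matrix, probes x samples
#' @param detection_p matching detection p-value matrix
#' @param probe_map data.frame with columns `probe` and `gene`
#' @param alpha detection threshold used for the detection rate
#' @param probes optional character vector restricting to pre-filtered
#'   probes (e.g. the output of [filter_gene_probes()])
#' @return numeric matrix, genes x samples
#' @export
collapse_probes_to_genes <- function(signal, detection_p, probe_map,
                                     alpha = 0.01, probes = NULL) {
  stopifnot(is.matrix(signal), is.matrix(detection_p),
            all(c("probe", "gene") %in% names(probe_map)))
  if (!identical(dim(signal), dim(detection_p)) ||
      !identical(rownames(signal), rownames(detection_p))) {
    stop("`signal` and `detection_p` must be aligned", call. = FALSE)
  }
  if (is.null(probes)) probes <- rownames(signal)
  probes <- intersect(probes, probe_map$probe)
  if (!length(probes)) stop("no probes to collapse", call. = FALSE)
  signal <- signal[probes, , drop = FALSE]
  detection_p <- detection_p[probes, , drop = FALSE]
  gene <- probe_map$gene[match(probes, probe_map$probe)]

  rate <- rowMeans(detection_p <= alpha)
  iqr <- apply(signal, 1, IQR)
  # order so that the best probe of each gene comes first:
  # rate desc, IQR desc, probe id asc
  ord <- order(gene, -rate, -iqr, probes, method = "radix")
  first <- !duplicated(gene[ord])
  chosen <- ord[first]
  out <- signal[chosen, , drop = FALSE]
  rownames(out) <- gene[chosen]
  out[order(rownames(out)), , drop = FALSE]
}

#' Summarize miRNA probes by total signal
#'
#' The total signal of a miRNA in a sample is the sum of its probes'
#' signals (each probe's replicate spots are assumed pre-averaged
#' upstream).
#'
#' @param signal numeric matrix, probes x samples
#' @param probe_map data.frame with columns `probe` and `mirna`
#' @return numeric matrix, miRNAs x samples
#' @export
summarize_mirna_signal <- function(signal, probe_map) {
  stopifnot(is.matrix(signal), all(c("probe", "mirna") %in% names(probe_map)))
  probes <- intersect(rownames(signal), probe_map$probe)
  if (!length(probes)) stop("no probes to summarize", call. = FALSE)
  signal <- signal[probes, , drop = FALSE]
  mirna <- probe_map$mirna[match(probes, probe_map$probe)]
  out <- rowsum(signal, group = mirna)
  out[order(rownames(out)), , drop = FALSE]
}

#' Call miRNA detection from probe signal and standard error
#'
#' A probe is detected in a sample when its signal strictly exceeds three
#' times its standard error; a miRNA is detected when at least one of its
#' probes is.
#'
#' @param signal numeric matrix, probes x samples
#' @param se matching standard-error matrix (>= 0)
#' @param probe_map data.frame with columns `probe` and `mirna`
#' @return logical matrix, miRNAs x samples
#' @export
call_mirna_detected <- function(signal, se, probe_map) {
  stopifnot(is.matrix(signal), is.matrix(se),
            all(c("probe", "mirna") %in% names(probe_map)))
  if (!identical(dim(signal), dim(se)) ||
      !identical(rownames(signal), rownames(se))) {
    stop("`signal` and `se` must be aligned", call. = FALSE)
  }
  if (any(se < 0, na.rm = TRUE)) {
    stop("negative standard errors are not allowed", call. = FALSE)
  }
  probes <- intersect(rownames(signal), probe_map$probe)
  detected <- signal[probes, , drop = FALSE] > 3 * se[probes, , drop = FALSE]
  mirna <- probe_map$mirna[match(probes, probe_map$probe)]
  out <- rowsum(detected + 0, group = mirna) > 0
  out[order(rownames(out)), , drop = FALSE]
}

#' Filter miRNAs by the number of samples in which they are detected
#'
#' @param detected logical matrix, miRNAs x samples
#' @param min_samples minimum number of detected samples (default 2,
#'   inclusive)
#' @return character vector of retained miRNA ids
#' @export
filter_mirnas <- function(detected, min_samples = 2) {
  stopifnot(is.matrix(detected), is.logical(detected))
  if (anyNA(detected)) stop("`detected` must be complete", call. = FALSE)
  rownames(detected)[rowSums(detected) >= min_samples]
}

#' Log2-transform and normalize an intensity matrix
#'
#' Values at or below zero are floored at `epsilon` before the log. With
#' `method = "quantile"` the log2 values are quantile-normalized (all
#' samples share the same sorted value distribution; within-sample rank
#' order is preserved); `method = "none"` gives the log2 transform only.
#' Quantile normalization is used as a pragmatic between-sample
#' normalization; it makes samples comparable without modelling the
#' platform's intensity-dependent smoothing.
#'
#' @param x numeric matrix of intensities, features x samples
#' @param method `"quantile"` or `"none"`
#' @param epsilon floor applied to non-positive intensities before log2
#' @return numeric matrix of normalized log2 values
#' @export
normalize_log2 <- function(x, method = c("quantile", "none"), epsilon = 1.0) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), is.numeric(x))
  if (any(colSums(abs(x)) == 0)) {
    stop("all-zero sample column: cannot normalize", call. = FALSE)
  }
  x[x <= 0] <- epsilon
  lx <- log2(x)
  if (method == "none") return(lx)
  out <- limma::normalizeQuantiles(lx)
  dimnames(out) <- dimnames(lx)
  out
}
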