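#' Construct an expression matrix with sample metadata
#'
#' The common currency of all pipeline stages: a numeric matrix of log2
#' expression values (features in rows, samples in columns) bundled with a
#' sample annotation table carrying, at minimum, the sample identifier and
#' usually a patient identifier and a condition label.
#'
#' @param values numeric matrix, features x samples, with rownames (feature
#'   ids) and colnames (sample ids)
#' @param samples data.frame with one row per column of `values`; must
#'   contain a `sample` column matching `colnames(values)`; typically also
#'   `patient` and `condition`
#' @return an object of class `expr_matrix`
#' @export
expression_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature ids in `values`", call. = FALSE)
  }
  if (!is.data.frame(samples) || !"sample" %in% names(samples)) {
    stop("`samples` must be a data.frame with a `sample` column", call. = FALSE)
  }
  if (!identical(as.character(samples$sample), colnames(values))) {
    stop("`samples$sample` must match colnames(values) in order", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("`values` must not contain missing values", call. = FALSE)
  }
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if ("condition" %in% names(x$samples)) {
    cat("conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by features and/or samples
#'
#' @param x an `expr_matrix`
#' @param i feature index (ids, positions or logical)
#' @param j sample index
#' @param ... ignored
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  v <- x$values
  s <- x$samples
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) {
    v <- v[, j, drop = FALSE]
    s <- s[match(colnames(v), s$sample), , drop = FALSE]
    rownames(s) <- NULL
  }
  expression_matrix(v, s)
}

#' Write / read an expression matrix as plain TSV
#'
#' The values table has a leading `feature` column and one column per
#' sample; the metadata table has one row per sample.
#'
#' @param em an `expr_matrix`
#' @param values_path path for the values TSV
#' @param samples_path path for the sample metadata TSV
#' @return `write_expression_tsv` returns the paths invisibly;
#'   `read_expression_tsv` returns an `expr_matrix`.
#' @export
write_expression_tsv <- function(em, values_path, samples_path) {
  stopifnot(inherits(em, "expr_matrix"))
  df <- data.frame(feature = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, values_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(em$samples, samples_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(values_path, samples_path))
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(values_path, samples_path) {
  df <- read.delim(values_path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  samples <- read.delim(samples_path, stringsAsFactors = FALSE)
  samples$sample <- as.character(samples$sample)
  expression_matrix(values, samples)
}

#' Read / write gene set collections in GMT format
#'
#' GMT is tab-delimited: set name, description, then member identifiers,
#' one set per line.
#'
#' @param path file path
#' @return `read_gmt` returns a named list of character vectors with a
#'   `description` attribute on each element.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("malformed GMT record: ", substr(l, 1, 50), call. = FALSE)
    }
    members <- unique(parts[-(1:2)])
    attr(members, "description") <- parts[2]
    members
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT", call. = FALSE)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors (optionally carrying a
#'   `description` attribute)
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    desc <- attr(sets[[i]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(names(sets)[i], desc, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
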