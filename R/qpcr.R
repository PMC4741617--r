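# Relative quantification of qPCR data by the delta-delta-Ct method.
#
# A Ct table is a long data.frame with columns sample, assay, replicate,
# ct and undetermined (logical); an optional group column carries the
# biological grouping. Technical replicate wells of one (sample, assay)
# are averaged before delta-Ct; delta-delta-Ct is computed per biological
# sample against a calibrator, assuming perfect doubling per cycle.

check_ct_table <- function(ct_table) {
  need <- c("sample", "assay", "ct", "undetermined")
  if (!is.data.frame(ct_table) || !all(need %in% names(ct_table))) {
    stop("a Ct table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(ct_table$ct) & ct_table$ct <= 0)) {
    stop("determined Ct values must be > 0", call. = FALSE)
  }
  invisible(ct_table)
}

#' Replace undetermined Ct values by a cap
#'
#' Wells flagged undetermined (no amplification within the run) get the
#' cap value — by convention the number of cycles run, 40 — while the
#' flag is preserved for auditability.
#'
#' @param ct_table a Ct table (see [delta_ct()])
#' @param cap Ct assigned to undetermined wells (default 40 cycles)
#' @return the Ct table with capped values
#' @export
cap_undetermined <- function(ct_table, cap = 40) {
  check_ct_table(ct_table)
  ct_table$ct[ct_table$undetermined] <- cap
  ct_table
}

#' Normalize target Ct to a reference assay (delta-Ct)
#'
#' Averages technical replicate wells per (sample, assay), then computes
#' delta-Ct = Ct_target - Ct_normalizer per sample. For cell-free media
#' the normalizer is a non-human spike-in assay; for cellular RNA a
#' reference gene.
#'
#' @param ct_table a Ct table with columns sample, assay, replicate, ct,
#'   undetermined (and optionally group)
#' @param target target assay id
#' @param normalizer normalizer assay id (reference gene or spike-in)
#' @return data.frame: sample (plus group if present), delta_ct
#' @export
delta_ct <- function(ct_table, target, normalizer) {
  check_ct_table(ct_table)
  if (anyNA(ct_table$ct)) {
    stop("Ct table contains missing values: cap undetermined wells first",
         call. = FALSE)
  }
  tgt <- ct_table[ct_table$assay == target, ]
  ref <- ct_table[ct_table$assay == normalizer, ]
  if (!nrow(tgt)) stop("target assay ", target, " not found", call. = FALSE)
  if (!nrow(ref)) stop("normalizer assay ", normalizer, " not found",
                       call. = FALSE)
  t_mean <- tapply(tgt$ct, tgt$sample, mean)
  r_mean <- tapply(ref$ct, ref$sample, mean)
  missing_ref <- setdiff(names(t_mean), names(r_mean))
  if (length(missing_ref)) {
    stop("normalizer missing for sample(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(sample = names(t_mean),
                    delta_ct = as.vector(t_mean - r_mean[names(t_mean)]),
                    row.names = NULL, stringsAsFactors = FALSE)
  if ("group" %in% names(ct_table)) {
    out$group <- ct_table$group[match(out$sample, ct_table$sample)]
  }
  out
}

#' Relative quantification against a calibrator (delta-delta-Ct)
#'
#' delta-delta-Ct = delta-Ct_sample - delta-Ct_calibrator; the relative
#' quantity is RQ = 2^-ddCt (perfect doubling assumed) and -ddCt = log2(RQ)
#' is reported alongside, the usual convention for plotting.
#'
#' @param dct data.frame from [delta_ct()]
#' @param calibrator sample id(s) of the calibrator; several ids (or a
#'   group's samples) are averaged into one calibrator delta-Ct
#' @return data.frame: sample, delta_ct, ddct, rq, neg_ddct
#' @export
delta_delta_ct <- function(dct, calibrator) {
  stopifnot(is.data.frame(dct), all(c("sample", "delta_ct") %in% names(dct)))
  cal <- dct$delta_ct[dct$sample %in% calibrator]
  if (!length(cal)) stop("calibrator sample(s) not found: ",
                         paste(calibrator, collapse = ", "), call. = FALSE)
  ddct <- dct$delta_ct - mean(cal)
  out <- data.frame(sample = dct$sample, delta_ct = dct$delta_ct,
                    ddct = ddct, rq = 2^(-ddct), neg_ddct = -ddct,
                    row.names = NULL, stringsAsFactors = FALSE)
  if ("group" %in% names(dct)) out$group <- dct$group
  out
}

#' Two-sided replicate comparison of relative quantification
#'
#' Two-sample two-tailed Student's t-test between independent biological
#' replicates of two groups, on the log scale (-ddCt) by default because
#' Ct noise is additive there; `scale = "linear"` tests RQ instead. Mean
#' and SD per group are reported alongside the p-value. Identical groups
#' (zero pooled variance, equal means) get p = 1 by convention.
#'
#' @param x,y numeric vectors of per-replicate values (>= 3 each)
#' @param scale `"log"` (values are -ddCt) or `"linear"` (values are RQ)
#' @return list: p, mean_x, sd_x, mean_y, sd_y, statistic
#' @export
replicate_test <- function(x, y, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (length(x) < 3 || length(y) < 3) {
    stop("need >= 3 replicates per group", call. = FALSE)
  }
  if (sd(x) == 0 && sd(y) == 0) {
    return(list(p = if (mean(x) == mean(y)) 1 else 0,
                mean_x = mean(x), sd_x = 0, mean_y = mean(y), sd_y = 0,
                statistic = if (mean(x) == mean(y)) 0 else Inf))
  }
  tt <- t.test(x, y, var.equal = TRUE)
  list(p = tt$p.value, mean_x = mean(x), sd_x = sd(x),
       mean_y = mean(y), sd_y = sd(y),
       statistic = unname(tt$statistic))
}

#' Full relative quantification of a Ct table
#'
#' Convenience chain: cap undetermined wells, average technical
#' replicates, delta-Ct against the normalizer, delta-delta-Ct against
#' the calibrator samples.
#'
#' @param ct_table a Ct table
#' @param target,normalizer assay ids
#' @param calibrator calibrator sample id(s)
#' @param cap Ct cap for undetermined wells
#' @return data.frame as in [delta_delta_ct()]
#' @export
quantify_relative <- function(ct_table, target, normalizer, calibrator,
                              cap = 40) {
  ct_table <- cap_undetermined(ct_table, cap = cap)
  delta_delta_ct(delta_ct(ct_table, target, normalizer), calibrator)
}
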