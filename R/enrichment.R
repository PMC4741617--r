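# Pre-ranked running-sum set enrichment with permutation significance.
#
# The enrichment score walks the ranked list, adding |r_j|^p / N_R at set
# members (N_R = sum of |r|^p over members) and subtracting 1/(N - N_H)
# elsewhere; the ES is the signed extremum of the running sum. Because the
# walk declines linearly between hits, its extrema occur only at hit
# positions (maxima just after a hit, minima just before one), which gives
# an O(N_H) evaluation used for the permutation null; the full O(N) walk
# is kept for observed sets, where the running sum itself is reported.

#' Construct a ranked feature list
#'
#' @param features character vector of unique feature ids, ordered by
#'   non-increasing ranking metric
#' @param scores numeric ranking metric aligned with `features`
#' @return a `ranked_list` data.frame with columns `feature`, `score`
#' @export
ranked_list <- function(features, scores) {
  if (anyDuplicated(features)) stop("duplicate features in ranked list",
                                    call. = FALSE)
  if (length(features) != length(scores)) {
    stop("`features` and `scores` lengths differ", call. = FALSE)
  }
  if (anyNA(scores)) stop("ranking metric must be complete", call. = FALSE)
  if (is.unsorted(rev(scores))) {
    stop("`scores` must be non-increasing", call. = FALSE)
  }
  structure(data.frame(feature = as.character(features), score = scores,
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' Running-sum enrichment score of a set on a ranked list
#'
#' @param ranked a [ranked_list()]
#' @param members character vector of set member ids
#' @param exponent weighting exponent p >= 0; `p = 0` is the classic
#'   unweighted statistic, `p = 1` (default) weights hits by |metric|
#' @return an `es_result` list: `es` (signed extremum), `running_sum`
#'   (length N), `hit_positions`, `members` (members found in the
#'   universe), `exponent`
#' @export
enrichment_score <- function(ranked, members, exponent = 1) {
  stopifnot(inherits(ranked, "ranked_list"), exponent >= 0)
  N <- nrow(ranked)
  hits <- which(ranked$feature %in% members)
  if (!length(hits)) stop("no set member is present in the ranked universe",
                          call. = FALSE)
  if (length(hits) == N) stop("set covers the whole ranked universe",
                              call. = FALSE)
  w <- abs(ranked$score)^exponent
  if (exponent > 0 && sum(w[hits]) == 0) {
    warning("all hit metrics are zero; falling back to the unweighted statistic")
    exponent <- 0
    w <- rep(1, N)
  }
  inc <- rep.int(-1 / (N - length(hits)), N)
  inc[hits] <- w[hits] / sum(w[hits])
  # sequential double-precision accumulation (not cumsum, which carries
  # extra internal precision): the walk is reproducible term by term, so
  # exact ties between the positive and negative extremum resolve the same
  # way in any straightforward re-implementation
  running <- Reduce(`+`, inc, accumulate = TRUE)
  pos <- which.max(abs(running))
  structure(list(
    es = running[pos], running_sum = running, hit_positions = hits,
    extremum = pos, members = ranked$feature[hits], exponent = exponent
  ), class = "es_result")
}

# O(N_H) enrichment score from sorted hit positions and their weights;
# exactly reproduces the signed extremum (first occurrence on ties) of the
# full running sum
es_stream <- function(hits, w_hits, N) {
  k <- length(hits)
  dec <- 1 / (N - k)
  nr <- sum(w_hits)
  if (nr == 0) { w_hits <- rep(1, k); nr <- k }
  cw <- cumsum(w_hits) / nr
  lag <- (hits - seq_len(k)) * dec
  after <- cw - lag                      # value at each hit position
  before <- c(0, cw[-k]) - lag           # value just before each hit
  i_max <- which.max(after)
  i_min <- which.min(before)
  hi <- after[i_max]
  lo <- before[i_min]
  if (hi >= -lo) {
    # on an exact tie the extremum reached first in the walk wins
    if (hi == -lo && (hits[i_min] - 1L) < hits[i_max]) return(lo)
    hi
  } else {
    lo
  }
}

#' Permutation significance for a collection of sets on one ranked list
#'
#' For `scheme = "set"` (the default) each permutation draws a random set
#' of the same size from the ranked universe. The permutation p-value is
#' one-sided on the observed sign with the add-one rule:
#' p = (1 + #\{same-sign |ES_perm| >= |ES_obs|\}) / (#same-sign + 1); ties
#' count as exceedances. NES divides the ES by the mean same-sign permuted
#' |ES|, and FDR q compares the observed NES against the pooled permuted
#' NES null, positive and negative sides handled separately. For
#' `scheme = "phenotype"` each permutation flips the sign of random
#' within-patient differences of the supplied expression matrix and
#' contrast, re-fits the moderated t and re-ranks; this null is very
#' sparse for small designs and is provided for larger cohorts.
#'
#' Randomness is drawn from a substream named after each set, so results
#' do not depend on the order of sets in the collection.
#'
#' @param ranked a [ranked_list()]
#' @param collection named list of character vectors (e.g. from
#'   [read_gmt()] or [generate_geneset_collection()])
#' @param B number of permutations (>= 99)
#' @param scheme `"set"` or `"phenotype"`
#' @param seed RNG seed
#' @param exponent weighting exponent (see [enrichment_score()])
#' @param min_size,max_size set-size bounds after restriction to the
#'   ranked universe; sets outside the bounds are dropped with a message
#' @param em,condition_a,condition_b required for `scheme = "phenotype"`
#' @return an `enrichment_result` data.frame: set, size, es, nes, p, q,
#'   leading_edge and hit_positions (list columns); the restricted sets
#'   are attached as attribute `restricted_sets`
#' @export
permutation_significance <- function(ranked, collection, B = 999,
                                     scheme = c("set", "phenotype"),
                                     seed = 1, exponent = 1,
                                     min_size = 3, max_size = Inf,
                                     em = NULL, condition_a = NULL,
                                     condition_b = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(ranked, "ranked_list"), is.list(collection),
            !is.null(names(collection)))
  if (B < 99) stop("B must be >= 99", call. = FALSE)
  N <- nrow(ranked)
  universe <- ranked$feature
  restricted <- lapply(collection, function(m) intersect(m, universe))
  sizes <- lengths(restricted)
  if (any(sizes > N - 1)) {
    stop("a set covers the whole ranked universe", call. = FALSE)
  }
  keep <- sizes >= min_size & sizes <= max_size
  if (!all(keep)) {
    message(sum(!keep), " set(s) outside size bounds [", min_size, ", ",
            max_size, "] dropped")
  }
  restricted <- restricted[keep]
  if (!length(restricted)) stop("no sets left after size restriction",
                                call. = FALSE)

  w <- abs(ranked$score)^exponent
  obs <- lapply(restricted, function(m) enrichment_score(ranked, m, exponent))
  es_obs <- vapply(obs, `[[`, numeric(1), "es")

  if (scheme == "set") {
    perm <- lapply(names(restricted), function(nm) {
      k <- length(restricted[[nm]])
      with_substream(seed, paste0("perm:", nm), {
        vapply(seq_len(B), function(b) {
          h <- sort.int(sample.int(N, k))
          es_stream(h, w[h], N)
        }, numeric(1))
      })
    })
  } else {
    perm <- phenotype_null(ranked, restricted, B, seed, exponent,
                           em, condition_a, condition_b)
  }
  names(perm) <- names(restricted)

  nes_obs <- numeric(length(obs))
  p <- numeric(length(obs))
  nes_null <- vector("list", length(obs))
  for (i in seq_along(obs)) {
    ep <- perm[[i]]
    same <- sign(ep) == sign(es_obs[i]) & sign(es_obs[i]) != 0
    if (es_obs[i] == 0 || !any(same)) {
      p[i] <- 1
      nes_obs[i] <- 0
    } else {
      p[i] <- (1 + sum(same & abs(ep) >= abs(es_obs[i]))) / (sum(same) + 1)
      nes_obs[i] <- es_obs[i] / mean(abs(ep[same]))
    }
    pos <- ep[ep > 0]; neg <- ep[ep < 0]
    nes_null[[i]] <- c(if (length(pos)) pos / mean(pos),
                       if (length(neg)) neg / abs(mean(neg)))
  }
  pooled <- unlist(nes_null, use.names = FALSE)
  q <- gsea_fdr(nes_obs, pooled)

  out <- data.frame(set = names(restricted), size = lengths(restricted),
                    es = es_obs, nes = nes_obs, p = p, q = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$leading_edge <- lapply(obs, leading_edge)
  out$hit_positions <- lapply(obs, `[[`, "hit_positions")
  structure(out, class = c("enrichment_result", "data.frame"),
            restricted_sets = restricted,
            params = list(B = B, scheme = scheme, seed = seed,
                          exponent = exponent))
}

# FDR by comparing observed NES to the pooled permuted-NES null,
# positive and negative sides separately; values clipped to [0, 1]
gsea_fdr <- function(nes_obs, pooled) {
  q <- rep(NA_real_, length(nes_obs))
  pos_null <- pooled[pooled > 0]
  neg_null <- pooled[pooled < 0]
  for (i in seq_along(nes_obs)) {
    v <- nes_obs[i]
    if (v > 0) {
      num <- if (length(pos_null)) mean(pos_null >= v) else 0
      den <- mean(nes_obs[nes_obs > 0] >= v)
      q[i] <- min(1, num / den)
    } else if (v < 0) {
      num <- if (length(neg_null)) mean(neg_null <= v) else 0
      den <- mean(nes_obs[nes_obs < 0] <= v)
      q[i] <- min(1, num / den)
    } else {
      q[i] <- 1
    }
  }
  q
}

# phenotype-permutation null: flip signs of random within-patient
# differences, re-moderate, re-rank, score every set
phenotype_null <- function(ranked, restricted, B, seed, exponent,
                           em, condition_a, condition_b) {
  if (is.null(em) || is.null(condition_a) || is.null(condition_b)) {
    stop("scheme=\"phenotype\" requires `em`, `condition_a`, `condition_b`",
         call. = FALSE)
  }
  fit <- fit_paired_contrast(em, condition_a, condition_b)
  meta <- em$samples
  a_cols <- meta$sample[meta$condition == condition_a][
    match(fit$patients, meta$patient[meta$condition == condition_a])]
  b_cols <- meta$sample[meta$condition == condition_b][
    match(fit$patients, meta$patient[meta$condition == condition_b])]
  diffs <- em$values[, a_cols, drop = FALSE] - em$values[, b_cols, drop = FALSE]
  n <- ncol(diffs)
  member_idx <- lapply(restricted, function(m) match(m, rownames(diffs)))
  with_substream(seed, "perm:phenotype", {
    per_b <- lapply(seq_len(B), function(b) {
      flip <- sample(c(-1, 1), n, replace = TRUE)
      d <- sweep(diffs, 2, flip, `*`)
      lfc <- rowMeans(d)
      s2 <- rowSums((d - lfc)^2) / (n - 1)
      prior <- estimate_prior(s2, n - 1)
      s2_post <- if (is.finite(prior$df_prior)) {
        (prior$df_prior * prior$s2_prior + (n - 1) * s2) /
          (prior$df_prior + n - 1)
      } else rep(prior$s2_prior, length(s2))
      t <- lfc / sqrt(s2_post / n)
      r <- rank(-t, ties.method = "first")
      ord_w <- abs(sort(t, decreasing = TRUE))^exponent
      vapply(member_idx, function(idx) {
        h <- sort.int(r[idx])
        es_stream(h, ord_w[h], length(t))
      }, numeric(1))
    })
    mat <- do.call(rbind, per_b)   # B x n_sets
    lapply(seq_len(ncol(mat)), function(j) mat[, j])
  })
}

#' Leading-edge members of an enrichment result
#'
#' For a positive ES, the set members ranked at or before the running-sum
#' extremum; for a negative ES, those at or after it.
#'
#' @param x an `es_result` from [enrichment_score()]
#' @return character vector of leading-edge feature ids
#' @export
leading_edge <- function(x) {
  stopifnot(inherits(x, "es_result"))
  if (x$es == 0) return(character(0))
  if (x$es > 0) {
    x$members[x$hit_positions <= x$extremum]
  } else {
    x$members[x$hit_positions >= x$extremum]
  }
}

#' Intersect leading edges across enrichment results
#'
#' @param edges list (length >= 2) of character vectors or `es_result`
#'   objects
#' @return character vector of features shared by every leading edge
#' @export
leading_edge_intersection <- function(edges) {
  if (!is.list(edges) || length(edges) < 2) {
    stop("need at least 2 leading edges to intersect", call. = FALSE)
  }
  edges <- lapply(edges, function(e) {
    if (inherits(e, "es_result")) leading_edge(e) else as.character(e)
  })
  Reduce(intersect, edges)
}

#' Build an enrichment network of significant sets
#'
#' Nodes are sets with p below `p_cut` (node weight = in-universe set
#' size, node sign = ES sign); an edge joins two nodes sharing at least
#' `min_shared` members, weighted by the intersection size.
#'
#' @param results an `enrichment_result`
#' @param min_shared minimum shared members for an edge
#' @param p_cut significance cutoff for node inclusion
#' @return a list with `nodes` (set, size, es, p) and `edges` (source,
#'   target, shared_count) data.frames
#' @export
enrichment_network <- function(results, min_shared = 1, p_cut = 0.01) {
  stopifnot(inherits(results, "enrichment_result"))
  sets <- attr(results, "restricted_sets")
  sig <- results[results$p < p_cut, , drop = FALSE]
  nodes <- data.frame(set = sig$set, size = sig$size, es = sig$es, p = sig$p,
                      row.names = NULL, stringsAsFactors = FALSE)
  edges <- data.frame(source = character(0), target = character(0),
                      shared_count = integer(0), stringsAsFactors = FALSE)
  if (nrow(nodes) >= 2) {
    cmb <- utils::combn(nodes$set, 2)
    shared <- apply(cmb, 2, function(pr) {
      length(intersect(sets[[pr[1]]], sets[[pr[2]]]))
    })
    ok <- shared >= min_shared
    edges <- data.frame(source = cmb[1, ok], target = cmb[2, ok],
                        shared_count = shared[ok],
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  list(nodes = nodes, edges = edges)
}

#' Summarize enrichment across contrasts as signed significance
#'
#' Retains sets significant (p < `p_cut`) in at least `min_contrasts`
#' contrasts; each cell is sign(ES) * -log10(p).
#'
#' @param results_list named list of `enrichment_result` objects, one per
#'   contrast, computed on the same collection
#' @param p_cut per-contrast significance cutoff
#' @param min_contrasts minimum number of significant contrasts
#' @return numeric matrix, retained sets x contrasts
#' @export
cross_comparison_summary <- function(results_list, p_cut = 0.05,
                                     min_contrasts = 2) {
  stopifnot(is.list(results_list), length(results_list) >= 1,
            !is.null(names(results_list)))
  all_sets <- unique(unlist(lapply(results_list, `[[`, "set")))
  sig_count <- integer(length(all_sets))
  mat <- matrix(NA_real_, length(all_sets), length(results_list),
                dimnames = list(all_sets, names(results_list)))
  for (j in seq_along(results_list)) {
    r <- results_list[[j]]
    idx <- match(r$set, all_sets)
    mat[idx, j] <- sign(r$es) * -log10(r$p)
    sig_count[idx] <- sig_count[idx] + (r$p < p_cut)
  }
  mat[sig_count >= min_contrasts, , drop = FALSE]
}
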