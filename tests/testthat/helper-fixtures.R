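# Shared fixtures and independent oracles used across test files.

# small paired expression matrix built by hand: `diffs` gives, per feature,
# the within-patient differences (condition_a - baseline) to embed
make_paired_em <- function(diffs, condition_a = "CAF", baseline = "HPF") {
  diffs <- as.matrix(diffs)
  n_pairs <- ncol(diffs)
  base <- matrix(5, nrow(diffs), n_pairs)
  values <- cbind(base, base + diffs)
  rownames(values) <- if (is.null(rownames(diffs))) {
    sprintf("G%03d", seq_len(nrow(diffs)))
  } else rownames(diffs)
  colnames(values) <- c(paste(baseline, seq_len(n_pairs), sep = "_"),
                        paste(condition_a, seq_len(n_pairs), sep = "_"))
  expression_matrix(values, data.frame(
    sample = colnames(values),
    patient = paste0("P", rep(seq_len(n_pairs), 2)),
    condition = rep(c(baseline, condition_a), each = n_pairs),
    stringsAsFactors = FALSE))
}

# independent brute-force running-sum oracle: literal walk down the list,
# every prefix value computed in a loop, extremum by scanning
oracle_es <- function(scores, hit_idx, p) {
  N <- length(scores)
  nh <- length(hit_idx)
  w <- abs(scores)^p
  nr <- sum(w[hit_idx])
  if (nr == 0) {
    w[] <- 1
    nr <- nh
  }
  run <- numeric(N)
  cur <- 0
  for (j in seq_len(N)) {
    cur <- cur + if (j %in% hit_idx) w[j] / nr else -1 / (N - nh)
    run[j] <- cur
  }
  run[which.max(abs(run))]
}

# default small cohort used where the exact design does not matter
small_cohort <- function(seed = 1, ...) {
  generate_cohort(cohort_design(n_genes = 500, n_mirnas = 60, seed = seed, ...))
}

small_collection <- function(truth, seed = 1, ...) {
  args <- list(truth = truth, n_sets = 12, n_planted = 2, planted_size = 20,
               set_size_range = c(10, 40), seed = seed)
  do.call(generate_geneset_collection, utils::modifyList(args, list(...)))
}
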