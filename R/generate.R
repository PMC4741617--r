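#' Generate a paired multi-omic fibroblast cohort with known ground truth
#'
#' Simulates log2 expression for the gene and miRNA layers of a paired
#' design (every patient contributes one sample per condition), together
#' with a ground-truth ledger naming the planted differentially expressed
#' features, the miRNA-gene latent couplings, and the activated-signature
#' genes. All randomness flows from `design$seed` through named substreams,
#' so an identical design yields bit-identical output and adding a new
#' generator does not perturb existing ones.
#'
#' @param design a [cohort_design()]
#' @return a list with elements `genes` (an `expr_matrix`), `mirnas` (an
#'   `expr_matrix`, or `NULL` when `n_mirnas = 0`) and `truth` (a
#'   `ground_truth` list: `de_genes`, `de_mirnas`, `mirna_gene_links`,
#'   `centroid_genes`, feature universes, and the design itself)
#' @export
generate_cohort <- function(design) {
  if (!inherits(design, "cohort_design")) {
    stop("`design` must be a cohort_design", call. = FALSE)
  }
  conds <- design$conditions
  np <- design$n_patients
  samples <- data.frame(
    sample = as.vector(outer(seq_len(np), conds,
                             function(p, cond) paste(cond, p, sep = "_"))),
    patient = paste0("P", rep(seq_len(np), times = length(conds))),
    condition = rep(conds, each = np),
    stringsAsFactors = FALSE
  )
  ns <- nrow(samples)

  gene_ids <- sprintf("GENE%05d", seq_len(design$n_genes))
  layout_g <- plant_layout(design$n_genes, round(design$frac_shared * design$n_genes),
                           round(design$frac_tgfb * design$n_genes),
                           design$n_latent, design$genes_per_factor)

  # patient-level latent factor scores shared by both layers: equally
  # spaced patient contrasts (unit variance), randomly permuted and
  # signed per factor, scaled by latent_sd. Planting a fixed-magnitude
  # contrast (rather than Gaussian draws) keeps the between-patient
  # variance of every factor at exactly latent_sd^2, so the strength of
  # the miRNA-gene coupling does not fluctuate from seed to seed
  scores <- with_substream(design$seed, "latent", {
    base <- if (np > 1) as.vector(scale(seq_len(np))) else 0
    t(vapply(seq_len(design$n_latent), function(f) {
      design$latent_sd * sample(c(-1, 1), 1) * base[sample(np)]
    }, numeric(np)))
  })
  if (design$n_latent == 0) scores <- matrix(0, 0, np)

  gene_vals <- with_substream(design$seed, "genes", {
    simulate_layer(gene_ids, samples, design, layout_g, scores)
  })

  mirna_vals <- NULL
  layout_m <- NULL
  if (design$n_mirnas > 0) {
    mirna_ids <- sprintf("hsa-miR-%04d", seq_len(design$n_mirnas))
    layout_m <- plant_layout(design$n_mirnas,
                             round(design$frac_mirna_shared * design$n_mirnas),
                             round(design$frac_mirna_tgfb * design$n_mirnas),
                             design$n_latent, design$mirnas_per_factor)
    mirna_vals <- with_substream(design$seed, "mirnas", {
      simulate_layer(mirna_ids, samples, design, layout_m, scores)
    })
  }

  if (!is.null(design$outlier_sample)) {
    with_substream(design$seed, "outlier", {
      j <- match(design$outlier_sample, samples$sample)
      gene_vals[, j] <- gene_vals[, j] +
        rnorm(nrow(gene_vals), sd = 5 * design$noise_sd)
      if (!is.null(mirna_vals)) {
        mirna_vals[, j] <- mirna_vals[, j] +
          rnorm(nrow(mirna_vals), sd = 5 * design$noise_sd)
      }
    })
  }

  truth <- build_truth(design, gene_ids, layout_g,
                       if (is.null(mirna_vals)) NULL else rownames(mirna_vals),
                       layout_m)

  list(
    genes = expression_matrix(gene_vals, samples),
    mirnas = if (is.null(mirna_vals)) NULL else expression_matrix(mirna_vals, samples),
    truth = truth
  )
}

# positions and signs of the planted blocks within one feature layer:
# shared CAF/IL6 block, TGFB-only block, then n_latent disjoint factor blocks
plant_layout <- function(n_feat, n_shared, n_tgfb, n_latent, per_factor) {
  idx <- seq_len(n_feat)
  shared <- head(idx, n_shared)
  tgfb <- idx[seq_len(n_tgfb) + n_shared]
  factor_blocks <- lapply(seq_len(n_latent), function(f) {
    start <- n_shared + n_tgfb + (f - 1L) * per_factor
    idx[start + seq_len(per_factor)]
  })
  list(
    shared = shared, shared_sign = block_signs(length(shared)),
    tgfb = tgfb, tgfb_sign = block_signs(length(tgfb)),
    factors = factor_blocks,
    factor_signs = lapply(factor_blocks, function(b) block_signs(length(b)))
  )
}

simulate_layer <- function(feature_ids, samples, design, layout, scores) {
  n_feat <- length(feature_ids)
  ns <- nrow(samples)
  patient_idx <- as.integer(factor(samples$patient,
                                   levels = unique(samples$patient)))
  baseline <- runif(n_feat, 6, 12)
  intercepts <- matrix(rnorm(n_feat * design$n_patients, sd = design$patient_sd),
                       nrow = n_feat)
  vals <- baseline + intercepts[, patient_idx, drop = FALSE] +
    matrix(rnorm(n_feat * ns, sd = design$noise_sd), nrow = n_feat)

  activated <- samples$condition %in% c("CAF", "IL6")
  if (length(layout$shared) && any(activated)) {
    vals[layout$shared, activated] <- vals[layout$shared, activated] +
      design$effect_size * layout$shared_sign
  }
  tgfb_cols <- samples$condition == "TGFB"
  if (length(layout$tgfb) && any(tgfb_cols)) {
    vals[layout$tgfb, tgfb_cols] <- vals[layout$tgfb, tgfb_cols] +
      design$effect_size * layout$tgfb_sign
  }
  for (f in seq_along(layout$factors)) {
    block <- layout$factors[[f]]
    if (!length(block)) next
    vals[block, ] <- vals[block, ] +
      outer(layout$factor_signs[[f]], scores[f, patient_idx])
  }
  dimnames(vals) <- list(feature_ids, samples$sample)
  vals
}

build_truth <- function(design, gene_ids, layout_g, mirna_ids, layout_m) {
  de_from_layout <- function(ids, layout) {
    shared <- data.frame(feature = ids[layout$shared],
                         effect = design$effect_size * layout$shared_sign,
                         stringsAsFactors = FALSE)
    tgfb <- data.frame(feature = ids[layout$tgfb],
                       effect = design$effect_size * layout$tgfb_sign,
                       stringsAsFactors = FALSE)
    list(CAF = shared, IL6 = shared, TGFB = tgfb)
  }
  links <- NULL
  if (!is.null(mirna_ids) && design$n_latent > 0) {
    links <- do.call(rbind, lapply(seq_len(design$n_latent), function(f) {
      g <- layout_g$factors[[f]]; gs <- layout_g$factor_signs[[f]]
      m <- layout_m$factors[[f]]; ms <- layout_m$factor_signs[[f]]
      grid <- expand.grid(mi = seq_along(m), gi = seq_along(g))
      data.frame(mirna = mirna_ids[m][grid$mi],
                 gene = gene_ids[g][grid$gi],
                 sign = ms[grid$mi] * gs[grid$gi],
                 factor = f, stringsAsFactors = FALSE)
    }))
  }
  structure(list(
    de_genes = de_from_layout(gene_ids, layout_g),
    de_mirnas = if (is.null(mirna_ids)) NULL else de_from_layout(mirna_ids, layout_m),
    mirna_gene_links = links,
    centroid_genes = data.frame(feature = gene_ids[layout_g$shared],
                                sign = layout_g$shared_sign,
                                stringsAsFactors = FALSE),
    genes = gene_ids,
    mirnas = mirna_ids,
    design = design
  ), class = "ground_truth")
}

#' Generate a gene-set collection with planted enriched sets
#'
#' Builds a GMT-style collection over the cohort's gene universe: a few
#' sets composed predominantly (at `planted_purity`, >= 80 percent) of
#' planted up-regulated genes of one contrast, the remainder uniform random
#' draws. Planted sets are created both for the shared CAF/IL6 signature
#' and for the TGFB-only block, so enrichment specificity can be tested.
#'
#' @param truth `ground_truth` from [generate_cohort()]
#' @param n_sets total number of sets
#' @param set_size_range (min, max) size of the random sets
#' @param seed RNG seed
#' @param n_planted planted sets per planted contrast (shared and TGFB)
#' @param planted_size size of each planted set
#' @param planted_purity fraction of each planted set drawn from the
#'   planted up-regulated genes (>= 0.8)
#' @return a named list of character vectors with a `planted` attribute
#'   (data.frame: set, contrast, direction); write with [write_gmt()]
#' @export
generate_geneset_collection <- function(truth, n_sets = 50,
                                        set_size_range = c(20, 100),
                                        seed = 1, n_planted = 5,
                                        planted_size = 50,
                                        planted_purity = 0.8) {
  stopifnot(inherits(truth, "ground_truth"))
  universe <- truth$genes
  if (max(set_size_range) > length(universe) || planted_size > length(universe)) {
    stop("requested set sizes exceed the gene universe", call. = FALSE)
  }
  if (planted_purity < 0.8 || planted_purity > 1) {
    stop_field("planted_purity", "must be in [0.8, 1]")
  }
  shared_up <- truth$de_genes$CAF$feature[truth$de_genes$CAF$effect > 0]
  tgfb_up <- truth$de_genes$TGFB$feature[truth$de_genes$TGFB$effect > 0]
  de_all <- unique(c(truth$de_genes$CAF$feature, truth$de_genes$TGFB$feature))
  background <- setdiff(universe, de_all)

  n_core <- ceiling(planted_purity * planted_size)
  pools <- list(SHARED = shared_up, TGFB = tgfb_up)
  for (nm in names(pools)) {
    if (2 * n_planted > 0 && length(pools[[nm]]) < n_core) {
      stop(sprintf("not enough planted up-regulated %s genes (%d < %d) for the requested sets",
                   nm, length(pools[[nm]]), n_core), call. = FALSE)
    }
  }

  with_substream(seed, "genesets", {
    sets <- list()
    planted <- data.frame(set = character(0), contrast = character(0),
                          direction = character(0), stringsAsFactors = FALSE)
    for (nm in names(pools)) {
      for (i in seq_len(n_planted)) {
        core <- sample(pools[[nm]], n_core)
        filler <- sample(background, planted_size - n_core)
        id <- sprintf("PLANTED_%s_UP_%d", nm, i)
        members <- c(core, filler)
        attr(members, "description") <- sprintf("planted %s up-set", nm)
        sets[[id]] <- members
        planted <- rbind(planted, data.frame(
          set = id, contrast = if (nm == "SHARED") "CAF" else "TGFB",
          direction = "up", stringsAsFactors = FALSE))
      }
    }
    n_random <- n_sets - length(sets)
    if (n_random < 0) stop("`n_sets` smaller than the number of planted sets",
                           call. = FALSE)
    for (i in seq_len(n_random)) {
      size <- sample(seq(set_size_range[1], set_size_range[2]), 1)
      members <- sample(universe, size)
      attr(members, "description") <- "random set"
      sets[[sprintf("RANDOM_%d", i)]] <- members
    }
    attr(sets, "planted") <- planted
    sets
  })
}

#' Generate an external validation dataset expressing the planted signature
#'
#' Emulates a public tumor-stroma dataset on a different platform: an
#' independent baseline per gene, tumor-labelled samples shifted on the
#' activated-signature genes in the planted direction, and only a fraction
#' of the cohort's gene identifiers present (to exercise cross-platform
#' matching).
#'
#' @param truth `ground_truth` from [generate_cohort()]
#' @param n_tumor,n_normal sample counts per group
#' @param overlap fraction of cohort gene ids present in the external
#'   dataset (default 0.9)
#' @param shift log2 shift applied to signature genes in tumor samples
#'   (default: the design's planted effect size)
#' @param noise_sd residual SD (default: the design's)
#' @param seed RNG seed
#' @return an `expr_matrix` with `condition` metadata `"tumor"`/`"normal"`
#' @export
generate_external_dataset <- function(truth, n_tumor = 6, n_normal = 6,
                                      overlap = 0.9,
                                      shift = truth$design$effect_size,
                                      noise_sd = truth$design$noise_sd,
                                      seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  check_count(n_tumor, "n_tumor")
  check_count(n_normal, "n_normal")
  if (overlap <= 0 || overlap > 1) stop_field("overlap", "must be in (0, 1]")
  with_substream(seed, "external", {
    keep <- sort(sample(seq_along(truth$genes), round(overlap * length(truth$genes))))
    ids <- truth$genes[keep]
    ns <- n_tumor + n_normal
    vals <- matrix(runif(length(ids), 5, 11), nrow = length(ids), ncol = ns) +
      matrix(rnorm(length(ids) * ns, sd = noise_sd), nrow = length(ids))
    sig <- match(truth$centroid_genes$feature, ids)
    present <- !is.na(sig)
    vals[sig[present], seq_len(n_tumor)] <-
      vals[sig[present], seq_len(n_tumor)] +
      shift * truth$centroid_genes$sign[present]
    dimnames(vals) <- list(ids, c(paste0("Tumor_", seq_len(n_tumor)),
                                  paste0("Normal_", seq_len(n_normal))))
    samples <- data.frame(
      sample = colnames(vals),
      condition = rep(c("tumor", "normal"), c(n_tumor, n_normal)),
      stringsAsFactors = FALSE
    )
    expression_matrix(vals, samples)
  })
}

#' Generate a qPCR Ct table with a planted fold change and a spike-in
#'
#' Emulates a relative-quantification experiment: target assays, a
#' reference assay and a non-human spike-in measured in control and treated
#' groups over biological replicates with technical replicate wells.
#' Treated target wells are shifted by -log2(`fold_change`) cycles, so the
#' delta-delta-Ct method should recover `fold_change`.
#'
#' @param n_targets number of target assays (TARGET1, ...)
#' @param n_samples biological replicates per group
#' @param spike_ct mean Ct of the spike-in assay (must lie in 15-35)
#' @param seed RNG seed
#' @param fold_change planted expression fold change in the treated group
#' @param base_ct,ref_ct mean target / reference Ct in the control group
#' @param noise_sd per-well Ct noise (cycles)
#' @param n_tech technical replicate wells per (sample, assay)
#' @param fraction_undetermined fraction of target wells reported as
#'   Undetermined (missing Ct)
#' @return a data.frame: sample, group, assay, replicate, ct, undetermined
#' @export
generate_ct_table <- function(n_targets = 2, n_samples = 3, spike_ct = 25,
                              seed = 1, fold_change = 2, base_ct = 28,
                              ref_ct = 20, noise_sd = 0.1, n_tech = 2,
                              fraction_undetermined = 0) {
  check_count(n_targets, "n_targets")
  check_count(n_samples, "n_samples")
  if (spike_ct < 15 || spike_ct > 35) {
    stop_field("spike_ct", "must lie in the plausible range 15-35")
  }
  if (fold_change <= 0) stop_field("fold_change", "must be > 0")
  with_substream(seed, "qpcr", {
    assays <- c(paste0("TARGET", seq_len(n_targets)), "REF", "SPIKE")
    grid <- expand.grid(replicate = seq_len(n_tech), assay = assays,
                        idx = seq_len(n_samples), group = c("control", "treated"),
                        stringsAsFactors = FALSE)
    grid$sample <- paste(grid$group, grid$idx, sep = "_")
    mean_ct <- ifelse(grid$assay == "REF", ref_ct,
               ifelse(grid$assay == "SPIKE", spike_ct,
                      base_ct - ifelse(grid$group == "treated",
                                       log2(fold_change), 0)))
    grid$ct <- mean_ct + rnorm(nrow(grid), sd = noise_sd)
    grid$undetermined <- FALSE
    is_target <- grepl("^TARGET", grid$assay)
    und <- is_target & runif(nrow(grid)) < fraction_undetermined
    grid$ct[und] <- NA_real_
    grid$undetermined[und] <- TRUE
    grid[, c("sample", "group", "assay", "replicate", "ct", "undetermined")]
  })
}
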