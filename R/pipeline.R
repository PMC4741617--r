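# End-to-end orchestration: simulate (or load) -> cluster/outlier screen ->
# paired DE -> enrichment (+ network, cross-comparison) -> centroids ->
# miRNA integration, with a manifest of every output file.

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample columns, Euclidean distance and
#' average linkage by default. Deterministic given the input: equal
#' distances are resolved by the pair order of the distance matrix, i.e.
#' the earliest pair in column-major order merges first.
#'
#' @param em an `expr_matrix`
#' @param metric distance metric (passed to [stats::dist()])
#' @param linkage agglomeration method (passed to [stats::hclust()])
#' @return an `hclust` object over the samples
#' @export
hierarchical_cluster <- function(em, metric = "euclidean",
                                 linkage = "average") {
  stopifnot(inherits(em, "expr_matrix"))
  if (ncol(em$values) < 2) stop("need >= 2 samples to cluster", call. = FALSE)
  if (anyNA(em$values)) stop("missing values: preprocess first", call. = FALSE)
  hclust(dist(t(em$values), method = metric), method = linkage)
}

#' Flag samples that are outliers by median inter-sample correlation
#'
#' A sample is flagged when the median of its correlations to all other
#' samples falls more than `threshold_sd` robust SDs (MAD) below the
#' cohort median of those medians. The robust SD is floored at
#' `scale_floor` correlation units: in highly cohesive cohorts the MAD is
#' near zero and an unfloored rule would flag ordinary patient-to-patient
#' variation. Flags are advisory: removal always requires an explicit
#' entry in the analysis config, mirroring judgment-based outlier
#' exclusion.
#'
#' @param em an `expr_matrix` with >= 4 samples
#' @param threshold_sd robust-SD multiplier (default 3)
#' @param scale_floor minimum robust SD, in correlation units
#' @return character vector of flagged sample ids (possibly empty)
#' @export
flag_outlier_samples <- function(em, threshold_sd = 3, scale_floor = 0.04) {
  stopifnot(inherits(em, "expr_matrix"))
  n <- ncol(em$values)
  if (n < 4) stop("need >= 4 samples to screen for outliers", call. = FALSE)
  cc <- cor(em$values)
  diag(cc) <- NA
  med <- apply(cc, 2, median, na.rm = TRUE)
  cut <- median(med) - threshold_sd * max(mad(med), scale_floor)
  names(med)[med < cut]
}

#' Assemble an analysis configuration
#'
#' Either a [cohort_design()] (simulation mode) or paths to preprocessed
#' log2 TSV matrices with sample metadata. All randomness downstream flows
#' from `seed`.
#'
#' @param design a `cohort_design`, or `NULL` when loading from files
#' @param gene_values,gene_samples,mirna_values,mirna_samples,gmt optional
#'   input file paths (file mode)
#' @param contrasts list of c(condition, baseline) pairs
#' @param B,exponent,scheme enrichment parameters
#' @param centroid_rules named list per contrast condition: list(p_cut,
#'   use_adjusted); the default uses raw p < 0.01 for CAF and IL6 and
#'   adjusted p < 1e-4 for TGFB so the signatures have comparable sizes
#' @param mirna_reference condition whose contrast ranks the reference
#'   miRNA list (default CAF)
#' @param mirna_p_cut miRNA-set selection cutoff
#' @param guide_mirnas miRNAs driving correlation-guided enrichment;
#'   `NULL` picks one linked miRNA per latent factor in simulation mode
#' @param geneset_args arguments for [generate_geneset_collection()]
#'   (simulation mode)
#' @param external_args arguments for [generate_external_dataset()]
#'   (simulation mode); set to `NULL` to skip centroid scoring
#' @param remove_samples sample ids to exclude before analysis (explicit
#'   opt-in; outlier flags never remove anything by themselves)
#' @param top_var optional count: restrict clustering to the most variable
#'   features (off by default)
#' @param seed master seed
#' @param out_dir output directory
#' @return an `analysis_config`
#' @export
analysis_config <- function(design = NULL,
                            gene_values = NULL, gene_samples = NULL,
                            mirna_values = NULL, mirna_samples = NULL,
                            gmt = NULL,
                            contrasts = list(c("CAF", "HPF"),
                                             c("IL6", "HPF"),
                                             c("TGFB", "HPF")),
                            B = 999, exponent = 1, scheme = "set",
                            centroid_rules = list(
                              CAF = list(p_cut = 0.01, use_adjusted = FALSE),
                              IL6 = list(p_cut = 0.01, use_adjusted = FALSE),
                              TGFB = list(p_cut = 1e-4, use_adjusted = TRUE)),
                            mirna_reference = "CAF",
                            mirna_p_cut = 0.05,
                            guide_mirnas = NULL,
                            geneset_args = list(),
                            external_args = list(),
                            remove_samples = character(0),
                            top_var = NULL,
                            seed = 1,
                            out_dir = "stromasig-out") {
  if (is.null(design)) {
    for (f in c("gene_values", "gene_samples")) {
      path <- get(f)
      if (is.null(path) || !file.exists(path)) {
        stop_field(f, "must be an existing file when no design is given")
      }
    }
    if (is.null(gmt) || !file.exists(gmt)) {
      stop_field("gmt", "must be an existing file when no design is given")
    }
  } else if (!inherits(design, "cohort_design")) {
    stop_field("design", "must be a cohort_design")
  }
  check_count(seed, "seed", positive = FALSE)
  structure(list(
    design = design, gene_values = gene_values, gene_samples = gene_samples,
    mirna_values = mirna_values, mirna_samples = mirna_samples, gmt = gmt,
    contrasts = contrasts, B = B, exponent = exponent, scheme = scheme,
    centroid_rules = centroid_rules, mirna_reference = mirna_reference,
    mirna_p_cut = mirna_p_cut, guide_mirnas = guide_mirnas,
    geneset_args = geneset_args, external_args = external_args,
    remove_samples = remove_samples, top_var = top_var,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "analysis_config")
}

stage_log <- function(stage, ...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), stage, ": ", ...)
}

run_stage <- function(stage, fingerprint, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage `%s` failed (input %s): %s", stage, fingerprint,
                 conditionMessage(e)), call. = FALSE)
  })
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# enrichment_result -> flat TSV-friendly table
flatten_enrichment <- function(res) {
  data.frame(set = res$set, size = res$size, es = res$es, nes = res$nes,
             p = res$p, q = res$q,
             leading_edge = vapply(res$leading_edge, paste, character(1),
                                   collapse = ","),
             stringsAsFactors = FALSE)
}

write_graphml <- function(network, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"size\" for=\"node\" attr.name=\"size\" attr.type=\"int\"/>",
    "  <key id=\"es\" for=\"node\" attr.name=\"es\" attr.type=\"double\"/>",
    "  <key id=\"shared\" for=\"edge\" attr.name=\"shared_count\" attr.type=\"int\"/>",
    "  <graph edgedefault=\"undirected\">",
    vapply(seq_len(nrow(network$nodes)), function(i) {
      n <- network$nodes[i, ]
      sprintf("    <node id=\"%s\"><data key=\"size\">%d</data><data key=\"es\">%.6g</data></node>",
              esc(n$set), n$size, n$es)
    }, character(1)),
    vapply(seq_len(nrow(network$edges)), function(i) {
      e <- network$edges[i, ]
      sprintf("    <edge source=\"%s\" target=\"%s\"><data key=\"shared\">%d</data></edge>",
              esc(e$source), esc(e$target), e$shared_count)
    }, character(1)),
    "  </graph>", "</graphml>")
  writeLines(lines, path)
  path
}

#' Run the full analysis end-to-end
#'
#' Simulates (or loads) the cohort, screens for outliers, clusters the
#' samples, fits every configured paired contrast, runs set enrichment
#' with network and cross-comparison summaries, derives and scores
#' centroid signatures, and performs the miRNA integration stages. Every
#' output is a plain-text table under `config$out_dir`, and a JSON
#' manifest lists each file with its MD5 hash, so re-running an identical
#' config reproduces identical bytes.
#'
#' @param config an [analysis_config()]
#' @return (invisibly) a list with the in-memory results and the manifest
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add <- function(path) files[[length(files) + 1]] <<- path

  # --- data ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$design)) {
    stage_log("simulate", "seed ", config$design$seed)
    cohort <- run_stage("simulate", paste0("seed=", config$design$seed), {
      generate_cohort(config$design)
    })
    genes <- cohort$genes; mirnas <- cohort$mirnas; truth <- cohort$truth
    collection <- do.call(generate_geneset_collection,
                          c(list(truth = truth, seed = config$seed),
                            config$geneset_args))
    jsonlite::write_json(
      truth[c("de_genes", "de_mirnas", "mirna_gene_links", "centroid_genes")],
      file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    add(file.path(out, "ground_truth.json"))
  } else {
    stage_log("load", config$gene_values)
    genes <- run_stage("load", config$gene_values, {
      read_expression_tsv(config$gene_values, config$gene_samples)
    })
    mirnas <- NULL
    if (!is.null(config$mirna_values)) {
      mirnas <- read_expression_tsv(config$mirna_values, config$mirna_samples)
    }
    collection <- read_gmt(config$gmt)
  }

  if (length(config$remove_samples)) {
    keep <- setdiff(genes$samples$sample, config$remove_samples)
    genes <- genes[, keep]
    if (!is.null(mirnas)) {
      mirnas <- mirnas[, setdiff(mirnas$samples$sample, config$remove_samples)]
    }
    stage_log("filter", "removed samples: ",
              paste(config$remove_samples, collapse = ", "))
  }

  add(write_expression_tsv(genes, file.path(out, "gene_matrix.tsv"),
                           file.path(out, "gene_samples.tsv"))[1])
  add(file.path(out, "gene_samples.tsv"))
  add(write_gmt(collection, file.path(out, "genesets.gmt")))

  # --- unsupervised -------------------------------------------------------
  cl_input <- genes
  if (!is.null(config$top_var)) {
    v <- apply(genes$values, 1, var)
    keep <- names(sort(v, decreasing = TRUE))[seq_len(config$top_var)]
    cl_input <- genes[keep, ]
  }
  dend <- run_stage("cluster", "gene matrix", hierarchical_cluster(cl_input))
  add(write_tsv(data.frame(merge1 = dend$merge[, 1], merge2 = dend$merge[, 2],
                           height = dend$height),
                file.path(out, "dendrogram_merges.tsv")))
  add(write_tsv(data.frame(order = dend$order, label = dend$labels[dend$order]),
                file.path(out, "dendrogram_leaves.tsv")))
  flags <- run_stage("outliers", "gene matrix", flag_outlier_samples(genes))
  add(write_tsv(data.frame(sample = if (length(flags)) flags else character(0)),
                file.path(out, "outlier_flags.tsv")))

  # --- differential expression & enrichment -------------------------------
  de <- list(); enr <- list()
  for (ct in config$contrasts) {
    key <- paste(ct[1], ct[2], sep = "_vs_")
    stage_log("de", key)
    de[[ct[1]]] <- run_stage("de", key, run_paired_de(genes, ct[1], ct[2]))
    add(write_tsv(as.data.frame(de[[ct[1]]]),
                  file.path(out, paste0("de_", key, ".tsv"))))
    ranked <- rank_features(de[[ct[1]]])
    add(write_tsv(ranked, file.path(out, paste0("ranked_", key, ".tsv"))))
    stage_log("enrich", key, " (B=", config$B, ")")
    enr[[ct[1]]] <- run_stage("enrich", key, {
      permutation_significance(ranked, collection, B = config$B,
                               scheme = config$scheme, seed = config$seed,
                               exponent = config$exponent,
                               em = genes, condition_a = ct[1],
                               condition_b = ct[2])
    })
    add(write_tsv(flatten_enrichment(enr[[ct[1]]]),
                  file.path(out, paste0("enrichment_", key, ".tsv"))))
    net <- enrichment_network(enr[[ct[1]]])
    add(write_tsv(net$edges, file.path(out, paste0("network_", key, ".tsv"))))
    add(write_graphml(net, file.path(out, paste0("network_", key, ".graphml"))))
  }
  cc <- cross_comparison_summary(enr)
  add(write_tsv(data.frame(set = rownames(cc), cc, check.names = FALSE),
                file.path(out, "cross_comparison.tsv")))

  # --- centroid signatures ------------------------------------------------
  score_mat <- NULL
  if (!is.null(config$external_args) &&
      (!is.null(truth) || !is.null(config$external_args$external))) {
    centroids <- list()
    for (cond in names(config$centroid_rules)) {
      if (!cond %in% names(de)) next
      rule <- config$centroid_rules[[cond]]
      centroids[[cond]] <- run_stage("centroid", cond, {
        derive_centroid(de[[cond]], genes, cond, p_cut = rule$p_cut,
                        use_adjusted = rule$use_adjusted)
      })
    }
    external <- if (!is.null(config$external_args$external)) {
      config$external_args$external
    } else {
      do.call(generate_external_dataset,
              c(list(truth = truth, seed = config$seed),
                config$external_args))
    }
    score_mat <- run_stage("signatures", "external dataset", {
      centroid_score_matrix(centroids, external)
    })
    add(write_tsv(data.frame(centroid = rownames(score_mat), score_mat,
                             check.names = FALSE),
                  file.path(out, "centroid_scores.tsv")))
  } else {
    stage_log("signatures", "no external dataset configured: stage skipped")
  }

  # --- miRNA integration --------------------------------------------------
  mirna_out <- NULL
  if (!is.null(mirnas)) {
    add(write_expression_tsv(mirnas, file.path(out, "mirna_matrix.tsv"),
                             file.path(out, "mirna_samples.tsv"))[1])
    add(file.path(out, "mirna_samples.tsv"))
    ref_cond <- config$mirna_reference
    mirna_de <- list()
    for (ct in config$contrasts) {
      mirna_de[[ct[1]]] <- run_stage("mirna_de", ct[1],
                                     run_paired_de(mirnas, ct[1], ct[2]))
    }
    ref_ranked <- rank_features(mirna_de[[ref_cond]])
    set_results <- list(); coherence <- list()
    for (cond in setdiff(names(mirna_de), ref_cond)) {
      for (dir in c("up", "down")) {
        key <- paste0(cond, "_", dir)
        ms <- tryCatch(define_mirna_set(mirna_de[[cond]], dir,
                                        config$mirna_p_cut),
                       error = function(e) NULL)
        if (is.null(ms)) {
          stage_log("mirna_sets", key, ": empty set, skipped")
          next
        }
        res <- tryCatch(test_mirna_set(ms, ref_ranked, B = config$B,
                                       seed = config$seed,
                                       exponent = config$exponent),
                        error = function(e) NULL)
        if (is.null(res)) {
          stage_log("mirna_sets", key, ": too few members in universe, skipped")
          next
        }
        res$set <- key
        set_results[[key]] <- res
        coherence[[key]] <- coherence_table(ms, mirna_de[[ref_cond]])
        add(write_tsv(coherence[[key]],
                      file.path(out, paste0("coherence_", key, ".tsv"))))
      }
    }
    if (length(set_results)) {
      add(write_tsv(do.call(rbind, lapply(set_results, flatten_enrichment)),
                    file.path(out, "mirna_set_enrichment.tsv")))
    }
    guides <- config$guide_mirnas
    if (is.null(guides) && !is.null(truth) &&
        !is.null(truth$mirna_gene_links)) {
      guides <- unique(tapply(truth$mirna_gene_links$mirna,
                              truth$mirna_gene_links$factor, `[`, 1))
    }
    guided <- list()
    for (g in guides) {
      ranked_g <- run_stage("mirna_corr", g, {
        correlate_genes_with_mirna(genes, mirnas, g)
      })
      guided[[g]] <- run_stage("mirna_enrich", g, {
        mirna_guided_enrichment(ranked_g, collection, B = config$B,
                                seed = config$seed,
                                exponent = config$exponent)
      })
    }
    if (length(guided)) {
      gm <- mirna_enrichment_matrix(guided)
      add(write_tsv(data.frame(set = rownames(gm), gm, check.names = FALSE),
                    file.path(out, "mirna_guided_enrichment.tsv")))
    }
    mirna_out <- list(de = mirna_de, sets = set_results,
                      coherence = coherence, guided = guided)
  } else {
    stage_log("mirna", "no miRNA matrix configured: miRNA stages skipped")
  }

  # --- manifest -----------------------------------------------------------
  files <- unlist(files)
  manifest <- list(
    package = "stromasig",
    version = as.character(utils::packageVersion("stromasig")),
    seed = config$seed,
    config = config[setdiff(names(config), c("design", "external_args"))],
    design = if (!is.null(config$design)) unclass(config$design),
    outputs = data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stage_log("done", length(files), " output files in ", out)
  invisible(list(genes = genes, mirnas = mirnas, truth = truth,
                 de = de, enrichment = enr, cross_comparison = cc,
                 centroid_scores = score_mat, mirna = mirna_out,
                 dendrogram = dend, outlier_flags = flags,
                 manifest = manifest))
}
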