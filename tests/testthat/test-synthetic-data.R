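# Cohort generator: determinism, planted structure, and the invariants the
# downstream recovery tests rely on.

test_that("identical designs produce bit-identical cohorts", {
  d <- cohort_design(n_genes = 200, n_mirnas = 30, seed = 11)
  a <- generate_cohort(d)
  b <- generate_cohort(d)
  expect_identical(a$genes$values, b$genes$values)
  expect_identical(a$mirnas$values, b$mirnas$values)
  expect_identical(a$truth$de_genes, b$truth$de_genes)
  # a different seed changes the data
  d2 <- cohort_design(n_genes = 200, n_mirnas = 30, seed = 12)
  expect_false(identical(generate_cohort(d2)$genes$values, a$genes$values))
})

test_that("cohort dimensions follow the design arithmetic", {
  co <- small_cohort(seed = 2)
  expect_equal(dim(co$genes$values), c(500, 12))
  expect_equal(dim(co$mirnas$values), c(60, 12))
  expect_setequal(unique(co$genes$samples$condition),
                  c("HPF", "CAF", "IL6", "TGFB"))
  expect_equal(as.vector(table(co$genes$samples$patient)), rep(4L, 3))
})

test_that("design validation names the offending field", {
  expect_error(cohort_design(n_patients = 0), "n_patients")
  expect_error(cohort_design(noise_sd = -1), "noise_sd")
  expect_error(cohort_design(conditions = c("CAF", "IL6")), "conditions")
  expect_error(cohort_design(outlier_sample = "nope"), "outlier_sample")
  expect_error(cohort_design(n_genes = 10), "n_genes")
})

test_that("planted condition effects are recovered by direct averaging", {
  d <- cohort_design(n_genes = 1000, n_mirnas = 0, effect_size = 2.0,
                     noise_sd = 0.1, seed = 5)
  co <- generate_cohort(d)
  tr <- co$truth$de_genes$CAF
  up <- tr$feature[tr$effect > 0]
  caf <- co$genes$samples$sample[co$genes$samples$condition == "CAF"]
  hpf <- co$genes$samples$sample[co$genes$samples$condition == "HPF"]
  gap <- mean(rowMeans(co$genes$values[up, caf]) -
                rowMeans(co$genes$values[up, hpf]))
  expect_lt(abs(gap - 2.0), 0.2)
  # the shared effect is identical in IL6, absent in TGFB
  il6 <- co$genes$samples$sample[co$genes$samples$condition == "IL6"]
  tgfb <- co$genes$samples$sample[co$genes$samples$condition == "TGFB"]
  expect_lt(abs(mean(rowMeans(co$genes$values[up, il6]) -
                       rowMeans(co$genes$values[up, hpf])) - 2.0), 0.2)
  expect_lt(abs(mean(rowMeans(co$genes$values[up, tgfb]) -
                       rowMeans(co$genes$values[up, hpf]))), 0.2)
})

test_that("gene set collections have the requested composition", {
  co <- small_cohort(seed = 3)
  coll <- small_collection(co$truth, seed = 4)
  expect_length(coll, 12)
  planted <- attr(coll, "planted")
  expect_equal(nrow(planted), 4)
  up_genes <- co$truth$de_genes$CAF$feature[co$truth$de_genes$CAF$effect > 0]
  share <- mean(coll[["PLANTED_SHARED_UP_1"]] %in% up_genes)
  expect_gte(share, 0.8)
  expect_error(small_collection(co$truth, set_size_range = c(10, 600)),
               "exceed")
  # GMT round trip
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path)
  expect_identical(lapply(back, as.character), lapply(coll, as.character))
})

test_that("external datasets express the planted signature in tumors", {
  co <- small_cohort(seed = 6)
  ext <- generate_external_dataset(co$truth, n_tumor = 6, n_normal = 6,
                                   overlap = 1.0, seed = 7)
  expect_equal(ncol(ext$values), 12)
  expect_true(all(co$truth$centroid_genes$feature %in% rownames(ext$values)))
  sig <- co$truth$centroid_genes
  tum <- ext$samples$sample[ext$samples$condition == "tumor"]
  nor <- ext$samples$sample[ext$samples$condition == "normal"]
  gap <- mean((rowMeans(ext$values[sig$feature, tum]) -
                 rowMeans(ext$values[sig$feature, nor])) * sig$sign)
  expect_lt(abs(gap - co$truth$design$effect_size), 0.3)
  # partial overlap drops identifiers
  ext9 <- generate_external_dataset(co$truth, overlap = 0.9, seed = 7)
  expect_equal(nrow(ext9$values), round(0.9 * 500))
})

test_that("Ct tables are deterministic and respect the undetermined fraction", {
  a <- generate_ct_table(seed = 9, fraction_undetermined = 0)
  b <- generate_ct_table(seed = 9, fraction_undetermined = 0)
  expect_identical(a, b)
  expect_false(any(a$undetermined))
  expect_false(anyNA(a$ct))
  c_tab <- generate_ct_table(seed = 9, fraction_undetermined = 1)
  expect_true(all(c_tab$undetermined[grepl("TARGET", c_tab$assay)]))
  expect_error(generate_ct_table(spike_ct = 10), "spike_ct")
})

test_that("miRNA-gene latent coupling carries the planted correlation sign", {
  hits <- 0L
  total <- 0L
  for (seed in 1:10) {
    co <- generate_cohort(cohort_design(n_genes = 300, n_mirnas = 40,
                                        seed = seed))
    links <- co$truth$mirna_gene_links
    links <- links[seq(1, nrow(links), length.out = 20), ]
    for (i in seq_len(nrow(links))) {
      r <- cor(co$genes$values[links$gene[i], ],
               co$mirnas$values[links$mirna[i], ])
      hits <- hits + (sign(r) == links$sign[i])
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("shared CAF/IL6 activation drives per-patient clustering", {
  ok <- 0L
  for (seed in 1:20) {
    co <- generate_cohort(cohort_design(n_genes = 500, n_mirnas = 0,
                                        effect_size = 1.5, seed = seed))
    dmat <- as.matrix(dist(t(co$genes$values)))
    diag(dmat) <- Inf
    good <- TRUE
    for (p in 1:3) {
      caf <- paste0("CAF_", p)
      il6 <- paste0("IL6_", p)
      good <- good && (names(which.min(dmat[caf, ])) == il6 ||
                         names(which.min(dmat[il6, ])) == caf)
    }
    ok <- ok + good
  }
  expect_gte(ok, 18)
})

test_that("outlier corruption adds large noise to the designated sample", {
  d_clean <- cohort_design(n_genes = 300, n_mirnas = 30, seed = 4)
  d_out <- cohort_design(n_genes = 300, n_mirnas = 30, seed = 4,
                         outlier_sample = "CAF_1")
  clean <- generate_cohort(d_clean)
  out <- generate_cohort(d_out)
  changed <- out$genes$values[, "CAF_1"] - clean$genes$values[, "CAF_1"]
  expect_gt(sd(changed), 1.5)  # 5 x noise_sd = 2.5, allow sampling slack
  untouched <- setdiff(colnames(clean$genes$values), "CAF_1")
  expect_identical(out$genes$values[, untouched],
                   clean$genes$values[, untouched])
})
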