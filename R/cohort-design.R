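#' Describe a synthetic paired fibroblast cohort
#'
#' Captures the design of the emulated study: a small number of patients,
#' each contributing one fibroblast sample per condition (baseline HPF,
#' patient-derived CAF, and the two in-vitro activations IL6 and TGFB).
#' The generative model is additive on the log2 scale:
#' value = baseline + patient intercept + condition effect
#'       + latent-factor loading + Gaussian noise.
#'
#' A designated block of genes (and of miRNAs) carries one shared
#' activation coefficient applied to both the CAF and IL6 conditions; a
#' disjoint block carries a TGFB-only coefficient. Patient intercepts are
#' gene-specific and shared across the four samples of a patient, which is
#' what drives per-patient clustering when they dominate the noise. Latent
#' factors are patient-level programs on which disjoint blocks of genes and
#' miRNAs load with signed unit weights; they couple the two layers
#' without confounding within-patient contrasts.
#'
#' @param n_patients number of patients (default 3)
#' @param conditions ordered condition labels; must contain the baseline
#'   `"HPF"`; the shared activation applies to `"CAF"` and `"IL6"`, the
#'   independent effect to `"TGFB"` (conditions absent from the design are
#'   simply not simulated)
#' @param n_genes,n_mirnas number of gene / miRNA features
#' @param patient_sd standard deviation of gene-specific per-patient random
#'   intercepts (log2 units)
#' @param noise_sd residual standard deviation (log2 units)
#' @param effect_size planted condition effect (log2 units); applied with
#'   sign +1 to the first half of each planted block and -1 to the second
#' @param frac_shared,frac_tgfb fraction of genes in the shared CAF/IL6
#'   block and the TGFB-only block
#' @param frac_mirna_shared,frac_mirna_tgfb same for the miRNA layer
#' @param n_latent number of patient-level latent factors coupling the two
#'   layers
#' @param genes_per_factor,mirnas_per_factor features loading on each factor
#' @param latent_sd standard deviation of latent factor scores
#' @param outlier_sample optional sample label (e.g. `"CAF_1"`) to corrupt
#'   with large independent noise (5 x `noise_sd`)
#' @param seed master RNG seed; fully determines the generated cohort
#' @return an object of class `cohort_design`
#' @export
cohort_design <- function(n_patients = 3,
                          conditions = c("HPF", "CAF", "IL6", "TGFB"),
                          n_genes = 2000,
                          n_mirnas = 300,
                          patient_sd = 0.5,
                          noise_sd = 0.5,
                          effect_size = 1.0,
                          frac_shared = 0.10,
                          frac_tgfb = 0.10,
                          frac_mirna_shared = 0.10,
                          frac_mirna_tgfb = 0.05,
                          n_latent = 3,
                          genes_per_factor = 20,
                          mirnas_per_factor = 5,
                          latent_sd = 2.0,
                          outlier_sample = NULL,
                          seed = 1) {
  check_count(n_patients, "n_patients")
  if (!is.character(conditions) || length(conditions) < 2 ||
      anyDuplicated(conditions)) {
    stop_field("conditions", "must be >= 2 distinct labels")
  }
  if (!"HPF" %in% conditions) {
    stop_field("conditions", "must contain the baseline label \"HPF\"")
  }
  check_count(n_genes, "n_genes")
  check_count(n_mirnas, "n_mirnas", positive = FALSE)
  check_sd(patient_sd, "patient_sd")
  check_sd(noise_sd, "noise_sd")
  if (!is.numeric(effect_size) || length(effect_size) != 1L || is.na(effect_size)) {
    stop_field("effect_size", "must be a single number")
  }
  for (f in c("frac_shared", "frac_tgfb", "frac_mirna_shared", "frac_mirna_tgfb")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 0.5) stop_field(f, "must be in [0, 0.5]")
  }
  check_count(n_latent, "n_latent", positive = FALSE)
  check_count(genes_per_factor, "genes_per_factor")
  check_count(mirnas_per_factor, "mirnas_per_factor")
  check_sd(latent_sd, "latent_sd")
  check_count(seed, "seed", positive = FALSE)
  design <- list(
    n_patients = as.integer(n_patients), conditions = conditions,
    n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
    patient_sd = patient_sd, noise_sd = noise_sd, effect_size = effect_size,
    frac_shared = frac_shared, frac_tgfb = frac_tgfb,
    frac_mirna_shared = frac_mirna_shared, frac_mirna_tgfb = frac_mirna_tgfb,
    n_latent = as.integer(n_latent),
    genes_per_factor = as.integer(genes_per_factor),
    mirnas_per_factor = as.integer(mirnas_per_factor),
    latent_sd = latent_sd,
    outlier_sample = outlier_sample, seed = as.integer(seed)
  )
  n_blocks <- round(frac_shared * n_genes) + round(frac_tgfb * n_genes) +
    n_latent * genes_per_factor
  if (n_blocks > n_genes) {
    stop_field("n_genes", "too small for the requested planted blocks")
  }
  if (n_mirnas > 0) {
    m_blocks <- round(frac_mirna_shared * n_mirnas) +
      round(frac_mirna_tgfb * n_mirnas) + n_latent * mirnas_per_factor
    if (m_blocks > n_mirnas) {
      stop_field("n_mirnas", "too small for the requested planted blocks")
    }
  }
  sample_ids <- as.vector(outer(seq_len(n_patients), conditions,
                                function(p, cond) paste(cond, p, sep = "_")))
  if (!is.null(outlier_sample) && !outlier_sample %in% sample_ids) {
    stop_field("outlier_sample", "does not name a sample of this design")
  }
  structure(design, class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    "cohort_design: %d patients x %d conditions (%s)\n%d genes, %d miRNAs, effect %.2g, noise sd %.2g, patient sd %.2g, seed %d\n",
    x$n_patients, length(x$conditions), paste(x$conditions, collapse = ", "),
    x$n_genes, x$n_mirnas, x$effect_size, x$noise_sd, x$patient_sd, x$seed))
  invisible(x)
}

# signed block assignment: +1 for the first half, -1 for the rest
block_signs <- function(n) {
  if (n == 0) return(integer(0))
  c(rep(1L, ceiling(n / 2)), rep(-1L, n - ceiling(n / 2)))
}
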