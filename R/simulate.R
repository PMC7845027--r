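#' Specification for a synthetic FPKM compendium
#'
#' Describes a multi-experiment RNA-seq compendium with planted stability
#' structure: a handful of truly stable, abundant genes (the screening
#' targets), a tier of housekeeping-like genes that are stable on average
#' but noisy in a few experiments (the classical pitfall the screen must
#' reject under simultaneous thresholds), and a variable background.
#' Defaults emulate a compendium of nine developmental experiments of
#' eight stages each.
#'
#' @param n_genes Total number of genes.
#' @param n_experiments Number of independent experiments (default 9).
#' @param samples_per_experiment Samples per experiment (default 8, one per
#'   developmental stage).
#' @param n_planted_stable Number of planted stable genes (default 9).
#' @param planted_cv_target Within-experiment CV of planted genes
#'   (default 0.08).
#' @param planted_log2_mean_fpkm log2 of the planted genes' mean FPKM
#'   (default `log2(300)`).
#' @param hkg_like_count Housekeeping-like genes (default 15).
#' @param hkg_cv_range Within-experiment CV of housekeeping-like genes in
#'   their quiet experiments (default `c(0.08, 0.12)`).
#' @param hkg_elevated_cv_range Their CV in the `hkg_elevated_experiments`
#'   experiments where they misbehave (default `c(0.25, 0.45)`).
#' @param hkg_elevated_experiments How many experiments per
#'   housekeeping-like gene are noisy (default 2).
#' @param background_cv_range Per-gene CV range of background genes
#'   (default `c(0.35, 0.65)`, centred on 0.5).
#' @param background_log_mean,background_log_sd Log-normal parameters (on
#'   the natural-log scale) of background gene mean FPKM.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000,
                           n_experiments = 9,
                           samples_per_experiment = 8,
                           n_planted_stable = 9,
                           planted_cv_target = 0.08,
                           planted_log2_mean_fpkm = log2(300),
                           hkg_like_count = 15,
                           hkg_cv_range = c(0.08, 0.12),
                           hkg_elevated_cv_range = c(0.25, 0.45),
                           hkg_elevated_experiments = 2,
                           background_cv_range = c(0.35, 0.65),
                           background_log_mean = log(50),
                           background_log_sd = 1.5,
                           seed = 42) {
  spec <- list(n_genes = n_genes, n_experiments = n_experiments,
               samples_per_experiment = samples_per_experiment,
               n_planted_stable = n_planted_stable,
               planted_cv_target = planted_cv_target,
               planted_log2_mean_fpkm = planted_log2_mean_fpkm,
               hkg_like_count = hkg_like_count,
               hkg_cv_range = hkg_cv_range,
               hkg_elevated_cv_range = hkg_elevated_cv_range,
               hkg_elevated_experiments = hkg_elevated_experiments,
               background_cv_range = background_cv_range,
               background_log_mean = background_log_mean,
               background_log_sd = background_log_sd,
               seed = as.integer(seed))
  stopifnot(n_genes >= 1, n_experiments >= 1, samples_per_experiment >= 2,
            n_planted_stable >= 0, hkg_like_count >= 0,
            n_planted_stable + hkg_like_count <= n_genes,
            planted_cv_target > 0, all(hkg_cv_range > 0),
            all(background_cv_range > 0),
            2 ^ planted_log2_mean_fpkm >= 100)
  class(spec) <- "synthetic_spec"
  spec
}

# Deterministic per-gene substream seed: reproducibility must not depend on
# the order genes are visited in. Knuth multiplicative hash, kept < 2^31.
gene_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 2654435) %% 2147483647)
}

# Log-normal draw with exact (mean, CV) control: sigma_ln = sqrt(ln(1+CV^2))
rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate an FPKM compendium with planted stability classes
#'
#' Per gene and experiment, samples are drawn from a log-normal
#' distribution with the gene's class-specific mean and CV (the log-scale
#' SD is `sqrt(log(1 + CV^2))`, so mean and CV are controlled exactly in
#' expectation). Gene classes, in row order: `stable` (constant mean >= 100,
#' low CV in every experiment), `hkg_like` (low CV in most experiments,
#' elevated CV in a random few), `background` (log-normal means, CV around
#' 0.5). Which experiments are elevated, and all per-gene parameters, come
#' from a per-gene substream so the output is invariant to iteration order.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `matrix` (an [expression_matrix()]), `truth`
#'   (data.frame gene_id, class) and `spec`.
#' @export
simulate_fpkm <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(n))
  classes <- rep("background", n)
  if (spec$n_planted_stable > 0)
    classes[seq_len(spec$n_planted_stable)] <- "stable"
  if (spec$hkg_like_count > 0)
    classes[spec$n_planted_stable + seq_len(spec$hkg_like_count)] <-
      "hkg_like"
  ne <- spec$n_experiments
  ns <- spec$samples_per_experiment
  sample_ids <- sprintf("E%02d_S%02d", rep(seq_len(ne), each = ns),
                        rep(seq_len(ns), ne))
  expt <- stats::setNames(sprintf("E%02d", rep(seq_len(ne), each = ns)),
                          sample_ids)
  vals <- matrix(0, n, ne * ns, dimnames = list(gene_ids, sample_ids))
  for (i in seq_len(n)) {
    set.seed(gene_seed(spec$seed, i))
    cls <- classes[i]
    if (cls == "stable") {
      mu <- rep(2 ^ spec$planted_log2_mean_fpkm, ne)
      cv <- rep(spec$planted_cv_target, ne)
    } else if (cls == "hkg_like") {
      mu <- rep(exp(stats::runif(1, log(150), log(400))), ne)
      cv <- stats::runif(ne, spec$hkg_cv_range[1], spec$hkg_cv_range[2])
      hot <- sample(ne, min(spec$hkg_elevated_experiments, ne))
      cv[hot] <- stats::runif(length(hot), spec$hkg_elevated_cv_range[1],
                              spec$hkg_elevated_cv_range[2])
    } else {
      mu <- rep(stats::rlnorm(1, spec$background_log_mean,
                              spec$background_log_sd), ne)
      cv <- rep(stats::runif(1, spec$background_cv_range[1],
                             spec$background_cv_range[2]), ne)
    }
    for (e in seq_len(ne))
      vals[i, (e - 1) * ns + seq_len(ns)] <- rlnorm_mean_cv(ns, mu[e], cv[e])
  }
  list(matrix = expression_matrix(vals, expt),
       truth = data.frame(gene_id = gene_ids, class = classes,
                          stringsAsFactors = FALSE),
       spec = spec)
}

#' Specification for a synthetic replicated Ct table
#'
#' The Cq model, in cycle space:
#' `ct = base + sample_effect + trend * (stage - 1) - log2(fold) + noise`,
#' with a shared Gaussian per-sample effect (e.g. input-RNA loading),
#' an optional per-gene linear drift across developmental stages, an
#' optional planted fold-change profile (the biology a target gene carries;
#' a 4-fold induction lowers Ct by 2 cycles), and i.i.d. Gaussian replicate
#' noise. Defaults emulate a 16-sample validation panel (8 stages x 2
#' cultivars) measured in 4 biological replicates.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples (default 16).
#' @param replicates Biological replicates per (gene, sample) (default 4).
#' @param n_stages Number of developmental stages; samples cycle through
#'   stages in blocks (default 8, two cultivar blocks of 8 when
#'   `n_samples = 16`).
#' @param base_ct Per-gene baseline Ct; scalar, vector, or `NULL` to draw
#'   uniformly in `[24, 30]` per gene.
#' @param sample_effect_sd SD (cycles) of the shared per-sample effect.
#' @param noise_sd Per-gene replicate noise SD (cycles); scalar or vector.
#' @param stage_trend Per-gene linear drift in cycles per stage (scalar or
#'   vector; 0 = no drift).
#' @param fold_profile Optional genes x samples matrix (or named list of
#'   per-sample vectors) of planted expression fold changes; default all 1.
#' @param stable_sd_max Noise SD at or below which a no-trend gene is
#'   truth-labelled `stable` (default 0.2 cycles).
#' @param gene_ids Optional character vector of gene names (default
#'   `gene01` ...).
#' @param seed Integer seed.
#' @return A list of class `ct_sim_spec`.
#' @export
ct_sim_spec <- function(n_genes = 6,
                        n_samples = 16,
                        replicates = 4,
                        n_stages = 8,
                        base_ct = NULL,
                        sample_effect_sd = 0.15,
                        noise_sd = 0.3,
                        stage_trend = 0,
                        fold_profile = NULL,
                        stable_sd_max = 0.2,
                        gene_ids = NULL,
                        seed = 42) {
  stopifnot(n_genes >= 1, n_samples >= 1, replicates >= 2,
            n_stages >= 1, sample_effect_sd >= 0, all(noise_sd >= 0))
  if (!is.null(gene_ids)) stopifnot(length(gene_ids) == n_genes,
                                    !anyDuplicated(gene_ids))
  spec <- list(n_genes = n_genes, n_samples = n_samples,
               replicates = replicates, n_stages = n_stages,
               base_ct = base_ct, sample_effect_sd = sample_effect_sd,
               noise_sd = rep_len(noise_sd, n_genes),
               stage_trend = rep_len(stage_trend, n_genes),
               fold_profile = fold_profile,
               stable_sd_max = stable_sd_max,
               gene_ids = gene_ids, seed = as.integer(seed))
  class(spec) <- "ct_sim_spec"
  spec
}

#' Simulate a replicated Ct table
#'
#' @param spec A [ct_sim_spec()].
#' @return A list with `ct` (a [ct_table()]), `truth` (data.frame gene_id,
#'   class, noise_sd, stage_trend), `sample_effect` (the drawn per-sample
#'   shifts), and `spec`. Truth classes: `drifting` if the stage trend is
#'   nonzero, else `stable` when `noise_sd <= stable_sd_max`, else
#'   `unstable`.
#' @export
simulate_ct <- function(spec) {
  stopifnot(inherits(spec, "ct_sim_spec"))
  n <- spec$n_genes
  gene_ids <- spec$gene_ids %||% sprintf("gene%02d", seq_len(n))
  sample_ids <- sprintf("S%02d", seq_len(spec$n_samples))
  stage_idx <- ((seq_len(spec$n_samples) - 1) %% spec$n_stages)
  set.seed(gene_seed(spec$seed, 0L))
  base <- spec$base_ct %||% stats::runif(n, 24, 30)
  base <- rep_len(base, n)
  sample_effect <- stats::rnorm(spec$n_samples, 0, spec$sample_effect_sd)
  fold <- matrix(1, n, spec$n_samples,
                 dimnames = list(gene_ids, sample_ids))
  if (!is.null(spec$fold_profile)) {
    fp <- spec$fold_profile
    if (is.list(fp)) {
      for (g in names(fp)) fold[g, ] <- rep_len(fp[[g]], spec$n_samples)
    } else fold[rownames(fp), ] <- fp
  }
  if (any(fold <= 0)) stop("fold profile must be strictly positive")
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(gene_seed(spec$seed, i))
    mu <- base[i] + sample_effect + spec$stage_trend[i] * stage_idx -
      log2(fold[i, ])
    eps <- matrix(stats::rnorm(spec$n_samples * spec$replicates, 0,
                               spec$noise_sd[i]),
                  spec$n_samples, spec$replicates)
    rec[[i]] <- data.frame(
      gene_id = gene_ids[i],
      sample_id = rep(sample_ids, spec$replicates),
      replicate = rep(seq_len(spec$replicates), each = spec$n_samples),
      ct = as.vector(mu + eps),
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rec)
  truth <- data.frame(
    gene_id = gene_ids,
    class = ifelse(spec$stage_trend != 0, "drifting",
                   ifelse(spec$noise_sd <= spec$stable_sd_max,
                          "stable", "unstable")),
    noise_sd = spec$noise_sd, stage_trend = spec$stage_trend,
    stringsAsFactors = FALSE)
  list(ct = ct_table(rec), truth = truth, sample_effect = sample_effect,
       spec = spec)
}
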