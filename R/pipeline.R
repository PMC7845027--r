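#' Default pipeline configuration
#'
#' A fully synthetic end-to-end configuration: a nine-experiment FPKM
#' compendium with planted stable genes for the screen, a replicated Cq
#' panel over the screened candidates with two near-noiseless genes (the
#' planted best reference pair) and noisier partners, and a planted target
#' gene with a stage-dependent induction for the delta-delta-Cq validation.
#'
#' @param seed Integer master seed for every stochastic stage.
#' @return A nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 42) {
  list(
    seed = as.integer(seed),
    synthetic = list(
      fpkm = list(n_genes = 500, n_experiments = 9,
                  samples_per_experiment = 8, n_planted_stable = 9,
                  hkg_like_count = 15),
      ct = list(replicates = 4, n_samples = 16, n_stages = 8,
                sample_effect_sd = 0.1,
                low_noise_sd = c(0.05, 0.08), other_noise_sd = 0.5,
                target = list(gene_id = "target01", noise_sd = 0.1,
                              base_ct = 27,
                              fold_stage_profile =
                                c(1, 1, 0.8, 1, 2, 4, 3.5, 3)))),
    screening = list(mode = "simultaneous", fpkm_min = 100, cv_max = 0.15),
    stability = list(bestkeeper_dispersion = "sd"),
    aggregation = list(distance = "footrule", rho = 0.1,
                       smoothing_w = 0.25, max_iter = 1000,
                       convergence_window = 15),
    pv = list(threshold = 0.15))
}

read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

merge_defaults <- function(cfg, def) {
  for (k in names(def)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- def[[k]]
    else if (is.list(def[[k]]) && is.list(cfg[[k]]))
      cfg[[k]] <- merge_defaults(cfg[[k]], def[[k]])
  }
  cfg
}

pipeline_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full reference-gene discovery and validation pipeline
#'
#' Stages, in workflow order: (1) obtain or simulate the FPKM compendium
#' and replicated Cq panel; (2) screen the compendium (simultaneous
#' per-experiment thresholds by default); (3) quality-control candidate Ct
#' levels (mean Ct must lie in (15, 30)); (4) score candidates with the
#' four-method stability panel; (5) merge the four rankings by
#' cross-entropy rank aggregation; (6) run the geNorm iterative ranking
#' and pairwise-variation series to fix the optimal number n of reference
#' genes; (7) recommend the top n consensus genes and, when a target gene
#' is configured, validate reference choices by delta-delta-Cq
#' normalization and Pearson concordance.
#'
#' @param config A config list (see [default_pipeline_config()]) or a path
#'   to a YAML/JSON file with the same structure. Omitted entries fall
#'   back to defaults.
#' @param outdir Optional output directory; when given, [write_report()]
#'   is called on the result.
#' @param seed Optional override of the config seed.
#' @param verbose Emit stage progress via `message()` (default `FALSE`).
#' @return A `pipeline_report` list: `screening`, `ct_qc`, `stability`,
#'   `consensus`, `genorm`, `pv`, `recommended`, `normalization`,
#'   `concordance`, `truth` (when synthetic), and `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir = NULL,
                         seed = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- merge_defaults(config, default_pipeline_config())
  if (!is.null(seed)) config$seed <- as.integer(seed)
  seed <- config$seed

  ## -- stage 1: data ------------------------------------------------------
  truth <- list()
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (p in unlist(inp[c("expression", "sample_sheet", "ct")]))
      if (!is.null(p) && !file.exists(p))
        stop("input stage: no such file: ", p)
    sheet <- read_sample_sheet(inp$sample_sheet)
    em <- read_expression_matrix(inp$expression, sheet)
    ct <- read_ct_table(inp$ct, efficiencies = inp$efficiencies,
                        sample_info = sheet)
    target_gene <- config$normalization$target
  } else {
    fs <- do.call(synthetic_spec,
                  c(config$synthetic$fpkm, list(seed = seed)))
    sim <- simulate_fpkm(fs)
    em <- sim$matrix
    truth$fpkm <- sim$truth
    pipeline_log(verbose, "simulate", "FPKM compendium: %d genes, %d samples",
                 nrow(em$values), ncol(em$values))
  }

  ## -- stage 2: screening -------------------------------------------------
  scr_cfg <- config$screening
  screening <- if (identical(scr_cfg$mode, "mean"))
    screen_mean(em, scr_cfg$fpkm_min, scr_cfg$cv_max)
  else
    screen_simultaneous(em, scr_cfg$fpkm_min, scr_cfg$cv_max)
  candidates <- screening$pass
  pipeline_log(verbose, "screen", "%d candidate genes pass (%s)",
               length(candidates), screening$mode)
  if (length(candidates) < 3)
    stop("screening stage: fewer than 3 candidates survive")

  ## -- synthetic Cq panel over the candidates -----------------------------
  if (is.null(config$inputs)) {
    ctc <- config$synthetic$ct
    tg <- ctc$target
    k <- length(candidates)
    noise <- c(rep_len(ctc$low_noise_sd, min(2, k)),
               rep(ctc$other_noise_sd, max(0, k - 2)))
    gene_ids <- c(candidates, tg$gene_id)
    fold <- NULL
    if (!is.null(tg$fold_stage_profile)) {
      per_sample <- tg$fold_stage_profile[
        ((seq_len(ctc$n_samples) - 1) %% ctc$n_stages) + 1]
      fold <- stats::setNames(list(per_sample), tg$gene_id)
    }
    # candidate baselines drawn from a dedicated substream of the master seed
    set.seed(gene_seed(seed, 999L))
    base <- c(stats::runif(k, 25, 29), tg$base_ct)
    cs <- ct_sim_spec(n_genes = k + 1, n_samples = ctc$n_samples,
                      replicates = ctc$replicates, n_stages = ctc$n_stages,
                      base_ct = base,
                      sample_effect_sd = ctc$sample_effect_sd,
                      noise_sd = c(noise, tg$noise_sd),
                      fold_profile = fold, gene_ids = gene_ids,
                      seed = seed + 1L)
    csim <- simulate_ct(cs)
    ct <- csim$ct
    truth$ct <- csim$truth
    target_gene <- tg$gene_id
  }

  ## -- stage 3: Ct QC -----------------------------------------------------
  ct_mat <- collapse_replicates(ct)
  qc <- ct_qc(ct_mat)
  panel <- setdiff(intersect(candidates, qc$gene_id[!qc$flagged]),
                   target_gene)
  if (length(panel) < 3)
    stop("ct_qc stage: fewer than 3 candidates remain after QC")
  pipeline_log(verbose, "ct_qc", "%d of %d candidates pass Ct QC",
               length(panel), length(candidates))

  ## -- stage 4: stability panel ------------------------------------------
  stab <- stability_panel(ct_mat, panel,
                          groups = config$stability$groups,
                          bestkeeper_dispersion =
                            config$stability$bestkeeper_dispersion)

  ## -- stage 5: consensus ranking ----------------------------------------
  agg <- config$aggregation
  lists <- build_ranked_lists(stab)
  consensus <- aggregate_ce(lists, distance = agg$distance, rho = agg$rho,
                            smoothing_w = agg$smoothing_w,
                            max_iter = agg$max_iter,
                            convergence_window = agg$convergence_window,
                            seed = seed + 2L)
  pipeline_log(verbose, "aggregate", "consensus: %s (phi = %g)",
               paste(consensus$ranking, collapse = " > "), consensus$phi)

  ## -- stage 6: optimal number of reference genes -------------------------
  q <- ct_to_quantities(ct_mat[panel, , drop = FALSE])
  gn <- genorm_rank(q, panel)
  pv <- pv_series(q, gn, threshold = config$pv$threshold)
  n_opt <- min(pv$optimal_n, length(panel))
  recommended <- consensus$ranking[seq_len(n_opt)]
  pipeline_log(verbose, "optimal-n", "optimal n = %d; recommended: %s",
               n_opt, paste(recommended, collapse = " + "))

  ## -- stage 7: delta-delta-Cq validation ---------------------------------
  normalization <- NULL; concordance <- NULL
  if (!is.null(target_gene) && target_gene %in% rownames(ct_mat)) {
    schemes <- c(list(recommended = recommended),
                 stats::setNames(as.list(panel), panel))
    schemes <- schemes[!duplicated(schemes)]
    cal <- config$normalization$calibrator
    normalization <- lapply(schemes, function(refs)
      relative_expression(ct_mat, target_gene, refs, calibrator = cal))
    concordance <- compare_normalizations(ct_mat, target_gene, schemes,
                                          reference_scheme = "recommended",
                                          calibrator = cal)
  }

  manifest <- list(package = "refstab",
                   version = as.character(utils::packageVersion("refstab")),
                   seed = seed,
                   config = config[setdiff(names(config), "inputs")],
                   inputs = config$inputs,
                   n_candidates = length(candidates),
                   panel = panel, recommended = recommended,
                   optimal_n = n_opt)
  report <- structure(list(screening = screening, ct_qc = qc,
                           stability = stab, consensus = consensus,
                           genorm = gn, pv = pv, recommended = recommended,
                           normalization = normalization,
                           concordance = concordance, truth = truth,
                           ct_matrix = ct_mat, manifest = manifest),
                      class = "pipeline_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d candidates -> optimal n = %d: %s\n",
              x$manifest$n_candidates, x$manifest$optimal_n,
              paste(x$recommended, collapse = " + ")))
  invisible(x)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer,
                                                      logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write a pipeline report to disk
#'
#' Emits a fixed file set: `screening.tsv`, `stability.tsv`,
#' `consensus.tsv`, `pv_series.tsv`, `normalization.tsv`,
#' `concordance.tsv` and `manifest.json`. Sections absent from the report
#' still produce a file with a header row only, so downstream consumers
#' can rely on the file set. Numeric columns carry 17 significant digits;
#' reruns with an identical config and seed are byte-identical.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_tsv(report$screening$per_gene, p("screening.tsv"))
  write_tsv(as.data.frame(report$stability), p("stability.tsv"))
  write_tsv(data.frame(rank = seq_along(report$consensus$ranking),
                       gene_id = report$consensus$ranking,
                       phi = report$consensus$phi,
                       distance = report$consensus$distance),
            p("consensus.tsv"))
  write_tsv(data.frame(n = report$pv$series$n, v = report$pv$series$v,
                       threshold = report$pv$threshold,
                       optimal_n = report$pv$optimal_n),
            p("pv_series.tsv"))
  if (is.null(report$normalization)) {
    writeLines("scheme\tsample_id\trelative_expression",
               p("normalization.tsv"))
  } else {
    rows <- do.call(rbind, lapply(names(report$normalization), function(s) {
      r <- report$normalization[[s]]
      data.frame(scheme = s, sample_id = names(r$relative),
                 relative_expression = as.numeric(r$relative),
                 stringsAsFactors = FALSE)
    }))
    write_tsv(rows, p("normalization.tsv"))
  }
  if (is.null(report$concordance)) {
    writeLines("scheme_a\tscheme_b\tpearson_r", p("concordance.tsv"))
  } else {
    cc <- report$concordance
    idx <- expand.grid(a = rownames(cc), b = colnames(cc),
                       stringsAsFactors = FALSE)
    write_tsv(data.frame(scheme_a = idx$a, scheme_b = idx$b,
                         pearson_r = as.numeric(cc[cbind(idx$a, idx$b)])),
              p("concordance.tsv"))
  }
  jsonlite::write_json(report$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(outdir)
}
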