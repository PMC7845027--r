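#!/usr/bin/env Rscript
# Generate the synthetic study data: a nine-experiment FPKM compendium with
# planted stable / housekeeping-like / background genes, and a replicated
# 16-sample Cq panel over the planted candidates plus a stage-induced
# target gene. Everything downstream (02-06) reads the files written here.

suppressPackageStartupMessages(library(refstab))
seed <- 42
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

fpkm_spec <- synthetic_spec(n_genes = 2000, n_experiments = 9,
                            samples_per_experiment = 8,
                            n_planted_stable = 9, hkg_like_count = 15,
                            seed = seed)
sim <- simulate_fpkm(fpkm_spec)
write_expression_matrix(sim$matrix, file.path(outdir, "fpkm.tsv"))
sheet <- data.frame(sample_id = colnames(sim$matrix$values),
                    experiment = unname(sim$matrix$experiment),
                    cultivar = "synthetic",
                    stage = sprintf("T%d", rep(1:8, 9)),
                    group = "", replicate = 1L)
write_sample_sheet(sheet, file.path(outdir, "sample_sheet.csv"))
write.table(sim$truth, file.path(outdir, "fpkm_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# Cq panel: planted stable genes (two of them near-noiseless) + target with
# a ripening-like induction peaking at stage 6.
stable <- sim$truth$gene_id[sim$truth$class == "stable"]
k <- length(stable)
fold <- c(1, 1, 0.8, 1, 2, 4, 3.5, 3)
set.seed(seed)
ct_spec <- ct_sim_spec(
  n_genes = k + 1, n_samples = 16, replicates = 4, n_stages = 8,
  base_ct = c(runif(k, 25, 29), 27),
  sample_effect_sd = 0.1,
  noise_sd = c(0.05, 0.08, rep(0.5, k - 2), 0.1),
  fold_profile = stats::setNames(list(rep(fold, 2)), "target01"),
  gene_ids = c(stable, "target01"), seed = seed + 1L)
csim <- simulate_ct(ct_spec)
write_ct_table(csim$ct, file.path(outdir, "ct.csv"),
               file.path(outdir, "efficiencies.csv"))
write.table(csim$truth, file.path(outdir, "ct_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
yaml::write_yaml(list(seed = seed,
                      fpkm = fpkm_spec[!vapply(fpkm_spec, is.null,
                                               logical(1))],
                      ct = ct_spec[!vapply(ct_spec, is.null, logical(1))]),
                 file.path(outdir, "simulation_spec.yaml"))

message(sprintf("FPKM compendium: %d genes x %d samples (9 experiments)",
                nrow(sim$matrix$values), ncol(sim$matrix$values)))
message(sprintf("planted stable genes: %s", paste(stable, collapse = ", ")))
message(sprintf("Cq panel: %d genes x 16 samples x 4 replicates; ",
                k + 1),
        "target01 carries a 4-fold induction peaking at stage 6")
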