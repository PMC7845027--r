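#!/usr/bin/env Rscript
# Merge rankings into consensus orders by cross-entropy Monte-Carlo rank
# aggregation (Spearman footrule objective): (a) the nine per-experiment
# CV rank lists from the RNA-seq compendium, restricted to the screened
# candidates; (b) the four stability-method rankings from the Cq panel.
# Small panels are cross-checked against the exact brute-force optimum.

suppressPackageStartupMessages(library(refstab))
seed <- 42
outdir <- "results/consensus"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

sheet <- read_sample_sheet("results/data/sample_sheet.csv")
em <- read_expression_matrix("results/data/fpkm.tsv", sheet)
candidates <- readLines("results/screening/candidates.txt")

cv_lists <- cv_rank_lists(em, candidates)
cons_rna <- aggregate_ce(cv_lists, "footrule", seed = seed)
exact_rna <- if (length(candidates) <= 8)
  aggregate_brute(cv_lists, "footrule") else NULL

st <- read.delim("results/stability/stability.tsv")
class(st) <- c("stability_table", "data.frame")
rl <- build_ranked_lists(st)
cons_qpcr <- aggregate_ce(rl, "footrule", seed = seed + 1L)
exact_qpcr <- if (nrow(st) <= 8) aggregate_brute(rl, "footrule") else NULL

write.table(data.frame(rank = seq_along(cons_rna$ranking),
                       gene_id = cons_rna$ranking, phi = cons_rna$phi),
            file.path(outdir, "consensus_rnaseq.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(rank = seq_along(cons_qpcr$ranking),
                       gene_id = cons_qpcr$ranking, phi = cons_qpcr$phi),
            file.path(outdir, "consensus_qpcr.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("RNA-seq consensus (9 CV lists, %d candidates): %s",
                length(candidates),
                paste(cons_rna$ranking, collapse = " > ")))
if (is.null(exact_rna)) {
  best_input <- min(vapply(cv_lists$lists, function(l)
    sum(vapply(cv_lists$lists, function(o)
      footrule_distance(l, o), numeric(1))), numeric(1)))
  message(sprintf("  CE phi = %g (panel too large for exhaustive check; best input list phi = %g)",
                  cons_rna$phi, best_input))
} else {
  message(sprintf("  CE phi = %g; exact brute-force phi = %g%s",
                  cons_rna$phi, exact_rna$phi,
                  if (cons_rna$phi <= exact_rna$phi + 1e-9)
                    " (CE attains the optimum)" else " (CE SUBOPTIMAL)"))
}
message(sprintf("qPCR consensus (4 method lists): %s",
                paste(cons_qpcr$ranking, collapse = " > ")))
if (is.null(exact_qpcr)) {
  message(sprintf("  CE phi = %g (panel too large for exhaustive check)",
                  cons_qpcr$phi))
} else {
  message(sprintf("  CE phi = %g; exact phi = %g%s", cons_qpcr$phi,
                  exact_qpcr$phi,
                  if (cons_qpcr$phi <= exact_qpcr$phi + 1e-9)
                    " (CE attains the optimum)" else " (CE SUBOPTIMAL)"))
}
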