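#!/usr/bin/env Rscript
# Determine how many reference genes normalization needs: run the geNorm
# iterative exclusion ranking on the Cq panel, then the pairwise-variation
# series V_n between normalization factors built from the n and n+1 best
# genes. The smallest n with V_n < 0.15 is the recommended panel size.

suppressPackageStartupMessages(library(refstab))
outdir <- "results/consensus"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

ct <- read_ct_table("results/data/ct.csv", "results/data/efficiencies.csv")
candidates <- readLines("results/screening/candidates.txt")
m <- collapse_replicates(ct)
panel <- setdiff(candidates, "target01")
q <- ct_to_quantities(m[panel, ])

gr <- genorm_rank(q, panel)
pv <- pv_series(q, gr, threshold = 0.15)

write.table(gr$ranking, file.path(outdir, "genorm_ranking.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(gr$m_steps, file.path(outdir, "genorm_m_steps.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(pv$series, threshold = pv$threshold,
                  optimal_n = pv$optimal_n),
            file.path(outdir, "pv_series.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

consensus <- read.delim(file.path(outdir, "consensus_qpcr.tsv"))
recommended <- consensus$gene_id[seq_len(min(pv$optimal_n,
                                             nrow(consensus)))]
writeLines(recommended, file.path(outdir, "recommended.txt"))

message("geNorm ranking (best first): ",
        paste(gr$ranking$gene_id, collapse = " > "))
message(sprintf("pairwise variation: %s",
                paste(sprintf("V%d/%d = %.3f", pv$series$n,
                              pv$series$n + 1, pv$series$v),
                      collapse = ", ")))
message(sprintf("optimal number of reference genes: %d (cutoff 0.15)",
                pv$optimal_n))
message("recommended reference set: ",
        paste(recommended, collapse = " + "))
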