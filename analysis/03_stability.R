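#!/usr/bin/env Rscript
# Score the screened candidates on the Cq panel: abundance QC (mean Ct must
# lie in (15, 30)), pooled Ct descriptives, and the four-method stability
# panel (geNorm M, NormFinder stability, BestKeeper SD/CV%/r, delta-Ct).

suppressPackageStartupMessages(library(refstab))
datadir <- "results/data"
outdir <- "results/stability"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

ct <- read_ct_table(file.path(datadir, "ct.csv"),
                    file.path(datadir, "efficiencies.csv"))
candidates <- readLines("results/screening/candidates.txt")
m <- collapse_replicates(ct)

qc <- ct_qc(m)
write.table(qc, file.path(outdir, "ct_qc.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
desc <- ct_descriptives(m)
write.table(desc, file.path(outdir, "ct_descriptives.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

panel <- setdiff(intersect(candidates, qc$gene_id[!qc$flagged]), "target01")
st <- stability_panel(m, panel)
write.table(as.data.frame(st), file.path(outdir, "stability.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("Ct QC: %d of %d panel genes flagged (%s)",
                sum(qc$flagged), nrow(qc),
                paste(qc$gene_id[qc$flagged], collapse = ", ")))
message(sprintf("candidate mean Ct range: %.2f - %.2f cycles",
                min(desc$mean_ct), max(desc$mean_ct)))
best <- st$gene_id[order(st$genorm_rank)][1:2]
message("stability panel over ", nrow(st), " candidates; geNorm top-2: ",
        paste(best, collapse = ", "))
message("per-method most stable gene: ",
        paste(sprintf("%s=%s", c("genorm", "normfinder", "bestkeeper",
                                 "deltact"),
                      c(st$gene_id[st$genorm_rank == 1],
                        st$gene_id[st$normfinder_rank == 1],
                        st$gene_id[st$bestkeeper_rank == 1],
                        st$gene_id[st$deltact_rank == 1])),
              collapse = ", "))
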