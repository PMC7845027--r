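#!/usr/bin/env Rscript
# Screen the compendium for candidate reference genes, two ways:
# MEAN   — thresholds on per-experiment statistics averaged across
#          experiments (FPKM >= 100, CV <= 0.2): the lenient housekeeping
#          screen; the planted housekeeping-like tier survives it.
# SIMULTANEOUS — thresholds in every experiment at once (FPKM >= 100,
#          CV <= 0.15): the stringent screen; only the planted stable
#          genes should survive.

suppressPackageStartupMessages(library(refstab))
datadir <- "results/data"
outdir <- "results/screening"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

sheet <- read_sample_sheet(file.path(datadir, "sample_sheet.csv"))
em <- read_expression_matrix(file.path(datadir, "fpkm.tsv"), sheet)
truth <- read.delim(file.path(datadir, "fpkm_truth.tsv"))

mr <- screen_mean(em, fpkm_min = 100, cv_max = 0.2)
sr <- screen_simultaneous(em, fpkm_min = 100, cv_max = 0.15)

write.table(mr$per_gene, file.path(outdir, "screen_mean.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sr$per_gene, file.path(outdir, "screen_simultaneous.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(sr$pass, file.path(outdir, "candidates.txt"))
venn <- data.frame(experiment = names(sr$pass_sets),
                   n_pass = lengths(sr$pass_sets))
write.table(venn, file.path(outdir, "venn_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cls <- function(ids) table(factor(truth$class[truth$gene_id %in% ids],
                                  levels = c("stable", "hkg_like",
                                             "background")))
message(sprintf("MEAN screen: %d genes pass; by truth class: %s",
                length(mr$pass),
                paste(names(cls(mr$pass)), cls(mr$pass), sep = "=",
                      collapse = ", ")))
message(sprintf("SIMULTANEOUS screen: %d genes pass; by truth class: %s",
                length(sr$pass),
                paste(names(cls(sr$pass)), cls(sr$pass), sep = "=",
                      collapse = ", ")))
message("per-experiment pass-set sizes (Venn strata): ",
        paste(venn$n_pass, collapse = ", "))
stable <- truth$gene_id[truth$class == "stable"]
if (setequal(sr$pass, stable)) {
  message("the stringent screen recovered exactly the planted stable genes")
} else {
  message("WARNING: stringent screen did not recover the planted set exactly")
}
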