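#!/usr/bin/env Rscript

## Filter, normalize and replicate-average both genotype cohorts: genes with
## any zero are dropped, samples are scaled by median-of-ratios size
## factors, and replicates are averaged per timepoint for the decomposition.

suppressMessages(library(rhythmpencil))
out <- "results"
grid <- sampling_grid()

for (geno in c("control", "knockout")) {
  raw <- read_expression_matrix(file.path(out, paste0(geno, "_raw.tsv")), grid)
  kept <- filter_zero_genes(raw)
  sf <- size_factors(kept)
  norm <- normalize_matrix(kept, sf)
  avg <- average_replicates(norm, grid)

  write_expression_tsv(norm, file.path(out, paste0(geno, "_normalized.tsv")))
  utils::write.table(
    data.frame(sample = names(sf), size_factor = sf),
    file.path(out, paste0(geno, "_sizefactors.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  df <- data.frame(gene_id = rownames(avg), avg, check.names = FALSE)
  utils::write.table(df, file.path(out, paste0(geno, "_averaged.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d of %d genes kept; size factors in [%.3f, %.3f]",
                  geno, nrow(kept), nrow(raw), min(sf), max(sf)))
}
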