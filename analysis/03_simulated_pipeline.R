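#!/usr/bin/env Rscript
# Full pipeline rehearsal on a synthetic lark-like mitogenome.
#
# Simulates an order-C genome (complete CR1 with conserved boxes,
# rCR2 = 5NR + 4 x 37 nt tandem units + 3NR) with the 3' end of the
# 3NR planted at the rrnS 5' end, writes it in the public file
# formats, reads it back, and runs every stage: gene-order
# classification, tandem-repeat decomposition, the seven-pattern
# homology scan, and composition statistics.
#
# Writes results/sim/*, results/scan_hits.tsv, results/composition.tsv.

suppressMessages(library(larkCR))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 1, order_type = "C", plant_rrns_overlap = TRUE,
                  cr2_spec = list(substitution_rate = 0))
paths <- write_simulation(cfg, "results/sim")
genome <- read_mitogenome(paths$fasta, paths$annotation)
cat("Simulated genome:", genome$id, "-", genome$length, "bp,",
    nrow(genome$features), "features\n")

ord <- extract_gene_order(genome)
cat("Extracted order classifies as", classify_gene_order(ord), "\n")

res <- scan_cr2_origin(genome, "rCR2")
dec <- res$decomposition
cat(sprintf("rCR2 decomposition: 5NR %d nt | %d units, period %d | 3NR %d nt\n",
            nchar(dec$five_nr), length(dec$units), dec$call$period,
            nchar(dec$three_nr)))
cat("Seven patterns scanned against the genome (rCR2 excluded):\n")
if (nrow(res$hits)) {
  print(res$hits[, c("pattern", "strand", "target_start", "target_end",
                     "identity_pct", "columns", "overlapping_features")],
        row.names = FALSE)
  cat("The 3NR aligns at 100% identity to the rrnS 5' end - the planted\n",
      "analogue of the homology observed in A. gulgula; no other region\n",
      "of the genome matches any rCR2-derived pattern.\n")
} else {
  cat("no hits above thresholds\n")
}
write.table(res$hits[, 1:8], "results/scan_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

comp <- composition_report(genome)
comp$at_content <- round(comp$at_content, 1)
comp$at_skew <- round(comp$at_skew, 3)
comp$gc_skew <- round(comp$gc_skew, 3)
write.table(comp, "results/composition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nComposition by partition (simulated sequence is unbiased, so\n",
    "skews hover near 0 - the statistics, not avian base bias, are\n",
    "what this rehearsal exercises):\n")
print(comp, row.names = FALSE)

rscu <- suppressWarnings(compute_rscu(
  vapply(genome$features$name[genome$features$kind == "PCG"],
         function(g) gene_sequence(genome, g), "")))
write.table(rscu, "results/rscu.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nwrote results/scan_hits.tsv, results/composition.tsv, results/rscu.tsv\n")
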