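#!/usr/bin/env Rscript
# Repeat-unit haplotype analysis of the lark rCR2 arrays.
#
# Decodes the per-species repeat-unit haplotypes from the bundled
# consensus/difference-mask table, computes pairwise local-alignment
# similarity (EMBOSS-water scoring: +5/-4, gap 10/0.5), flags divergent
# initial units and subunit-fusion signatures, counts the shared AAAG
# motif, and scores each unit's Watson-Crick pairing potential.
#
# Writes results/repeat_unit_summary.tsv and results/unit_folding.tsv.

suppressMessages(library(larkCR))
dir.create("results", showWarnings = FALSE)

tab <- suppressWarnings(read_repeat_unit_table())

rows <- list()
fold_rows <- list()
for (sp in names(tab)) {
  haps <- tab[[sp]]$haplotypes
  # the M. mongolica array is tiled by the combined H_1+H_2 unit (plus
  # a truncated copy); H_1/H_2 are its subunits, analysed via the
  # fusion signature below
  units <- if (sp == "Melanocorypha_mongolica")
    haps[c("H_1+H_2", "H_3")] else haps
  rs <- repeat_unit_set(units)
  cons <- if (sp == "Melanocorypha_mongolica")
    haps[["H_1+H_2"]] else tab[[sp]]$reference
  cons <- gsub("-", "", cons)
  rows[[sp]] <- data.frame(
    species = sp,
    n_haplotypes = length(haps),
    consensus_len = nchar(cons),
    min_sim = if (is.null(rs$min_sim)) NA else round(rs$min_sim, 1),
    max_sim = if (is.null(rs$max_sim)) NA else round(rs$max_sim, 1),
    excluded = paste(names(rs$excluded)[rs$excluded], collapse = ","),
    divergent_initial = rs$divergent_initial,
    fusion_hamming = if (is.null(detect_subunit_fusion(cons))) NA_integer_
      else detect_subunit_fusion(cons)$hamming,
    aaag_count = count_motif(cons, "AAAG"))
  for (h in names(haps)) {
    one <- fold_score(haps[[h]])
    two <- fold_score(strrep(haps[[h]], 2))
    fold_rows[[paste(sp, h)]] <- data.frame(
      species = sp, haplotype = h, length = nchar(haps[[h]]),
      pairs_one_unit = one$pairs, pairs_two_units = two$pairs)
  }
}
summary <- do.call(rbind, rows)
folding <- do.call(rbind, fold_rows)
write.table(summary, "results/repeat_unit_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(folding, "results/unit_folding.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Per-species repeat-unit similarity (percent of alignment columns):\n")
print(summary[, c("species", "min_sim", "max_sim", "divergent_initial",
                  "fusion_hamming", "aaag_count")], row.names = FALSE)

mm <- tab$Melanocorypha_mongolica$haplotypes
cat(sprintf("\nH_1 vs H_2 differ at %d of %d sites; their concatenation is\n",
            hamming(mm[["H_1"]], mm[["H_2"]]), nchar(mm[["H_1"]])),
    sprintf("the %d-nt combined repeat unit found in M. mongolica.\n",
            nchar(mm[["H_1+H_2"]])))
h2_alone <- fold_score(mm[["H_2"]])$pairs
h2_comb <- fold_score(mm[["H_1+H_2"]])$pairs
cat(sprintf("H_2 alone pairs %d bases; combined with H_1 it pairs %d —\n",
            h2_alone, h2_comb),
    "the poorly folding half gains structure inside the fused unit.\n")
cat("\nDivergent first units (A. arvensis, A. razae, C. cinerea) are\n",
    "excluded from similarity, matching how the published ranges are\n",
    "computed; terminal truncations are kept (local alignment trims them).\n")
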