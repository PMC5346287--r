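#!/usr/bin/env Rscript
# Stage 5: presentation-layer outputs -- clustered heat-map matrices of the
# pause propensity and of -S log10(p), an occupancy-filtered candidate list
# against a synthetic occupancy table, and a synonymous-SNP report for a
# variant placed on one of the generated sequences.

suppressPackageStartupMessages(library(bicodonbias))

index <- enumerate_bicodons()
stats <- read_stats_tsv("results/bicodon_classified.tsv")

orders <- cluster_axes(heatmap_matrix(stats, "pi", index))
hm_pi <- export_heatmap(stats, "pi", orders, "results/heatmap_pi.tsv", index)
hm_lp <- export_heatmap(stats, "signed_logp", orders,
                        "results/heatmap_signed_logp.tsv", index)
cat("heat maps written (61 sense P rows clustered; 192 stop-P cells masked)\n")

# synthetic occupancy table: seeded lognormal noise so the filter has
# something realistic to bite on; real analyses substitute a ribosome
# profiling summary here
set.seed(31)
occ <- data.frame(bicodon = index$bicodon,
                  occupancy = round(rlnorm(nrow(index), log(0.02), 0.5), 5))
write_stats_tsv(occ, "results/occupancy_synthetic.tsv",
                "synthetic cumulative ribosome occupancy per bicodon")
cand <- occupancy_candidates(stats, occ)
write_stats_tsv(cand[, c("bicodon", "dipeptide", "pi", "p_value",
                         "occupancy", "category")],
                "results/occupancy_candidates.tsv",
                "bicodons with pi > 0.75, p < 0.01, occupancy > 0.03")
cat(sprintf("occupancy-filtered pause candidates: %d\n", nrow(cand)))

# synonymous-SNP report on a sequence carrying the planted GTA-CGA pair
low <- read_cds_fasta("results/sample_low.fasta")
hit <- regexpr("GTACGA", low$nt)
i <- which(hit > 0 & (hit %% 3) == 1)[1]
if (!is.na(i)) {
  pos <- (hit[i] - 1) %/% 3 + 1   # codon position of the GTA
  snp <- snp_effect(low[i, ], pos, "GTG", stats,
                    counts = count_sample(low, index))
  print(snp)
}
cat("done; all stage outputs are under results/\n")
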