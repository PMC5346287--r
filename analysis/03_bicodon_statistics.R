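#!/usr/bin/env Rscript
# Stage 3: count codons and bicodons in both samples and compute the full
# per-bicodon statistics: relative synonymous bicodon usage, the pause
# propensity pi = RSBU_L - RSBU_H, the Fisher exact p-value on the
# synonymous-group contingency table, and the chi-squared residuals against
# the amino-acid-pair-normalized single-codon expectation.

suppressPackageStartupMessages(library(bicodonbias))

index <- enumerate_bicodons()
low <- read_cds_fasta("results/sample_low.fasta")
high <- read_cds_fasta("results/sample_high.fasta")
counts_l <- count_sample(low, index)
counts_h <- count_sample(high, index)

cat(sprintf("low : %d codons, %d bicodons\n", counts_l$n_tot, counts_l$n_p))
cat(sprintf("high: %d codons, %d bicodons\n", counts_h$n_tot, counts_h$n_p))

counts_tab <- data.frame(dipeptide = index$dipeptide,
                         bicodon = index$bicodon,
                         o_L = as.numeric(counts_l$o),
                         o_H = as.numeric(counts_h$o))
write_stats_tsv(counts_tab, "results/bicodon_counts.tsv",
                "observed bicodon counts per sample")

stats <- bicodon_stats(counts_l, counts_h, index)
write_stats_tsv(stats, "results/bicodon_stats.tsv",
                "per-bicodon bias statistics")

cat(sprintf("bicodons with p < 0.01: %d of %d (%.2f%%)\n",
            sum(stats$p_value < 0.01), nrow(stats),
            100 * mean(stats$p_value < 0.01)))
top <- stats[order(stats$p_value), c("bicodon", "dipeptide", "o_L", "o_H",
                                     "pi", "p_value")]
cat("strongest differential usage:\n")
print(head(top, 5), row.names = FALSE)
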