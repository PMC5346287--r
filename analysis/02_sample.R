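#!/usr/bin/env Rscript
# Stage 2: select the two 500-sequence samples -- lowest and highest protein
# abundance -- with matched length distributions, by walking the
# abundance-ordered list and accepting each candidate with Gaussian
# probability exp(-(l - l_o)^2 / (2 sigma)).

suppressPackageStartupMessages(library(bicodonbias))

abund <- read_abundance_table("results/abundance.tsv")
abund <- dedupe_isoforms(abund)

low <- select_length_matched(abund, sampler_config(500, "low", seed = 11))
high <- select_length_matched(abund, sampler_config(500, "high", seed = 12))
write_abundance_table(low, "results/sample_low.tsv")
write_abundance_table(high, "results/sample_high.tsv")

seqs <- read_cds_fasta("results/proteome.fasta")
seqs <- join_sequences_abundance(seqs, abund)
pick <- function(sel) {
  out <- seqs[match(sel$id, seqs$id), ]
  class(out) <- c("cds_set", "data.frame")
  out
}
write_cds_fasta(pick(low), "results/sample_low.fasta")
write_cds_fasta(pick(high), "results/sample_high.fasta")

pooled_sd <- sd(abund$cds_length)
cat(sprintf("low : %d seqs, abundance median %.3g, mean length %.0f nt\n",
            nrow(low), median(low$abundance), mean(low$cds_length)))
cat(sprintf("high: %d seqs, abundance median %.3g, mean length %.0f nt\n",
            nrow(high), median(high$abundance), mean(high$cds_length)))
cat(sprintf("|mean length difference| = %.2f nt = %.3f pooled SD\n",
            abs(mean(low$cds_length) - mean(high$cds_length)),
            abs(mean(low$cds_length) - mean(high$cds_length)) / pooled_sd))
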