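# Shared fixtures: tiny sequence sets and independent oracles.

# Brute-force two-sided Fisher p-values for one margin set, enumerated with
# stats::dhyper (independent of the package's log-factorial path).
# Returns the p-value for every admissible first cell.
oracle_hyper_pvals <- function(r1, r2, t, rel_tol = 1e-7) {
  lo <- max(0L, t - r2)
  hi <- min(r1, t)
  k <- lo:hi
  pr <- dhyper(k, r1, r2, t)
  ord <- order(pr)
  cs <- cumsum(pr[ord])
  pmin(1, cs[findInterval(pr * (1 + rel_tol), pr[ord])])
}

# Draw one element of a vector (immune to sample()'s scalar expansion).
pick1 <- function(v) v[sample.int(length(v), 1L)]

# A random 2x2 table with the given row margins whose p-value stays
# representable: the observed cell is a hypergeometric draw plus a bounded
# shift, so two-sided p-values span moderate magnitudes without underflow.
random_table <- function(r1, r2, t, max_shift = 20L) {
  lo <- max(0L, t - r2)
  hi <- min(r1, t)
  k <- rhyper(1, r1, r2, t) + pick1(-max_shift:max_shift)
  min(hi, max(lo, k))
}

# A small valid cds_set with known composition.
tiny_cds <- function() {
  cds_set(c("g1", "g2", "g3"),
          c("ATGAAGAAGTAA",          # M K K *
            "ATGGTACGAGTACGATGA",    # M V R V R *
            "ATGTTTTAA"),            # M F *
          abundance = c(1, 10, 100))
}

write_tmp_fasta <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(paste0(">", seqs$id, "\n", seqs$nt), path)
  path
}

# Generator config used by null-calibration style tests: identical processes
# in both classes, no couplings.
null_config <- function(n_genes, seed) {
  generator_config(n_genes = n_genes, seed = seed)
}

# Run sampling + counting on a generated proteome; returns counts and the
# sampled cds_sets.
sample_and_count <- function(sim, n_select, seed, index) {
  low <- select_length_matched(
    sim$abundance, sampler_config(n_select, "low", seed = seed + 1L))
  high <- select_length_matched(
    sim$abundance, sampler_config(n_select, "high", seed = seed + 2L))
  sl <- sim$seqs[match(low$id, sim$seqs$id), ]
  sh <- sim$seqs[match(high$id, sim$seqs$id), ]
  class(sl) <- class(sh) <- c("cds_set", "data.frame")
  list(seqs_low = sl, seqs_high = sh,
       counts_low = count_sample(sl, index),
       counts_high = count_sample(sh, index))
}
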