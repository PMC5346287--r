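test_that("generation is deterministic and emits strictly valid CDS", {
  cfg <- generator_config(n_genes = 2, seed = 42)
  a <- generate_proteome(cfg)
  b <- generate_proteome(cfg)
  expect_identical(a, b)

  sim <- generate_proteome(generator_config(n_genes = 100, seed = 3))
  expect_length(validate_cds(sim$seqs, "strict"), 0)
  expect_true(all(startsWith(sim$seqs$nt, "ATG")))  # first residue is Met
  expect_identical(sim$abundance$cds_length, nchar(sim$seqs$nt))
})

test_that("degenerate configurations are rejected before generation", {
  prof <- synonymous_profile()
  prof$K <- c(AAA = 0, AAG = 0)
  expect_error(generator_config(n_genes = 10, codon_profile_low = prof),
               "degenerate")
  expect_error(generator_config(n_genes = 10,
                                couplings = data.frame(p_codon = "GTA",
                                                       a_codon = "CGA",
                                                       m = -1, class = "low")),
               "positive")
  expect_error(generator_config(n_genes = 10,
                                couplings = data.frame(p_codon = "TAA",
                                                       a_codon = "CGA",
                                                       m = 2, class = "low")),
               "sense")
  expect_error(generator_config(n_genes = 1), "n_genes")
})

test_that("the conditional codon distribution matches hand arithmetic", {
  uniform <- synonymous_profile(ratio = 1)
  cfg <- generator_config(
    n_genes = 10,
    codon_profile_low = uniform, codon_profile_high = uniform,
    couplings = data.frame(p_codon = "GTA", a_codon = "AAG", m = 3,
                           class = "low"))
  # 0.5 : 1.5 renormalized
  expect_equal(expected_pair_frequency(cfg, "GTA", "K", "low"),
               c(AAA = 0.25, AAG = 0.75))
  # no coupling applies -> raw profile row
  expect_equal(expected_pair_frequency(cfg, "GGG", "K", "low"),
               c(AAA = 0.5, AAG = 0.5))
  expect_equal(expected_pair_frequency(cfg, "GTA", "K", "high"),
               c(AAA = 0.5, AAG = 0.5))
  expect_error(expected_pair_frequency(cfg, "GTA", "B"), "unknown")

  # multiplier 1 is neutral
  cfg1 <- generator_config(
    n_genes = 10,
    couplings = data.frame(p_codon = "GTA", a_codon = "CGA", m = 1,
                           class = "both"))
  cfg0 <- generator_config(n_genes = 10)
  expect_equal(expected_pair_frequency(cfg1, "GTA", "R"),
               expected_pair_frequency(cfg0, "GTA", "R"))
})

test_that("empirical codon usage converges to the configured profiles", {
  cfg <- generator_config(n_genes = 2000, seed = 11)
  sim <- generate_proteome(cfg)
  idx <- enumerate_bicodons()
  cnt <- count_sample(sim$seqs, idx)
  tab <- standard_codon_table()
  aa_of <- setNames(tab$aa, tab$codon)
  # within-family empirical frequencies vs the (identical low/high) profile,
  # total-variation distance per family
  for (aa in c("L", "K", "V", "A", "R")) {
    fam <- names(cfg$codon_profile_low[[aa]])
    emp <- cnt$f[fam] / sum(cnt$f[fam])
    tv <- 0.5 * sum(abs(emp - cfg$codon_profile_low[[aa]]))
    expect_lt(tv, 0.02)
  }
})

test_that("log length and log abundance correlate at the configured rho", {
  for (rho in c(-0.3, 0)) {
    sim <- generate_proteome(generator_config(n_genes = 2000, seed = 21,
                                              length_abundance_cor = rho))
    r <- cor(log(sim$abundance$cds_length), log(sim$abundance$abundance))
    expect_lt(abs(r - rho), 0.1)
  }
})

test_that("a planted coupling shifts pair usage in the targeted class only", {
  cfg <- generator_config(
    n_genes = 1500, seed = 5,
    couplings = data.frame(p_codon = "GTA", a_codon = "CGA", m = 6,
                           class = "low"))
  sim <- generate_proteome(cfg)
  idx <- enumerate_bicodons()
  med <- median(sim$abundance$abundance)
  low <- sim$seqs[sim$seqs$abundance < med, ]
  high <- sim$seqs[sim$seqs$abundance >= med, ]
  class(low) <- class(high) <- c("cds_set", "data.frame")
  cl <- count_sample(low, idx)
  ch <- count_sample(high, idx)
  vr <- idx$dipeptide == "VR"
  frac_low <- cl$o["GTACGA"] / sum(cl$o[vr])
  frac_high <- ch$o["GTACGA"] / sum(ch$o[vr])
  expect_gt(frac_low, frac_high)
  st <- bicodon_stats(cl, ch, idx)
  expect_gt(st$pi[st$bicodon == "GTACGA"], 0)

  # empirical conditional distribution after GTA matches the analytic oracle
  enc <- lapply(low$nt, function(s) {
    n <- nchar(s); substring(s, seq(1, n - 2, 3), seq(3, n, 3))
  })
  p <- unlist(lapply(enc, function(v) v[-length(v)]))
  a <- unlist(lapply(enc, function(v) v[-1]))
  arg_codons <- names(cfg$codon_profile_low$R)
  obs <- table(factor(a[p == "GTA" & a %in% arg_codons], levels = arg_codons))
  emp <- as.numeric(obs) / sum(obs)
  oracle <- expected_pair_frequency(cfg, "GTA", "R", "low")
  expect_lt(0.5 * sum(abs(emp - as.numeric(oracle))), 0.05)
})
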