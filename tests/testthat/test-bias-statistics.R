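# Oracles: dhyper enumeration (helper-fixtures.R) and stats::fisher.test for
# the Fisher machinery; hand arithmetic for the scaling identities.

test_that("RSBU is count scaled by group size over the group total", {
  idx <- enumerate_bicodons()
  # KK group (q = 4): counts (2,1,1,0) give RSBU = 4*count/4 = counts
  seqs <- cds_set(
    "x", paste0("ATG", "AAAAAA", "AAAAAA", "AAAAAG", "AAGAAA", "TAA"))
  # adjacent K pairs: AAAAAA, AAAAAA(2?), ... build counts directly instead
  cnt <- count_sample(seqs, idx)
  kk <- idx$dipeptide == "KK"
  expect_equal(sum(cnt$o[kk]), 7L)  # 8 codons of K -> 7 internal KK pairs
  rsbu <- compute_rsbu(cnt, idx)
  expect_equal(sum(rsbu[kk]), 4)    # sums to q_ap within a represented group

  # uniform usage within a group -> RSBU 1 for every member
  cnt$o[kk] <- 5
  rsbu <- compute_rsbu(cnt, idx)
  expect_true(all(rsbu[kk] == 1))

  # single-member group present -> RSBU 1
  mw <- idx$dipeptide == "MW"
  cnt$o[mw] <- 3
  expect_equal(unname(compute_rsbu(cnt, idx)[mw]), 1)

  # empty groups flagged and zero
  cnt0 <- count_sample(cds_set("y", "ATGTAA"), idx)
  r0 <- compute_rsbu(cnt0, idx)
  expect_true(all(r0[idx$dipeptide == "VR"] == 0))
  expect_true("VR" %in% attr(r0, "empty_groups"))
})

test_that("pause propensity is the RSBU difference with zero group sums", {
  idx <- enumerate_bicodons()
  cnt <- count_sample(tiny_cds(), idx)
  expect_true(all(compute_pause_propensity(compute_rsbu(cnt, idx),
                                           compute_rsbu(cnt, idx)) == 0))

  # q=2 group (MK: ATGAAA, ATGAAG) with counts L=(3,1), H=(1,3):
  # RSBU_L = (1.5, 0.5), RSBU_H = (0.5, 1.5)
  cl <- cnt; ch <- cnt
  members <- which(idx$dipeptide == "MK")
  expect_length(members, 2L)
  cl$o[] <- 0; ch$o[] <- 0
  cl$o[members] <- c(3, 1)
  ch$o[members] <- c(1, 3)
  pi_v <- compute_pause_propensity(compute_rsbu(cl, idx),
                                   compute_rsbu(ch, idx))
  expect_equal(unname(pi_v[members]), c(1, -1))

  # property: pi sums to zero within every doubly represented group
  sim <- generate_proteome(generator_config(n_genes = 400, seed = 2))
  res <- sample_and_count(sim, 100, 7, idx)
  st <- bicodon_stats(res$counts_low, res$counts_high, idx)
  sums <- tapply(st$pi, st$dipeptide, sum)
  nl <- tapply(st$o_L, st$dipeptide, sum)
  nh <- tapply(st$o_H, st$dipeptide, sum)
  expect_true(all(abs(sums[nl > 0 & nh > 0]) < 1e-9))
})

test_that("fisher_bicodon reproduces enumeration and fisher.test", {
  expect_equal(fisher_bicodon(5, 5, 10, 10), 1)
  # two extreme tables out of choose(20, 10)
  expect_equal(fisher_bicodon(10, 0, 10, 10), 2 / 184756, tolerance = 1e-12)

  # exhaustive small-table check against the dhyper enumeration oracle
  for (r1 in 0:12) for (r2 in 0:12) for (t in 0:(r1 + r2)) {
    hp <- hyper_pvalues(r1, r2, t)
    expect_equal(hp$p, oracle_hyper_pvals(r1, r2, t), tolerance = 1e-12)
  }

  # random larger tables against stats::fisher.test (same min-likelihood
  # two-sided convention)
  set.seed(99)
  for (i in 1:200) {
    r1 <- pick1(0:400); r2 <- pick1(0:400)
    if (r1 + r2 == 0) next
    t <- pick1(0:(r1 + r2))
    k <- random_table(r1, r2, t)
    mine <- fisher_bicodon(k, t - k, r1, r2)
    ref <- stats::fisher.test(matrix(c(k, t - k, r1 - k, r2 - t + k), 2))
    expect_equal(mine, ref$p.value, tolerance = 1e-7)
  }
  expect_error(fisher_bicodon(-1, 0, 5, 5), "negative")
  expect_error(fisher_bicodon(6, 0, 5, 5), "exceeds")
})

test_that("Stirling factorials are accurate from n = 25 and improving", {
  n <- c(25, 50, 100, 1000, 5000)
  rel <- abs(log_factorial(n, "stirling25") - lgamma(n + 1)) / lgamma(n + 1)
  expect_lt(rel[1], 1e-3)
  expect_true(all(diff(rel) < 0))
  # below 25 the exact product is used
  expect_equal(log_factorial(0:24, "stirling25"), lgamma(1:25))

  set.seed(7)
  for (i in 1:200) {
    r1 <- pick1(1:5000); r2 <- pick1(1:5000)
    t <- pick1(0:(r1 + r2))
    k <- random_table(r1, r2, t)
    pe <- fisher_bicodon(k, t - k, r1, r2, factorial_mode = "exact")
    ps <- fisher_bicodon(k, t - k, r1, r2, factorial_mode = "stirling25")
    expect_lt(abs(log10(ps) - log10(pe)), 0.01)
  }
})

test_that("signed log significance follows the orientation convention", {
  # low-preferring bicodons come out positive
  expect_equal(signed_logp(0.01, +1), 2)
  expect_equal(signed_logp(0.01, -1), -2)
  expect_equal(signed_logp(1, +1), 0)
  expect_equal(signed_logp(0.5, 0), 0)  # tied proportions
  expect_warning(out <- signed_logp(0, +1), "clamped")
  expect_true(is.finite(out) && out > 300)
})

test_that("expected counts follow f_i f_j N_p / N_tot^2", {
  idx <- enumerate_bicodons()
  cnt <- count_sample(cds_set("x", "ATGAAGAAGTAA"), idx)
  e <- expected_counts(cnt, idx)
  expect_equal(unname(e["ATGAAG"]), 1 * 2 * 3 / 16)   # 0.375
  expect_equal(unname(e["AAGATG"]), 0.375)            # symmetric in f_i f_j
  # over the full 64 x 64 product space the expectation sums to N_p exactly
  f <- as.numeric(cnt$f)
  expect_equal(sum(outer(f, f)) * cnt$n_p / cnt$n_tot^2, cnt$n_p)
  expect_error(expected_counts(count_sample(cds_set(character(0),
                                                    character(0)), idx), idx),
               "n_tot")
})

test_that("group normalization conserves observed totals", {
  idx <- enumerate_bicodons()
  sim <- generate_proteome(generator_config(n_genes = 300, seed = 13))
  cnt <- count_sample(sim$seqs, idx)
  e <- expected_counts(cnt, idx)
  ehat <- normalize_expected(e, cnt$o, idx)
  # conservation within every group to 1e-9
  diff <- tapply(ehat, idx$dipeptide, sum) - tapply(cnt$o, idx$dipeptide, sum)
  expect_true(all(abs(diff) < 1e-9))
  # o = e within a group -> scale 1
  expect_equal(unname(normalize_expected(e, e, idx)), unname(e))
})

test_that("residual scores apply the chi-squared formula and conventions", {
  expect_equal(residual_score(3, 2), 0.5)
  expect_equal(residual_score(2, 2), 0)
  expect_equal(residual_score(0, 0), 0)
  expect_equal(residual_score(3, 0), Inf)
  expect_equal(residual_score(c(3, 0, 5), c(2, 0, 5)), c(0.5, 0, 0))
})

test_that("pooled normalization and sample background variants behave", {
  idx <- enumerate_bicodons()
  sim <- generate_proteome(generator_config(n_genes = 300, seed = 23))
  res <- sample_and_count(sim, 80, 31, idx)
  per <- bicodon_stats(res$counts_low, res$counts_high, idx)
  pooled <- bicodon_stats(res$counts_low, res$counts_high, idx,
                          normalization = "pooled")
  # pooled pi = q (o_L - o_H) / (N_ap_L + N_ap_H)
  g <- build_groups(idx, res$counts_low, res$counts_high)
  gof <- attr(g, "group_of")
  tot <- (g$n_ap_L + g$n_ap_H)[gof]
  manual <- ifelse(tot > 0,
                   g$q_ap[gof] * (per$o_L - per$o_H) / tot, 0)
  expect_equal(pooled$pi, manual)

  ws <- bicodon_stats(res$counts_low, res$counts_high, idx,
                      background = "sample")
  expect_false(identical(ws$p_value, per$p_value))
  expect_true(all(ws$p_value > 0 & ws$p_value <= 1))
  expect_true(all(per$p_value > 0 & per$p_value <= 1))
  expect_true("p_bh" %in% names(per))
})
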