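test_that("axis clustering is deterministic and groups similar profiles", {
  # two identical rows merge at distance zero and end up adjacent
  m <- matrix(NA_real_, 64, 64, dimnames = list(rownames <- NULL, NULL))
  set.seed(4)
  sense <- !rownames(heatmap_matrix(
    data.frame(bicodon = enumerate_bicodons()$bicodon, pi = 0), "pi")) %in%
    c("TAA", "TAG", "TGA")
  m[sense, ] <- matrix(rnorm(61 * 64), 61, 64)
  m[which(sense)[5], ] <- m[which(sense)[40], ]
  ord <- cluster_axes(m)
  pos <- match(which(sense)[c(5, 40)], ord$row_order)
  expect_equal(abs(diff(pos)), 1)
  expect_identical(cluster_axes(m), ord)
  # stop-codon P rows stay at the bottom
  expect_equal(sort(tail(ord$row_order, 3)), which(!sense))
})

test_that("well-separated blocks come out contiguous", {
  # embed a 4-column two-block pattern: columns {1,2} vs {3,4} far apart
  idx <- enumerate_bicodons()
  st <- data.frame(bicodon = idx$bicodon, pi = 0)
  m <- heatmap_matrix(st, "pi", idx)
  m[!is.na(m)] <- 0
  blockA <- c(1, 7); blockB <- c(20, 33)  # A-site column indices
  m[1:30, blockA] <- 5
  m[31:61, blockB] <- -5
  ord <- cluster_axes(m)
  posA <- sort(match(blockA, ord$col_order))
  posB <- sort(match(blockB, ord$col_order))
  expect_equal(diff(posA), 1)  # block members adjacent
  expect_equal(diff(posB), 1)
})

test_that("heat-map export masks stop P rows and round-trips via TSV", {
  idx <- enumerate_bicodons()
  sim <- generate_proteome(generator_config(n_genes = 200, seed = 6))
  cnt <- count_sample(sim$seqs, idx)
  st <- bicodon_stats(cnt, cnt, idx)
  expect_true(all(st$pi == 0))       # identical samples
  path <- withr::local_tempfile(fileext = ".tsv")
  hm <- export_heatmap(st, "pi", path = path, index = idx)
  expect_equal(attr(hm, "n_masked"), 192L)  # 64^2 - 3904
  expect_true(all(hm[!is.na(hm)] == 0))
  back <- read_heatmap_tsv(path)
  expect_equal(unclass(back), unclass(hm)[rownames(back), colnames(back)],
               ignore_attr = TRUE)
  expect_equal(attr(back, "measure"), "pi")
})

test_that("shared bicodons intersect organisms and shrink monotonically", {
  idx <- enumerate_bicodons()
  base <- data.frame(bicodon = idx$bicodon, dipeptide = idx$dipeptide,
                     p_value = 1, pi = 0, chi2_L = 0, chi2_H = 0,
                     z_L = 0, z_H = 0, stringsAsFactors = FALSE)
  hit <- function(s, bics, p = 1e-4, z = 5, pi = 1) {
    i <- match(bics, s$bicodon)
    s$p_value[i] <- p; s$z_L[i] <- z; s$pi[i] <- pi
    s$chi2_L[i] <- 10
    s
  }
  a <- hit(base, c("ATGAAA", "GTACGA"))
  b <- hit(base, c("GTACGA", "TTTAAA"))
  # single organism degenerates to its own filtered list
  solo <- shared_bicodons(list(yeast = a))
  expect_setequal(solo$bicodon, c("ATGAAA", "GTACGA"))
  # two organisms: only the common hit survives
  both <- shared_bicodons(list(a = a, b = b))
  expect_equal(both$bicodon, "GTACGA")
  expect_true(all(c("chi2sum_a", "zsum_b", "neglog10p_a") %in% names(both)))
  # disjoint filtered sets give an empty table
  dis <- shared_bicodons(list(a = hit(base, "ATGAAA"),
                              b = hit(base, "TTTAAA")))
  expect_equal(nrow(dis), 0L)
  # direction filtering
  neg <- hit(base, "GTACGA", pi = -1)
  expect_equal(nrow(shared_bicodons(list(a = a, b = neg))), 0L)
  expect_equal(shared_bicodons(list(a = neg), direction = "high")$bicodon,
               "GTACGA")
  # monotonicity: tightening thresholds never adds rows
  loose <- shared_bicodons(list(a = a, b = b), alpha = 0.01, z_threshold = 3)
  tight1 <- shared_bicodons(list(a = a, b = b), alpha = 1e-6, z_threshold = 3)
  tight2 <- shared_bicodons(list(a = a, b = b), alpha = 0.01, z_threshold = 6)
  expect_true(all(tight1$bicodon %in% loose$bicodon))
  expect_true(all(tight2$bicodon %in% loose$bicodon))
})

test_that("occupancy filtering is strict and warns about missing bicodons", {
  st <- data.frame(bicodon = c("AAATTT", "CCCGGG", "TTTAAA", "GGGCCC"),
                   pi = c(0.75, 0.9, 0.9, 0.9),
                   p_value = c(1e-4, 1e-4, 0.5, 1e-4))
  occ <- data.frame(bicodon = c("AAATTT", "CCCGGG", "TTTAAA"),
                    occupancy = c(0.1, 0.1, 0.1))
  expect_warning(out <- occupancy_candidates(st, occ), "1 bicodon")
  expect_equal(out$bicodon, "CCCGGG")  # pi = 0.75 exactly is excluded
  expect_equal(out$occupancy, 0.1)
  empty <- data.frame(bicodon = character(0), occupancy = numeric(0))
  expect_warning(none <- occupancy_candidates(st, empty), "4 bicodon")
  expect_equal(nrow(none), 0L)
})

test_that("the SNP report recovers the documented human MDR1-style values", {
  # fixture carrying the printed pause propensities around the ATC codon
  st <- data.frame(bicodon = c("ATCGTG", "ATTGTG", "ATAGTG", "AAAATC",
                               "AAAATT"),
                   pi = c(0.1, -0.8, -0.55, 0.2, 0.3),
                   stringsAsFactors = FALSE)
  cds <- cds_set("MDR1_like", "ATGAAAATCGTGTAA")  # M K I V *
  rep_t <- snp_effect(cds, 3, "ATT", st)
  expect_equal(rep_t$downstream$bicodon_ref, "ATCGTG")
  expect_equal(rep_t$downstream$bicodon_alt, "ATTGTG")
  expect_equal(rep_t$downstream$delta_pi, -0.9)
  expect_equal(rep_t$upstream$delta_pi, 0.1)

  rep_a <- snp_effect(cds, 3, "ATA", st)
  expect_equal(rep_a$downstream$pi_alt, -0.55)
  expect_true(is.na(rep_a$upstream$pi_alt))  # AAAATA absent, reported NA

  # identity variant: all deltas 0
  rep_same <- snp_effect(cds, 3, "ATC", st)
  expect_equal(rep_same$downstream$delta_pi, 0)
  # antisymmetry: swapping ref and alt negates the deltas
  cds_alt <- cds_set("alt", "ATGAAAATTGTGTAA")
  rep_back <- snp_effect(cds_alt, 3, "ATC", st)
  expect_equal(rep_back$downstream$delta_pi, -rep_t$downstream$delta_pi)

  expect_error(snp_effect(cds, 3, "AAA", st), "not synonymous")
  expect_error(snp_effect(cds, 99, "ATT", st), "out of range")
  # edge position: no upstream bicodon
  rep_edge <- snp_effect(cds_set("e", "ATAGTGTAA"), 1, "ATC", st)
  expect_true(is.na(rep_edge$upstream$bicodon_ref))
  expect_equal(rep_edge$downstream$bicodon_ref, "ATAGTG")
  expect_output(print(rep_t), "downstream ATCGTG -> ATTGTG")
})

test_that("RSCU accompanies the SNP report when counts are given", {
  idx <- enumerate_bicodons()
  cnt <- count_sample(cds_set("x", "ATGATCATCATTTAA"), idx)  # I: 2x ATC, ATT
  st <- data.frame(bicodon = "X", pi = 0)
  rep_t <- snp_effect(cds_set("y", "ATGATCGTGTAA"), 2, "ATT", st,
                      counts = cnt)
  expect_equal(rep_t$rscu_ref, 2)  # 3 * 2/3
  expect_equal(rep_t$rscu_alt, 1)  # 3 * 1/3
})

test_that("statistics TSVs round-trip bit-identically", {
  idx <- enumerate_bicodons()
  sim <- generate_proteome(generator_config(n_genes = 150, seed = 14))
  res <- sample_and_count(sim, 40, 5, idx)
  st <- bicodon_stats(res$counts_low, res$counts_high, idx)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stats_tsv(st, path)
  back <- read_stats_tsv(path)
  expect_identical(back, st)
})
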