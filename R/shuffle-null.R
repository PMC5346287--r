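# Codon-shuffling null: destroys codon-pair correlations while preserving
# single-codon usage exactly, calibrates the chi-squared residuals, and
# classifies every bicodon.

#' Shuffle the codon order of a coding sequence
#'
#' Permutes codons 1..c-1 uniformly at random, preserving the terminal stop
#' codon. The codon multiset (hence the codon count vector f) is unchanged;
#' only codon-pair correlations are destroyed. Uses R's global random stream.
#'
#' @param nt Character vector of valid CDS nucleotide strings (each with a
#'   terminal stop codon).
#' @return Character vector of shuffled sequences.
#' @export
#' @examples
#' set.seed(1)
#' shuffle_codons("ATGAAGTAA")  # "ATGAAGTAA" or "AAGATGTAA"
shuffle_codons <- function(nt) {
  vapply(nt, function(s) {
    v <- .encode_codons(s)
    n <- length(v)
    if (is.na(v[n]) || !.CODONS[v[n]] %in% .STOP_CODONS)
      stop("sequence has no terminal stop codon; cannot shuffle")
    if (n > 2L) v <- c(v[sample.int(n - 1L)], v[n])
    paste(.CODONS[v], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Empirical null moments of the residual scores
#'
#' For each of \code{n_reps} replicates, shuffles the codon order of every
#' sequence in the sample (terminal stop fixed), recounts bicodons, and
#' recomputes the group-normalized expectation and chi-squared residual
#' inside the replicate (shuffling changes o but not f, and the
#' normalization scale depends on o, so both are refreshed). Returns the
#' per-bicodon mean and standard deviation of the null residuals. One master
#' seed spawns per-replicate streams, so the full set of replicates is
#' deterministic given the seed. The procedure is run per sample,
#' independently for the low and high sets.
#'
#' @param seqs A [cds_set()] of valid CDS with terminal stops.
#' @param index A [enumerate_bicodons()] index.
#' @param n_reps Number of shuffle replicates (>= 2; the reference analysis
#'   uses 200).
#' @param seed Master seed.
#' @return List of class \code{null_moments}: \code{mean}, \code{sd}
#'   (per-bicodon, named), \code{n_reps}, \code{seed}.
#' @export
null_moments <- function(seqs, index = enumerate_bicodons(), n_reps = 200L,
                         seed = 1L) {
  stopifnot(n_reps >= 2)
  bad <- validate_cds(seqs, "strict")
  if (length(bad))
    stop("invalid CDS in sample: '", names(bad)[1], "': ", bad[1])
  enc <- lapply(seqs$nt, .encode_codons)
  base <- .count_encoded(enc, index)
  e <- expected_counts(base, index)
  gof <- attr(build_groups(index), "group_of")
  sum_e <- as.vector(rowsum(as.numeric(e), gof))
  lookup <- attr(index, "lookup")
  nb <- nrow(index)

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)

  chi <- matrix(0, nb, n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    shuf <- lapply(enc, function(v) {
      n <- length(v)
      if (n > 2L) c(v[sample.int(n - 1L)], v[n]) else v
    })
    p <- unlist(lapply(shuf, function(v) v[-length(v)]), use.names = FALSE)
    a <- unlist(lapply(shuf, function(v) v[-1L]), use.names = FALSE)
    o <- tabulate(lookup[cbind(p, a)], nb)
    sum_o <- as.vector(rowsum(as.numeric(o), gof))
    scale <- ifelse(sum_e > 0, sum_o / sum_e, 0)
    ehat <- e * scale[gof]
    ch <- (o - ehat)^2 / ehat
    ch[ehat == 0] <- 0  # ehat 0 implies o 0 within a replicate
    chi[, r] <- ch
  }
  m <- rowMeans(chi)
  s <- sqrt(rowSums((chi - m)^2) / (n_reps - 1))
  structure(list(mean = stats::setNames(m, index$bicodon),
                 sd = stats::setNames(s, index$bicodon),
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "null_moments")
}

#' Standardize residual scores against the shuffle null
#'
#' Expresses each bicodon's residual as the number of null standard
#' deviations from the null mean: \code{z = (chi2 - mean_ran) / sd_ran}.
#' Where the null SD is 0, z is 0 if the residual equals the null mean and
#' NA (an undefined sentinel, excluded from classification) otherwise.
#'
#' @param chi2 Residual scores for the unshuffled sample.
#' @param moments A [null_moments()] result for the same sample.
#' @return Numeric vector of z-scores; attribute \code{n_undefined} counts
#'   the NA sentinels.
#' @export
standardize_residuals <- function(chi2, moments) {
  stopifnot(inherits(moments, "null_moments"),
            length(chi2) == length(moments$mean))
  z <- (chi2 - moments$mean) / moments$sd
  zero_sd <- moments$sd == 0
  z[zero_sd & chi2 == moments$mean] <- 0
  z[zero_sd & chi2 != moments$mean] <- NA_real_
  structure(z, n_undefined = sum(is.na(z)))
}

#' Two-sided normal tail probability of a z threshold
#'
#' The significance level implied by calling residuals beyond z null SDs
#' discrepant; at the conventional z = 3 this is 0.0027, i.e. 0.003 to one
#' significant figure.
#'
#' @param z Threshold in SD units.
#' @return \code{2 * pnorm(-|z|)}.
#' @export
z_to_alpha <- function(z) {
  2 * stats::pnorm(-abs(z))
}

#' Four-way bicodon classification
#'
#' Combines the Fisher p-value, the pause propensity sign and the
#' null-standardized residuals into the four categories:
#' \describe{
#'   \item{low_unexplained}{p < alpha, residual z at/above the threshold,
#'     pi > 0 — used more in low-abundance sequences, not explained by
#'     single-codon bias.}
#'   \item{high_unexplained}{as above with pi <= 0.}
#'   \item{explained_biased}{p < alpha but residuals below the threshold —
#'     a real usage difference that codon bias accounts for.}
#'   \item{unbiased}{p >= alpha.}
#' }
#' The residual criterion is \code{max(z_L, z_H) >= z_threshold} by default
#' (each sample judged on its own axis); \code{rule = "sum"} uses
#' \code{z_L + z_H >= z_threshold} (a single whole-residual score).
#' Significant bicodons with an undefined z are withheld and reported as
#' their own level.
#'
#' @param stats A [bicodon_stats()] data frame.
#' @param z_l,z_h [standardize_residuals()] z-scores for the two samples.
#' @param alpha Raw p-value threshold (default 0.01).
#' @param z_threshold Residual threshold in null SD units (default 3).
#' @param rule \code{"max"} or \code{"sum"}.
#' @return Factor with levels low_unexplained, high_unexplained,
#'   explained_biased, unbiased, withheld.
#' @export
classify_bicodons <- function(stats, z_l, z_h, alpha = 0.01,
                              z_threshold = 3, rule = c("max", "sum")) {
  rule <- match.arg(rule)
  stopifnot(nrow(stats) == length(z_l), length(z_l) == length(z_h))
  score <- if (rule == "max") pmax(z_l, z_h) else z_l + z_h
  out <- rep("unbiased", nrow(stats))
  sig <- stats$p_value < alpha
  out[sig & is.na(score)] <- "withheld"
  ok <- sig & !is.na(score)
  out[ok & score >= z_threshold & stats$pi > 0] <- "low_unexplained"
  out[ok & score >= z_threshold & stats$pi <= 0] <- "high_unexplained"
  out[ok & score < z_threshold] <- "explained_biased"
  factor(out, levels = c("low_unexplained", "high_unexplained",
                         "explained_biased", "unbiased", "withheld"))
}
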