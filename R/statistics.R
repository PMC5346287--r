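# Per-bicodon bias statistics: relative synonymous bicodon usage, pause
# propensity, Fisher exact significance (exact log-gamma or Stirling n>=25
# factorials), single-codon expectations and chi-squared residual scores.

#' Log-factorial, exact or by Stirling's formula
#'
#' \code{exact} evaluates \code{lgamma(n + 1)}. \code{stirling25} uses
#' Stirling's approximation \code{sqrt(2 pi n) (n/e)^n} for n >= 25 and the
#' exact sum of logs below, reproducing the factorial evaluation the
#' reference analysis used inside Fisher's test.
#'
#' @param n Non-negative integer vector.
#' @param mode \code{"exact"} or \code{"stirling25"}.
#' @return \code{log(n!)}.
#' @export
log_factorial <- function(n, mode = c("exact", "stirling25")) {
  mode <- match.arg(mode)
  if (mode == "exact") return(lgamma(n + 1))
  out <- numeric(length(n))
  small <- n < 25
  out[small] <- vapply(n[small], function(m) sum(log(seq_len(m))), numeric(1))
  b <- n[!small]
  out[!small] <- 0.5 * log(2 * pi * b) + b * log(b) - b
  out
}

#' Two-sided hypergeometric p-values for one margin set
#'
#' For the 2 x 2 margins (row totals \code{syn_l}, \code{syn_h}; first-column
#' total \code{t}) returns, for every admissible first cell k, the two-sided
#' Fisher exact p-value by the minimum-likelihood rule: the sum of the
#' probabilities of all tables with the same margins whose probability is at
#' most that of the observed table, with relative tolerance \code{rel_tol}
#' on the comparison (exact ties included). This is the computational core of
#' [fisher_bicodon()].
#'
#' @param syn_l,syn_h Row margins (>= 0).
#' @param t First-column total, between 0 and \code{syn_l + syn_h}.
#' @param factorial_mode Factorial evaluation, see [log_factorial()].
#' @param rel_tol Relative tolerance for probability comparison.
#' @return List with \code{k} (support, \code{max(0, t - syn_h)} to
#'   \code{min(syn_l, t)}), \code{prob} (table probabilities) and \code{p}
#'   (two-sided p-values, capped at 1).
#' @export
hyper_pvalues <- function(syn_l, syn_h, t,
                          factorial_mode = c("exact", "stirling25"),
                          rel_tol = 1e-7) {
  factorial_mode <- match.arg(factorial_mode)
  if (syn_l < 0 || syn_h < 0 || t < 0 || t > syn_l + syn_h)
    stop("inadmissible margins")
  lo <- max(0L, t - syn_h)
  hi <- min(syn_l, t)
  k <- lo:hi
  lf <- if (factorial_mode == "exact") function(x) lgamma(x + 1)
        else function(x) log_factorial(x, "stirling25")
  lp <- lf(syn_l) - lf(k) - lf(syn_l - k) +
    lf(syn_h) - lf(t - k) - lf(syn_h - t + k) -
    (lf(syn_l + syn_h) - lf(t) - lf(syn_l + syn_h - t))
  prob <- exp(lp)
  ord <- order(prob)
  cs <- cumsum(prob[ord])
  p <- pmin(1, cs[findInterval(prob * (1 + rel_tol), prob[ord])])
  list(k = k, prob = prob, p = p)
}

#' Fisher exact test for one bicodon
#'
#' Two-sided Fisher exact p-value on the contingency table
#' \code{[[o_l, syn_l - o_l], [o_h, syn_h - o_h]]}, where the backgrounds
#' \code{syn_l}, \code{syn_h} are typically the totals of the bicodon's
#' synonymous group in the low and high abundance samples. Vectorized over
#' its arguments.
#'
#' @param o_l,o_h Observed bicodon counts in the two samples.
#' @param syn_l,syn_h Background totals (\code{0 <= o <= syn}).
#' @param factorial_mode Factorial evaluation, see [log_factorial()].
#' @return p-value(s) in (0, 1].
#' @export
#' @examples
#' fisher_bicodon(5, 5, 10, 10)    # perfectly balanced: 1
#' fisher_bicodon(10, 0, 10, 10)   # 2 / choose(20, 10)
fisher_bicodon <- function(o_l, o_h, syn_l, syn_h,
                           factorial_mode = c("exact", "stirling25")) {
  factorial_mode <- match.arg(factorial_mode)
  n <- max(length(o_l), length(o_h), length(syn_l), length(syn_h))
  o_l <- rep_len(o_l, n); o_h <- rep_len(o_h, n)
  syn_l <- rep_len(syn_l, n); syn_h <- rep_len(syn_h, n)
  if (any(o_l < 0) || any(o_h < 0))
    stop("negative counts")
  if (any(o_l > syn_l) || any(o_h > syn_h))
    stop("observed count exceeds its background total")
  vapply(seq_len(n), function(i) {
    hp <- hyper_pvalues(syn_l[i], syn_h[i], o_l[i] + o_h[i], factorial_mode)
    hp$p[o_l[i] - hp$k[1] + 1L]
  }, numeric(1))
}

#' Relative synonymous bicodon usage
#'
#' RSBU of bicodon ij in one sample: \code{q_ap * o_ij / N_ap}, with
#' \code{q_ap} the size of the bicodon's synonymous (dipeptide) group and
#' \code{N_ap} the group's total count. By default \code{N_ap} is the
#' sample's own group total, so RSBU sums to \code{q_ap} within each
#' represented group; a pooled total may be supplied instead (see
#' [bicodon_stats()]'s \code{normalization} flag). Groups with zero total
#' yield RSBU 0 for all members and are flagged.
#'
#' @param counts A [count_sample()] result.
#' @param index A [enumerate_bicodons()] index.
#' @param n_ap Optional per-group totals (aligned with
#'   [build_groups()] rows) to use instead of the sample's own.
#' @return Numeric vector over the bicodon index; attribute
#'   \code{empty_groups} names dipeptides with zero total.
#' @export
compute_rsbu <- function(counts, index, n_ap = NULL) {
  groups <- build_groups(index, counts_L = counts)
  gof <- attr(groups, "group_of")
  tot <- if (is.null(n_ap)) groups$n_ap_L else n_ap
  stopifnot(length(tot) == nrow(groups))
  rsbu <- ifelse(tot[gof] > 0, groups$q_ap[gof] * counts$o / tot[gof], 0)
  structure(stats::setNames(as.numeric(rsbu), index$bicodon),
            empty_groups = groups$dipeptide[tot == 0])
}

#' Pause propensity score
#'
#' Elementwise difference of relative synonymous bicodon usage between the
#' low- and high-abundance samples, pi = RSBU_L - RSBU_H. Positive values
#' mark bicodons preferentially used in lowly abundant proteins (candidate
#' translational-pause signals); negative values mark high-abundance
#' preference. Under per-sample normalization pi sums to zero within every
#' group represented in both samples.
#'
#' @param rsbu_l,rsbu_h RSBU vectors over the same bicodon index.
#' @return Numeric vector of pi values.
#' @export
compute_pause_propensity <- function(rsbu_l, rsbu_h) {
  stopifnot(length(rsbu_l) == length(rsbu_h))
  rsbu_l - rsbu_h
}

#' Sign-oriented log significance
#'
#' Returns \code{-S * log10(p)} with S = +1 for bicodons preferring the
#' low-abundance sample and -1 for the high side, so low-preferring bicodons
#' come out positive. Ties (S = 0) give 0 regardless of p; p = 0 is clamped
#' to the smallest representable positive double with a warning.
#'
#' @param p p-values in [0, 1].
#' @param preference_sign +1, -1 or 0 per bicodon.
#' @return Signed log10 significance.
#' @export
signed_logp <- function(p, preference_sign) {
  stopifnot(length(p) == length(preference_sign))
  if (any(p == 0, na.rm = TRUE)) {
    warning("p-value(s) of 0 clamped to .Machine$double.xmin")
    p[p == 0] <- .Machine$double.xmin
  }
  -preference_sign * log10(p)
}

#' Expected bicodon counts from single-codon usage
#'
#' The random-pairing expectation \code{e_ij = f_i * f_j * N_p / N_tot^2},
#' with f over all 64 codons (stop codons occur at A-sites). Summed over the
#' full 64 x 64 codon-pair space this recovers N_p exactly.
#'
#' @param counts A [count_sample()] result (\code{n_tot > 0}).
#' @param index A [enumerate_bicodons()] index.
#' @return Numeric vector of expected counts over the bicodon index.
#' @export
expected_counts <- function(counts, index) {
  if (counts$n_tot == 0) stop("empty sample: n_tot is 0")
  f <- as.numeric(counts$f)
  names(f) <- names(counts$f)
  e <- f[index$p_codon] * f[index$a_codon] * counts$n_p / counts$n_tot^2
  stats::setNames(as.numeric(e), index$bicodon)
}

#' Group-normalized expected counts
#'
#' Removes the contribution of non-random amino-acid pairing by rescaling the
#' raw expectations within each synonymous group to match the observed group
#' total: \code{ehat_ij = e_ij * (sum* o) / (sum* e)}, the starred sums
#' running over the bicodon's dipeptide group. Conserves the observed total
#' within every group; groups with zero summed expectation yield 0.
#'
#' @param e Raw expected counts from [expected_counts()].
#' @param o Observed counts (same index).
#' @param index A [enumerate_bicodons()] index.
#' @return Numeric vector of normalized expectations.
#' @export
normalize_expected <- function(e, o, index) {
  gof <- attr(build_groups(index), "group_of")
  sum_o <- as.vector(rowsum(as.numeric(o), gof))
  sum_e <- as.vector(rowsum(as.numeric(e), gof))
  scale <- ifelse(sum_e > 0, sum_o / sum_e, 0)
  stats::setNames(as.numeric(e * scale[gof]), index$bicodon)
}

#' Chi-squared residual score
#'
#' \code{(o - ehat)^2 / ehat} per bicodon: large values mean the pair's
#' frequency cannot be explained by single-codon (and amino-acid-pair)
#' usage. By convention 0/0 gives 0; a positive count against a zero
#' expectation gives Inf (flagged downstream).
#'
#' @param o Observed counts.
#' @param ehat Normalized expectations from [normalize_expected()].
#' @return Numeric vector of residual scores (>= 0).
#' @export
residual_score <- function(o, ehat) {
  stopifnot(length(o) == length(ehat), all(ehat >= 0))
  out <- (o - ehat)^2 / ehat
  out[ehat == 0 & o == 0] <- 0
  out[ehat == 0 & o > 0] <- Inf
  out
}

#' Full per-bicodon bias statistics
#'
#' Computes, for every bicodon: observed counts, RSBU in both samples, the
#' pause propensity pi, the Fisher exact p-value (synonymous-group margins by
#' default), the preference sign S and -S log10(p), raw and group-normalized
#' expected counts, and chi-squared residual scores per sample.
#'
#' @param counts_l,counts_h [count_sample()] results for the low- and
#'   high-abundance samples.
#' @param index A [enumerate_bicodons()] index.
#' @param normalization \code{"per_sample"} (RSBU uses each sample's own
#'   group total; the default) or \code{"pooled"} (a single pooled group
#'   total for both samples, the literal reading of the defining equation).
#' @param background Fisher margins: \code{"group"} (other bicodons of the
#'   same dipeptide; the default) or \code{"sample"} (all other bicodons).
#' @param factorial_mode Factorial evaluation inside Fisher's test.
#' @param bh If TRUE, append a Benjamini-Hochberg adjusted p column
#'   (informational; the classification thresholds raw p).
#' @return Data frame with one row per bicodon: \code{bicodon},
#'   \code{dipeptide}, \code{o_L}, \code{o_H}, \code{rsbu_L}, \code{rsbu_H},
#'   \code{pi}, \code{p_value}, \code{S}, \code{signed_logp}, \code{e_L},
#'   \code{e_H}, \code{ehat_L}, \code{ehat_H}, \code{chi2_L}, \code{chi2_H}
#'   (+ \code{p_bh}).
#' @export
bicodon_stats <- function(counts_l, counts_h, index = enumerate_bicodons(),
                          normalization = c("per_sample", "pooled"),
                          background = c("group", "sample"),
                          factorial_mode = c("exact", "stirling25"),
                          bh = TRUE) {
  normalization <- match.arg(normalization)
  background <- match.arg(background)
  factorial_mode <- match.arg(factorial_mode)

  groups <- build_groups(index, counts_l, counts_h)
  gof <- attr(groups, "group_of")

  if (normalization == "per_sample") {
    rsbu_l <- compute_rsbu(counts_l, index)
    rsbu_h <- compute_rsbu(counts_h, index)
  } else {
    pooled <- groups$n_ap_L + groups$n_ap_H
    rsbu_l <- compute_rsbu(counts_l, index, n_ap = pooled)
    rsbu_h <- compute_rsbu(counts_h, index, n_ap = pooled)
  }
  pi <- compute_pause_propensity(rsbu_l, rsbu_h)

  if (background == "group") {
    syn_l <- groups$n_ap_L[gof]
    syn_h <- groups$n_ap_H[gof]
  } else {
    syn_l <- rep(counts_l$n_p, nrow(index))
    syn_h <- rep(counts_h$n_p, nrow(index))
  }
  p_value <- fisher_bicodon(counts_l$o, counts_h$o, syn_l, syn_h,
                            factorial_mode)

  prop_l <- ifelse(syn_l > 0, counts_l$o / syn_l, 0)
  prop_h <- ifelse(syn_h > 0, counts_h$o / syn_h, 0)
  s <- sign(prop_l - prop_h)

  e_l <- expected_counts(counts_l, index)
  e_h <- expected_counts(counts_h, index)
  ehat_l <- normalize_expected(e_l, counts_l$o, index)
  ehat_h <- normalize_expected(e_h, counts_h$o, index)

  out <- data.frame(
    bicodon = index$bicodon, dipeptide = index$dipeptide,
    o_L = as.numeric(counts_l$o), o_H = as.numeric(counts_h$o),
    rsbu_L = as.numeric(rsbu_l), rsbu_H = as.numeric(rsbu_h),
    pi = as.numeric(pi), p_value = p_value, S = as.numeric(s),
    signed_logp = signed_logp(p_value, s),
    e_L = as.numeric(e_l), e_H = as.numeric(e_h),
    ehat_L = as.numeric(ehat_l), ehat_H = as.numeric(ehat_h),
    chi2_L = residual_score(as.numeric(counts_l$o), as.numeric(ehat_l)),
    chi2_H = residual_score(as.numeric(counts_h$o), as.numeric(ehat_h)),
    stringsAsFactors = FALSE
  )
  if (bh) out$p_bh <- stats::p.adjust(p_value, method = "BH")
  out
}
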