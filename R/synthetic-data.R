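# Synthetic proteome generator: coding sequences with realistic abundance and
# length structure and, optionally, planted first-order codon-pair couplings
# that single-codon usage cannot explain.

#' Default amino-acid frequencies
#'
#' A typical eukaryotic proteome composition (normalized to sum to 1) used by
#' the generator to draw residues i.i.d.
#'
#' @return Named numeric vector over the 20 amino acids.
#' @export
default_aa_frequencies <- function() {
  f <- c(A = 7.5, R = 5.2, N = 4.5, D = 5.2, C = 1.7, Q = 4.0, E = 6.4,
         G = 6.9, H = 2.2, I = 5.5, L = 9.1, K = 5.8, M = 2.3, F = 4.0,
         P = 5.1, S = 7.4, T = 5.6, W = 1.3, Y = 3.3, V = 6.4)
  f / sum(f)
}

#' Synonymous codon usage profile
#'
#' Builds a per-amino-acid codon weight list. Within each amino acid the
#' synonymous codons (alphabetical order) get geometrically decaying weights
#' \code{ratio^(rank-1)}, normalized to sum to 1. \code{ratio = 1} gives
#' uniform (unbiased) usage; the default 0.6 gives a moderate codon usage
#' bias of the kind real genomes show.
#'
#' @param ratio Geometric decay of within-family codon weights, in (0, 1].
#' @param table Codon table.
#' @return Named list over amino acids; each element a named weight vector
#'   over that amino acid's codons, summing to 1.
#' @export
synonymous_profile <- function(ratio = 0.6, table = standard_codon_table()) {
  stopifnot(ratio > 0, ratio <= 1)
  fams <- split(table$codon[!table$is_stop], table$aa[!table$is_stop])
  lapply(fams, function(cods) {
    w <- ratio^(seq_along(cods) - 1)
    stats::setNames(w / sum(w), cods)
  })
}

.normalize_profile <- function(profile, label) {
  for (aa in names(profile)) {
    w <- profile[[aa]]
    if (any(!is.finite(w)) || any(w < 0) || sum(w) <= 0)
      stop("degenerate ", label, " profile row for amino acid ", aa)
    profile[[aa]] <- w / sum(w)
  }
  profile
}

#' Configuration of the synthetic proteome generator
#'
#' Collects every knob of the generator. Defaults emulate a yeast-like
#' proteome: right-skewed (lognormal) abundance, lognormal sequence length
#' negatively correlated with abundance, moderate synonymous codon bias
#' (identical in both expression classes unless overridden) and no codon-pair
#' couplings.
#'
#' @param n_genes Number of genes (>= 2).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param abundance_meanlog,abundance_sdlog Lognormal abundance parameters
#'   (natural-log scale, abundance in ppm-like units).
#' @param length_meanlog,length_sdlog Lognormal parameters of the sense-codon
#'   count.
#' @param length_abundance_cor Target correlation of log length with log
#'   abundance; must be <= 0 (short proteins tend to be abundant).
#' @param min_codons Lower clamp on the sense-codon count.
#' @param aa_frequencies Distribution over the 20 amino acids.
#' @param codon_profile_low,codon_profile_high Per-amino-acid codon weight
#'   lists (see [synonymous_profile()]) used for genes below / above the
#'   median abundance.
#' @param couplings Optional data frame with columns \code{p_codon},
#'   \code{a_codon}, \code{m} (multiplier > 0) and \code{class} (one of
#'   \code{"low"}, \code{"high"}, \code{"both"}). For an applicable gene the
#'   weight of \code{a_codon} is multiplied by \code{m} whenever the previous
#'   codon equals \code{p_codon}, then renormalized within the amino acid's
#'   synonymous codons; marginal amino-acid usage is untouched.
#' @param stop_codon_weights Distribution over TAA/TAG/TGA.
#' @return A list of class \code{generator_config}.
#' @export
generator_config <- function(n_genes,
                             seed = 1L,
                             abundance_meanlog = 2,
                             abundance_sdlog = 1.5,
                             length_meanlog = log(400),
                             length_sdlog = 0.45,
                             length_abundance_cor = -0.3,
                             min_codons = 30L,
                             aa_frequencies = default_aa_frequencies(),
                             codon_profile_low = synonymous_profile(),
                             codon_profile_high = synonymous_profile(),
                             couplings = NULL,
                             stop_codon_weights = c(TAA = 0.47, TAG = 0.23,
                                                    TGA = 0.30)) {
  stopifnot(n_genes >= 2, length_abundance_cor <= 0,
            length_abundance_cor >= -1, length_sdlog > 0,
            abundance_sdlog > 0, min_codons >= 2)
  if (any(aa_frequencies < 0) || sum(aa_frequencies) <= 0)
    stop("degenerate amino-acid frequency vector")
  aa_frequencies <- aa_frequencies / sum(aa_frequencies)
  codon_profile_low <- .normalize_profile(codon_profile_low, "low")
  codon_profile_high <- .normalize_profile(codon_profile_high, "high")
  if (any(stop_codon_weights < 0) || sum(stop_codon_weights) <= 0)
    stop("degenerate stop codon weights")
  stop_codon_weights <- stop_codon_weights / sum(stop_codon_weights)
  if (!is.null(couplings)) {
    stopifnot(all(c("p_codon", "a_codon", "m", "class") %in% names(couplings)))
    if (any(!is.finite(couplings$m)) || any(couplings$m <= 0))
      stop("coupling multipliers must be finite and positive")
    if (any(!couplings$class %in% c("low", "high", "both")))
      stop("coupling class must be low, high or both")
    tab <- standard_codon_table()
    if (any(couplings$p_codon %in% .STOP_CODONS) ||
        any(couplings$a_codon %in% .STOP_CODONS) ||
        any(!couplings$p_codon %in% tab$codon) ||
        any(!couplings$a_codon %in% tab$codon))
      stop("coupling codons must be sense codons")
  }
  structure(list(
    n_genes = as.integer(n_genes), seed = as.integer(seed),
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    length_abundance_cor = length_abundance_cor,
    min_codons = as.integer(min_codons),
    aa_frequencies = aa_frequencies,
    codon_profile_low = codon_profile_low,
    codon_profile_high = codon_profile_high,
    couplings = couplings,
    stop_codon_weights = stop_codon_weights
  ), class = "generator_config")
}

#' Conditional codon distribution used by the generator
#'
#' The exact renormalized distribution from which the generator draws the
#' codon of an amino acid given the previous codon: profile weights times any
#' applicable coupling multipliers, renormalized. This closed form is the
#' analytic oracle for planted couplings.
#'
#' @param config A [generator_config()].
#' @param prev Previous (P-site) codon.
#' @param aa One-letter amino acid of the current position.
#' @param class Expression class of the gene, \code{"low"} or \code{"high"}.
#' @return Named probability vector over the amino acid's synonymous codons.
#' @export
#' @examples
#' cfg <- generator_config(n_genes = 10)
#' expected_pair_frequency(cfg, "GTA", "R")
expected_pair_frequency <- function(config, prev, aa,
                                    class = c("low", "high")) {
  class <- match.arg(class)
  profile <- if (class == "low") config$codon_profile_low
             else config$codon_profile_high
  if (!aa %in% names(profile)) stop("unknown amino acid: ", aa)
  w <- profile[[aa]]
  cp <- config$couplings
  if (!is.null(cp)) {
    use <- cp$p_codon == prev & (cp$class == class | cp$class == "both") &
      cp$a_codon %in% names(w)
    for (r in which(use)) {
      w[cp$a_codon[r]] <- w[cp$a_codon[r]] * cp$m[r]
    }
  }
  w / sum(w)
}

#' Generate a synthetic proteome
#'
#' Draws, for each gene: a lognormal abundance; a sense-codon count whose log
#' correlates with log abundance at the configured (negative) coefficient; an
#' i.i.d. amino-acid sequence with the first residue forced to Met; codons
#' from the class profile (low below the median abundance, high above) with
#' first-order coupling multipliers applied and renormalized within each
#' synonymous family; and a terminal stop codon. Output passes strict CDS
#' validation and is deterministic given the seed.
#'
#' @param config A [generator_config()].
#' @return A list with elements \code{seqs} (a [cds_set()] with abundance
#'   set) and \code{abundance} (the matching 4-column abundance table).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  tab <- standard_codon_table()
  aa_of <- stats::setNames(tab$aa, tab$codon)
  n <- config$n_genes
  set.seed(config$seed)

  # abundance and correlated length (bivariate normal on the log scale)
  z_a <- rnorm(n)
  rho <- config$length_abundance_cor
  z_l <- rho * z_a + sqrt(1 - rho^2) * rnorm(n)
  abundance <- exp(config$abundance_meanlog + config$abundance_sdlog * z_a)
  len <- pmax(config$min_codons,
              as.integer(round(exp(config$length_meanlog +
                                   config$length_sdlog * z_l))))
  cls <- ifelse(abundance < median(abundance), "low", "high")

  # amino-acid sequences: position 1 is Met, the rest i.i.d.
  gene_of <- rep.int(seq_len(n), len)
  first <- c(1L, cumsum(len)[-n] + 1L)
  aa_seq <- sample(names(config$aa_frequencies), sum(len), replace = TRUE,
                   prob = config$aa_frequencies)
  aa_seq[first] <- "M"

  # codons drawn i.i.d. per (class, amino acid) from the class profile
  codons <- character(sum(len))
  for (cl in c("low", "high")) {
    profile <- if (cl == "low") config$codon_profile_low
               else config$codon_profile_high
    in_cl <- cls[gene_of] == cl
    for (aa in names(profile)) {
      pos <- which(in_cl & aa_seq == aa)
      if (!length(pos)) next
      w <- profile[[aa]]
      codons[pos] <- if (length(w) == 1L) names(w)
                     else sample(names(w), length(pos), replace = TRUE, prob = w)
    }
  }

  # first-order couplings: walk affected genes left to right, redrawing the
  # codon wherever the (already final) previous codon triggers a coupling;
  # untouched positions keep their i.i.d. draw, which is the correct
  # conditional when no coupling applies.
  cp <- config$couplings
  if (!is.null(cp) && nrow(cp)) {
    p_set <- unique(cp$p_codon)
    for (g in seq_len(n)) {
      gene_cp <- cp[cp$class == "both" | cp$class == cls[g], , drop = FALSE]
      if (!nrow(gene_cp)) next
      lo <- first[g]
      v <- codons[lo:(lo + len[g] - 1L)]
      a <- aa_seq[lo:(lo + len[g] - 1L)]
      t <- 2L
      while (t <= len[g]) {
        if (v[t - 1L] %in% p_set) {
          hit <- gene_cp$p_codon == v[t - 1L] &
            aa_of[gene_cp$a_codon] == a[t]
          if (any(hit)) {
            profile <- if (cls[g] == "low") config$codon_profile_low
                       else config$codon_profile_high
            w <- profile[[a[t]]]
            for (r in which(hit)) {
              w[gene_cp$a_codon[r]] <- w[gene_cp$a_codon[r]] * gene_cp$m[r]
            }
            v[t] <- sample(names(w), 1L, prob = w)
          }
        }
        t <- t + 1L
      }
      codons[lo:(lo + len[g] - 1L)] <- v
    }
  }

  stops <- sample(names(config$stop_codon_weights), n, replace = TRUE,
                  prob = config$stop_codon_weights)
  nt <- vapply(split(codons, gene_of), paste, character(1), collapse = "")
  nt <- paste0(nt, stops)
  ids <- sprintf("SYNG%05d", seq_len(n))
  seqs <- cds_set(ids, nt, abundance)
  abund <- data.frame(index = seq_len(n), id = ids, abundance = abundance,
                      cds_length = nchar(nt), stringsAsFactors = FALSE)
  list(seqs = seqs, abundance = abund)
}
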