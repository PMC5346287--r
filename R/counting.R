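# Codon and bicodon counting over a sequence sample, synonymous groups,
# and relative synonymous codon usage.

# Encode a normalized nt string as integer codon indices into .CODONS.
.encode_codons <- function(nt) {
  n <- nchar(nt)
  match(substring(nt, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L)), .CODONS)
}

# Counting core shared with the shuffle null: `enc` is a list of integer
# codon vectors, one per sequence.
.count_encoded <- function(enc, index) {
  lookup <- attr(index, "lookup")
  all_c <- unlist(enc, use.names = FALSE)
  f <- tabulate(all_c, 64L)
  p <- unlist(lapply(enc, function(v) v[-length(v)]), use.names = FALSE)
  a <- unlist(lapply(enc, function(v) v[-1L]), use.names = FALSE)
  bid <- lookup[cbind(p, a)]
  o <- tabulate(bid[!is.na(bid)], nrow(index))
  structure(list(f = stats::setNames(f, .CODONS),
                 o = stats::setNames(o, index$bicodon),
                 n_tot = sum(f), n_p = sum(o)),
            class = "sample_counts")
}

#' Count codons and bicodons over a sequence sample
#'
#' Reads every sequence in frame 0 and counts all 64 codons (vector
#' \code{f}, total \code{n_tot}) and all overlapping adjacent codon pairs
#' (vector \code{o} over the 3,904-bicodon universe, total \code{n_p}) —
#' each codon participates in up to two bicodons, and the final sense:stop
#' pair is included. For a sample of valid CDS with codon counts c_k,
#' \code{n_p} equals the sum of (c_k - 1). Counts are additive over
#' sequences and invariant to their order.
#'
#' @param seqs A [cds_set()] of valid CDS.
#' @param index A [enumerate_bicodons()] index.
#' @return A list of class \code{sample_counts} with elements \code{f},
#'   \code{o}, \code{n_tot}, \code{n_p}.
#' @export
#' @examples
#' s <- cds_set("x", "ATGAAGAAGTAA")
#' cnt <- count_sample(s, enumerate_bicodons())
#' cnt$n_tot  # 4 codons
#' cnt$n_p    # 3 bicodons
count_sample <- function(seqs, index = enumerate_bicodons()) {
  bad <- validate_cds(seqs, "lenient")
  if (length(bad))
    stop("invalid CDS in sample: '", names(bad)[1], "': ", bad[1])
  if (!nrow(seqs)) {
    return(structure(list(
      f = stats::setNames(integer(64L), .CODONS),
      o = stats::setNames(integer(nrow(index)), index$bicodon),
      n_tot = 0L, n_p = 0L), class = "sample_counts"))
  }
  .count_encoded(lapply(seqs$nt, .encode_codons), index)
}

#' Synonymous bicodon groups
#'
#' Partitions the bicodon universe into its dipeptide groups: all bicodons
#' encoding the same amino-acid pair (the three stop codons count as one
#' A-site symbol, \code{"*"}). Group size \code{q_ap} is the number of member
#' bicodons; when counts are supplied, the per-sample totals \code{n_ap_L}
#' and \code{n_ap_H} are the summed member counts.
#'
#' @param index A [enumerate_bicodons()] index.
#' @param counts_L,counts_H Optional [count_sample()] results.
#' @return Data frame with one row per dipeptide: \code{dipeptide},
#'   \code{q_ap} and (if counts given) \code{n_ap_L}, \code{n_ap_H}.
#'   Attribute \code{group_of} maps each bicodon row of \code{index} to its
#'   group row.
#' @export
build_groups <- function(index, counts_L = NULL, counts_H = NULL) {
  grp <- factor(index$dipeptide)
  out <- data.frame(dipeptide = levels(grp),
                    q_ap = as.integer(tabulate(grp, nlevels(grp))),
                    stringsAsFactors = FALSE)
  if (!is.null(counts_L))
    out$n_ap_L <- as.vector(rowsum(as.numeric(counts_L$o), grp))
  if (!is.null(counts_H))
    out$n_ap_H <- as.vector(rowsum(as.numeric(counts_H$o), grp))
  attr(out, "group_of") <- as.integer(grp)
  out
}

#' Relative synonymous codon usage
#'
#' Classic RSCU over single codons: a codon's count scaled by its synonymous
#' family size over the family's total count. Families with zero total yield
#' RSCU 0. The three stop codons form one family.
#'
#' @param counts A [count_sample()] result.
#' @param table Codon table.
#' @return Named numeric vector over the 64 codons.
#' @export
compute_rscu <- function(counts, table = standard_codon_table()) {
  fam <- factor(table$aa)
  q <- tabulate(fam, nlevels(fam))[as.integer(fam)]
  tot <- as.vector(rowsum(as.numeric(counts$f), fam))[as.integer(fam)]
  out <- ifelse(tot > 0, q * counts$f / tot, 0)
  stats::setNames(out, table$codon)
}
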