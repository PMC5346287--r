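# Codon universe and the 3,904-bicodon index.

.CODON_BASES <- c("A", "C", "G", "T")

# 64 codons in lexicographic order.
.CODONS <- sort(do.call(
  paste0,
  expand.grid(.CODON_BASES, .CODON_BASES, .CODON_BASES,
              stringsAsFactors = FALSE)
))

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Standard genetic code as a codon table
#'
#' Returns the 64 codons of the standard genetic code in lexicographic order
#' with their amino-acid assignments (one-letter code; stop codons are
#' \code{"*"}). Exactly 61 sense and 3 stop codons.
#'
#' @return A data frame with columns \code{codon}, \code{aa} and
#'   \code{is_stop}.
#' @export
#' @examples
#' tab <- standard_codon_table()
#' sum(!tab$is_stop)  # 61 sense codons
standard_codon_table <- function() {
  aa <- as.character(Biostrings::GENETIC_CODE[.CODONS])
  data.frame(codon = .CODONS, aa = aa, is_stop = aa == "*",
             stringsAsFactors = FALSE)
}

#' Enumerate the bicodon universe
#'
#' Builds the ordered index of all valid bicodons: a sense codon in the
#' ribosomal P-site followed by any codon (sense or stop) in the A-site,
#' 61 x 64 = 3904 pairs. Pairs with a stop codon in the P-site are excluded
#' (a stop is always terminal in a valid CDS). Dipeptide labels use one-letter
#' amino acids with \code{"*"} for the stop signal, so the three stop codons
#' form a single A-site symbol and an aa:stop group has size
#' (codons of aa) x 3.
#'
#' @param table Codon table, as returned by [standard_codon_table()].
#' @return A data frame of class \code{bicodon_index} with one row per
#'   bicodon, in lexicographic order of the 6-mer: columns \code{bicodon},
#'   \code{p_codon}, \code{a_codon}, \code{dipeptide}. Attribute
#'   \code{lookup} is a 64 x 64 integer matrix mapping (P-site, A-site) codon
#'   index pairs to rows (NA for stop P-sites).
#' @export
#' @examples
#' idx <- enumerate_bicodons()
#' nrow(idx)                    # 3904
#' "ATGTAA" %in% idx$bicodon    # sense:stop pairs are included
#' "TAAATG" %in% idx$bicodon    # stop:sense pairs are not
enumerate_bicodons <- function(table = standard_codon_table()) {
  sense <- table$codon[!table$is_stop]
  p_codon <- rep(sense, each = 64L)
  a_codon <- rep(table$codon, times = length(sense))
  bic <- paste0(p_codon, a_codon)
  ord <- order(bic)
  idx <- data.frame(
    bicodon = bic[ord],
    p_codon = p_codon[ord],
    a_codon = a_codon[ord],
    stringsAsFactors = FALSE
  )
  aa_of <- stats::setNames(table$aa, table$codon)
  idx$dipeptide <- paste0(aa_of[idx$p_codon], aa_of[idx$a_codon])

  lookup <- matrix(NA_integer_, 64L, 64L,
                   dimnames = list(table$codon, table$codon))
  lookup[cbind(match(idx$p_codon, table$codon),
               match(idx$a_codon, table$codon))] <- seq_len(nrow(idx))
  attr(idx, "lookup") <- lookup
  attr(idx, "codons") <- table$codon
  class(idx) <- c("bicodon_index", "data.frame")
  idx
}
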