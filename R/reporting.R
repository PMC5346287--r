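# Heat-map matrices with clustered axes, cross-organism shared-bicodon
# tables, occupancy-filtered candidates, and synonymous-SNP reports.

# Deterministic leaf order from an hclust merge matrix: at every internal
# node the subtree containing the smallest leaf index comes first.
.leaf_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    l <- expand(merge[node, 1]); r <- expand(merge[node, 2])
    if (min(l) <= min(r)) c(l, r) else c(r, l)
  }
  expand(nrow(merge))
}

#' Build the P-site x A-site value matrix for one measure
#'
#' A 64 x 64 matrix (rows: P-site codons, columns: A-site codons) holding
#' one value per bicodon; the 3 stop-codon P-site rows (192 cells, the
#' difference between 64^2 and the 3,904-pair universe) are masked as NA.
#'
#' @param stats A [bicodon_stats()] data frame.
#' @param measure Column to spread: \code{"pi"} or \code{"signed_logp"}.
#' @param index The bicodon index the stats were computed on.
#' @return A 64 x 64 matrix with codon dimnames; attribute \code{measure}.
#' @export
heatmap_matrix <- function(stats, measure = c("pi", "signed_logp"),
                           index = enumerate_bicodons()) {
  measure <- match.arg(measure)
  stopifnot(measure %in% names(stats), nrow(stats) == nrow(index))
  m <- matrix(NA_real_, 64L, 64L, dimnames = list(.CODONS, .CODONS))
  m[cbind(match(index$p_codon, .CODONS), match(index$a_codon, .CODONS))] <-
    stats[[match(measure, names(stats))]][match(index$bicodon, stats$bicodon)]
  attr(m, "measure") <- measure
  m
}

#' Cluster the heat-map axes
#'
#' Average-linkage (UPGMA) hierarchical clustering of Euclidean distances
#' between codon profile vectors, independently for the P-site rows (the 61
#' sense codons; the 3 masked stop rows are appended at the bottom in input
#' order) and the A-site columns (all 64). Masked cells count as 0 in the
#' distances. Leaf order is deterministic: ties resolve by input order and
#' every subtree is oriented smallest-leaf-first.
#'
#' @param values A [heatmap_matrix()] (64 x 64, stop P rows NA).
#' @return List with integer permutations \code{row_order} (length 64) and
#'   \code{col_order} (length 64).
#' @export
cluster_axes <- function(values) {
  stopifnot(is.matrix(values), nrow(values) == 64L, ncol(values) == 64L)
  filled <- values
  filled[is.na(filled)] <- 0
  sense <- which(rowSums(!is.na(values)) > 0)
  masked <- setdiff(seq_len(64L), sense)

  row_hc <- stats::hclust(stats::dist(filled[sense, , drop = FALSE]),
                          method = "average")
  col_hc <- stats::hclust(stats::dist(t(filled)), method = "average")
  list(row_order = c(sense[.leaf_order(row_hc$merge)], masked),
       col_order = .leaf_order(col_hc$merge))
}

#' Export a clustered heat-map matrix
#'
#' Reorders the value matrix by the clustered axis permutations and
#' optionally writes it as TSV (one commented metadata line, a header of
#' A-site codons, one row per P-site codon). The TSV round-trips losslessly
#' via [read_heatmap_tsv()]. Rendering to an image is left to the caller
#' (the matrix is plot-ready).
#'
#' @param stats A [bicodon_stats()] data frame.
#' @param measure \code{"pi"} or \code{"signed_logp"}.
#' @param orders Axis permutations from [cluster_axes()]; computed when NULL.
#' @param path Optional TSV output path.
#' @param index Bicodon index.
#' @return The reordered matrix (attributes \code{measure},
#'   \code{row_order}, \code{col_order}, \code{n_masked}).
#' @export
export_heatmap <- function(stats, measure = c("pi", "signed_logp"),
                           orders = NULL, path = NULL,
                           index = enumerate_bicodons()) {
  m <- heatmap_matrix(stats, measure, index)
  if (is.null(orders)) orders <- cluster_axes(m)
  out <- m[orders$row_order, orders$col_order]
  attr(out, "measure") <- attr(m, "measure")
  attr(out, "row_order") <- orders$row_order
  attr(out, "col_order") <- orders$col_order
  attr(out, "n_masked") <- sum(is.na(out))
  if (!is.null(path)) {
    lines <- c(paste0("# bicodon heat map; measure=", attr(out, "measure")),
               paste(c("p_codon", colnames(out)), collapse = "\t"),
               vapply(seq_len(nrow(out)), function(i) {
                 paste(c(rownames(out)[i], .fmt_num(out[i, ])),
                       collapse = "\t")
               }, character(1)))
    writeLines(lines, path)
  }
  out
}

#' Read back a heat-map TSV
#'
#' @param path TSV written by [export_heatmap()].
#' @return Numeric matrix with codon dimnames; attribute \code{measure}.
#' @export
read_heatmap_tsv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  cols <- fields[[1]][-1]
  rows <- vapply(fields[-1], `[`, character(1), 1L)
  m <- t(vapply(fields[-1],
                function(f) suppressWarnings(as.numeric(f[-1])),
                numeric(length(cols))))
  dimnames(m) <- list(rows, cols)
  attr(m, "measure") <- sub("^.*measure=", "", meta[1])
  m
}

#' Bicodons with a shared, unexplained preference across organisms
#'
#' Intersects per-organism classified statistics: a bicodon is reported when,
#' in every organism, it is significant (p < alpha), its residual exceeds
#' the null threshold (max(z_L, z_H) >= z_threshold), and its pause
#' propensity has the requested sign (positive for \code{direction = "low"},
#' negative for \code{"high"}). Tightening alpha or the z threshold can only
#' remove rows.
#'
#' @param per_organism Named list of data frames, each a [bicodon_stats()]
#'   result augmented with \code{z_L} and \code{z_H} columns (as produced by
#'   [run_pipeline()]); all on the same bicodon index.
#' @param alpha,z_threshold Selection thresholds.
#' @param direction \code{"low"} or \code{"high"}.
#' @return Data frame: \code{dipeptide}, \code{bicodon}, then per organism
#'   the summed raw residual \code{chi2sum_*}, its SD-unit analogue
#'   \code{zsum_*}, and \code{neglog10p_*}.
#' @export
shared_bicodons <- function(per_organism, alpha = 0.01, z_threshold = 3,
                            direction = c("low", "high")) {
  direction <- match.arg(direction)
  stopifnot(length(per_organism) >= 1)
  if (is.null(names(per_organism)))
    names(per_organism) <- paste0("org", seq_along(per_organism))
  ref <- per_organism[[1]]
  for (s in per_organism[-1]) {
    if (!identical(s$bicodon, ref$bicodon))
      stop("per-organism statistics are not on the same bicodon index")
  }
  pass <- lapply(per_organism, function(s) {
    z <- pmax(s$z_L, s$z_H)
    ok <- s$p_value < alpha & !is.na(z) & z >= z_threshold
    ok & if (direction == "low") s$pi > 0 else s$pi < 0
  })
  shared <- Reduce(`&`, pass)
  out <- data.frame(dipeptide = ref$dipeptide[shared],
                    bicodon = ref$bicodon[shared],
                    stringsAsFactors = FALSE)
  for (org in names(per_organism)) {
    s <- per_organism[[org]]
    out[[paste0("chi2sum_", org)]] <- (s$chi2_L + s$chi2_H)[shared]
    out[[paste0("zsum_", org)]] <- (s$z_L + s$z_H)[shared]
    out[[paste0("neglog10p_", org)]] <- -log10(s$p_value[shared])
  }
  out
}

#' Occupancy-filtered pause candidates
#'
#' Bicodons with a strong low-abundance preference (pi > pi_min), a
#' significant Fisher test (p < alpha) and a cumulative ribosome occupancy
#' above occ_min — all inequalities strict. Bicodons absent from the
#' occupancy table are excluded with a warning.
#'
#' @param stats A [bicodon_stats()] data frame.
#' @param occupancy Data frame with columns \code{bicodon} and
#'   \code{occupancy} (cumulative ribosome occupancy per bicodon).
#' @param pi_min,alpha,occ_min Thresholds (defaults 0.75, 0.01, 0.03).
#' @return The passing rows of \code{stats} with an \code{occupancy} column
#'   appended.
#' @export
occupancy_candidates <- function(stats, occupancy, pi_min = 0.75,
                                 alpha = 0.01, occ_min = 0.03) {
  stopifnot(all(c("bicodon", "occupancy") %in% names(occupancy)))
  occ <- occupancy$occupancy[match(stats$bicodon, occupancy$bicodon)]
  n_missing <- sum(is.na(occ))
  if (n_missing > 0)
    warning(n_missing, " bicodon(s) missing from the occupancy table ",
            "were excluded")
  keep <- !is.na(occ) & stats$pi > pi_min & stats$p_value < alpha &
    occ > occ_min
  out <- stats[keep, , drop = FALSE]
  out$occupancy <- occ[keep]
  out
}

#' Pause-propensity effect of a synonymous SNP
#'
#' For a synonymous codon substitution at a given position of a coding
#' sequence, reports the pause propensities of the two flanking bicodons
#' under the reference and variant codon, the change delta_pi = pi(alt) -
#' pi(ref) on each side, and (when sample counts are supplied) the relative
#' synonymous codon usage of both codons. The downstream bicodon
#' (ref/alt codon in the P-site, next codon in the A-site) is the one the
#' reference analysis discusses. Values missing from the statistics table
#' are reported as NA, not zero; edge positions yield a one-sided report.
#'
#' @param cds A single-row [cds_set()] (or list with \code{id} and
#'   \code{nt}).
#' @param codon_pos 1-based codon position of the SNP.
#' @param alt_codon Variant codon; must be synonymous with the reference.
#' @param stats A [bicodon_stats()] data frame supplying pi values.
#' @param counts Optional [count_sample()] result for RSCU of ref and alt.
#' @return A list of class \code{snp_report}.
#' @export
snp_effect <- function(cds, codon_pos, alt_codon, stats, counts = NULL) {
  nt <- cds$nt[1]
  cods <- .CODONS[.encode_codons(nt)]
  if (codon_pos < 1 || codon_pos > length(cods))
    stop("codon_pos out of range")
  ref <- cods[codon_pos]
  gc <- Biostrings::GENETIC_CODE
  if (!alt_codon %in% names(gc)) stop("unknown codon: ", alt_codon)
  if (gc[[ref]] != gc[[alt_codon]])
    stop("variant codon ", alt_codon, " is not synonymous with ", ref,
         " (", gc[[ref]], " vs ", gc[[alt_codon]], ")")
  pi_of <- function(bic) {
    if (is.na(bic)) return(NA_real_)
    i <- match(bic, stats$bicodon)
    if (is.na(i)) NA_real_ else stats$pi[i]
  }
  prev <- if (codon_pos > 1) cods[codon_pos - 1] else NA_character_
  nxt <- if (codon_pos < length(cods)) cods[codon_pos + 1] else NA_character_
  up <- data.frame(
    bicodon_ref = ifelse(is.na(prev), NA, paste0(prev, ref)),
    bicodon_alt = ifelse(is.na(prev), NA, paste0(prev, alt_codon)),
    stringsAsFactors = FALSE)
  up$pi_ref <- pi_of(up$bicodon_ref)
  up$pi_alt <- pi_of(up$bicodon_alt)
  up$delta_pi <- up$pi_alt - up$pi_ref
  down <- data.frame(
    bicodon_ref = ifelse(is.na(nxt), NA, paste0(ref, nxt)),
    bicodon_alt = ifelse(is.na(nxt), NA, paste0(alt_codon, nxt)),
    stringsAsFactors = FALSE)
  down$pi_ref <- pi_of(down$bicodon_ref)
  down$pi_alt <- pi_of(down$bicodon_alt)
  down$delta_pi <- down$pi_alt - down$pi_ref
  rscu <- if (!is.null(counts)) compute_rscu(counts) else NULL
  structure(list(
    id = cds$id[1], codon_pos = codon_pos, ref_codon = ref,
    alt_codon = alt_codon, aa = unname(gc[[ref]]),
    upstream = up, downstream = down,
    rscu_ref = if (is.null(rscu)) NA_real_ else unname(rscu[ref]),
    rscu_alt = if (is.null(rscu)) NA_real_ else unname(rscu[alt_codon])
  ), class = "snp_report")
}

#' @export
print.snp_report <- function(x, ...) {
  cat(sprintf("Synonymous SNP in %s at codon %d: %s -> %s (%s)\n",
              x$id, x$codon_pos, x$ref_codon, x$alt_codon, x$aa))
  cat(sprintf("  upstream   %s -> %s: pi %s -> %s (delta %s)\n",
              x$upstream$bicodon_ref, x$upstream$bicodon_alt,
              format(x$upstream$pi_ref), format(x$upstream$pi_alt),
              format(x$upstream$delta_pi)))
  cat(sprintf("  downstream %s -> %s: pi %s -> %s (delta %s)\n",
              x$downstream$bicodon_ref, x$downstream$bicodon_alt,
              format(x$downstream$pi_ref), format(x$downstream$pi_alt),
              format(x$downstream$delta_pi)))
  if (!is.na(x$rscu_ref))
    cat(sprintf("  RSCU: ref %s = %.3f, alt %s = %.3f\n",
                x$ref_codon, x$rscu_ref, x$alt_codon, x$rscu_alt))
  invisible(x)
}

#' Write a statistics table as commented TSV
#'
#' One commented column-description line, a header row, then the data;
#' numeric columns round-trip bit-identically through [read_stats_tsv()].
#'
#' @param stats Data frame.
#' @param path Output path.
#' @param comment Text for the leading comment line.
#' @return Invisibly, \code{path}.
#' @export
write_stats_tsv <- function(stats, path, comment = "bicodon statistics") {
  cols <- lapply(stats, function(col) {
    if (is.numeric(col)) .fmt_num(col) else as.character(col)
  })
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(paste0("# ", comment),
               paste(names(stats), collapse = "\t"), body), path)
  invisible(path)
}

#' Read back a commented statistics TSV
#'
#' @param path TSV written by [write_stats_tsv()].
#' @return Data frame; columns that parse fully as numbers become numeric.
#' @export
read_stats_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  m <- do.call(rbind, fields[-1])
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- header
  for (j in seq_along(out)) {
    v <- suppressWarnings(as.numeric(out[[j]]))
    if (!any(is.na(v) & out[[j]] != "NA")) {
      out[[j]] <- v
    }
  }
  out
}
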