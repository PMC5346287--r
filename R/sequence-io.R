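# Reading, validating and writing coding sequences and abundance tables.

#' Construct a set of coding sequences
#'
#' A \code{cds_set} is a data frame with one row per coding sequence:
#' \code{id}, the nucleotide string \code{nt} (A/C/G/T), an optional
#' \code{abundance} (e.g. ppm) and the codon count \code{n_codons}
#' (= nchar(nt)/3, terminal stop included).
#'
#' @param id Character vector of identifiers.
#' @param nt Character vector of nucleotide strings (normalized with
#'   [normalize_nt()] first if needed).
#' @param abundance Optional numeric vector of protein abundances.
#' @return A data frame of class \code{cds_set}.
#' @export
cds_set <- function(id, nt, abundance = NA_real_) {
  stopifnot(length(id) == length(nt))
  out <- data.frame(id = as.character(id), nt = as.character(nt),
                    abundance = rep_len(as.numeric(abundance), length(id)),
                    stringsAsFactors = FALSE)
  out$n_codons <- nchar(out$nt) %/% 3L
  class(out) <- c("cds_set", "data.frame")
  out
}

#' Normalize a nucleotide string
#'
#' Case-folds to upper case and converts U to T, so RNA-style records become
#' plain DNA coding sequences.
#'
#' @param nt Character vector.
#' @return Normalized character vector.
#' @export
#' @examples
#' normalize_nt("augaagaaguaa")  # "ATGAAGAAGTAA"
normalize_nt <- function(nt) {
  chartr("U", "T", toupper(nt))
}

# Validates one normalized sequence; returns NULL if valid, else a short
# message describing the first violated rule under the given policy.
.cds_problem <- function(nt, policy) {
  n <- nchar(nt)
  if (n == 0L || n %% 3L != 0L)
    return(sprintf("length %d is not a positive multiple of 3", n))
  if (grepl("[^ACGT]", nt))
    return("contains characters other than A/C/G/T")
  if (policy == "strict") {
    cods <- substring(nt, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
    k <- length(cods)
    if (!cods[k] %in% .STOP_CODONS)
      return("final codon is not a stop codon")
    if (k > 1L && any(cods[-k] %in% .STOP_CODONS))
      return("internal stop codon")
  }
  NULL
}

#' Validate a set of coding sequences
#'
#' Under the \code{strict} policy a valid CDS has length a positive multiple
#' of 3, only A/C/G/T, a terminal stop codon and no internal stop. The
#' \code{lenient} policy drops the two stop-codon rules (real-world CDS
#' exports sometimes omit the stop).
#'
#' @param seqs A [cds_set()].
#' @param policy \code{"strict"} or \code{"lenient"}.
#' @return Character vector of problem messages, named by sequence id; empty
#'   when all records validate.
#' @export
validate_cds <- function(seqs, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  problems <- vapply(seqs$nt, function(s) {
    p <- .cds_problem(s, policy)
    if (is.null(p)) NA_character_ else p
  }, character(1), USE.NAMES = FALSE)
  stats::setNames(problems, seqs$id)[!is.na(problems)]
}

#' Read coding sequences from a FASTA file
#'
#' Records are normalized (case-folded, U to T) and validated. Under the
#' \code{strict} policy (the default, appropriate for synthetic data and
#' clean CDS exports) any invalid record aborts with its identifier; the
#' \code{lenient} policy skips invalid records with a warning.
#'
#' @param path Path to a FASTA file (gzipped accepted).
#' @param policy \code{"strict"} or \code{"lenient"}.
#' @return A [cds_set()] of the validated records (abundance unset).
#' @export
read_cds_fasta <- function(path, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  nt <- normalize_nt(as.character(raw))
  seqs <- cds_set(ids, nt)
  bad <- validate_cds(seqs, policy)
  if (length(bad)) {
    if (policy == "strict") {
      stop("invalid CDS record '", names(bad)[1], "': ", bad[1])
    }
    warning(length(bad), " invalid record(s) skipped: ",
            paste(utils::head(names(bad), 5L), collapse = ", "),
            if (length(bad) > 5L) ", ..." else "")
    seqs <- seqs[!seqs$id %in% names(bad), , drop = FALSE]
    class(seqs) <- c("cds_set", "data.frame")
  }
  seqs
}

#' Write coding sequences to a FASTA file
#'
#' @param seqs A [cds_set()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_cds_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(seqs$nt, seqs$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Shortest decimal string that reads back to the identical double.
.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- as.character(v)
    if (!is.na(as.numeric(s)) && as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1))
}

#' Read a protein-abundance table
#'
#' Parses a 4-column whitespace- or tab-separated table: internal index,
#' gene/transcript/protein identifier, protein abundance, coding-sequence
#' length (nucleotides). Lines starting with \code{#} and an optional header
#' line are skipped. Rows with a non-numeric abundance abort with their row
#' number.
#'
#' @param path Path to the table.
#' @return A data frame with columns \code{index}, \code{id},
#'   \code{abundance}, \code{cds_length}.
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("abundance table not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("abundance table is empty: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 4L))
    stop("malformed abundance table row ", which(ncols < 4L)[1],
         ": fewer than 4 columns")
  # header detection: first row whose index or abundance field is non-numeric
  first <- fields[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[3]))) ||
    is.na(suppressWarnings(as.numeric(first[1])))
  if (has_header) fields <- fields[-1]
  if (!length(fields)) stop("abundance table has a header but no rows: ", path)
  m <- do.call(rbind, lapply(fields, `[`, 1:4))
  abundance <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(abundance))
    stop("non-numeric abundance in data row(s): ",
         paste(which(is.na(abundance)), collapse = ", "))
  cds_length <- suppressWarnings(as.numeric(m[, 4]))
  if (anyNA(cds_length))
    stop("non-numeric length in data row(s): ",
         paste(which(is.na(cds_length)), collapse = ", "))
  data.frame(index = as.integer(m[, 1]), id = m[, 2],
             abundance = abundance, cds_length = as.integer(cds_length),
             stringsAsFactors = FALSE)
}

#' Write a protein-abundance table
#'
#' Writes the 4-column layout read by [read_abundance_table()], preceded by a
#' commented header line. Numeric values round-trip bit-identically.
#'
#' @param tab Data frame with columns \code{index}, \code{id},
#'   \code{abundance}, \code{cds_length}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_abundance_table <- function(tab, path) {
  lines <- c("# index\tid\tabundance\tcds_length",
             paste(tab$index, tab$id, .fmt_num(tab$abundance),
                   tab$cds_length, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Attach abundances to coding sequences by identifier
#'
#' Joins an abundance table onto a sequence set by exact identifier match
#' (optionally after stripping trailing \code{.N} version suffixes, as
#' carried by Ensembl identifiers). Unmatched identifiers on either side are
#' reported; sequences whose stored \code{cds_length} disagrees with the
#' actual sequence length draw a warning. Identifier mapping between
#' databases is the caller's responsibility.
#'
#' @param seqs A [cds_set()].
#' @param tab Abundance table as from [read_abundance_table()].
#' @param strip_versions If TRUE, strip \code{.N} suffixes from both sides
#'   before matching.
#' @return The matched subset of \code{seqs} with \code{abundance} filled in.
#' @export
join_sequences_abundance <- function(seqs, tab, strip_versions = FALSE) {
  sid <- seqs$id
  tid <- tab$id
  if (strip_versions) {
    sid <- sub("\\.[0-9]+$", "", sid)
    tid <- sub("\\.[0-9]+$", "", tid)
  }
  if (anyDuplicated(tid))
    stop("duplicate id(s) in abundance table: ",
         paste(unique(tid[duplicated(tid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate id(s) among sequences: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  hit <- match(sid, tid)
  if (!any(!is.na(hit)))
    stop("no sequence id matches the abundance table; ",
         "likely an identifier-scheme mismatch")
  unmatched_seq <- seqs$id[is.na(hit)]
  unmatched_tab <- tab$id[!tid %in% sid]
  if (length(unmatched_seq) || length(unmatched_tab))
    message(length(unmatched_seq), " sequence(s) and ", length(unmatched_tab),
            " table row(s) had no match and were dropped")
  keep <- !is.na(hit)
  out <- seqs[keep, , drop = FALSE]
  out$abundance <- tab$abundance[hit[keep]]
  mismatch <- tab$cds_length[hit[keep]] != nchar(out$nt)
  if (any(mismatch))
    warning("cds_length disagrees with sequence length for: ",
            paste(utils::head(out$id[mismatch], 5L), collapse = ", "),
            if (sum(mismatch) > 5L) ", ..." else "")
  class(out) <- c("cds_set", "data.frame")
  out
}
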