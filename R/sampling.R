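# Length-matched selection of low- and high-abundance sequence samples.

#' Keep one isoform per gene
#'
#' When several records map to the same gene, only the most abundant one is
#' retained (ties broken by lexicographically smallest id, so the result is
#' deterministic).
#'
#' @param records Abundance table (see [read_abundance_table()]).
#' @param id_to_gene Optional named character vector mapping record ids to
#'   gene ids; the identity mapping is used when omitted.
#' @return The deduplicated subset of \code{records}, in input order.
#' @export
dedupe_isoforms <- function(records, id_to_gene = NULL) {
  gene <- if (is.null(id_to_gene)) records$id else {
    if (any(!records$id %in% names(id_to_gene)))
      stop("id_to_gene mapping is missing some record ids")
    unname(id_to_gene[records$id])
  }
  ord <- order(gene, -records$abundance, records$id)
  keep_rows <- ord[!duplicated(gene[ord])]
  records[sort(keep_rows), , drop = FALSE]
}

#' Gaussian length-acceptance function
#'
#' The acceptance probability of the rejection sampler,
#' \code{exp(-(l - l_o)^2 / (2 * sigma))}: maximal (= 1) at \code{l = l_o}
#' and strictly decreasing in \code{|l - l_o|}. \code{sigma} plays a
#' variance-like role (squared length units).
#'
#' @param l Sequence length(s).
#' @param l_o Target mean length (same units as \code{l}).
#' @param sigma Spread parameter (> 0), in squared length units.
#' @return Acceptance probabilities in (0, 1].
#' @export
length_acceptance <- function(l, l_o, sigma) {
  stopifnot(sigma > 0)
  exp(-(l - l_o)^2 / (2 * sigma))
}

#' Fit the acceptance-rule parameters from a candidate pool
#'
#' Sets the target \code{l_o} to the pooled mean length and \code{sigma} to
#' \code{(SD/3)^2}, i.e. an acceptance kernel whose standard deviation is one
#' third of the pooled length SD. That bandwidth makes the mean lengths of
#' the two selected tails agree to well under 0.2 pooled SD while keeping the
#' selection inside the extreme ~30% of the abundance ordering (see the
#' methods vignette for the calibration).
#'
#' @param records Abundance table; lengths taken from \code{cds_length}.
#' @return List with \code{l_o} and \code{sigma}.
#' @export
fit_length_params <- function(records) {
  l <- records$cds_length
  list(l_o = mean(l), sigma = (stats::sd(l) / 3)^2)
}

#' Sampler configuration
#'
#' @param n_select Number of records to select (the reference analysis uses
#'   500 per class).
#' @param direction \code{"low"} to walk from the lowest-abundance end,
#'   \code{"high"} from the highest.
#' @param l_o,sigma Acceptance-rule parameters; when NULL they are fitted
#'   from the candidate pool with [fit_length_params()].
#' @param seed Integer seed for the acceptance draws.
#' @param max_passes Maximum number of passes over still-unaccepted records
#'   before giving up.
#' @return A list of class \code{sampler_config}.
#' @export
sampler_config <- function(n_select = 500L, direction = c("low", "high"),
                           l_o = NULL, sigma = NULL, seed = 1L,
                           max_passes = 100L) {
  direction <- match.arg(direction)
  stopifnot(n_select >= 1, max_passes >= 1, is.null(sigma) || sigma > 0)
  structure(list(n_select = as.integer(n_select), direction = direction,
                 l_o = l_o, sigma = sigma, seed = as.integer(seed),
                 max_passes = as.integer(max_passes)),
            class = "sampler_config")
}

#' Select a length-matched abundance-extreme sample
#'
#' Orders records by increasing abundance (ties by id) and walks from the
#' low- or high-abundance end. Each candidate is accepted when
#' \code{exp(-(l - l_o)^2/(2 sigma)) > r}, with \code{r} uniform on (0, 1)
#' from the seeded stream; the walk stops as soon as \code{n_select} records
#' are accepted. If a full pass over the list accepts fewer, further passes
#' revisit the unaccepted records with fresh draws, up to
#' \code{max_passes}. Deterministic given (records, config).
#'
#' @param records Abundance table with \code{abundance} and
#'   \code{cds_length}.
#' @param config A [sampler_config()].
#' @return The selected records in acceptance order (exactly
#'   \code{n_select} rows), or an error if the quota cannot be met.
#' @export
select_length_matched <- function(records, config) {
  stopifnot(inherits(config, "sampler_config"))
  n_select <- config$n_select
  if (nrow(records) < n_select)
    stop("fewer candidate records (", nrow(records), ") than n_select (",
         n_select, ")")
  fit <- fit_length_params(records)
  l_o <- if (is.null(config$l_o)) fit$l_o else config$l_o
  sigma <- if (is.null(config$sigma)) fit$sigma else config$sigma

  ord <- order(records$abundance, records$id)
  if (config$direction == "high") ord <- rev(ord)

  set.seed(config$seed)
  accepted <- integer(0)
  remaining <- ord
  for (pass in seq_len(config$max_passes)) {
    r_l <- length_acceptance(records$cds_length[remaining], l_o, sigma)
    r <- runif(length(remaining))
    hits <- which(r_l > r)
    need <- n_select - length(accepted)
    take <- utils::head(hits, need)
    accepted <- c(accepted, remaining[take])
    if (length(accepted) == n_select) break
    if (length(hits)) remaining <- remaining[-hits]
    if (!length(remaining)) break
  }
  if (length(accepted) < n_select)
    stop("only ", length(accepted), " of ", n_select, " records accepted ",
         "after ", config$max_passes, " passes; consider a larger sigma")
  records[accepted, , drop = FALSE]
}
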