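#' Majority consensus at one site
#'
#' Calls the strictly most frequent base when it carries at least 50% of
#' the counted reads. An exact two-way tie at 50% yields no call and the
#' site is treated as uncovered; likewise any multi-way tie for the
#' maximum, and zero depth.
#'
#' @param counts Named integer vector over `A`, `C`, `G`, `T`.
#' @return List with `base` (`NA` for no-call), `coverage`, and
#'   `agreement` (majority count / coverage; 0 when no call).
#' @examples
#' majority_consensus(c(A = 4L, C = 0L, G = 0L, T = 2L))
#' @export
majority_consensus <- function(counts) {
  counts <- counts[c("A", "C", "G", "T")]
  stopifnot(!anyNA(counts), all(counts >= 0))
  depth <- sum(counts)
  if (depth == 0L)
    return(list(base = NA_character_, coverage = 0L, agreement = 0))
  mx <- max(counts)
  agree <- mx / depth
  if (sum(counts == mx) != 1L || agree < 0.5)
    return(list(base = NA_character_, coverage = as.integer(depth),
                agreement = 0))
  list(base = names(counts)[which.max(counts)],
       coverage = as.integer(depth), agreement = agree)
}

#' Add consensus columns to a site table
#'
#' Vectorised [majority_consensus()] over a pileup site table: appends
#' `cons` (consensus base, `NA` for no-call) and `agree` (agreement
#' fraction, 0 for no-call).
#'
#' @param sites Site table as returned by [read_pileup()].
#' @return A copy of `sites` with `cons` and `agree` columns.
#' @export
consensus_calls <- function(sites) {
  sites <- data.table::copy(sites)
  cm <- as.matrix(sites[, .(A, C, G, T)])
  depth <- rowSums(cm)
  mx <- do.call(pmax, as.data.frame(cm))
  n_at_max <- rowSums(cm == mx)
  agree <- ifelse(depth > 0, mx / depth, 0)
  called <- depth > 0 & n_at_max == 1L & agree >= 0.5
  cons <- rep(NA_character_, nrow(cm))
  cons[called] <- colnames(cm)[max.col(cm[called, , drop = FALSE],
                                       ties.method = "first")]
  sites[, cons := cons]
  sites[, agree := ifelse(called, agree, 0)]
  sites[]
}

#' Mean coverage over uniquely mappable, covered sites
#'
#' Arithmetic mean of counted depth over sites that are uniquely
#' mappable and have depth at least 1. Lines sequenced to different
#' depths get different means; the high-coverage cap in the calling
#' rules multiplies each line's own mean.
#'
#' @param sites Site table for one line.
#' @param mask A [mappability_mask] aligned with `sites`, or `NULL` to
#'   use all sites.
#' @param line Optional line identifier carried into the result.
#' @return List with `line`, `mean_coverage`, `n_sites`.
#' @export
mean_coverage <- function(sites, mask = NULL, line = NA_character_) {
  keep <- sites$depth >= 1L
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "mappability_mask"),
              length(mask$unique) >= max(sites$pos))
    keep <- keep & mask$unique[sites$pos]
  }
  if (!any(keep)) stop("mean_coverage: no covered unique sites")
  list(line = line, mean_coverage = mean(sites$depth[keep]),
       n_sites = sum(keep))
}
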