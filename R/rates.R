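#' Exact (Garwood) Poisson confidence interval for a count
#'
#' Chi-square construction: lower bound `qchisq(alpha/2, 2k)/2` (0 for
#' `k = 0`), upper bound `qchisq(1 - alpha/2, 2k + 2)/2`. Coverage is
#' conservative (at least the nominal level).
#'
#' @param k Observed count (non-negative integer).
#' @param level Confidence level (default 0.95).
#' @return An object of class `poisson_interval` with fields `count`,
#'   `level`, `lower`, `upper`.
#' @examples
#' poisson_ci(1)   # upper bound 5.572
#' @export
poisson_ci <- function(k, level = 0.95) {
  stopifnot(length(k) == 1L, k >= 0, k == round(k), level > 0, level < 1)
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qchisq(alpha / 2, 2 * k) / 2
  upper <- stats::qchisq(1 - alpha / 2, 2 * k + 2) / 2
  structure(list(count = as.integer(k), level = level,
                 lower = lower, upper = upper),
            class = "poisson_interval")
}

#' @export
print.poisson_interval <- function(x, ...) {
  cat(sprintf("Poisson %.0f%% CI for count %d: [%.4g, %.4g]\n",
              100 * x$level, x$count, x$lower, x$upper))
  invisible(x)
}

#' Point mutation rate per site per generation
#'
#' @param m Number of mutations.
#' @param n Number of sites at which a mutation could have been
#'   observed.
#' @param g Number of cell generations.
#' @return A `rate_estimate` without an interval.
#' @examples
#' point_rate(1, 34653718, 1000)  # 2.9e-11
#' @export
point_rate <- function(m, n, g) {
  stopifnot(m >= 0, n >= 1, g >= 1)
  structure(list(m = m, n = n, g = g, rate = m / (n * g),
                 ci_lower = NA_real_, ci_upper = NA_real_,
                 level = NA_real_),
            class = "rate_estimate")
}

#' Mutation rate with an exact Poisson confidence interval
#'
#' The Poisson interval on the mutation count is divided by `n * g`,
#' giving bounds on the per-site per-generation rate.
#'
#' @inheritParams point_rate
#' @param level Confidence level (default 0.95).
#' @return A `rate_estimate` with fields `m`, `n`, `g`, `rate`,
#'   `ci_lower`, `ci_upper`, `level`.
#' @examples
#' rate_ci(1, 34653718, 1000)  # upper bound 1.6e-10
#' @export
rate_ci <- function(m, n, g, level = 0.95) {
  est <- point_rate(m, n, g)
  ci <- poisson_ci(m, level)
  est$ci_lower <- ci$lower / (n * g)
  est$ci_upper <- ci$upper / (n * g)
  est$level <- level
  est
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Mutation rate: %s per site per generation (m=%s, n=%s, g=%s)\n",
              signif(x$rate, 2), format(x$m), format(x$n, big.mark = ","),
              format(x$g)))
  if (!is.na(x$ci_lower))
    cat(sprintf("  %.0f%% Poisson CI: [%s, %s]\n", 100 * x$level,
                signif(x$ci_lower, 2), signif(x$ci_upper, 2)))
  invisible(x)
}

#' Sequencing/alignment error rate from disagreement with the majority
#'
#' Per site, the error fraction is the fraction of counted reads that
#' disagree with the majority base, `(depth - majority count) / depth`.
#' The estimate is the average over sites for each line individually,
#' and the overall value is the unweighted mean of the line means.
#'
#' With `filtered = TRUE` the sites are restricted to those passing the
#' focal selection criteria (uniquely mappable, depth within
#' `[min_cov_focal, max_cov_factor * line mean]`, a majority call with
#' at least `min_agree_focal` agreement), which mirrors the error rate
#' among the sites actually used for calling.
#'
#' @param pileups Named list of per-line site tables.
#' @param mask A [mappability_mask] (required when `filtered = TRUE`).
#' @param filtered Restrict to sites passing the focal filters.
#' @param params A [filter_params] used when `filtered = TRUE`.
#' @return List with `per_line` (named means), `overall`, `sd`,
#'   `ci_halfwidth` (t-based, across lines), `n_sites` per line.
#' @export
error_rate <- function(pileups, mask = NULL, filtered = FALSE,
                       params = filter_params()) {
  stopifnot(is.list(pileups), length(pileups) >= 1L)
  per_line <- numeric(0)
  n_sites <- integer(0)
  for (l in names(pileups)) {
    s <- consensus_calls(pileups[[l]])
    cm <- as.matrix(s[, .(A, C, G, T)])
    mx <- do.call(pmax, as.data.frame(cm))
    keep <- s$depth >= 1L
    if (filtered) {
      if (is.null(mask)) stop("error_rate: filtered=TRUE requires a mask")
      mu <- mean_coverage(pileups[[l]], mask, l)$mean_coverage
      keep <- keep & mask$unique[s$pos] &
        s$depth >= params$min_cov_focal &
        s$depth <= params$max_cov_factor * mu &
        !is.na(s$cons) & s$agree >= params$min_agree_focal
    }
    if (!any(keep)) stop("error_rate: no eligible sites for line ", l)
    frac <- (s$depth[keep] - mx[keep]) / s$depth[keep]
    per_line[l] <- mean(frac)
    n_sites[l] <- sum(keep)
  }
  k <- length(per_line)
  sdv <- if (k > 1L) stats::sd(per_line) else NA_real_
  list(per_line = per_line,
       overall = mean(per_line),
       sd = sdv,
       ci_halfwidth = if (k > 1L) stats::qt(0.975, k - 1L) * sdv / sqrt(k)
       else NA_real_,
       n_sites = n_sites)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Cell generations from per-plaque cell counts
#'
#' Cell divisions per transfer are estimated as the base-2 logarithm of
#' the number of cells in each plaque at transfer time (each plaque
#' grows from a single founder cell); the total is the mean number of
#' divisions per transfer multiplied by the number of transfers, rounded
#' half away from zero.
#'
#' @param cell_counts Positive integer cell counts, one per plaque.
#' @param transfers Number of single-cell bottleneck transfers.
#' @return List with `divisions` (per plaque), `mean_divisions`,
#'   `sd_divisions`, `transfers`, `total_generations`.
#' @examples
#' generations_from_counts(rep(16384, 16), 70)  # 14 x 70 = 980
#' @export
generations_from_counts <- function(cell_counts, transfers) {
  stopifnot(all(cell_counts >= 1), transfers >= 1)
  div <- log2(cell_counts)
  m <- mean(div)
  list(divisions = div, mean_divisions = m,
       sd_divisions = if (length(div) > 1L) stats::sd(div) else NA_real_,
       transfers = as.integer(transfers),
       total_generations = as.integer(round_half_away(m * transfers)))
}
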