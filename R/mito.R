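#' Mitochondrial heteroplasmy-calling parameters
#'
#' The mitochondrial genome is present in hundreds of copies per cell,
#' so new mutations appear as heteroplasmic alternate alleles at
#' intermediate frequencies. A frequency cutoff separates true
#' (often low-frequency) heteroplasmies from sequencing errors; sites
#' must also clear a minimum coverage, by default a tenth of the line's
#' mean mitochondrial coverage (resolved once per line at run start).
#'
#' @param cutoff Minimum alternate-allele frequency counted as a
#'   heteroplasmic mutation; an allele at exactly the cutoff is
#'   retained (default 0.03).
#' @param min_cov Minimum read depth for an eligible site; `NULL`
#'   (default) resolves per line to `floor(mean coverage / 10)`.
#' @param generations Number of cell generations g.
#' @param circular Mitochondrial contig circularity (default `TRUE`).
#' @return An object of class `mito_params`.
#' @export
mito_params <- function(cutoff = 0.03, min_cov = NULL,
                        generations = 1000L, circular = TRUE) {
  stopifnot(cutoff > 0, cutoff < 0.5,
            is.null(min_cov) || min_cov >= 1, generations >= 1)
  structure(list(cutoff = cutoff,
                 min_cov = if (is.null(min_cov)) NULL else
                   as.integer(min_cov),
                 generations = as.integer(generations),
                 circular = isTRUE(circular)),
            class = "mito_params")
}

#' Alternate-allele frequencies at covered sites
#'
#' For each base differing from the reference, its frequency is its
#' count divided by the counted depth.
#'
#' @param sites Site table from [read_pileup()] with depth >= 1.
#' @return Long `data.table` with columns `contig`, `pos`, `ref`,
#'   `alt`, `freq`, `depth` (one row per alternate base per site;
#'   zero-frequency alternates included).
#' @export
allele_frequencies <- function(sites) {
  s <- sites[depth >= 1L]
  long <- data.table::melt(
    s[, .(contig, pos, ref, depth, A, C, G, T)],
    id.vars = c("contig", "pos", "ref", "depth"),
    variable.name = "alt", value.name = "count",
    variable.factor = FALSE)
  long <- long[alt != ref]
  long[, freq := count / depth]
  long[, count := NULL]
  data.table::setorderv(long, c("contig", "pos", "alt"))
  long[]
}

# eligible mitochondrial sites and above-cutoff candidates per line
mito_candidates <- function(pileups, mask, params) {
  lines <- names(pileups)
  min_cov <- stats::setNames(vapply(lines, function(l) {
    if (!is.null(params$min_cov)) return(params$min_cov)
    mu <- mean_coverage(pileups[[l]], mask, l)$mean_coverage
    max(1L, as.integer(floor(mu / 10)))
  }, 0L), lines)
  per_line <- lapply(lines, function(l) {
    s <- pileups[[l]]
    keep <- s$depth >= min_cov[[l]]
    if (!is.null(mask)) keep <- keep & mask$unique[s$pos]
    eligible <- s[keep]
    af <- if (nrow(eligible) > 0L) allele_frequencies(eligible) else
      data.table::data.table(contig = character(), pos = integer(),
                             ref = character(), alt = character(),
                             freq = numeric(), depth = integer())
    af[, line := l]
    list(n_sites = nrow(eligible), af = af)
  })
  names(per_line) <- lines
  list(min_cov = min_cov,
       n_sites = stats::setNames(vapply(per_line, `[[`, 0L, "n_sites"),
                                 lines),
       af = data.table::rbindlist(lapply(per_line, `[[`, "af")))
}

# apply the cutoff and the single-line rule to a frequency table
apply_cutoff <- function(af, cutoff) {
  cand <- af[freq >= cutoff]
  if (nrow(cand) == 0L) return(cand)
  cand[, n_above := .N, by = .(contig, pos, alt)]
  cand <- cand[n_above == 1L]
  cand[, n_above := NULL]
  cand[]
}

#' Call heteroplasmic mitochondrial mutations
#'
#' Restricts to uniquely mappable sites covered by at least the per-line
#' minimum depth, retains alternate alleles whose frequency is at or
#' above the cutoff, and excludes any allele that exceeds the cutoff in
#' more than one line (mutations arise independently, so a shared
#' allele is ancestral or artefactual, not a new mutation -- it is
#' removed from every line).
#'
#' @param pileups Named list of per-line mitochondrial site tables.
#' @param mask A [mappability_mask] for the mitochondrial contig, or
#'   `NULL` to skip the uniqueness filter.
#' @param params A [mito_params].
#' @return List with `calls` (`data.table`: `line`, `contig`, `pos`,
#'   `ref`, `alt`, `freq`, `depth`), `n_sites` (eligible-site count per
#'   line), `min_cov` (resolved per line), `cutoff`.
#' @export
call_heteroplasmies <- function(pileups, mask = NULL,
                                params = mito_params()) {
  stopifnot(inherits(params, "mito_params"))
  cand <- mito_candidates(pileups, mask, params)
  calls <- apply_cutoff(cand$af, params$cutoff)
  data.table::setcolorder(
    calls, c("line", "contig", "pos", "ref", "alt", "freq", "depth"))
  list(calls = calls[], n_sites = cand$n_sites, min_cov = cand$min_cov,
       cutoff = params$cutoff)
}

#' Frequency-weighted mitochondrial mutation rate
#'
#' Under mutation-drift equilibrium the fixation probability of a
#' heteroplasmic mutation equals its current frequency, so each
#' mutation contributes its frequency: per line,
#' `rate = sum(f(m)) / (n_sites * g)`; the overall estimate is the
#' unweighted mean across lines. The exact Poisson interval is computed
#' on the pooled retained-mutation count and applied multiplicatively
#' to the mean rate.
#'
#' @param het Result of [call_heteroplasmies()], or a list with `calls`
#'   and `n_sites`.
#' @param g Number of cell generations.
#' @param level Confidence level for the Poisson interval.
#' @return List with `per_line` rates, `rate` (mean across lines with
#'   eligible sites), `k` (pooled mutation count), `ci_lower`,
#'   `ci_upper`, `level`, `n_sites`, `g`.
#' @export
mito_rate <- function(het, g, level = 0.95) {
  stopifnot(g >= 1)
  lines <- names(het$n_sites)
  usable <- het$n_sites > 0L
  if (any(!usable))
    warning("mito_rate: lines with zero eligible sites excluded: ",
            paste(lines[!usable], collapse = ", "))
  if (!any(usable)) stop("mito_rate: no line has eligible sites")
  per_line <- stats::setNames(vapply(lines[usable], function(l) {
    fs <- het$calls[line == l, sum(freq)]
    fs / (het$n_sites[[l]] * g)
  }, 0), lines[usable])
  rate <- mean(per_line)
  k <- nrow(het$calls)
  if (k > 0L) {
    ci <- poisson_ci(k, level)
    lo <- rate * ci$lower / k
    hi <- rate * ci$upper / k
  } else {
    lo <- 0; hi <- NA_real_
  }
  list(per_line = per_line, rate = rate, k = k,
       ci_lower = lo, ci_upper = hi, level = level,
       n_sites = het$n_sites[usable], g = g)
}

#' Choose the frequency cutoff by grid search for a rate minimum
#'
#' Evaluates the full heteroplasmy-calling and rate pipeline at each
#' candidate cutoff and picks the cutoff minimising the rate estimate:
#' too low a cutoff admits sequencing errors as mutations (inflating
#' the rate), too high a cutoff can only remove real low-frequency
#' mutations, so a minimum in between balances the two. Ties resolve to
#' the smallest cutoff.
#'
#' @inheritParams call_heteroplasmies
#' @param grid Ascending candidate cutoffs (default 0.01 to 0.10 in
#'   hundredths).
#' @param g Number of cell generations.
#' @return An object of class `cutoff_selection`: `method`, `grid`,
#'   `chosen`, and `diagnostics` (`data.table` of cutoff and rate).
#' @export
select_cutoff_grid <- function(pileups, mask = NULL,
                               params = mito_params(),
                               grid = seq(0.01, 0.10, by = 0.01),
                               g = params$generations) {
  stopifnot(length(grid) >= 1L, !is.unsorted(grid))
  cand <- mito_candidates(pileups, mask, params)
  rates <- vapply(grid, function(f) {
    calls <- apply_cutoff(cand$af, f)
    het <- list(calls = calls, n_sites = cand$n_sites)
    suppressWarnings(mito_rate(het, g)$rate)
  }, 0)
  chosen <- grid[[which.min(rates)]]  # which.min takes the first minimum
  structure(list(method = "grid_minimum", grid = grid, chosen = chosen,
                 diagnostics = data.table::data.table(cutoff = grid,
                                                      rate = rates)),
            class = "cutoff_selection")
}

#' Choose the frequency cutoff from a binomial error bound
#'
#' Given a per-read error rate (the empirical estimate, typically
#' doubled by the caller to allow for systematically error-prone
#' sites), a representative coverage, and a per-site significance
#' threshold (by default 1 / number of mitochondrial sites across
#' lines, so that less than one false mutation is expected over all
#' sites), picks the smallest cutoff `f` in the grid for which the
#' binomial probability of more than `coverage * f` erroneous reads is
#' below the threshold:
#' `P[Binomial(coverage, error) > coverage * f] < alpha_per_site`.
#' The inequality on the read count is strict.
#'
#' @param error_per_read Per-read error probability (already inflated
#'   by the caller if desired).
#' @param coverage Representative read depth.
#' @param alpha_per_site Per-site probability threshold.
#' @param grid Ascending candidate cutoffs.
#' @param inclusive Use `>=` instead of `>` on the erroneous-read count
#'   (for sensitivity checks; default `FALSE`).
#' @return A `cutoff_selection` with per-candidate tail probabilities
#'   in `diagnostics`.
#' @examples
#' select_cutoff_binomial(0.004, 400, 6.7e-6)$chosen  # 0.03
#' @export
select_cutoff_binomial <- function(error_per_read, coverage, alpha_per_site,
                                   grid = seq(0.01, 0.10, by = 0.01),
                                   inclusive = FALSE) {
  stopifnot(error_per_read > 0, error_per_read < 1, coverage >= 1,
            alpha_per_site > 0, length(grid) >= 1L, !is.unsorted(grid))
  thresh <- if (inclusive) ceiling(coverage * grid - 1e-9) - 1 else
    floor(coverage * grid + 1e-9)
  tails <- stats::pbinom(thresh, coverage, error_per_read,
                         lower.tail = FALSE)
  ok <- tails < alpha_per_site
  if (!any(ok)) stop("select_cutoff_binomial: no admissible cutoff in grid")
  structure(list(method = "binomial_bound", grid = grid,
                 chosen = grid[[which(ok)[[1L]]]],
                 diagnostics = data.table::data.table(cutoff = grid,
                                                      tail_prob = tails)),
            class = "cutoff_selection")
}

#' @export
print.cutoff_selection <- function(x, ...) {
  cat(sprintf("<cutoff_selection> method=%s chosen f=%.3g (grid of %d)\n",
              x$method, x$chosen, length(x$grid)))
  invisible(x)
}
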