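#' Filtering parameters for nuclear site classification
#'
#' Focal criteria identify candidate mutations and candidate unchanged
#' sites in the line under consideration; the deliberately weaker
#' confirmation criteria are applied symmetrically in the other lines,
#' both when vetoing a candidate mutation seen elsewhere and when
#' confirming the reference at an unchanged site. Defaults are the
#' standard thresholds for ~10X data: minimum focal coverage 5
#' (about half the mean) with 90% agreement,
#' confirmation at coverage 1 with 50% agreement, a cap at 3x each
#' line's own mean coverage, and restriction to uniquely mappable sites.
#'
#' @param min_cov_focal Minimum read depth in the focal line (default 5).
#' @param min_agree_focal Minimum agreement fraction in the focal line
#'   (default 0.90).
#' @param min_cov_confirm Minimum depth for a confirming line (default 1).
#' @param min_agree_confirm Minimum agreement for a confirming line
#'   (default 0.5).
#' @param max_cov_factor Depth cap as a multiple of the focal line's own
#'   mean coverage (default 3).
#' @param require_unique Restrict to uniquely mappable sites (default
#'   `TRUE`).
#' @param strict_confirm Off-by-default strict mode: a candidate
#'   mutation additionally requires every other line to positively
#'   confirm the reference under the weak criteria, instead of only
#'   requiring absence of the alternate base as their majority.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(min_cov_focal = 5L, min_agree_focal = 0.90,
                          min_cov_confirm = 1L, min_agree_confirm = 0.5,
                          max_cov_factor = 3.0, require_unique = TRUE,
                          strict_confirm = FALSE) {
  min_cov_focal <- as.integer(min_cov_focal)
  min_cov_confirm <- as.integer(min_cov_confirm)
  stopifnot(min_cov_confirm >= 1L, min_cov_focal >= min_cov_confirm,
            min_agree_confirm >= 0.5, min_agree_focal >= min_agree_confirm,
            min_agree_focal <= 1, max_cov_factor > 0)
  structure(list(min_cov_focal = min_cov_focal,
                 min_agree_focal = min_agree_focal,
                 min_cov_confirm = min_cov_confirm,
                 min_agree_confirm = min_agree_confirm,
                 max_cov_factor = max_cov_factor,
                 require_unique = isTRUE(require_unique),
                 strict_confirm = isTRUE(strict_confirm)),
            class = "filter_params")
}

#' Classify every site, per line, as mutation, unchanged, or excluded
#'
#' Implements the decision rules for identifying unique point mutations
#' and unchanged (reference-confirming) nucleotides across MA lines:
#'
#' 1. Sites that are not uniquely mappable, or not covered (depth >= 1)
#'    in every line, are excluded for all lines.
#' 2. Per focal line, the site must reach `min_cov_focal` reads, stay at
#'    or below `max_cov_factor` times that line's own mean coverage,
#'    have a majority call, and reach `min_agree_focal` agreement.
#' 3. A focal majority differing from the reference is a candidate
#'    mutation; it is excluded as a shared candidate if the same
#'    alternate base is the majority (at the weak confirmation criteria,
#'    even a single read) in any other line, and accepted as a MUTATION
#'    otherwise. A third base as another line's majority does not veto.
#' 4. A focal majority equal to the reference is UNCHANGED only if every
#'    other line's weak-criteria majority also equals the reference.
#'
#' Sites whose reference base is `N` are dropped from the stream (an
#' unreadable reference cannot be confirmed or mutated).
#'
#' @param pileups Named list (one element per line, >= 2 lines) of
#'   full-genome site tables from [read_pileup()] with `extend = TRUE`,
#'   all over identical positions.
#' @param mask A [mappability_mask] for the contig, or `NULL` if
#'   `params$require_unique` is `FALSE`.
#' @param params A [filter_params].
#' @param line_means Optional named numeric vector of per-line mean
#'   coverages; computed with [mean_coverage()] when `NULL`.
#' @return `data.table` with one row per (site, line): `contig`, `pos`,
#'   `ref`, `line`, `outcome` (`MUTATION`/`UNCHANGED`/`EXCLUDED`),
#'   `reason` (for exclusions), `cons`, `alt`, `depth`, `agree`.
#' @export
classify_sites <- function(pileups, mask = NULL, params = filter_params(),
                           line_means = NULL) {
  stopifnot(is.list(pileups), length(pileups) >= 2L,
            !is.null(names(pileups)), inherits(params, "filter_params"))
  lines <- names(pileups)
  ref_dt <- pileups[[1L]][, .(contig, pos, ref)]
  for (l in lines[-1L]) {
    p <- pileups[[l]]
    if (nrow(p) != nrow(ref_dt) || !all(p$pos == ref_dt$pos) ||
        !all(p$contig == ref_dt$contig))
      stop("classify_sites: pileup streams out of alignment ",
           "(position mismatch between lines)")
    if (!all(p$ref == ref_dt$ref))
      stop("classify_sites: pileup streams disagree on reference bases")
  }
  if (params$require_unique && is.null(mask))
    stop("classify_sites: mask required when require_unique is TRUE")

  if (is.null(line_means)) {
    line_means <- vapply(lines, function(l)
      mean_coverage(pileups[[l]], mask, l)$mean_coverage, 0)
  }
  stopifnot(all(lines %in% names(line_means)))

  withcons <- lapply(pileups, consensus_calls)
  ns <- nrow(ref_dt)
  nl <- length(lines)
  depth <- matrix(vapply(withcons, `[[`, integer(ns), "depth"), ns, nl)
  cons <- matrix(vapply(withcons, `[[`, character(ns), "cons"), ns, nl)
  agree <- matrix(vapply(withcons, `[[`, numeric(ns), "agree"), ns, nl)
  ref <- ref_dt$ref

  keep_rows <- ref != "N"
  uniq <- if (params$require_unique) mask$unique[ref_dt$pos] else
    rep(TRUE, ns)
  covered_all <- rowSums(depth >= 1L) == nl

  # weak-criteria majority per line: the consensus base where the line
  # has at least min_cov_confirm reads and min_agree_confirm agreement
  wm <- cons
  wm[!(depth >= params$min_cov_confirm &
         agree >= params$min_agree_confirm)] <- NA_character_
  wm_is_ref <- !is.na(wm) & wm == ref

  out <- vector("list", nl)
  for (li in seq_len(nl)) {
    d <- depth[, li]; cb <- cons[, li]; ag <- agree[, li]
    cap <- params$max_cov_factor * line_means[[lines[[li]]]]
    outcome <- rep(NA_character_, ns)
    reason <- rep(NA_character_, ns)

    ineligible <- !uniq | !covered_all
    reason[!covered_all] <- "not_covered_all_lines"
    reason[!uniq] <- "not_unique"
    outcome[ineligible] <- "EXCLUDED"

    open <- !ineligible
    low <- open & d < params$min_cov_focal
    reason[low] <- "low_coverage"; outcome[low] <- "EXCLUDED"; open <- open & !low
    high <- open & d > cap
    reason[high] <- "high_coverage"; outcome[high] <- "EXCLUDED"; open <- open & !high
    tie <- open & is.na(cb)
    reason[tie] <- "tie_no_call"; outcome[tie] <- "EXCLUDED"; open <- open & !tie
    lowa <- open & ag < params$min_agree_focal
    reason[lowa] <- "low_agreement"; outcome[lowa] <- "EXCLUDED"; open <- open & !lowa

    others <- setdiff(seq_len(nl), li)
    all_others_ref <- rowSums(wm_is_ref[, others, drop = FALSE]) ==
      length(others)

    is_cand <- open & cb != ref
    shared <- is_cand &
      rowSums(!is.na(wm[, others, drop = FALSE]) &
                wm[, others, drop = FALSE] == cb) > 0L
    reason[shared] <- "shared_candidate"; outcome[shared] <- "EXCLUDED"
    accept <- is_cand & !shared
    if (params$strict_confirm) {
      unconf <- accept & !all_others_ref
      reason[unconf] <- "confirmation_failed"; outcome[unconf] <- "EXCLUDED"
      accept <- accept & all_others_ref
    }
    outcome[accept] <- "MUTATION"

    is_same <- open & cb == ref
    conf <- is_same & all_others_ref
    outcome[conf] <- "UNCHANGED"
    unconf <- is_same & !all_others_ref
    reason[unconf] <- "confirmation_failed"; outcome[unconf] <- "EXCLUDED"

    out[[li]] <- data.table::data.table(
      contig = ref_dt$contig, pos = ref_dt$pos, ref = ref,
      line = lines[[li]], outcome = outcome, reason = reason,
      cons = cb,
      alt = ifelse(outcome == "MUTATION" |
                     (!is.na(reason) & reason == "shared_candidate"),
                   cb, NA_character_),
      depth = d, agree = ag)[keep_rows]
  }
  res <- data.table::rbindlist(out)
  data.table::setorderv(res, c("contig", "pos", "line"))
  res[]
}

#' Extract accepted mutation calls from a classification table
#'
#' @param classifications Output of [classify_sites()].
#' @return `data.table` with columns `contig`, `pos`, `line`, `ref`,
#'   `alt`, `depth`, `agree`.
#' @export
mutation_calls <- function(classifications) {
  classifications[outcome == "MUTATION",
                  .(contig, pos, line, ref, alt, depth, agree)]
}

#' Tally classifications into mutation and unchanged-site counts
#'
#' @param classifications Output of [classify_sites()].
#' @return List with `per_line` (`data.table` of per-line `m` mutations
#'   and `n_unchanged`), pooled `m` and `n_unchanged`, an
#'   excluded-by-reason histogram over (site, line) records,
#'   `shared_candidates` (line-site level count),
#'   `shared_candidate_sites` (distinct (contig, pos, alt) count), and
#'   `candidates` = `m` + `shared_candidate_sites`.
#' @export
tally_classifications <- function(classifications) {
  per_line <- classifications[, .(
    m = sum(outcome == "MUTATION"),
    n_unchanged = sum(outcome == "UNCHANGED")), by = line]
  reasons <- classifications[outcome == "EXCLUDED", table(reason)]
  shared_ls <- classifications[!is.na(reason) & reason == "shared_candidate"]
  list(per_line = per_line,
       m = sum(per_line$m),
       n_unchanged = sum(per_line$n_unchanged),
       excluded_by_reason = reasons,
       shared_candidates = nrow(shared_ls),
       shared_candidate_sites =
         nrow(unique(shared_ls[, .(contig, pos, alt)])),
       candidates = sum(per_line$m) +
         nrow(unique(shared_ls[, .(contig, pos, alt)])))
}

#' Nuclear mutation rate from a tally
#'
#' The per-site per-generation rate is `m / (sites * g)` where the site
#' count is the pooled number of unchanged bases plus the accepted
#' mutations (every classified base is a site where a mutation could
#' have been seen). The exact Poisson interval on the mutation count is
#' divided through by `sites * g`.
#'
#' @param tally Output of [tally_classifications()].
#' @param g Number of cell generations.
#' @param level Confidence level (default 0.95).
#' @return A `rate_estimate`, see [rate_ci()].
#' @export
nuclear_rate <- function(tally, g, level = 0.95) {
  rate_ci(tally$m, tally$n_unchanged + tally$m, g, level)
}

#' Sensitivity of the tally and rate to the filtering parameters
#'
#' Re-runs classification and tallying under each parameter set in a
#' grid and reports the resulting mutation count, unchanged-site count,
#' and rate.
#'
#' @inheritParams classify_sites
#' @param grid List of [filter_params] objects.
#' @param g Number of cell generations.
#' @return `data.table` with one row per parameter set: the parameter
#'   fields plus `m`, `n_unchanged`, `rate`.
#' @export
sensitivity_sweep <- function(pileups, mask, grid, g) {
  stopifnot(length(grid) >= 1L)
  rows <- lapply(grid, function(p) {
    stopifnot(inherits(p, "filter_params"))
    tl <- tally_classifications(classify_sites(pileups, mask, p))
    data.table::data.table(
      min_cov_focal = p$min_cov_focal, min_agree_focal = p$min_agree_focal,
      min_cov_confirm = p$min_cov_confirm,
      min_agree_confirm = p$min_agree_confirm,
      max_cov_factor = p$max_cov_factor,
      m = tl$m, n_unchanged = tl$n_unchanged,
      rate = if (tl$m + tl$n_unchanged > 0)
        tl$m / ((tl$n_unchanged + tl$m) * g) else NA_real_)
  })
  data.table::rbindlist(rows)
}
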