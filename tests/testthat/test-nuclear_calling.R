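# pad the single informative site with unanimous reference sites so that
# per-line mean coverages are well-defined and uninfluential
padded_pileups <- function(ref, counts_per_line, pad = 30L, depth = 10L) {
  lapply(counts_per_line, function(ct) {
    sites <- unanimous_sites(strrep("A", pad + 1L), rep(depth, pad + 1L))
    data.table::set(sites, 1L, "ref", ref)
    set_site_counts(sites, 1L, as.list(ct[c("A", "C", "G", "T")]))
  })
}

cnt <- function(A = 0, C = 0, G = 0, T = 0) c(A = A, C = C, G = G, T = T)

test_that("stated calling rules classify the canonical examples", {
  mask <- all_unique_mask(31L)
  # line1 all-T at depth 7, others carry the reference
  p <- padded_pileups("A", list(MA1 = cnt(T = 7), MA2 = cnt(A = 3),
                                MA3 = cnt(A = 1)))
  cls <- classify_sites(p, mask)[pos == 1L]
  expect_equal(cls[line == "MA1", outcome], "MUTATION")
  expect_equal(cls[line == "MA1", alt], "T")
  # the confirming lines are themselves too shallow to be focal
  expect_equal(cls[line == "MA2", reason], "low_coverage")
  expect_equal(cls[line == "MA3", reason], "low_coverage")

  # same candidate as majority in another line -- even a single read
  p <- padded_pileups("A", list(MA1 = cnt(T = 7), MA2 = cnt(T = 1),
                                MA3 = cnt(A = 5)))
  cls <- classify_sites(p, mask)[pos == 1L]
  expect_equal(cls[line == "MA1", outcome], "EXCLUDED")
  expect_equal(cls[line == "MA1", reason], "shared_candidate")

  # unchanged site confirmed by weak-majority reference in both others
  p <- padded_pileups("A", list(MA1 = cnt(A = 6), MA2 = cnt(A = 1),
                                MA3 = cnt(A = 2)))
  cls <- classify_sites(p, mask)[pos == 1L]
  expect_equal(cls[line == "MA1", outcome], "UNCHANGED")
  expect_equal(cls[line == "MA2", reason], "low_coverage")
  expect_equal(cls[line == "MA3", reason], "low_coverage")
})

test_that("non-unique and not-covered sites are excluded for all lines", {
  p <- padded_pileups("A", list(MA1 = cnt(T = 7), MA2 = cnt(A = 3),
                                MA3 = cnt(A = 1)))
  m <- all_unique_mask(31L)
  m$unique[1L] <- FALSE
  cls <- classify_sites(p, m)[pos == 1L]
  expect_true(all(cls$outcome == "EXCLUDED"))
  expect_true(all(cls$reason == "not_unique"))

  p <- padded_pileups("A", list(MA1 = cnt(T = 7), MA2 = cnt(),
                                MA3 = cnt(A = 1)))
  cls <- classify_sites(p, all_unique_mask(31L))[pos == 1L]
  expect_true(all(cls$outcome == "EXCLUDED"))
  expect_true(all(cls$reason == "not_covered_all_lines"))
})

test_that("a third base in another line does not veto a candidate", {
  p <- padded_pileups("A", list(MA1 = cnt(T = 7), MA2 = cnt(G = 2),
                                MA3 = cnt(A = 5)))
  cls <- classify_sites(p, all_unique_mask(31L))[pos == 1L]
  expect_equal(cls[line == "MA1", outcome], "MUTATION")
  # but strict mode requires positive reference confirmation everywhere
  cls <- classify_sites(p, all_unique_mask(31L),
                        filter_params(strict_confirm = TRUE))[pos == 1L]
  expect_equal(cls[line == "MA1", outcome], "EXCLUDED")
  expect_equal(cls[line == "MA1", reason], "confirmation_failed")
})

test_that("unchanged calls need reference confirmation in every other line", {
  # MA3's majority is not the reference: confirmation fails for MA1
  p <- padded_pileups("A", list(MA1 = cnt(A = 6), MA2 = cnt(A = 1),
                                MA3 = cnt(G = 2)))
  cls <- classify_sites(p, all_unique_mask(31L))[pos == 1L]
  expect_equal(cls[line == "MA1", outcome], "EXCLUDED")
  expect_equal(cls[line == "MA1", reason], "confirmation_failed")
})

test_that("high-coverage sites are excluded for the focal line only", {
  pad_depth <- 10L
  p <- padded_pileups("A", list(MA1 = cnt(A = 50), MA2 = cnt(A = 8),
                                MA3 = cnt(T = 8)), depth = pad_depth)
  cls <- classify_sites(p, all_unique_mask(31L))[pos == 1L]
  expect_equal(cls[line == "MA1", reason], "high_coverage")
  # MA1 still serves as a confirming line: MA3's T candidate is accepted
  # because no other line shows T, and MA1's deep A cannot confirm ref
  # for MUTATION acceptance in literal mode (absence of alt suffices)
  expect_equal(cls[line == "MA3", outcome], "MUTATION")
})

test_that("classification matches a rule-enumeration oracle site by site", {
  set.seed(51)
  n <- 200L
  lines <- c("MA1", "MA2", "MA3")
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  mk <- function() {
    counts <- matrix(0L, n, 4L)
    # mix of deep, shallow, zero, and contaminated sites
    base_idx <- match(ref, c("A", "C", "G", "T"))
    d <- rpois(n, 8) * rbinom(n, 1L, 0.9)
    counts[cbind(seq_len(n), base_idx)] <- d
    # sprinkle alternate reads and occasional full substitutions
    flip <- which(rbinom(n, 1L, 0.25) == 1L)
    for (i in flip) {
      a <- sample(setdiff(1:4, base_idx[i]), 1L)
      counts[i, a] <- counts[i, a] + sample(0:9, 1L)
    }
    make_sites(counts, ref)
  }
  pileups <- stats::setNames(lapply(lines, function(l) mk()), lines)
  u <- rbinom(n, 1L, 0.9) == 1L
  mask <- mappability_mask_from_unique("chr1", u)
  params <- filter_params()
  means <- vapply(pileups, function(s) mean_coverage(s, mask)$mean_coverage, 0)

  cls <- classify_sites(pileups, mask, params)
  expect_equal(nrow(cls), n * 3L)
  for (i in sort(sample.int(n, 80L))) {
    counts_i <- lapply(pileups, function(s)
      stats::setNames(as.integer(s[pos == i, .(A, C, G, T)]),
                      c("A", "C", "G", "T")))
    want <- oracle_classify_site(ref[i], counts_i, u[i], means, params)
    for (l in lines) {
      got <- cls[pos == i & line == l]
      expect_equal(got$outcome, want[[l]][[1L]],
                   info = sprintf("pos %d line %s", i, l))
      if (got$outcome == "EXCLUDED")
        expect_equal(got$reason, want[[l]][[2L]],
                     info = sprintf("pos %d line %s reason", i, l))
    }
  }

  # partition: every line-site has exactly one outcome and the tally adds up
  tl <- tally_classifications(cls)
  expect_equal(tl$m + tl$n_unchanged + sum(tl$excluded_by_reason), n * 3L)
})

test_that("misaligned pileup streams are rejected", {
  p <- padded_pileups("A", list(MA1 = cnt(A = 6), MA2 = cnt(A = 6),
                                MA3 = cnt(A = 6)))
  p$MA2 <- p$MA2[-3L]
  expect_error(classify_sites(p, all_unique_mask(31L)), "alignment")
})

test_that("the weak confirmation criteria gate both rule paths symmetrically", {
  # one other line holds the candidate alt with a single read (vetoes the
  # mutation); at another site one other line holds ref with a single
  # read (confirms unchanged). Raising min_cov_confirm to 2 must flip both.
  mask <- all_unique_mask(31L)
  mk <- function(site1, site2) {
    sites <- unanimous_sites(strrep("A", 31L), rep(10L, 31L))
    sites <- set_site_counts(sites, 1L, site1)
    set_site_counts(sites, 2L, site2)
  }
  p <- list(MA1 = mk(list(A = 0, C = 0, G = 0, T = 8),  # candidate A->T
                     list(A = 8, C = 0, G = 0, T = 0)), # candidate unchanged
            MA2 = mk(list(A = 0, C = 0, G = 0, T = 1),  # 1-read veto
                     list(A = 1, C = 0, G = 0, T = 0)), # 1-read confirm
            MA3 = mk(list(A = 5, C = 0, G = 0, T = 0),
                     list(A = 5, C = 0, G = 0, T = 0)))
  weak1 <- classify_sites(p, mask, filter_params(min_cov_confirm = 1))
  expect_equal(weak1[pos == 1L & line == "MA1", reason], "shared_candidate")
  expect_equal(weak1[pos == 2L & line == "MA1", outcome], "UNCHANGED")
  weak2 <- classify_sites(p, mask, filter_params(min_cov_confirm = 2))
  # the 1-read evidence no longer counts on either path
  expect_equal(weak2[pos == 1L & line == "MA1", outcome], "MUTATION")
  expect_equal(weak2[pos == 2L & line == "MA1", reason],
               "confirmation_failed")
})

test_that("m and n are non-increasing under stricter focal filters", {
  set.seed(61)
  cfg <- simulation_config(seed = 61, genome_length = 3000L,
                           true_rate = 1e-6, per_read_error = 0.02)
  sim <- simulate_ma_experiment(cfg)
  mask <- all_unique_mask(3000L)
  base <- tally_classifications(classify_sites(sim$pileups, mask,
                                               filter_params()))
  for (p in list(filter_params(min_cov_focal = 7),
                 filter_params(min_agree_focal = 0.95),
                 filter_params(min_cov_focal = 7, min_agree_focal = 1.0))) {
    tl <- tally_classifications(classify_sites(sim$pileups, mask, p))
    expect_lte(tl$m, base$m)
    expect_lte(tl$n_unchanged, base$n_unchanged)
  }
})

test_that("sensitivity sweep matches individual tallies and known trends", {
  set.seed(71)
  cfg <- simulation_config(seed = 71, genome_length = 4000L,
                           true_rate = 5e-7, per_read_error = 0.01,
                           mean_coverage = c(12, 12, 12))
  sim <- simulate_ma_experiment(cfg)
  mask <- all_unique_mask(4000L)
  grid <- list(filter_params(),
               filter_params(min_agree_focal = 1.0),
               filter_params(min_cov_focal = 3),
               filter_params(min_cov_focal = 7))
  sw <- sensitivity_sweep(sim$pileups, mask, grid, g = 1000L)
  expect_equal(nrow(sw), 4L)
  for (i in seq_along(grid)) {
    tl <- tally_classifications(classify_sites(sim$pileups, mask, grid[[i]]))
    expect_equal(sw$m[i], tl$m)
    expect_equal(sw$n_unchanged[i], tl$n_unchanged)
  }
  # demanding 100% agreement cannot add mutations and removes unchanged
  expect_lte(sw$m[2L], sw$m[1L])
  expect_lte(sw$n_unchanged[2L], sw$n_unchanged[1L])

  # on an everywhere-deep zero-error fixture, lowering min coverage is inert
  cfg0 <- simulation_config(seed = 72, genome_length = 2000L,
                            true_rate = 1e-6, per_read_error = 0,
                            mean_coverage = c(30, 30, 30))
  sim0 <- simulate_ma_experiment(cfg0)
  m0 <- all_unique_mask(2000L)
  sw0 <- sensitivity_sweep(sim0$pileups, m0,
                           list(filter_params(min_cov_focal = 5),
                                filter_params(min_cov_focal = 2)), 1000L)
  expect_equal(sw0$m[1L], sw0$m[2L])
  expect_equal(sw0$n_unchanged[1L], sw0$n_unchanged[2L])
})
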