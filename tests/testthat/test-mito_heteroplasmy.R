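test_that("alternate-allele frequencies are counts over depth", {
  s <- make_sites(matrix(c(380L, 0L, 20L, 0L), 1L), "A")
  af <- allele_frequencies(s)
  expect_equal(af[alt == "G", freq], 0.05)
  expect_equal(af[alt == "C", freq], 0)

  s <- make_sites(matrix(c(400L, 0L, 0L, 0L), 1L), "A")
  af <- allele_frequencies(s)
  expect_true(all(af$freq == 0))
  expect_equal(nrow(af), 3L)  # three alternates per site, ref excluded

  # a high-frequency heteroplasmy: 176 alternate reads of 400, f = 0.44
  s <- make_sites(matrix(c(224L, 0L, 0L, 176L), 1L), "A")
  expect_equal(allele_frequencies(s)[alt == "T", freq], 0.44)
})

# helper: three deep mito lines with chosen alternate reads planted
mito_fixture <- function(n = 50L, depth = 1000L,
                         plant = list()) {
  ref <- strsplit(strrep("ACGTT", n / 5L), "", fixed = TRUE)[[1L]]
  lines <- c("MA1", "MA2", "MA3")
  pileups <- stats::setNames(lapply(lines, function(l) {
    s <- unanimous_sites(paste(ref, collapse = ""), rep(depth, n))
    for (pl in plant) {
      if (pl$line != l) next
      base_ct <- as.list(stats::setNames(rep(0L, 4L), c("A", "C", "G", "T")))
      k <- as.integer(round(pl$freq * depth))
      base_ct[[ref[pl$pos]]] <- depth - k
      base_ct[[pl$alt]] <- k
      s <- set_site_counts(s, pl$pos, base_ct)
    }
    s
  }), lines)
  pileups
}

test_that("heteroplasmy calls honor the cutoff boundary and min coverage", {
  p <- mito_fixture(plant = list(
    list(line = "MA1", pos = 7L, alt = "G", freq = 0.05),
    list(line = "MA2", pos = 12L, alt = "T", freq = 0.029),
    list(line = "MA3", pos = 17L, alt = "A", freq = 0.03)))
  het <- call_heteroplasmies(p, all_unique_mask(50L),
                             mito_params(cutoff = 0.03, min_cov = 100L))
  expect_equal(nrow(het$calls), 2L)
  expect_equal(het$calls[line == "MA1", freq], 0.05)
  # 0.029 < cutoff: excluded; exactly 0.03: retained ("equal or exceeded")
  expect_equal(nrow(het$calls[line == "MA2"]), 0L)
  expect_equal(het$calls[line == "MA3", freq], 0.03)
  expect_equal(unname(het$n_sites), rep(50L, 3L))
})

test_that("alleles above cutoff in more than one line are excluded everywhere", {
  p <- mito_fixture(plant = list(
    list(line = "MA1", pos = 7L, alt = "G", freq = 0.05),
    list(line = "MA2", pos = 7L, alt = "G", freq = 0.05),
    list(line = "MA3", pos = 21L, alt = "C", freq = 0.06)))
  het <- call_heteroplasmies(p, all_unique_mask(50L),
                             mito_params(min_cov = 100L))
  expect_equal(het$calls$line, "MA3")
  # a different alternate at the same position does not cross-exclude
  p <- mito_fixture(plant = list(
    list(line = "MA1", pos = 7L, alt = "G", freq = 0.05),
    list(line = "MA2", pos = 7L, alt = "T", freq = 0.05)))
  het <- call_heteroplasmies(p, all_unique_mask(50L),
                             mito_params(min_cov = 100L))
  expect_equal(sort(het$calls$line), c("MA1", "MA2"))
})

test_that("min coverage defaults to a tenth of each line's mean", {
  p <- mito_fixture(depth = 1000L)
  het <- call_heteroplasmies(p, all_unique_mask(50L), mito_params())
  expect_equal(unname(het$min_cov), rep(100L, 3L))
})

test_that("frequency-weighted rate sums frequencies over sites and generations", {
  calls <- data.table::data.table(line = "MA1", contig = "m", pos = 1L,
                                  ref = "A", alt = "T", freq = 1.0,
                                  depth = 1000L)
  het <- list(calls = calls, n_sites = c(MA1 = 1000L))
  r <- mito_rate(het, g = 1000L)
  expect_equal(r$rate, 1e-6)

  # no calls: rate 0
  het0 <- list(calls = calls[0L], n_sites = c(MA1 = 1000L, MA2 = 1000L))
  expect_equal(mito_rate(het0, 1000L)$rate, 0)

  # all frequencies 1 reduces to the discrete m/(n*g)
  calls2 <- data.table::data.table(line = rep("MA1", 3L), contig = "m",
                                   pos = 1:3, ref = "A", alt = "T",
                                   freq = 1.0, depth = 1000L)
  het2 <- list(calls = calls2, n_sites = c(MA1 = 500L))
  expect_equal(mito_rate(het2, 100L)$rate, 3 / (500 * 100))

  # linearity: splitting the call list changes nothing
  half <- mito_rate(list(calls = calls2[1:2], n_sites = c(MA1 = 500L)),
                    100L)$rate +
    mito_rate(list(calls = calls2[3L], n_sites = c(MA1 = 500L)), 100L)$rate
  expect_equal(half, mito_rate(het2, 100L)$rate)

  # a line with zero eligible sites is dropped with a warning
  hetz <- list(calls = calls, n_sites = c(MA1 = 1000L, MA2 = 0L))
  expect_warning(r <- mito_rate(hetz, 1000L), "zero eligible")
  expect_equal(r$rate, 1e-6)
})

test_that("raising the cutoff never raises the rate for a fixed call set", {
  set.seed(81)
  cfg <- mito_simulation_config(
    seed = 81, genome_length = 500L, mean_coverage = c(800, 800, 800),
    per_read_error = 0.01,
    heteroplasmy = list(frequencies = c(0.04, 0.1, 0.3)))
  sim <- simulate_ma_experiment(cfg)
  mask <- all_unique_mask(500L, contig = "mito")
  het <- call_heteroplasmies(sim$pileups, mask,
                             mito_params(cutoff = 0.01, min_cov = 50L))
  prev <- Inf
  for (f in c(0.01, 0.03, 0.05, 0.2)) {
    sub <- list(calls = het$calls[freq >= f], n_sites = het$n_sites)
    r <- suppressWarnings(mito_rate(sub, 1000L)$rate)
    expect_lte(r, prev + 1e-15)
    prev <- r
  }
})

test_that("grid cutoff selection finds the rate minimum above error noise", {
  set.seed(91)
  cfg <- mito_simulation_config(
    seed = 91, genome_length = 3000L, mean_coverage = c(400, 400, 400),
    per_read_error = 0.012,
    heteroplasmy = list(rate = 2e-6, freq_range = c(0.05, 0.5)))
  sim <- simulate_ma_experiment(cfg)
  mask <- all_unique_mask(3000L, contig = "mito")
  sel <- select_cutoff_grid(sim$pileups, mask,
                            mito_params(min_cov = 40L), g = 1000L)
  # cutoffs at/below 0.02 admit floods of binomial sequencing errors
  expect_gte(sel$chosen, 0.03)
  expect_equal(nrow(sel$diagnostics), 10L)
  expect_gt(sel$diagnostics$rate[1L], sel$diagnostics$rate[3L])
  expect_equal(sel$chosen, sel$diagnostics$cutoff[which.min(sel$diagnostics$rate)])

  # zero alternate reads: every estimate 0, smallest cutoff wins the tie
  cfg0 <- mito_simulation_config(seed = 92, genome_length = 200L,
                                 mean_coverage = c(500, 500, 500),
                                 per_read_error = 0)
  sim0 <- simulate_ma_experiment(cfg0)
  sel0 <- select_cutoff_grid(sim0$pileups, all_unique_mask(200L, "mito"),
                             mito_params(min_cov = 50L), g = 1000L)
  expect_true(all(sel0$diagnostics$rate == 0))
  expect_equal(sel0$chosen, 0.01)

  # single-value grid returns that value
  sel1 <- select_cutoff_grid(sim0$pileups, all_unique_mask(200L, "mito"),
                             mito_params(min_cov = 50L), grid = 0.07,
                             g = 1000L)
  expect_equal(sel1$chosen, 0.07)
})

test_that("binomial cutoff selection matches exhaustive tail summation", {
  grid <- seq(0.01, 0.10, by = 0.01)
  sel <- select_cutoff_binomial(0.004, 400L, 6.7e-6, grid)
  expect_equal(sel$chosen, 0.03)
  for (i in seq_along(grid)) {
    expect_equal(sel$diagnostics$tail_prob[i],
                 oracle_binom_tail(floor(400 * grid[i] + 1e-9), 400L, 0.004),
                 tolerance = 1e-12)
  }
  # at these parameters the strict/non-strict count inequality
  # does not move the chosen cutoff
  sel_incl <- select_cutoff_binomial(0.004, 400L, 6.7e-6, grid,
                                     inclusive = TRUE)
  expect_equal(sel_incl$chosen, sel$chosen)

  # error rate -> 0 admits the smallest cutoff
  expect_equal(select_cutoff_binomial(1e-12, 400L, 6.7e-6, grid)$chosen, 0.01)

  # an impossible threshold is an error, not a silent fallback
  expect_error(select_cutoff_binomial(0.5, 400L, 1e-300, grid),
               "no admissible cutoff")
})

test_that("frequency-sum estimator recovers the true rate over replicates", {
  set.seed(101)
  mu <- 5e-7
  n_rep <- 50L
  est <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- mito_simulation_config(
      genome_length = 2000L, mean_coverage = c(4000, 7000, 3000),
      per_read_error = 0.002,
      heteroplasmy = list(rate = mu, freq_range = c(0.05, 0.5)))
    sim <- simulate_ma_experiment(cfg)
    het <- call_heteroplasmies(sim$pileups, all_unique_mask(2000L, "mito"),
                               mito_params(cutoff = 0.03))
    est[r] <- suppressWarnings(mito_rate(het, 1000L)$rate)
  }
  se <- stats::sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - mu), 3 * se)
})
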