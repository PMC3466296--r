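#' Simulation configuration
#'
#' Describes a synthetic MA sequencing experiment with known truth:
#' an AT-rich genome with optional exact repeat blocks, per-line point
#' mutations planted at a stated true rate over `generations` cell
#' divisions, ancestor-vs-reference differences shared by every line,
#' optional heteroplasmic sites, and per-read base errors with
#' Poisson-distributed coverage. Defaults describe a typical three-line
#' nuclear MA sequencing experiment: 1000 generations, 78% AT,
#' mean coverages 11/10/9, per-read error 0.002; see
#' [mito_simulation_config()] for mitochondrial defaults.
#'
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param genome_length Contig length in bp.
#' @param at_fraction Genome AT fraction (P(A) = P(T) = half of it).
#' @param repeat_spec List of `c(block_length, copies)` exact
#'   duplications to plant.
#' @param n_lines Number of MA lines.
#' @param generations Cell generations g.
#' @param true_rate True per-site per-generation mutation rate.
#' @param shared_diff_count Ancestor-vs-reference differences planted
#'   identically in every line.
#' @param mean_coverage Per-line mean read depth (recycled to
#'   `n_lines`).
#' @param per_read_error Per-read base error probability e: a read
#'   reports the true base with probability `1 - e`, otherwise one of
#'   the other three bases uniformly.
#' @param heteroplasmy `NULL`, or a list describing heteroplasmic
#'   sites: either `list(frequencies = c(...))` planting each listed
#'   frequency once per line, or `list(rate =, freq_range = c(lo, hi))`
#'   planting per line a Poisson number of sites with mean
#'   `rate * genome_length * generations / mean(frequency)` and
#'   frequencies uniform on `freq_range` (the division by the mean
#'   frequency makes the frequency-sum rate estimator unbiased at
#'   `rate`).
#' @param contig Contig name.
#' @param circular Is the contig circular?
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = NULL, genome_length = 100000L,
                              at_fraction = 0.78, repeat_spec = list(),
                              n_lines = 3L, generations = 1000L,
                              true_rate = 2.9e-11, shared_diff_count = 0L,
                              mean_coverage = c(11, 10, 9),
                              per_read_error = 0.002,
                              heteroplasmy = NULL,
                              contig = "chr1", circular = FALSE) {
  stopifnot(genome_length >= 1, at_fraction >= 0, at_fraction <= 1,
            n_lines >= 1, generations >= 1, true_rate >= 0,
            shared_diff_count >= 0, all(mean_coverage > 0),
            per_read_error >= 0, per_read_error < 1)
  mean_coverage <- rep_len(mean_coverage, n_lines)
  structure(list(seed = seed, genome_length = as.integer(genome_length),
                 at_fraction = at_fraction, repeat_spec = repeat_spec,
                 n_lines = as.integer(n_lines),
                 generations = as.integer(generations),
                 true_rate = true_rate,
                 shared_diff_count = as.integer(shared_diff_count),
                 mean_coverage = mean_coverage,
                 per_read_error = per_read_error,
                 heteroplasmy = heteroplasmy,
                 contig = contig, circular = isTRUE(circular)),
            class = "simulation_config")
}

#' Mitochondrial simulation defaults
#'
#' Same machinery as [simulation_config()] with defaults for a
#' high-copy mitochondrial contig: 55,564 bp, circular, 72.57% AT, deep per-line
#' coverage (4655/7141/3033), and no nuclear-style planted mutations
#' unless requested.
#'
#' @param ... Overrides passed to [simulation_config()].
#' @export
mito_simulation_config <- function(...) {
  defaults <- list(genome_length = 55564L, at_fraction = 0.7257,
                   mean_coverage = c(4655, 7141, 3033),
                   true_rate = 0, contig = "mito", circular = TRUE)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

#' Simulate a reference genome
#'
#' Independent draws per position with `P(A) = P(T) = at_fraction / 2`
#' and `P(C) = P(G) = (1 - at_fraction) / 2`; then each requested
#' repeat block is copied exactly to non-overlapping positions.
#'
#' @param config A [simulation_config].
#' @return A [genome_sequence] with a `repeats` attribute
#'   (`data.table` of `block`, `start`, `end`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  len <- config$genome_length
  p <- c(A = config$at_fraction / 2, C = (1 - config$at_fraction) / 2,
         G = (1 - config$at_fraction) / 2, T = config$at_fraction / 2)
  bases <- sample(names(p), len, replace = TRUE, prob = p)
  repeats <- data.table::data.table(block = integer(), start = integer(),
                                    end = integer())
  if (length(config$repeat_spec) > 0L) {
    total <- sum(vapply(config$repeat_spec,
                        function(r) r[[1L]] * r[[2L]], 0))
    if (total > len)
      stop("simulate_genome: repeat blocks exceed genome length")
    cursor <- 1L
    for (bi in seq_along(config$repeat_spec)) {
      blen <- as.integer(config$repeat_spec[[bi]][[1L]])
      copies <- as.integer(config$repeat_spec[[bi]][[2L]])
      block <- bases[seq.int(cursor, cursor + blen - 1L)]
      gap <- max(1L, (len - cursor - blen * copies) %/% (copies + 1L))
      for (ci in seq_len(copies)) {
        start <- cursor + (ci - 1L) * (blen + gap)
        if (start + blen - 1L > len)
          stop("simulate_genome: repeat blocks exceed genome length")
        bases[seq.int(start, start + blen - 1L)] <- block
        repeats <- rbind(repeats,
                         data.table::data.table(block = bi, start = start,
                                                end = start + blen - 1L))
      }
      cursor <- max(repeats$end) + gap + 1L
    }
  }
  g <- genome_sequence(config$contig, paste(bases, collapse = ""),
                       circular = config$circular)
  attr(g, "repeats") <- repeats
  g
}

BASES <- c("A", "C", "G", "T")

# pick, for each reference base, one of the three other bases uniformly
random_alt <- function(ref_bases) {
  vapply(ref_bases,
         function(b) sample(setdiff(BASES, b), 1L), "",
         USE.NAMES = FALSE)
}

#' Plant mutations and shared ancestral differences
#'
#' Per line, the number of unique mutations is Poisson with mean
#' `true_rate * genome_length * generations`; positions are uniform
#' without replacement within a line and alternate bases uniform over
#' the three non-reference bases. Shared ancestor-vs-reference
#' differences are applied identically to every line, emulating
#' reference errors and pre-experiment divergence that later show up as
#' candidates in all lines.
#'
#' @param genome A [genome_sequence] from [simulate_genome()].
#' @param config A [simulation_config].
#' @return List with `line_genomes` (named list of per-line sequences as
#'   character vectors) and `truth` (`data.table`: `line` (`NA` for
#'   shared differences), `pos`, `ref`, `alt`, `type`
#'   `unique`/`shared`).
#' @export
plant_mutations <- function(genome, config) {
  stopifnot(inherits(genome, "genome_sequence"))
  len <- nchar(genome$sequence)
  ref <- strsplit(genome$sequence, "", fixed = TRUE)[[1L]]
  lines <- paste0("MA", seq_len(config$n_lines))
  truth <- list()

  shared_pos <- integer(0)
  shared_alt <- character(0)
  if (config$shared_diff_count > 0L) {
    shared_pos <- sort(sample.int(len, config$shared_diff_count))
    shared_alt <- random_alt(ref[shared_pos])
    truth[["shared"]] <- data.table::data.table(
      line = NA_character_, pos = shared_pos, ref = ref[shared_pos],
      alt = shared_alt, type = "shared")
  }

  lam <- config$true_rate * len * config$generations
  line_genomes <- list()
  for (l in lines) {
    seq_l <- ref
    if (length(shared_pos)) seq_l[shared_pos] <- shared_alt
    k <- stats::rpois(1L, lam)
    if (k > 0L) {
      avail <- setdiff(seq_len(len), shared_pos)
      mpos <- sort(sample(avail, min(k, length(avail))))
      malt <- random_alt(ref[mpos])
      seq_l[mpos] <- malt
      truth[[l]] <- data.table::data.table(
        line = l, pos = mpos, ref = ref[mpos], alt = malt, type = "unique")
    }
    line_genomes[[l]] <- seq_l
  }
  truth <- if (length(truth)) data.table::rbindlist(truth) else
    data.table::data.table(line = character(), pos = integer(),
                           ref = character(), alt = character(),
                           type = character())
  list(line_genomes = line_genomes, truth = truth)
}

# multinomial counts over ACGT drawn as a chain of conditional binomials,
# vectorised over sites with unequal depths
sample_counts <- function(depth, pmat) {
  n <- length(depth)
  out <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
  rem <- depth
  prem <- rep(1, n)
  for (b in 1:3) {
    pb <- pmat[, b] / prem
    pb[!is.finite(pb)] <- 0
    pb <- pmin(pmax(pb, 0), 1)
    cb <- stats::rbinom(n, rem, pb)
    out[, b] <- cb
    rem <- rem - cb
    prem <- prem - pmat[, b]
  }
  out[, 4L] <- rem
  out
}

#' Simulate a per-line pileup from a line genome
#'
#' Per site, depth is Poisson(`mean_cov`); each read reports the line's
#' true base with probability `1 - e` and one of the other three bases
#' uniformly otherwise. At heteroplasmic sites each read's true base is
#' the alternate with probability equal to the site's true frequency.
#'
#' @param line_seq Character vector of the line's true bases.
#' @param ref_seq Character vector of reference bases (for the `ref`
#'   column).
#' @param mean_cov Mean coverage for the line.
#' @param e Per-read error probability.
#' @param contig Contig name.
#' @param het Optional `data.table` with `pos`, `alt`, `freq` of
#'   heteroplasmic sites in this line.
#' @return Full-genome site table (`contig`, `pos`, `ref`, `A`, `C`,
#'   `G`, `T`, `depth`).
#' @export
simulate_pileup <- function(line_seq, ref_seq, mean_cov, e,
                            contig = "chr1", het = NULL) {
  n <- length(line_seq)
  stopifnot(length(ref_seq) == n)
  depth <- stats::rpois(n, mean_cov)
  true_idx <- match(line_seq, BASES)
  # P(observe b) = (1-e)[b == true] + e/3 [b != true]
  pmat <- matrix(e / 3, n, 4L)
  pmat[cbind(seq_len(n), true_idx)] <- 1 - e
  if (!is.null(het) && nrow(het) > 0L) {
    stopifnot(all(c("pos", "alt", "freq") %in% names(het)))
    for (i in seq_len(nrow(het))) {
      p <- het$pos[[i]]; f <- het$freq[[i]]
      alt_idx <- match(het$alt[[i]], BASES)
      row <- rep(e / 3, 4L)
      row[true_idx[[p]]] <- (1 - f) * (1 - e) + f * e / 3
      row[alt_idx] <- f * (1 - e) + (1 - f) * e / 3
      if (alt_idx == true_idx[[p]]) row[alt_idx] <- 1 - e
      pmat[p, ] <- row
    }
  }
  counts <- sample_counts(depth, pmat)
  data.table::data.table(contig = contig, pos = seq_len(n), ref = ref_seq,
                         A = counts[, 1L], C = counts[, 2L],
                         G = counts[, 3L], T = counts[, 4L],
                         depth = as.integer(depth))
}

# draw heteroplasmy truth for one line under the config's spec
draw_heteroplasmies <- function(ref, config, exclude_pos = integer(0)) {
  spec <- config$heteroplasmy
  if (is.null(spec)) return(NULL)
  len <- length(ref)
  if (!is.null(spec$frequencies)) {
    freqs <- spec$frequencies
  } else {
    mean_f <- mean(spec$freq_range)
    lam <- spec$rate * len * config$generations / mean_f
    k <- stats::rpois(1L, lam)
    freqs <- stats::runif(k, spec$freq_range[[1L]], spec$freq_range[[2L]])
  }
  if (length(freqs) == 0L) return(NULL)
  avail <- setdiff(seq_len(len), exclude_pos)
  pos <- sort(sample(avail, min(length(freqs), length(avail))))
  data.table::data.table(pos = pos, ref = ref[pos],
                         alt = random_alt(ref[pos]),
                         freq = freqs[seq_along(pos)])
}

#' Simulate a complete MA sequencing experiment
#'
#' Generates the reference genome, plants per-line mutations, shared
#' differences, and heteroplasmies, and simulates per-line pileups.
#' Bit-reproducible for a given config and seed.
#'
#' @param config A [simulation_config].
#' @return List with `genome`, `truth` (planted mutations and shared
#'   differences), `het_truth` (named list per line, or `NULL`),
#'   `pileups` (named list of site tables), and `config`.
#' @export
simulate_ma_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  genome <- simulate_genome(config)
  planted <- plant_mutations(genome, config)
  ref <- strsplit(genome$sequence, "", fixed = TRUE)[[1L]]
  lines <- names(planted$line_genomes)
  het_truth <- NULL
  pileups <- list()
  for (li in seq_along(lines)) {
    l <- lines[[li]]
    het <- draw_heteroplasmies(
      ref, config, exclude_pos = planted$truth[["pos"]])
    if (!is.null(het)) {
      if (is.null(het_truth)) het_truth <- list()
      het_truth[[l]] <- het
    }
    pileups[[l]] <- simulate_pileup(
      planted$line_genomes[[l]], ref, config$mean_coverage[[li]],
      config$per_read_error, contig = config$contig, het = het)
  }
  list(genome = genome, truth = planted$truth, het_truth = het_truth,
       pileups = pileups, config = config)
}

#' Write a simulated experiment to disk
#'
#' Writes the reference FASTA, per-line simple-TSV pileups, the truth
#' table as TSV, and the resolved configuration as YAML.
#'
#' @param sim Result of [simulate_ma_experiment()].
#' @param dir Output directory (created if absent).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fasta = file.path(dir, "reference.fa"),
                truth = file.path(dir, "truth.tsv"),
                config = file.path(dir, "config.yaml"))
  write_fasta(sim$genome, paths$fasta)
  data.table::fwrite(sim$truth, paths$truth, sep = "\t")
  cfg <- sim$config
  cfg$repeat_spec <- lapply(cfg$repeat_spec, as.integer)
  yaml::write_yaml(unclass(cfg), paths$config)
  for (l in names(sim$pileups)) {
    paths[[paste0("pileup_", l)]] <- file.path(dir, paste0(l, ".pileup.tsv"))
    write_pileup_simple(sim$pileups[[l]], paths[[paste0("pileup_", l)]])
  }
  invisible(paths)
}
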