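#' Assemble a pipeline configuration
#'
#' Either points at existing inputs (`fasta`, per-line `pileups`) or
#' requests a simulation; validates paths before any computation. All
#' randomness flows from the single `seed`: each stage derives a child
#' seed by an indexed offset, so stages are independently rerunnable.
#'
#' @param outdir Output directory.
#' @param seed Integer master seed.
#' @param fasta Path to the reference FASTA (ignored when `simulate`
#'   is given).
#' @param pileups Named character vector of per-line pileup paths.
#' @param pileup_dialect Dialect passed to [read_pileup()].
#' @param simulate `NULL`, or a [simulation_config] (its seed is
#'   derived from the pipeline seed).
#' @param mito_simulate `NULL`, or a [simulation_config] for the
#'   mitochondrial contig.
#' @param filter A [filter_params].
#' @param mito A [mito_params], or `NULL` to skip the mitochondrial
#'   stage.
#' @param selfmap A [self_map_params].
#' @param generations Cell generations g.
#' @param level Confidence level for intervals.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, fasta = NULL, pileups = NULL,
                            pileup_dialect = "simple_tsv",
                            simulate = NULL, mito_simulate = NULL,
                            filter = filter_params(), mito = mito_params(),
                            selfmap = self_map_params(),
                            generations = 1000L, level = 0.95) {
  if (is.null(simulate)) {
    if (is.null(fasta) || !file.exists(fasta))
      stop("pipeline_config: reference FASTA not found: ",
           if (is.null(fasta)) "<missing>" else fasta)
    if (is.null(pileups) || is.null(names(pileups)))
      stop("pipeline_config: named per-line pileup paths are required")
    missing <- pileups[!file.exists(pileups)]
    if (length(missing))
      stop("pipeline_config: pileup file not found: ",
           paste(missing, collapse = ", "))
  }
  structure(list(outdir = outdir, seed = as.integer(seed), fasta = fasta,
                 pileups = pileups, pileup_dialect = pileup_dialect,
                 simulate = simulate, mito_simulate = mito_simulate,
                 filter = filter, mito = mito, selfmap = selfmap,
                 generations = as.integer(generations), level = level),
            class = "pipeline_config")
}

#' A small self-contained demo configuration
#'
#' Simulates a 30-kb nuclear contig with a planted duplication, shared
#' ancestral differences and a handful of true mutations, plus a 3-kb
#' deep-coverage mitochondrial contig with heteroplasmies, then runs
#' the full pipeline on it.
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @return A `pipeline_config`.
#' @export
demo_pipeline_config <- function(outdir, seed = 1L) {
  pipeline_config(
    outdir = outdir, seed = seed,
    simulate = simulation_config(
      genome_length = 30000L, repeat_spec = list(c(60L, 2L)),
      true_rate = 1e-7, shared_diff_count = 5L),
    mito_simulate = mito_simulation_config(
      genome_length = 3000L,
      heteroplasmy = list(frequencies = c(0.05, 0.08, 0.44))),
    generations = 1000L)
}

stage_seed <- function(seed, stage) (seed + 1000L * stage) %% .Machine$integer.max

#' Run the full analysis pipeline
#'
#' simulate (optional) -> mappability -> nuclear calling -> mito
#' calling -> rate estimation, writing a deterministic artifact set to
#' `outdir`: mask BED + per-position coverage TSV, mutation VCF,
#' classification TSV, rates JSON (with every stage's parameters echoed
#' for provenance), and a MANIFEST with content hashes.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the in-memory stage results
#'   (`mask`, `tally`, `nuclear`, `mito`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  # stage 1: obtain inputs
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- stage_seed(config$seed, 1L)
    sim <- simulate_ma_experiment(sim_cfg)
    genome <- sim$genome
    pileups <- sim$pileups
    paths <- c(paths, write_simulation(sim, file.path(config$outdir, "sim")))
  } else {
    genomes <- read_fasta(config$fasta)
    genome <- genomes[[1L]]
    pileups <- lapply(config$pileups, read_pileup,
                      dialect = config$pileup_dialect,
                      genome = genome, extend = TRUE)
  }

  # stage 2: mappability
  sm <- config$selfmap
  sm$circular <- sm$circular || genome$circular
  mask <- self_map_coverage(genome, sm)
  paths$mask_bed <- file.path(config$outdir, "mask.bed")
  write_mask_bed(mask, paths$mask_bed)
  paths$self_coverage <- file.path(config$outdir, "self_coverage.tsv")
  data.table::fwrite(
    data.table::data.table(contig = mask$contig,
                           pos = seq_along(mask$self_coverage),
                           self_coverage = mask$self_coverage,
                           unique = mask$unique),
    paths$self_coverage, sep = "\t")

  # stage 3: nuclear calling
  cls <- classify_sites(pileups, mask, config$filter)
  tally <- tally_classifications(cls)
  nuc <- nuclear_rate(tally, config$generations, config$level)
  calls <- mutation_calls(cls)
  paths$vcf <- file.path(config$outdir, "mutations.vcf")
  write_vcf(calls, paths$vcf)
  paths$classifications <- file.path(config$outdir, "classifications.tsv")
  write_classifications(cls, paths$classifications)

  # stage 4: mitochondrial calling (optional)
  mito_out <- NULL
  if (!is.null(config$mito_simulate)) {
    mito_cfg <- config$mito_simulate
    mito_cfg$seed <- stage_seed(config$seed, 4L)
    mito_sim <- simulate_ma_experiment(mito_cfg)
    mito_sm <- config$selfmap
    mito_sm$circular <- TRUE
    mito_mask <- self_map_coverage(mito_sim$genome, mito_sm)
    het <- call_heteroplasmies(mito_sim$pileups, mito_mask, config$mito)
    mrate <- mito_rate(het, config$mito$generations, config$level)
    paths$mito_calls <- file.path(config$outdir, "mito_calls.tsv")
    data.table::fwrite(het$calls, paths$mito_calls, sep = "\t")
    mito_out <- list(het = het, rate = mrate)
  }

  # stage 5: rate report
  report <- list(
    parameters = list(
      seed = config$seed,
      filter = unclass(config$filter),
      selfmap = unclass(config$selfmap)[c("read_length", "max_mismatch")],
      mito = if (!is.null(mito_out)) unclass(config$mito) else NULL,
      generations = config$generations, level = config$level),
    mappability = unique_fraction(mask),
    tally = list(m = tally$m, n_unchanged = tally$n_unchanged,
                 candidates = tally$candidates,
                 shared_candidates = tally$shared_candidates),
    nuclear = unclass(nuc),
    mito = if (!is.null(mito_out)) mito_out$rate[
      c("rate", "k", "ci_lower", "ci_upper", "per_line")] else NULL)
  paths$rates <- file.path(config$outdir, "rates.json")
  write_rates_json(report, paths$rates)

  # manifest with content hashes
  files <- unlist(paths)
  manifest <- data.table::data.table(
    file = basename(files), md5 = unname(tools::md5sum(files)))
  data.table::fwrite(manifest, file.path(config$outdir, "MANIFEST.tsv"),
                     sep = "\t")

  invisible(list(mask = mask, classifications = cls, tally = tally,
                 nuclear = nuc, mito = mito_out, report = report,
                 paths = paths))
}
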