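#' Self-mapping parameters
#'
#' Parameters for the self-mapping procedure that measures short-read
#' mapping ambiguity: every possible read of length `read_length` is
#' taken from both strands of the reference and aligned back to it
#' allowing up to `max_mismatch` mismatches.
#'
#' @param read_length Read length L in bp (default 31).
#' @param max_mismatch Allowed mismatches per read, 0 or 1 (default 1).
#' @param circular Treat the contig as circular (windows wrap).
#' @return An object of class `self_map_params`.
#' @export
self_map_params <- function(read_length = 31L, max_mismatch = 1L,
                            circular = FALSE) {
  read_length <- as.integer(read_length)
  max_mismatch <- as.integer(max_mismatch)
  stopifnot(read_length >= 2L, max_mismatch %in% c(0L, 1L),
            is.logical(circular), length(circular) == 1L)
  if (read_length %% 2L == 0L)
    warning("even read_length admits palindromic windows ",
            "(a window equal to its own reverse complement)")
  structure(list(read_length = read_length, max_mismatch = max_mismatch,
                 circular = circular), class = "self_map_params")
}

#' Enumerate all self-mapping reads of a genome
#'
#' Every length-L window of the forward strand plus its reverse
#' complement, one pair per offset. Circular genomes wrap across the
#' origin, so every position starts a window.
#'
#' @param genome A [genome_sequence].
#' @param params A [self_map_params]; `circular` is taken from the
#'   genome unless set in `params`.
#' @return `data.table` with columns `seq`, `offset` (1-based origin),
#'   `strand` (`+`/`-`). Empty (with a warning) if the genome is linear
#'   and shorter than L.
#' @export
enumerate_self_reads <- function(genome, params = self_map_params()) {
  stopifnot(inherits(genome, "genome_sequence"))
  L <- params$read_length
  circular <- params$circular || genome$circular
  n <- nchar(genome$sequence)
  n_off <- if (circular) n else n - L + 1L
  if (n_off <= 0L) {
    warning("genome shorter than read length and not circular: no reads")
    return(data.table::data.table(seq = character(), offset = integer(),
                                  strand = character()))
  }
  s <- if (circular) paste0(genome$sequence,
                            substr(genome$sequence, 1L, L - 1L)) else
    genome$sequence
  fwd <- substring(s, seq_len(n_off), seq_len(n_off) + L - 1L)
  data.table::data.table(
    seq = c(fwd, revcomp(fwd)),
    offset = rep(seq_len(n_off), 2L),
    strand = rep(c("+", "-"), each = n_off))
}

#' Self-mapping coverage and the uniquely-mappable mask
#'
#' Aligns every self-read (both strands) to every position of the genome
#' at Hamming distance at most `max_mismatch`, allowing reads to map to
#' multiple placements, and counts for each position the number of
#' (read, placement) pairs spanning it. A position is uniquely mappable
#' exactly when its self-mapping coverage equals `2 * read_length`
#' (62 for 31-bp reads): only the windows originating over the position
#' map there, each once per strand.
#'
#' Candidate placements are found by pigeonhole seeding (a placement
#' within one mismatch matches at least one of the two read halves
#' exactly) and then verified by full-read Hamming comparison, so the
#' result is exact.
#'
#' @inheritParams enumerate_self_reads
#' @return An object of class `mappability_mask`: fields `contig`,
#'   `self_coverage` (integer per position), `unique` (logical per
#'   position), plus the parameters used.
#' @export
self_map_coverage <- function(genome, params = self_map_params()) {
  stopifnot(inherits(genome, "genome_sequence"))
  L <- params$read_length
  circular <- params$circular || genome$circular
  n <- nchar(genome$sequence)
  cov <- if (!circular && n < L) {
    warning("genome shorter than read length and not circular: ",
            "self-mapping coverage is zero everywhere")
    integer(n)
  } else {
    selfmap_coverage_cpp(genome$sequence, L, params$max_mismatch, circular)
  }
  new_mappability_mask(genome$name, cov, L, params$max_mismatch, circular)
}

new_mappability_mask <- function(contig, self_coverage, read_length,
                                 max_mismatch, circular) {
  structure(list(contig = contig,
                 self_coverage = as.integer(self_coverage),
                 unique = self_coverage == 2L * read_length,
                 read_length = as.integer(read_length),
                 max_mismatch = as.integer(max_mismatch),
                 circular = circular),
            class = "mappability_mask")
}

#' Construct a mask directly from a uniqueness vector
#'
#' Used when the per-position self-mapping coverage is not available
#' (e.g. a mask read back from BED, or an all-unique mask for simulated
#' repeat-free genomes). Coverage is filled with `2L` at unique
#' positions and `NA` elsewhere.
#'
#' @param contig Contig identifier.
#' @param unique Logical vector, one entry per position.
#' @param read_length Read length the mask refers to.
#' @return A `mappability_mask`.
#' @export
mappability_mask_from_unique <- function(contig, unique, read_length = 31L) {
  cov <- ifelse(unique, 2L * as.integer(read_length), NA_integer_)
  m <- new_mappability_mask(contig, cov, read_length, NA_integer_, FALSE)
  m$unique <- as.logical(unique)
  m
}

#' @export
print.mappability_mask <- function(x, ...) {
  cat(sprintf(
    "<mappability_mask> %s: %d bp, %d uniquely mappable (%.1f%%), L=%d, mm<=%s\n",
    x$contig, length(x$unique), sum(x$unique),
    100 * mean(x$unique), x$read_length, x$max_mismatch))
  invisible(x)
}

#' Fraction of the genome that is uniquely mappable
#'
#' @param mask A [mappability_mask].
#' @return List with `fraction` (unique positions / genome length),
#'   `n_unique`, and `genome_length`.
#' @export
unique_fraction <- function(mask) {
  stopifnot(inherits(mask, "mappability_mask"))
  n <- length(mask$unique)
  k <- sum(mask$unique)
  list(fraction = if (n == 0L) 0 else k / n, n_unique = k, genome_length = n)
}
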