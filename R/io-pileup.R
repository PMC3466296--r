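#' Decode a classic pileup read-base string into base counts
#'
#' Decodes the samtools `pileup -c` read-base encoding: `.`/`,` count as
#' the reference base, `ACGT`/`acgt` as mismatch bases, `^X` (read start
#' plus mapping-quality character) and `$` (read end) are stripped,
#' `+n<seq>`/`-n<seq>` insertions/deletions, `*` deletion placeholders,
#' and `N` are skipped. Counts are returned over `{A,C,G,T}` only.
#'
#' @param read_string Pileup read-base string (character scalar).
#' @param ref_base Reference base at the site.
#' @return Named integer vector `c(A=,C=,G=,T=)`.
#' @examples
#' decode_pileup_bases("..,,TT", "A")  # A=4, T=2
#' @export
decode_pileup_bases <- function(read_string, ref_base) {
  stopifnot(length(read_string) == 1L, length(ref_base) == 1L)
  m <- decode_pileup_cpp(as.character(read_string), as.character(ref_base))
  stats::setNames(as.integer(m[1L, ]), c("A", "C", "G", "T"))
}

PILEUP_COLS <- c("contig", "pos", "ref", "A", "C", "G", "T", "depth")

#' Read a pileup file into per-site base counts
#'
#' Two dialects are supported and must be named explicitly (no
#' autodetection: silently misreading column 4 vs 9 would corrupt
#' counts):
#' * `classic10col` -- the classic samtools `pileup -c` layout:
#'   chromosome, position, reference base, consensus base, consensus
#'   quality, SNP quality, RMS mapping quality, depth, read bases, base
#'   qualities. Read-base strings are decoded with
#'   [decode_pileup_bases()]; base-quality strings are parsed but
#'   ignored (the calling rules use only base identity, coverage, and
#'   agreement).
#' * `simple_tsv` -- contig, position, reference base, countA, countC,
#'   countG, countT.
#'
#' The stored `depth` is always the sum of the ACGT counts (N and indel
#' symbols are excluded before counting). With `extend = TRUE` and a
#' reference `genome`, positions absent from the file are emitted with
#' depth 0, giving a full-genome site table.
#'
#' @param path Path to a plain-text pileup file.
#' @param dialect `"classic10col"` or `"simple_tsv"`.
#' @param genome Optional [genome_sequence] supplying reference bases for
#'   extension; required when `extend = TRUE`.
#' @param extend Emit depth-0 rows for positions absent from the file.
#' @return A `data.table` with columns `contig`, `pos`, `ref`,
#'   `A`, `C`, `G`, `T`, `depth`, ordered by position.
#' @export
read_pileup <- function(path, dialect = c("simple_tsv", "classic10col"),
                        genome = NULL, extend = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_pileup: no such file: ", path)
  dt <- if (file.size(path) == 0L) data.table::data.table() else
    data.table::fread(path, header = FALSE, sep = "\t", quote = "",
                      colClasses = list(character = 1L), fill = TRUE)
  need <- if (dialect == "classic10col") 10L else 7L
  if (nrow(dt) > 0L) {
    if (ncol(dt) != need) {
      stop(sprintf(
        "read_pileup: %s expects %d columns, found %d (first offending row: 1)",
        dialect, need, ncol(dt)))
    }
    nc <- rowSums(!is.na(dt))
    if (any(nc != need))
      stop(sprintf("read_pileup: column-count mismatch at row %d",
                   which(nc != need)[[1L]]))
  }
  if (nrow(dt) == 0L) {
    sites <- data.table::data.table(contig = character(), pos = integer(),
                                    ref = character(), A = integer(),
                                    C = integer(), G = integer(),
                                    T = integer(), depth = integer())
  } else if (dialect == "simple_tsv") {
    sites <- data.table::data.table(
      contig = as.character(dt[[1L]]), pos = as.integer(dt[[2L]]),
      ref = toupper(as.character(dt[[3L]])),
      A = as.integer(dt[[4L]]), C = as.integer(dt[[5L]]),
      G = as.integer(dt[[6L]]), T = as.integer(dt[[7L]]))
  } else {
    counts <- decode_pileup_cpp(as.character(dt[[9L]]),
                                toupper(as.character(dt[[3L]])))
    sites <- data.table::data.table(
      contig = as.character(dt[[1L]]), pos = as.integer(dt[[2L]]),
      ref = toupper(as.character(dt[[3L]])),
      A = counts[, 1L], C = counts[, 2L], G = counts[, 3L], T = counts[, 4L])
  }
  sites[, depth := A + C + G + T]
  if (extend) {
    if (is.null(genome))
      stop("read_pileup: extension to full genome length requires `genome`")
    sites <- extend_sites(sites, genome)
  }
  data.table::setorderv(sites, c("contig", "pos"))
  sites[]
}

# fill positions absent from `sites` with depth-0 rows over the genome
extend_sites <- function(sites, genome) {
  len <- nchar(genome$sequence)
  full <- data.table::data.table(
    contig = genome$name, pos = seq_len(len),
    ref = strsplit(genome$sequence, "", fixed = TRUE)[[1L]])
  have <- sites[contig == genome$name]
  out <- merge(full, have[, c("pos", "A", "C", "G", "T", "depth"), with = FALSE],
               by = "pos", all.x = TRUE)
  for (col in c("A", "C", "G", "T", "depth"))
    data.table::set(out, which(is.na(out[[col]])), col, 0L)
  data.table::setcolorder(out, PILEUP_COLS)
  out
}

#' Write per-site base counts in the simple TSV pileup dialect
#'
#' @param sites Site table as returned by [read_pileup()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup_simple <- function(sites, path) {
  data.table::fwrite(sites[, .(contig, pos, ref, A, C, G, T)], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}
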