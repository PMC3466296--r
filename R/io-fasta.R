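#' Genome sequence
#'
#' A single contig: its name, an upper-case sequence over `{A,C,G,T,N}`,
#' and whether the molecule is circular. Nuclear contigs are linear; the
#' mitochondrial contig may be circular, in which case read windows are
#' allowed to wrap across the origin.
#'
#' @param name Contig identifier.
#' @param sequence Character scalar over `A`, `C`, `G`, `T`, `N`
#'   (lower case accepted and folded to upper).
#' @param circular Logical; is the molecule circular?
#' @return An object of class `genome_sequence` with fields `name`,
#'   `sequence`, `circular`.
#' @export
genome_sequence <- function(name, sequence, circular = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L,
            is.logical(circular), length(circular) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L)
    stop("genome_sequence: sequence must have length >= 1")
  if (grepl("[^ACGTN]", sequence))
    stop("genome_sequence: illegal character in sequence (alphabet is ACGTN)")
  structure(list(name = name, sequence = sequence, circular = circular),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s: %d bp (%s)\n", x$name,
              nchar(x$sequence), if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' @export
length.genome_sequence <- function(x) nchar(x$sequence)

#' Read a FASTA file into genome sequences
#'
#' Records are case-folded to upper case and order is preserved. Contigs
#' named in `circular` are flagged circular (typically the mitochondrial
#' contig).
#'
#' @param path Path to a plain-text FASTA file.
#' @param circular Character vector of contig names to mark circular.
#' @return A named list of [genome_sequence] objects.
#' @export
read_fasta <- function(path, circular = character()) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(trimws(lines[[1L]]), ">"))
    stop("read_fasta: malformed header at line 1 (expected '>')")
  is_header <- startsWith(lines, ">")
  bad <- which(!is_header & grepl("[^ACGTNacgtn]", lines) & nzchar(trimws(lines)))
  if (length(bad))
    stop(sprintf("read_fasta: illegal sequence character at line %d", bad[[1L]]))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("read_fasta: no records in ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  out <- lapply(seq_along(seqs), function(i) {
    genome_sequence(nm[[i]], toupper(as.character(seqs[[i]])),
                    circular = nm[[i]] %in% circular)
  })
  names(out) <- nm
  out
}

#' Write genome sequences to FASTA
#'
#' @param genomes A [genome_sequence] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_sequence")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(ss) <- vapply(genomes, `[[`, "", "name")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# reverse complement of character sequences, preserving N
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
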