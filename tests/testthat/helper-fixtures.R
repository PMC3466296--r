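# Small programmatic fixtures shared across test files.

random_genome_string <- function(n, seed = NULL,
                                 bases = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

all_unique_mask <- function(n, contig = "chr1") {
  mappability_mask_from_unique(contig, rep(TRUE, n))
}

# build a site table from a counts matrix (columns A,C,G,T)
make_sites <- function(counts, ref, contig = "chr1",
                       pos = seq_len(nrow(counts))) {
  data.table::data.table(
    contig = contig, pos = pos, ref = ref,
    A = as.integer(counts[, 1L]), C = as.integer(counts[, 2L]),
    G = as.integer(counts[, 3L]), T = as.integer(counts[, 4L]),
    depth = as.integer(rowSums(counts)))
}

# unanimous-coverage site table over a genome string with chosen depths
unanimous_sites <- function(seq_string, depths, contig = "chr1") {
  ref <- strsplit(seq_string, "", fixed = TRUE)[[1L]]
  n <- length(ref)
  counts <- matrix(0L, n, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[cbind(seq_len(n), match(ref, c("A", "C", "G", "T")))] <-
    as.integer(depths)
  make_sites(counts, ref, contig)
}

# override the counts at one position of a site table
set_site_counts <- function(sites, position, counts) {
  sites <- data.table::copy(sites)
  for (b in c("A", "C", "G", "T"))
    data.table::set(sites, which(sites$pos == position), b,
                    as.integer(counts[[b]]))
  data.table::set(sites, which(sites$pos == position), "depth",
                  as.integer(sum(unlist(counts))))
  sites
}
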