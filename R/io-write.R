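#' Write mutation calls as a minimal VCF
#'
#' One data line per call: `CHROM POS ID REF ALT QUAL FILTER INFO`, with
#' the line identifier, agreement fraction, and read depth carried in
#' INFO (`LINE=`, `AGREE=`, `DP=`). Positions are 1-based as in the
#' internal convention. An empty call set yields a valid header-only VCF.
#'
#' @param calls `data.table` with columns `contig`, `pos`, `ref`, `alt`,
#'   `line`, and optionally `agree`, `depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=malines",
    '##INFO=<ID=LINE,Number=1,Type=String,Description="MA line carrying the mutation">',
    '##INFO=<ID=AGREE,Number=1,Type=Float,Description="Fraction of reads agreeing with the majority base">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Counted read depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  body <- character()
  if (!is.null(calls) && nrow(calls) > 0L) {
    info <- sprintf("LINE=%s", calls$line)
    if (!is.null(calls$agree))
      info <- paste0(info, sprintf(";AGREE=%.4g", calls$agree))
    if (!is.null(calls$depth))
      info <- paste0(info, sprintf(";DP=%d", as.integer(calls$depth)))
    body <- paste(calls$contig, calls$pos, ".", calls$ref, calls$alt,
                  ".", "PASS", info, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the uniquely-mappable mask as BED
#'
#' Runs of uniquely mappable positions are merged into intervals and
#' written as 0-based half-open BED records.
#'
#' @param mask A [mappability_mask].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_bed <- function(mask, path) {
  stopifnot(inherits(mask, "mappability_mask"))
  gr <- mask_to_granges(mask)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

mask_to_granges <- function(mask) {
  r <- rle(mask$unique)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  GenomicRanges::GRanges(
    seqnames = mask$contig,
    ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]))
}

#' Read a uniquely-mappable mask back from BED
#'
#' Inverse of [write_mask_bed()] up to the per-position self-mapping
#' coverage, which BED does not carry.
#'
#' @param path BED file of uniquely mappable intervals.
#' @param contig Contig identifier.
#' @param genome_length Contig length in bp.
#' @return A logical vector of length `genome_length`.
#' @export
read_mask_bed <- function(path, contig, genome_length) {
  gr <- rtracklayer::import(path, format = "BED")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == contig]
  unique_flag <- logical(genome_length)
  if (length(gr) > 0L) {
    for (i in seq_along(gr)) {
      s <- GenomicRanges::start(gr)[i]
      e <- GenomicRanges::end(gr)[i]
      unique_flag[s:e] <- TRUE
    }
  }
  unique_flag
}

#' Write per-site classifications as TSV
#'
#' @param classifications Classification table from [classify_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(classifications, path) {
  data.table::fwrite(classifications, path, sep = "\t")
  invisible(path)
}

#' Write a structured rate report as JSON
#'
#' @param rates A named list of rate estimates and diagnostics.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rates_json <- function(rates, path) {
  jsonlite::write_json(rates, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
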