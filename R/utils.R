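# Internal helpers shared across modules.

# round-half-up; base round() is round-half-even and would give 46 for 46.5
.roundHalfUp <- function(x) floor(x + 0.5)

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# condition constructors so the CLI can map error classes to exit codes
.configError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("riboUORF_config_error", "riboUORF_error")))
}

.dataError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("riboUORF_data_error", "riboUORF_error")))
}

# "start1-end1;start2-end2" in 0-based half-open genome coordinates,
# blocks listed 5'->3' along the transcript
.blocksToString <- function(gr) {
  paste(sprintf("%d-%d", GenomicRanges::start(gr) - 1L,
                GenomicRanges::end(gr)), collapse = ";")
}

.stringToBlocks <- function(s, chrom, strand) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- do.call(rbind, strsplit(parts, "-", fixed = TRUE))
  start0 <- as.integer(m[, 1])
  end0 <- as.integer(m[, 2])
  if (any(is.na(start0)) || any(is.na(end0)) || any(start0 >= end0))
    .dataError("malformed genome_blocks string: '%s'", s)
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1L, end = end0),
                         strand = strand)
}

.msg <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}
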