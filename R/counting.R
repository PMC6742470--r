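#' P-site assignment and read-filter parameters
#'
#' RPFs are assigned to features by a single inferred P-site position: the
#' genomic base `psiteOffset` nucleotides into the read from its 5' end in
#' transcript direction, walking through aligned blocks and skipping junction
#' gaps. A fixed offset of 12 nt is the usual convention for 28-32 nt RPFs.
#'
#' @param psiteOffset 0-based offset of the P-site from the read 5' end
#'   (default 12).
#' @param strandedness `"forward"` (read strand equals feature strand, the
#'   default for standard ribo-seq protocols), `"reverse"`, or
#'   `"unstranded"`.
#' @param primaryOnly drop secondary/supplementary alignments (default
#'   `TRUE`), avoiding double counting of multimappers.
#' @param minReadLen,maxReadLen admissible read lengths in nt (defaults 25
#'   and 35, the usual RPF window).
#'
#' @return a list of class `RpfCountParam`.
#' @export
rpfCountParam <- function(psiteOffset = 12L, strandedness = "forward",
                          primaryOnly = TRUE, minReadLen = 25L,
                          maxReadLen = 35L) {
  strandedness <- match.arg(strandedness,
                            c("forward", "reverse", "unstranded"))
  psiteOffset <- as.integer(psiteOffset)
  minReadLen <- as.integer(minReadLen)
  maxReadLen <- as.integer(maxReadLen)
  if (psiteOffset < 0L || minReadLen < 0L || minReadLen > maxReadLen)
    .configError("rpfCountParam: need psiteOffset >= 0 and 0 <= minReadLen <= maxReadLen")
  structure(list(psiteOffset = psiteOffset, strandedness = strandedness,
                 primaryOnly = primaryOnly, minReadLen = minReadLen,
                 maxReadLen = maxReadLen),
            class = "RpfCountParam")
}

#' @export
print.RpfCountParam <- function(x, ...) {
  cat(sprintf("RpfCountParam: P-site offset %d nt, %s, read length %d-%d, primary only: %s\n",
              x$psiteOffset, x$strandedness, x$minReadLen, x$maxReadLen,
              x$primaryOnly))
  invisible(x)
}

#' Infer P-site positions for aligned reads
#'
#' For every alignment, walks `psiteOffset` nucleotides into the read from
#' its 5' end in transcript direction (for minus-strand alignments the 5'
#' end is the highest genomic coordinate and the walk runs towards lower
#' coordinates), skipping junction (`N`) gaps. Reads failing the length
#' filter, or whose aligned span is shorter than the offset, yield no
#' position.
#'
#' @param gal a [GenomicAlignments::GAlignments].
#' @param param an [rpfCountParam()] list.
#'
#' @return a [GenomicRanges::GRanges] of width-1 P-site positions (strand =
#'   read strand), one per passing read.
#' @export
psitePositions <- function(gal, param = rpfCountParam()) {
  qw <- GenomicAlignments::qwidth(gal)
  keep <- qw >= param$minReadLen & qw <= param$maxReadLen
  gal <- gal[keep]
  if (!length(gal))
    return(GenomicRanges::GRanges())
  blocks <- GenomicAlignments::grglist(gal)   # ascending genomic order
  ul <- unlist(blocks, use.names = FALSE)
  nblk <- S4Vectors::elementNROWS(blocks)
  grp <- rep(seq_along(blocks), nblk)
  w <- GenomicRanges::width(ul)
  cw <- cumsum(w)
  lastOfGrp <- cumsum(nblk)
  before <- rep(c(0L, cw[lastOfGrp])[seq_along(blocks)], nblk)
  cwIn <- cw - before                 # cumulative width within read, incl. block
  offStart <- cwIn - w                # ascending-order offset at block start
  totalW <- rep(cw[lastOfGrp] - c(0L, cw[lastOfGrp])[seq_along(blocks)], nblk)
  strandPlus <- rep(as.character(GenomicRanges::strand(gal)) == "+", nblk)
  o <- param$psiteOffset
  # transcript-direction offsets covered by each block
  tOff1 <- ifelse(strandPlus, offStart, totalW - cwIn)
  hit <- o >= tOff1 & o < tOff1 + w
  pos <- integer(sum(hit))
  hs <- GenomicRanges::start(ul)[hit]
  he <- GenomicRanges::end(ul)[hit]
  pos <- ifelse(strandPlus[hit], hs + (o - tOff1[hit]),
                he - (o - tOff1[hit]))
  readIdx <- grp[hit]
  nDropped <- length(gal) - length(readIdx)
  if (nDropped > 0L)
    message(sprintf("psitePositions: offset beyond aligned length for %d read(s)",
                    nDropped))
  GenomicRanges::GRanges(
    GenomicRanges::seqnames(ul)[hit],
    IRanges::IRanges(start = pos, width = 1L),
    strand = GenomicRanges::strand(gal)[readIdx])
}

.openAsBam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    return(Rsamtools::asBam(path, destination = dest,
                            indexDestination = TRUE, overwrite = TRUE))
  }
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path)))
    .configError("BAM index missing for %s (sort and index the file first)",
                 path)
  path
}

#' Count P-site-assigned RPFs on feature blocks
#'
#' For each sample (BAM/SAM file) and each feature, counts the reads whose
#' inferred P-site falls inside any block of the feature on a compatible
#' strand. Point assignment means one read increments at most one feature of
#' a set of disjoint features; if blocks of two features overlap, both are
#' incremented (a warning is emitted once per feature set).
#'
#' @param bamPaths vector of sorted, indexed BAM files (plain SAM files are
#'   converted on the fly).
#' @param features a named [GenomicRanges::GRangesList] (e.g. from
#'   [cdsFeatures()] or [uorfFeatures()]).
#' @param featureKind `"CDS"` or `"uORF"`.
#' @param param an [rpfCountParam()] list.
#' @param sampleIds column names; default file basenames.
#'
#' @return an [RpfCounts-class] with one integer `counts` assay.
#' @export
countFeatures <- function(bamPaths, features, featureKind = c("CDS", "uORF"),
                          param = rpfCountParam(), sampleIds = NULL) {
  featureKind <- match.arg(featureKind)
  if (is.null(names(features)) || anyDuplicated(names(features)))
    .configError("features must be uniquely named")
  if (is.null(sampleIds))
    sampleIds <- sub("\\.(bam|sam)$", "", basename(bamPaths),
                     ignore.case = TRUE)
  if (anyDuplicated(sampleIds))
    .configError("duplicate sample ids")
  ulFeat <- unlist(features, use.names = FALSE)
  fid <- rep(seq_along(features), S4Vectors::elementNROWS(features))
  selfHits <- GenomicRanges::findOverlaps(ulFeat, ulFeat)
  cross <- fid[S4Vectors::queryHits(selfHits)] !=
    fid[S4Vectors::subjectHits(selfHits)]
  if (any(cross))
    warning(sprintf("%d overlapping block pair(s) between distinct features; reads there count to both",
                    sum(cross) %/% 2L))
  mat <- matrix(0L, nrow = length(features), ncol = length(bamPaths),
                dimnames = list(names(features), sampleIds))
  featStrand <- as.character(GenomicRanges::strand(ulFeat))
  for (j in seq_along(bamPaths)) {
    bam <- .openAsBam(bamPaths[j])
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    missingChrom <- setdiff(
      unique(as.character(GenomicRanges::seqnames(ulFeat))), names(hdr))
    if (length(missingChrom))
      warning(sprintf("%s: sequence(s) %s absent from BAM header; features there count 0",
                      basename(bamPaths[j]),
                      paste(missingChrom, collapse = ",")))
    flag <- Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = if (param$primaryOnly) FALSE else NA,
      isSupplementaryAlignment = if (param$primaryOnly) FALSE else NA)
    gal <- GenomicAlignments::readGAlignments(
      bam, param = Rsamtools::ScanBamParam(flag = flag))
    ps <- psitePositions(gal, param)
    if (!length(ps)) next
    if (param$strandedness == "reverse")
      GenomicRanges::strand(ps) <- ifelse(
        as.character(GenomicRanges::strand(ps)) == "+", "-", "+")
    ignoreStrand <- param$strandedness == "unstranded"
    hits <- GenomicRanges::findOverlaps(ulFeat, ps,
                                        ignore.strand = ignoreStrand)
    if (length(hits)) {
      cnt <- tabulate(fid[S4Vectors::queryHits(hits)],
                      nbins = length(features))
      mat[, j] <- as.integer(cnt)
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat),
    colData = S4Vectors::DataFrame(sample_id = sampleIds,
                                   row.names = sampleIds))
  new("RpfCounts", se, featureKind = featureKind)
}

#' Write a raw count table as CSV
#'
#' Header row is `feature_id,<sample1>,<sample2>,...`.
#'
#' @param counts an [RpfCounts-class] or matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(counts, path) {
  m <- if (is(counts, "RpfCounts")) counts(counts) else as.matrix(counts)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
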