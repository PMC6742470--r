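#' Construct uORF scan parameters
#'
#' @param startCodons candidate start codons; default canonical `ATG` only.
#' @param minLen,maxLen admissible uORF span in nt including the stop codon;
#'   defaults 9 (start + one codon + stop) and 400 (uORFs are short by
#'   definition).
#' @param requireContained require the uORF to end at or before the main-ORF
#'   start (default `TRUE`); switch off to also report leader-initiated ORFs
#'   running into the CDS.
#'
#' @return a [UorfScanParam-class].
#' @examples
#' uorfScanParam()
#' uorfScanParam(startCodons = c("ATG", "CTG"))
#' @export
uorfScanParam <- function(startCodons = "ATG", minLen = 9L, maxLen = 400L,
                          requireContained = TRUE) {
  new("UorfScanParam", startCodons = toupper(startCodons),
      minLen = as.integer(minLen), maxLen = as.integer(maxLen),
      requireContained = isTRUE(requireContained))
}

#' Scan a transcript leader sequence for upstream open reading frames
#'
#' Enumerates every span that begins with a configured start codon and runs
#' to the first in-frame stop codon (TAA/TAG/TGA), entirely within the given
#' sequence. Each distinct start position yields at most one uORF; nested and
#' stop-sharing uORFs with different starts are all reported. Codons
#' containing `N` never match a start or stop. Spans outside
#' `[minLen, maxLen]` (stop codon included) are discarded.
#'
#' @param tls the leader sequence (character, [Biostrings::DNAString], 5'->3').
#' @param param a [UorfScanParam-class].
#'
#' @return data.frame with columns `t_start`, `t_end` (0-based half-open,
#'   local to the scanned sequence, stop codon included) and `start_codon`,
#'   sorted by `t_start` then `t_end`. Zero rows when nothing is found.
#' @examples
#' scanUorfs("AAATGTTTTAACC")   # one 9-nt uORF at [2,11)
#' @export
scanUorfs <- function(tls, param = uorfScanParam()) {
  s <- toupper(as.character(tls))
  n <- nchar(s)
  empty <- data.frame(t_start = integer(), t_end = integer(),
                      start_codon = character(),
                      stringsAsFactors = FALSE)
  if (n < param@minLen) return(empty)
  pos <- seq_len(n - 2L)
  codons <- substring(s, pos, pos + 2L)
  startIdx <- pos[codons %in% param@startCodons]
  stopIdx <- pos[codons %in% .STOP_CODONS]
  if (!length(startIdx) || !length(stopIdx)) return(empty)
  hits <- lapply(startIdx, function(st) {
    inframe <- stopIdx[stopIdx >= st + 3L & (stopIdx - st) %% 3L == 0L]
    if (!length(inframe)) return(NULL)
    sp <- inframe[1]
    len <- sp + 3L - st
    if (len < param@minLen || len > param@maxLen) return(NULL)
    data.frame(t_start = st - 1L, t_end = sp + 2L,
               start_codon = substring(s, st, st + 2L),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(empty)
  hits[order(hits$t_start, hits$t_end), , drop = FALSE]
}

#' Peptide length encoded by an ORF span
#'
#' The number of amino acids encoded by an ORF of `lengthNt` nucleotides
#' (stop codon included): `lengthNt / 3 - 1`, i.e. the initiator methionine
#' counts and the stop codon does not.
#'
#' @param lengthNt ORF span in nt including the stop codon; must be a
#'   multiple of 3 and at least 6.
#'
#' @return integer vector of amino-acid counts.
#' @examples
#' peptideLength(81)  # 26 aa
#' peptideLength(9)   # minimal uORF: 2 aa
#' @export
peptideLength <- function(lengthNt) {
  lengthNt <- as.integer(lengthNt)
  if (any(is.na(lengthNt)) || any(lengthNt %% 3L != 0L) || any(lengthNt < 6L))
    .dataError("ORF length must be a multiple of 3 and >= 6 nt")
  lengthNt %/% 3L - 1L
}

#' Build a uORF annotation for a reduced gene set
#'
#' Scans the transcript leader of every transcript in `reduced`, lifts each
#' hit to its genomic blocks, and assigns ids `<transcript_id>.u<k>` with
#' ordinals by ascending transcript start. With
#' `requireContained = FALSE` the whole transcript is scanned and any ORF
#' starting within the leader is reported, including ones running into the
#' CDS.
#'
#' @param reduced a [ReducedAnnotation-class].
#' @param genome named [Biostrings::DNAStringSet] or FASTA path; must cover
#'   every sequence name used by the annotation.
#' @param param a [UorfScanParam-class].
#'
#' @return a [UorfAnnotation-class].
#' @export
buildUorfAnnotation <- function(reduced, genome, param = uorfScanParam()) {
  genome <- .asGenome(genome)
  chroms <- unique(vapply(transcripts(reduced), function(t) t@chrom,
                          character(1)))
  missing <- setdiff(chroms, names(genome))
  if (length(missing))
    .configError("genome is missing sequence(s) required by the annotation: %s",
                 paste(missing, collapse = ", "))
  rows <- list()
  for (tm in transcripts(reduced)) {
    scanEnd <- if (param@requireContained) tm@cdsStartT else matureLength(tm)
    if (tm@cdsStartT == 0L) next                 # no leader, no uORFs
    if (param@requireContained && tm@cdsStartT < param@minLen) next
    seq <- transcriptSeq(tm, genome, 0L, scanEnd)
    hits <- scanUorfs(seq, param)
    # a uORF must start upstream of the main ORF
    hits <- hits[hits$t_start < tm@cdsStartT, , drop = FALSE]
    if (!nrow(hits)) next
    hits <- hits[order(hits$t_start, hits$t_end), , drop = FALSE]
    for (k in seq_len(nrow(hits))) {
      blocks <- transcriptToGenome(tm, hits$t_start[k], hits$t_end[k])
      rows[[length(rows) + 1L]] <- data.frame(
        uorf_id = sprintf("%s.u%d", tm@txId, k),
        transcript_id = tm@txId, gene_id = tm@geneId,
        chrom = tm@chrom, strand = tm@strand,
        genome_blocks = .blocksToString(blocks),
        t_start = hits$t_start[k], t_end = hits$t_end[k],
        length_nt = hits$t_end[k] - hits$t_start[k],
        peptide_len_aa = (hits$t_end[k] - hits$t_start[k]) %/% 3L - 1L,
        start_codon = hits$start_codon[k],
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(ncol = length(.UORF_COLUMNS), nrow = 0)),
                    .UORF_COLUMNS)
  tab <- .coerceUorfTable(tab)
  new("UorfAnnotation", table = tab)
}

.coerceUorfTable <- function(tab) {
  chr <- c("uorf_id", "transcript_id", "gene_id", "chrom", "strand",
           "genome_blocks", "start_codon")
  int <- c("t_start", "t_end", "length_nt", "peptide_len_aa")
  for (cc in chr) tab[[cc]] <- as.character(tab[[cc]])
  for (cc in int) tab[[cc]] <- as.integer(tab[[cc]])
  rownames(tab) <- NULL
  tab[, .UORF_COLUMNS, drop = FALSE]
}

#' Genomic blocks of annotated uORFs
#'
#' @param uorfs a [UorfAnnotation-class].
#' @return a named [GenomicRanges::GRangesList], one element per uORF, blocks
#'   in genomic (ascending) order.
#' @export
uorfFeatures <- function(uorfs) {
  tab <- as.data.frame(uorfs)
  grl <- lapply(seq_len(nrow(tab)), function(i) {
    gr <- .stringToBlocks(tab$genome_blocks[i], tab$chrom[i], tab$strand[i])
    sort(gr)
  })
  names(grl) <- tab$uorf_id
  GenomicRanges::GRangesList(grl)
}

#' Genomic blocks of main-ORF coding sequences
#'
#' @param reduced a [ReducedAnnotation-class].
#' @return a [GenomicRanges::GRangesList] named by transcript id, one
#'   element per transcript, the CDS blocks in genomic order.
#' @export
cdsFeatures <- function(reduced) {
  txs <- transcripts(reduced)
  grl <- lapply(txs, function(tm)
    sort(transcriptToGenome(tm, tm@cdsStartT, tm@cdsEndT)))
  names(grl) <- vapply(txs, txId, character(1))
  GenomicRanges::GRangesList(grl)
}

#' Filter candidate uORFs by ribosome-profiling read evidence
#'
#' Keeps candidates whose summed raw counts across all samples reach
#' `minTotalReads`. With `minTotalReads = 0` every candidate passes, which is
#' the comprehensive-annotation behaviour where uORFs without any RPF counts
#' are retained. Candidates absent from the count table count as zero.
#'
#' @param uorfs a [UorfAnnotation-class].
#' @param counts an [RpfCounts-class] (uORF features) or a counts matrix with
#'   uORF ids as rownames.
#' @param minTotalReads minimum summed raw count (default 1).
#'
#' @return the filtered [UorfAnnotation-class].
#' @export
filterByEvidence <- function(uorfs, counts, minTotalReads = 1L) {
  m <- if (is(counts, "RpfCounts")) counts(counts) else as.matrix(counts)
  ids <- as.data.frame(uorfs)$uorf_id
  missing <- setdiff(ids, rownames(m))
  if (length(missing))
    message(sprintf("filterByEvidence: %d candidate(s) missing from counts, treated as zero",
                    length(missing)))
  tot <- stats::setNames(rep(0, length(ids)), ids)
  present <- intersect(ids, rownames(m))
  tot[present] <- rowSums(m[present, , drop = FALSE])
  uorfs[tot >= minTotalReads]
}

#' Read and write uORF annotation CSV files
#'
#' The on-disk format is a plain CSV with header
#' `uorf_id,transcript_id,gene_id,chrom,strand,genome_blocks,t_start,t_end,length_nt,peptide_len_aa,start_codon`;
#' `genome_blocks` is `start1-end1;start2-end2` in 0-based half-open genome
#' coordinates, blocks 5'->3' along the transcript. `writeUorfAnnotation`
#' followed by `readUorfAnnotation` is the identity on all fields. The reader
#' validates every row: rows whose span length is not a multiple of 3 (or
#' that are otherwise inconsistent) are rejected with a warning naming them;
#' duplicated uORF ids are a fatal error.
#'
#' @param path CSV file path.
#' @param uorfs a [UorfAnnotation-class].
#'
#' @return `readUorfAnnotation`: a [UorfAnnotation-class];
#'   `writeUorfAnnotation`: `path`, invisibly.
#' @export
readUorfAnnotation <- function(path) {
  if (!file.exists(path))
    .configError("uORF annotation not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.UORF_COLUMNS, colnames(tab))
  if (length(missing))
    .dataError("uORF annotation %s lacks column(s): %s", path,
               paste(missing, collapse = ", "))
  tab <- .coerceUorfTable(tab)
  bad <- which(tab$length_nt %% 3L != 0L |
                 tab$length_nt != tab$t_end - tab$t_start |
                 tab$peptide_len_aa != tab$length_nt %/% 3L - 1L |
                 !tab$strand %in% c("+", "-"))
  if (length(bad)) {
    warning(sprintf("rejected %d invalid row(s) (%s): length not divisible by 3 or inconsistent fields",
                    length(bad),
                    paste(utils::head(tab$uorf_id[bad], 5), collapse = ",")))
    tab <- tab[-bad, , drop = FALSE]
  }
  if (anyDuplicated(tab$uorf_id))
    .dataError("duplicate uorf_id in %s", path)
  new("UorfAnnotation", table = .coerceUorfTable(tab))
}

#' @rdname readUorfAnnotation
#' @export
writeUorfAnnotation <- function(uorfs, path) {
  utils::write.csv(as.data.frame(uorfs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write uORFs as BED12
#'
#' One record per uORF; spliced footprints are encoded as BED blocks
#' (ascending genomic order, starts relative to `chromStart`). BED uses
#' 0-based half-open coordinates.
#'
#' @param uorfs a [UorfAnnotation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeUorfBed <- function(uorfs, path) {
  tab <- as.data.frame(uorfs)
  lines <- vapply(seq_len(nrow(tab)), function(i) {
    gr <- sort(.stringToBlocks(tab$genome_blocks[i], tab$chrom[i],
                               tab$strand[i]))
    cs <- GenomicRanges::start(gr) - 1L    # 0-based
    ce <- GenomicRanges::end(gr)
    chromStart <- min(cs); chromEnd <- max(ce)
    paste(tab$chrom[i], chromStart, chromEnd, tab$uorf_id[i], 0L,
          tab$strand[i], chromStart, chromEnd, "0", length(gr),
          paste0(paste(ce - cs, collapse = ","), ","),
          paste0(paste(cs - chromStart, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
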