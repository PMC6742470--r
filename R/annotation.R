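#' Construct a TranscriptModel
#'
#' @param txId,geneId transcript and gene identifiers.
#' @param chrom sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons [IRanges::IRanges] (or anything coercible) of exon blocks in
#'   genomic coordinates (1-based closed), sorted and non-overlapping.
#' @param cdsStartT,cdsEndT CDS span in transcript coordinates, 0-based
#'   half-open, 5'->3'.
#' @param level Gencode confidence level; defaults to 3 (unknown provenance).
#' @param txType transcript biotype.
#'
#' @return a [TranscriptModel-class] object.
#' @examples
#' tm <- transcriptModel("tx1", "g1", "chr1", "+",
#'                       IRanges::IRanges(1001, 2000), 100L, 900L)
#' matureLength(tm)
#' @export
transcriptModel <- function(txId, geneId, chrom, strand, exons,
                            cdsStartT, cdsEndT, level = 3L,
                            txType = "protein_coding") {
  new("TranscriptModel", txId = as.character(txId),
      geneId = as.character(geneId), chrom = as.character(chrom),
      strand = as.character(strand), exons = as(exons, "IRanges"),
      cdsStartT = as.integer(cdsStartT), cdsEndT = as.integer(cdsEndT),
      level = as.integer(level), txType = as.character(txType))
}

# exon widths in transcript (5'->3') order
.txExonOrder <- function(tm) {
  n <- length(tm@exons)
  if (tm@strand == "+") seq_len(n) else rev(seq_len(n))
}

#' Map a transcript-space span to genomic blocks
#'
#' Converts a 0-based half-open span in transcript coordinates to the ordered
#' list of genomic blocks it occupies, splitting at exon junctions. Blocks
#' are returned 5'->3' along the transcript, so for minus-strand transcripts
#' genomic coordinates decrease along the returned ranges.
#'
#' @param tm a [TranscriptModel-class].
#' @param tStart,tEnd transcript span, 0-based half-open; must satisfy
#'   `0 <= tStart < tEnd <= matureLength(tm)`.
#'
#' @return a [GenomicRanges::GRanges] whose widths sum to `tEnd - tStart`.
#' @examples
#' tm <- transcriptModel("tx1", "g1", "chr1", "+",
#'                       IRanges::IRanges(c(1, 101), c(50, 150)), 0L, 60L)
#' transcriptToGenome(tm, 40L, 60L)
#' @export
transcriptToGenome <- function(tm, tStart, tEnd) {
  tStart <- as.integer(tStart); tEnd <- as.integer(tEnd)
  ml <- matureLength(tm)
  if (is.na(tStart) || is.na(tEnd) || tStart < 0L || tStart >= tEnd ||
      tEnd > ml)
    .dataError("transcript span [%d,%d) outside mature length %d of %s",
               tStart, tEnd, ml, tm@txId)
  ord <- .txExonOrder(tm)
  w <- IRanges::width(tm@exons)[ord]
  offEnd <- cumsum(w)              # transcript offset just past each exon
  offStart <- offEnd - w
  gs <- IRanges::start(tm@exons)[ord]
  ge <- IRanges::end(tm@exons)[ord]
  hit <- which(offStart < tEnd & offEnd > tStart)
  o1 <- pmax(tStart, offStart[hit]) - offStart[hit]
  o2 <- pmin(tEnd, offEnd[hit]) - offStart[hit]
  if (tm@strand == "+") {
    bs <- gs[hit] + o1
    be <- gs[hit] + o2 - 1L
  } else {
    bs <- ge[hit] - o2 + 1L
    be <- ge[hit] - o1
  }
  GenomicRanges::GRanges(tm@chrom, IRanges::IRanges(start = bs, end = be),
                         strand = tm@strand)
}

# genomic position (1-based) -> transcript offset (0-based); NA if intronic
.genomePosToTx <- function(tm, gpos) {
  ord <- .txExonOrder(tm)
  w <- IRanges::width(tm@exons)[ord]
  offStart <- cumsum(w) - w
  gs <- IRanges::start(tm@exons)[ord]
  ge <- IRanges::end(tm@exons)[ord]
  for (k in seq_along(ord)) {
    if (gpos >= gs[k] && gpos <= ge[k]) {
      return(if (tm@strand == "+") offStart[k] + (gpos - gs[k])
             else offStart[k] + (ge[k] - gpos))
    }
  }
  NA_integer_
}

#' Extract transcript-space sequence from a genome
#'
#' `transcriptSeq` returns the spliced 5'->3' sequence of a transcript span;
#' `extractTls` returns the transcript leader sequence (TLS / 5'UTR), i.e.
#' the span upstream of the main-ORF start codon. Minus-strand transcripts
#' are reverse-complemented so the result always reads 5'->3'.
#'
#' @param tm a [TranscriptModel-class].
#' @param genome a named [Biostrings::DNAStringSet] (or a FASTA file path).
#' @param tStart,tEnd transcript span, 0-based half-open.
#'
#' @return a [Biostrings::DNAString]; for `extractTls` an empty sequence when
#'   the transcript has no leader (`cdsStartT == 0`).
#' @export
transcriptSeq <- function(tm, genome, tStart, tEnd) {
  genome <- .asGenome(genome)
  if (!tm@chrom %in% names(genome))
    .configError("sequence '%s' not found in genome", tm@chrom)
  if (tEnd == tStart) return(Biostrings::DNAString(""))
  blocks <- transcriptToGenome(tm, tStart, tEnd)
  chromSeq <- genome[[tm@chrom]]
  parts <- lapply(seq_along(blocks), function(i) {
    s <- Biostrings::subseq(chromSeq, GenomicRanges::start(blocks)[i],
                            GenomicRanges::end(blocks)[i])
    if (tm@strand == "-") Biostrings::reverseComplement(s) else s
  })
  do.call(Biostrings::xscat, parts)
}

#' @rdname transcriptSeq
#' @export
extractTls <- function(tm, genome) {
  transcriptSeq(tm, genome, 0L, tm@cdsStartT)
}

.asGenome <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L) {
    if (!file.exists(genome))
      .configError("genome FASTA not found: %s", genome)
    g <- Biostrings::readDNAStringSet(genome)
    # Gencode-style headers may carry descriptions after the first word
    names(g) <- sub("\\s.*$", "", names(g))
    return(g)
  }
  .configError("genome must be a DNAStringSet or a FASTA path")
}

# cheap structural pre-scan so malformed records are reported with their
# line number (rtracklayer's errors do not carry one)
.prescanGtf <- function(path, maxLines = Inf) {
  con <- file(path, "r")
  on.exit(close(con))
  lineNo <- 0L
  repeat {
    chunk <- readLines(con, n = 5000L)
    if (!length(chunk)) break
    for (ln in chunk) {
      lineNo <- lineNo + 1L
      if (lineNo > maxLines) return(invisible(TRUE))
      if (!nzchar(ln) || startsWith(ln, "#")) next
      fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(fields) != 9L)
        .dataError("malformed GTF record at line %d: expected 9 tab-separated fields, found %d",
                   lineNo, length(fields))
      if (!grepl("\\w+\\s+\"[^\"]*\"", fields[9]) &&
          !grepl("\\w+\\s+[^\";]+;", fields[9]))
        .dataError("malformed GTF attribute block at line %d", lineNo)
    }
  }
  invisible(TRUE)
}

#' Read gene models from a Gencode-style GTF
#'
#' Parses a GTF file (Gencode attribute dialect: `gene_id`, `transcript_id`,
#' `transcript_type`, `level`) into [TranscriptModel-class] objects. Only
#' transcripts with at least one exon and a CDS are returned; coordinates are
#' converted from the GTF's 1-based closed convention to the package's
#' internal transcript-space convention (0-based half-open). Transcripts
#' whose Gencode `level` attribute is missing are assigned level 3
#' (fail-closed: excluded by the default reduction filter).
#'
#' @param path GTF file path.
#' @param enforceCdsFrame if `TRUE`, transcripts whose CDS length is not a
#'   multiple of 3 are dropped; by default they are kept and flagged via a
#'   warning (real annotations contain such models).
#' @param verbose emit progress messages.
#'
#' @return a list of [TranscriptModel-class] objects.
#' @export
readGtf <- function(path, enforceCdsFrame = FALSE, verbose = FALSE) {
  if (!file.exists(path))
    .configError("GTF file not found: %s", path)
  .prescanGtf(path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keepTypes <- as.character(md$type) %in% c("exon", "CDS")
  gr <- gr[keepTypes]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) return(list())
  txIds <- as.character(md$transcript_id)
  if (anyNA(txIds))
    .dataError("GTF exon/CDS records without transcript_id attribute")
  lvl <- if ("level" %in% colnames(md))
    suppressWarnings(as.integer(as.character(md$level))) else
      rep(NA_integer_, length(gr))
  ttype <- if ("transcript_type" %in% colnames(md))
    as.character(md$transcript_type) else rep(NA_character_, length(gr))
  gid <- as.character(md$gene_id)
  typ <- as.character(md$type)

  out <- list()
  nSkipped <- 0L
  for (tx in unique(txIds)) {
    sel <- txIds == tx
    exSel <- sel & typ == "exon"
    cdsSel <- sel & typ == "CDS"
    if (!any(cdsSel)) next                       # non-coding: excluded
    if (!any(exSel)) {
      warning(sprintf("transcript %s has CDS but no exon records; skipped", tx))
      nSkipped <- nSkipped + 1L
      next
    }
    ex <- IRanges::reduce(IRanges::IRanges(
      start = GenomicRanges::start(gr)[exSel],
      end = GenomicRanges::end(gr)[exSel]))
    strand <- as.character(GenomicRanges::strand(gr))[which(exSel)[1]]
    chrom <- as.character(GenomicRanges::seqnames(gr))[which(exSel)[1]]
    cdsStartG <- min(GenomicRanges::start(gr)[cdsSel])
    cdsEndG <- max(GenomicRanges::end(gr)[cdsSel])
    cdsWidth <- sum(GenomicRanges::width(gr)[cdsSel])
    level <- lvl[which(sel)[1]]
    if (is.na(level)) level <- 3L
    txType <- ttype[which(sel)[1]]
    if (is.na(txType)) txType <- "unknown"
    tmTmp <- transcriptModel(tx, gid[which(sel)[1]], chrom, strand, ex,
                             0L, sum(IRanges::width(ex)), level, txType)
    fivePrime <- if (strand == "+") cdsStartG else cdsEndG
    cdsStartT <- .genomePosToTx(tmTmp, fivePrime)
    if (is.na(cdsStartT)) {
      warning(sprintf("transcript %s: CDS start not inside an exon; skipped", tx))
      nSkipped <- nSkipped + 1L
      next
    }
    cdsEndT <- cdsStartT + cdsWidth
    if (cdsWidth %% 3L != 0L) {
      if (enforceCdsFrame) {
        warning(sprintf("transcript %s: CDS length %d not divisible by 3; dropped (strict mode)",
                        tx, cdsWidth))
        nSkipped <- nSkipped + 1L
        next
      }
      warning(sprintf("transcript %s: CDS length %d not divisible by 3; kept",
                      tx, cdsWidth))
    }
    out[[tx]] <- transcriptModel(tx, gid[which(sel)[1]], chrom, strand, ex,
                                 cdsStartT, cdsEndT, level, txType)
  }
  .msg(verbose, "readGtf: %d coding transcript model(s), %d skipped",
       length(out), nSkipped)
  unname(out)
}

#' Reduce gene models to one longest high-confidence transcript per gene
#'
#' Keeps, per gene, only protein-coding transcripts whose Gencode confidence
#' level lies in `acceptedLevels` (default 1 = validated, 2 = manually
#' annotated) and then selects the one with the greatest mature length (sum
#' of exon lengths). Ties are broken by the lexicographically smallest
#' transcript id so results are deterministic. Genes without any qualifying
#' transcript are dropped (their number is recorded in the provenance).
#'
#' @param txs list of [TranscriptModel-class] objects.
#' @param acceptedLevels accepted confidence levels.
#' @param source free-text provenance label (e.g. the GTF path).
#'
#' @return a [ReducedAnnotation-class].
#' @export
reduceAnnotation <- function(txs, acceptedLevels = c(1L, 2L),
                             source = NA_character_) {
  if (!length(txs))
    .dataError("reduceAnnotation: empty transcript list")
  ok <- vapply(txs, function(t)
    t@txType == "protein_coding" && t@level %in% acceptedLevels, logical(1))
  allGenes <- unique(vapply(txs, geneId, character(1)))
  txs <- txs[ok]
  kept <- list()
  if (length(txs)) {
    gids <- vapply(txs, geneId, character(1))
    for (g in unique(gids)) {
      cand <- txs[gids == g]
      len <- vapply(cand, matureLength, integer(1))
      ids <- vapply(cand, txId, character(1))
      best <- order(-len, ids)[1]
      kept[[g]] <- cand[[best]]
    }
  }
  nDropped <- length(allGenes) - length(kept)
  if (nDropped > 0L)
    message(sprintf("reduceAnnotation: %d gene(s) had no qualifying transcript",
                    nDropped))
  new("ReducedAnnotation", transcripts = kept,
      provenance = list(source = source, accepted_levels = acceptedLevels,
                        n_genes_in = length(allGenes),
                        n_genes_kept = length(kept),
                        n_genes_dropped = nDropped))
}

#' Write the reduced annotation back out as GTF
#'
#' Subsets the original GTF to the records of the kept transcripts,
#' preserving their attributes, and adds a `longest_protein_coding` tag so
#' downstream tools can recognize the reduction.
#'
#' @param reduced a [ReducedAnnotation-class].
#' @param gtfPath the original GTF the reduction was computed from.
#' @param outPath output GTF path.
#'
#' @return `outPath`, invisibly.
#' @export
writeReducedGtf <- function(reduced, gtfPath, outPath) {
  gr <- rtracklayer::import(gtfPath, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keepTx <- vapply(transcripts(reduced), txId, character(1))
  keepGenes <- names(transcripts(reduced))
  sel <- (!is.na(md$transcript_id) & md$transcript_id %in% keepTx) |
    (as.character(md$type) == "gene" & md$gene_id %in% keepGenes)
  out <- gr[sel]
  S4Vectors::mcols(out)$longest_protein_coding <- "true"
  rtracklayer::export(out, outPath, format = "gtf")
  invisible(outPath)
}
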