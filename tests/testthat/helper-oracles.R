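# Independent oracles and fixture builders used across the suite.
# The oracles deliberately use naive per-base / per-position walks so they
# share no code path with the package implementation.

# genome position (1-based) of every transcript base in [tStart, tEnd),
# walking exon by exon, base by base
walkTxToGenome <- function(tm, tStart, tEnd) {
  ex <- tm@exons
  n <- length(ex)
  order5to3 <- if (tm@strand == "+") seq_len(n) else rev(seq_len(n))
  gpos <- integer(0)
  for (i in order5to3) {
    s <- IRanges::start(ex)[i]
    e <- IRanges::end(ex)[i]
    gpos <- c(gpos, if (tm@strand == "+") s:e else e:s)
  }
  gpos[(tStart + 1L):tEnd]
}

# collapse a per-base genome walk into blocks (transcript order): split
# wherever consecutive positions do not step by +/-1 in strand direction
walkToBlocks <- function(gpos) {
  step <- if (length(gpos) > 1L && gpos[2] < gpos[1]) -1L else 1L
  cuts <- which(diff(gpos) != step)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, length(gpos))
  cbind(lo = pmin(gpos[starts], gpos[ends]),
        hi = pmax(gpos[starts], gpos[ends]))
}

# exhaustive ORF scan: test every position as a start, walk codons to the
# first stop
oracleScanUorfs <- function(seq, startCodons = "ATG", minLen = 9L,
                            maxLen = 400L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- NULL
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(max(0L, n - 2L))) {
    if (!substr(seq, i, i + 2L) %in% startCodons) next
    j <- i + 3L
    while (j + 2L <= n) {
      if (substr(seq, j, j + 2L) %in% stops) {
        len <- j + 3L - i
        if (len >= minLen && len <= maxLen)
          out <- rbind(out, data.frame(t_start = i - 1L, t_end = j + 2L,
                                       start_codon = substr(seq, i, i + 2L),
                                       stringsAsFactors = FALSE))
        break
      }
      j <- j + 3L
    }
  }
  if (is.null(out))
    return(data.frame(t_start = integer(), t_end = integer(),
                      start_codon = character(), stringsAsFactors = FALSE))
  out <- out[order(out$t_start, out$t_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# random multi-exon transcript model on a virtual chromosome
randomTm <- function(id = "tx", nExons = sample(1:4, 1),
                     strand = sample(c("+", "-"), 1)) {
  w <- sample(20:120, nExons, replace = TRUE)
  gaps <- sample(10:80, nExons, replace = TRUE)
  starts <- cumsum(gaps + c(0L, w[-nExons]))
  ml <- sum(w)
  cdsStart <- sample.int(ml - 2L, 1L) - 1L
  transcriptModel(id, paste0("g_", id), "chrT", strand,
                  IRanges::IRanges(starts, width = w),
                  cdsStart, ml, level = 1L)
}

# minimal GTF writer for annotation tests (1-based closed coordinates)
writeTestGtf <- function(path, rows) {
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_type "%s"; level %s;',
                     r$gene, r$tx, r$type2, r$level)
    sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
            r$chrom, r$feature, r$start, r$end, r$strand, attrs)
  }, character(1))
  writeLines(lines, path)
  path
}

gtfRow <- function(chrom, feature, start, end, strand, gene, tx,
                   type2 = "protein_coding", level = 1) {
  data.frame(chrom = chrom, feature = feature, start = start, end = end,
             strand = strand, gene = gene, tx = tx, type2 = type2,
             level = level, stringsAsFactors = FALSE)
}

# minimal single-chromosome SAM writer for counting tests
writeTestSam <- function(path, reads, chromLen = 10000L, chrom = "chrT") {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, chromLen))
  lines <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
            r$qname, if (r$strand == "+") 0L else 16L, chrom, r$pos,
            r$cigar)
  }, character(1))
  writeLines(c(hdr, lines), path)
  path
}

samRead <- function(qname, pos, cigar, strand = "+") {
  data.frame(qname = qname, pos = pos, cigar = cigar, strand = strand,
             stringsAsFactors = FALSE)
}

randomUorfTable <- function(n) {
  tab <- lapply(seq_len(n), function(i) {
    len <- 3L * sample(3:20, 1L)
    t0 <- sample(0:200, 1L)
    strand <- sample(c("+", "-"), 1L)
    gstart <- sample(1000:2000, 1L)
    data.frame(
      uorf_id = sprintf("TX%03d.1.u1", i),
      transcript_id = sprintf("TX%03d.1", i),
      gene_id = sprintf("G%03d", i), chrom = "chrT", strand = strand,
      genome_blocks = sprintf("%d-%d", gstart, gstart + len),
      t_start = t0, t_end = t0 + len, length_nt = len,
      peptide_len_aa = len %/% 3L - 1L, start_codon = "ATG",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, tab)
}
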