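test_that("GTF records convert from 1-based closed to transcript coordinates", {
  gtf <- writeTestGtf(tempfile(fileext = ".gtf"), rbind(
    gtfRow("chr1", "exon", 1001, 2000, "+", "g1", "t1"),
    gtfRow("chr1", "CDS", 1101, 1900, "+", "g1", "t1")))
  txs <- suppressWarnings(readGtf(gtf))   # CDS width 800 is out of frame
  expect_length(txs, 1)
  tm <- txs[[1]]
  expect_equal(IRanges::start(tm@exons), 1001L)
  expect_equal(IRanges::end(tm@exons), 2000L)
  expect_equal(tm@cdsStartT, 100L)
  expect_equal(tm@cdsEndT, 900L)
  expect_warning(readGtf(gtf), "not divisible by 3")
  expect_length(readGtf(gtf, enforceCdsFrame = TRUE) |> suppressWarnings(), 0)
})

test_that("minus-strand transcript coordinates run 5'->3' along the minus strand", {
  # exons at [101,150] and [201,260] (1-based); transcript 5' end is the
  # genomic base 260; CDS occupies genomic 101..130 -> transcript 80..110
  gtf <- writeTestGtf(tempfile(fileext = ".gtf"), rbind(
    gtfRow("chr1", "exon", 201, 260, "-", "g1", "t1"),
    gtfRow("chr1", "exon", 101, 150, "-", "g1", "t1"),
    gtfRow("chr1", "CDS", 101, 130, "-", "g1", "t1")))
  tm <- readGtf(gtf)[[1]]
  expect_equal(IRanges::start(tm@exons), c(101L, 201L))  # genomic order
  # independent per-base walk: transcript offset of genomic position 130
  walk <- walkTxToGenome(tm, 0L, matureLength(tm))
  expect_equal(which(walk == 130L) - 1L, tm@cdsStartT)
  expect_equal(tm@cdsStartT, 80L)
  expect_equal(tm@cdsEndT, 110L)
})

test_that("transcripts without CDS are excluded and CDS-without-exon skipped", {
  gtf <- writeTestGtf(tempfile(fileext = ".gtf"), rbind(
    gtfRow("chr1", "exon", 1, 300, "+", "g1", "t1"),
    gtfRow("chr1", "CDS", 101, 250, "+", "g1", "t1"),
    gtfRow("chr1", "exon", 400, 700, "+", "g2", "t2"),       # no CDS
    gtfRow("chr1", "CDS", 801, 900, "+", "g3", "t3")))       # no exon
  expect_warning(txs <- readGtf(gtf), "no exon records")
  expect_equal(vapply(txs, txId, character(1)), "t1")
})

test_that("malformed GTF records are reported with their line number", {
  path <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttest\texon\t1\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "chr1\ttest\texon\t1\t300\t+"), path)
  expect_error(readGtf(path), "line 2")
})

test_that("annotation reduction keeps the longest qualifying transcript per gene", {
  mk <- function(id, gene, len, level = 1L, type = "protein_coding")
    transcriptModel(id, gene, "chr1", "+", IRanges::IRanges(1, len),
                    0L, len, level = level, txType = type)
  txs <- list(mk("tA1", "gA", 1200), mk("tA2", "gA", 800),
              mk("tB1", "gB", 500, level = 3L),
              mk("tC2", "gC", 400), mk("tC1", "gC", 400),
              mk("tD1", "gD", 600, type = "lncRNA"))
  red <- suppressMessages(reduceAnnotation(txs))
  expect_equal(txId(red[["gA"]]), "tA1")          # longest wins
  expect_false("gB" %in% names(transcripts(red))) # level 3 dropped
  expect_equal(txId(red[["gC"]]), "tC1")          # tie: smallest id
  expect_false("gD" %in% names(transcripts(red))) # wrong biotype
  expect_equal(provenance(red)$n_genes_dropped, 2L)
  # size bound and idempotence
  expect_lte(length(red), length(unique(vapply(txs, geneId, character(1)))))
  red2 <- suppressMessages(reduceAnnotation(transcripts(red)))
  expect_identical(lapply(transcripts(red2), txId),
                   lapply(transcripts(red), txId))
  # every kept transcript at least as long as any discarded qualifying sibling
  expect_gte(matureLength(red[["gA"]]), 800L)
})

test_that("transcript spans map to genome blocks matching a per-base walk", {
  tm1 <- transcriptModel("t", "g", "c", "+", IRanges::IRanges(1001, 2000),
                         0L, 1000L)
  gr <- transcriptToGenome(tm1, 10L, 20L)
  expect_equal(GenomicRanges::start(gr), 1011L)   # 0-based [1010,1020)
  expect_equal(GenomicRanges::end(gr), 1020L)

  tm2 <- transcriptModel("t", "g", "c", "+",
                         IRanges::IRanges(c(1, 101), c(50, 150)), 0L, 100L)
  gr2 <- transcriptToGenome(tm2, 40L, 60L)        # 0-based blocks [40,50)+[100,110)
  expect_equal(GenomicRanges::start(gr2), c(41L, 101L))
  expect_equal(GenomicRanges::end(gr2), c(50L, 110L))

  tm3 <- transcriptModel("t", "g", "c", "-", IRanges::IRanges(1001, 2000),
                         0L, 1000L)
  gr3 <- transcriptToGenome(tm3, 0L, 10L)         # 0-based [1990,2000)
  expect_equal(GenomicRanges::start(gr3), 1991L)
  expect_equal(GenomicRanges::end(gr3), 2000L)

  expect_error(transcriptToGenome(tm1, 10L, 1001L), "outside mature length")
})

test_that("random spans round-trip through the per-base walk oracle", {
  set.seed(42)
  for (rep in 1:60) {
    tm <- randomTm(paste0("t", rep))
    ml <- matureLength(tm)
    s <- sample.int(ml, 1L) - 1L
    e <- s + sample.int(ml - s, 1L)
    gr <- transcriptToGenome(tm, s, e)
    expect_equal(sum(GenomicRanges::width(gr)), e - s)
    oracle <- walkToBlocks(walkTxToGenome(tm, s, e))
    expect_equal(GenomicRanges::start(gr), unname(oracle[, "lo"]))
    expect_equal(GenomicRanges::end(gr), unname(oracle[, "hi"]))
  }
})

test_that("leader extraction reads 5'->3' on both strands", {
  genome <- Biostrings::DNAStringSet(c(chrT = paste(
    rep(c("A", "C", "G", "T"), 50), collapse = "")))
  tmPlus <- transcriptModel("t", "g", "chrT", "+",
                            IRanges::IRanges(1, 120), 50L, 110L)
  expect_equal(as.character(extractTls(tmPlus, genome)),
               substr(as.character(genome[[1]]), 1, 50))
  # no leader -> empty sequence
  tm0 <- transcriptModel("t", "g", "chrT", "+", IRanges::IRanges(1, 120),
                         0L, 110L)
  expect_equal(length(extractTls(tm0, genome)), 0L)
  # minus strand: matches an independent reverse-complement per-base walk
  set.seed(7)
  tmMinus <- transcriptModel("t", "g", "chrT", "-",
                             IRanges::IRanges(c(11, 61), c(40, 100)),
                             30L, 60L)
  walk <- walkTxToGenome(tmMinus, 0L, 30L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expected <- paste(comp[strsplit(as.character(genome[[1]]), "")[[1]][walk]],
                    collapse = "")
  expect_equal(as.character(extractTls(tmMinus, genome)), expected)
})

test_that("reduced annotation exports GTF with the reduction tag", {
  gtf <- writeTestGtf(tempfile(fileext = ".gtf"), rbind(
    gtfRow("chr1", "exon", 1, 300, "+", "g1", "t1"),
    gtfRow("chr1", "CDS", 101, 250, "+", "g1", "t1"),
    gtfRow("chr1", "exon", 1, 200, "+", "g1", "t1b"),
    gtfRow("chr1", "CDS", 101, 190, "+", "g1", "t1b")))
  red <- suppressWarnings(reduceAnnotation(readGtf(gtf), source = gtf))
  out <- tempfile(fileext = ".gtf")
  suppressWarnings(writeReducedGtf(red, gtf, out))  # test GTF carries no phase
  reparsed <- rtracklayer::import(out, format = "gtf")
  expect_true(all(reparsed$transcript_id == "t1", na.rm = TRUE))
  expect_true(all(reparsed$longest_protein_coding == "true"))
})
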