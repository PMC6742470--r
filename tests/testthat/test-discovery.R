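test_that("leader scan finds maximal start-to-first-stop spans", {
  hits <- scanUorfs("AAATGTTTTAACC")
  expect_equal(hits$t_start, 2L)
  expect_equal(hits$t_end, 11L)
  expect_equal(hits$start_codon, "ATG")

  # ATG without an in-frame stop inside the sequence: no hit
  expect_equal(nrow(scanUorfs("AAATGTTTTTTT")), 0L)
  # the first in-frame stop terminates the uORF
  one <- scanUorfs("ATGAAATAAAAATAA")
  expect_equal(one$t_end, 9L)
  # codons containing N never match start or stop
  expect_equal(nrow(scanUorfs("AANGTTTTAACC")), 0L)
  expect_equal(nrow(scanUorfs("AAATGTTTTNACC")), 0L)
})

test_that("span length limits are enforced including the stop codon", {
  long <- paste0("ATG", strrep("TTT", 132), "TAA")   # 402 nt
  expect_equal(nrow(scanUorfs(long)), 0L)
  expect_equal(nrow(scanUorfs(long, uorfScanParam(maxLen = 402L))), 1L)
  # 9 nt is the smallest admissible span; 6 nt (start+stop) is rejected
  expect_equal(nrow(scanUorfs("ATGTAA")), 0L)
  expect_equal(scanUorfs("ATGTTTTAA")$t_end, 9L)
})

test_that("scan equals the exhaustive brute-force oracle on random leaders", {
  set.seed(101)
  for (i in 1:300) {
    len <- sample(0:600, 1L)
    s <- if (len) randomDna(len) else ""
    got <- scanUorfs(s)
    want <- oracleScanUorfs(s)
    rownames(got) <- NULL
    expect_identical(got, want)
  }
})

test_that("scan is monotone in its configuration", {
  set.seed(202)
  for (i in 1:40) {
    s <- randomDna(400)
    base <- scanUorfs(s, uorfScanParam(maxLen = 200L))
    wide <- scanUorfs(s, uorfScanParam(maxLen = 400L))
    # enlarging maxLen never removes a hit
    expect_true(all(interaction(base$t_start, base$t_end) %in%
                      interaction(wide$t_start, wide$t_end)))
    # shrinking the start-codon set never adds a hit
    multi <- scanUorfs(s, uorfScanParam(startCodons = c("ATG", "CTG")))
    expect_true(all(interaction(wide$t_start, wide$t_end) %in%
                      interaction(multi$t_start, multi$t_end)))
  }
})

test_that("peptide length excludes the stop codon and keeps the initiator", {
  expect_equal(peptideLength(81), 26L)
  expect_equal(peptideLength(69), 22L)
  expect_equal(peptideLength(9), 2L)
  expect_error(peptideLength(10), "multiple of 3")
  expect_error(peptideLength(3), "multiple of 3")
})

test_that("annotation building assigns ordinal ids and exact genome blocks", {
  spec <- syntheticSpec(nGenes = 8, nPlantedEffects = 0L,
                        exonsPerGene = c(2L, 3L), seed = 31L)
  world <- makeWorld(spec, tempfile("disc_world_"))
  red <- suppressMessages(reduceAnnotation(readGtf(world$gtf)))
  uorfs <- buildUorfAnnotation(red, world$genome)
  tab <- as.data.frame(uorfs)
  expect_setequal(tab$uorf_id, world$truth$uorf_id)
  m <- merge(tab, world$truth, by = "uorf_id")
  expect_equal(m$t_start.x, m$t_start.y)
  expect_equal(m$t_end.x, m$t_end.y)
  # ordinals follow ascending transcript start within each transcript
  for (tx in unique(tab$transcript_id)) {
    sub <- tab[tab$transcript_id == tx, ]
    ord <- order(sub$t_start)
    expect_equal(sub$uorf_id[ord],
                 sprintf("%s.u%d", tx, seq_len(nrow(sub))))
  }
  # genome blocks re-extracted from the genome start with ATG, end with stop
  for (i in seq_len(nrow(tab))) {
    tm <- red[[tab$gene_id[i]]]
    seq <- as.character(transcriptSeq(tm, world$genome, tab$t_start[i],
                                      tab$t_end[i]))
    expect_equal(substr(seq, 1, 3), tab$start_codon[i])
    expect_true(substr(seq, nchar(seq) - 2, nchar(seq)) %in%
                  c("TAA", "TAG", "TGA"))
    expect_equal(tab$length_nt[i],
                 sum(GenomicRanges::width(uorfFeatures(uorfs[i])[[1]])))
  }
  # at least one planted uORF straddles an exon junction in this world
  nBlocks <- lengths(uorfFeatures(uorfs))
  expect_gte(max(nBlocks), 2L)
})

test_that("empty leaders and genome mismatches are handled", {
  tm <- transcriptModel("t1", "g1", "chrT", "+", IRanges::IRanges(1, 300),
                        0L, 300L)
  red <- new("ReducedAnnotation", transcripts = stats::setNames(list(tm), "g1"),
             provenance = list())
  genome <- Biostrings::DNAStringSet(c(chrT = randomDna(300)))
  expect_length(buildUorfAnnotation(red, genome), 0L)
  genomeWrong <- Biostrings::DNAStringSet(c(other = randomDna(300)))
  expect_error(buildUorfAnnotation(red, genomeWrong), "missing sequence")
})

test_that("read-evidence filter thresholds summed raw counts", {
  tab <- randomUorfTable(3)
  uorfs <- new("UorfAnnotation", table = tab)
  m <- matrix(c(0L, 0L,  2L, 1L,  1L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(tab$uorf_id, c("s1", "s2")))
  expect_equal(as.data.frame(filterByEvidence(uorfs, m, 2))$uorf_id,
               tab$uorf_id[2])
  expect_equal(length(filterByEvidence(uorfs, m, 1)), 2L)
  expect_equal(length(filterByEvidence(uorfs, m, 0)), 3L)   # identity
  # candidates missing from the table count as zero
  m2 <- m[1:2, , drop = FALSE]
  expect_length(suppressMessages(filterByEvidence(uorfs, m2, 1)), 1L)
})

test_that("uORF annotation CSV round-trips and rejects invalid rows", {
  set.seed(55)
  tab <- randomUorfTable(10)
  uorfs <- new("UorfAnnotation", table = tab)
  path <- tempfile(fileext = ".csv")
  writeUorfAnnotation(uorfs, path)
  expect_identical(as.data.frame(readUorfAnnotation(path)), tab)

  # a row whose length is not a multiple of 3 is rejected with a warning
  bad <- tab
  bad$length_nt[4] <- 10L
  bad$t_end[4] <- bad$t_start[4] + 10L
  utils::write.csv(bad, path, row.names = FALSE, quote = FALSE)
  expect_warning(res <- readUorfAnnotation(path), "rejected 1")
  expect_equal(length(res), 9L)

  dup <- rbind(tab, tab[1, ])
  utils::write.csv(dup, path, row.names = FALSE, quote = FALSE)
  expect_error(suppressWarnings(readUorfAnnotation(path)), "duplicate uorf_id")
})

test_that("BED12 export encodes spliced footprints as blocks", {
  tab <- randomUorfTable(1)
  tab$genome_blocks <- "100-130;200-215"
  tab$length_nt <- 45L; tab$t_end <- tab$t_start + 45L
  tab$peptide_len_aa <- 14L
  uorfs <- new("UorfAnnotation", table = tab)
  path <- tempfile(fileext = ".bed")
  writeUorfBed(uorfs, path)
  f <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(as.integer(f[c(2, 3, 10)]), c(100L, 215L, 2L))
  expect_equal(f[11], "30,15,")
  expect_equal(f[12], "0,100,")
  sizes <- as.integer(strsplit(f[11], ",")[[1]])
  expect_equal(sum(sizes), tab$length_nt)
})
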