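#' Describe a synthetic ribosome-profiling study
#'
#' Builds the parameter object for [makeWorld()] and [simulateRpfs()]. The
#' defaults describe the reference simulation used throughout the package's
#' tests: 200 uORF-bearing genes on two toy chromosomes (half of them on the
#' minus strand), four control and four treatment libraries, negative-
#' binomial library noise with dispersion 0.1, and ten genes carrying a
#' planted log2 shift of +/-2 in the main-ORF-to-uORF read allocation.
#' Planted uORF lengths are drawn from 9-75 nt (multiples of 3, mean about
#' 42 nt, matching the short uORFs seen in human annotations); the baseline
#' uORF read allocation of 0.15 emulates strongly translated uORFs, giving
#' baseline main-ORF-to-uORF ratios around 5-6.
#'
#' @param nGenes number of uORF-bearing genes (default 200).
#' @param exonsPerGene range of exon counts per transcript (default 1-3).
#' @param tlsLen range of transcript-leader lengths in nt (default 150-300).
#' @param plantedUorfsPerGene range of uORFs planted per gene (default 1-2).
#' @param strandMix fraction of minus-strand genes (default 0.5).
#' @param repsPerCondition named vector `c(control=, treatment=)`
#'   (default 4 and 4).
#' @param baseReadsPerFeature expected RPF total per transcript per library
#'   (default 500).
#' @param uorfAllocation baseline fraction of a transcript's reads falling in
#'   its uORFs (default 0.15).
#' @param nPlantedEffects number of genes with a planted ratio shift
#'   (default 10; half up, half down).
#' @param effectLog2 planted |log2| shift of the CDS:uORF allocation odds in
#'   treatment libraries (default 2).
#' @param nbDispersion negative-binomial dispersion of per-library transcript
#'   totals (default 0.1; 0 gives Poisson totals).
#' @param readLen range of simulated read lengths in nt (default 28-32).
#' @param seed integer seed; mandatory, fixed per world.
#'
#' @return a [SyntheticSpec-class].
#' @examples
#' syntheticSpec(nGenes = 5, seed = 7L)
#' @export
syntheticSpec <- function(nGenes = 200L, exonsPerGene = c(1L, 3L),
                          tlsLen = c(150L, 300L),
                          plantedUorfsPerGene = c(1L, 2L), strandMix = 0.5,
                          repsPerCondition = c(control = 4L, treatment = 4L),
                          baseReadsPerFeature = 500,
                          uorfAllocation = 0.15, nPlantedEffects = 10L,
                          effectLog2 = 2, nbDispersion = 0.1,
                          readLen = c(28L, 32L), seed = 1001L) {
  new("SyntheticSpec", nGenes = as.integer(nGenes),
      exonsPerGene = as.integer(exonsPerGene), tlsLen = as.integer(tlsLen),
      plantedUorfsPerGene = as.integer(plantedUorfsPerGene),
      strandMix = strandMix,
      repsPerCondition = stats::setNames(
        as.integer(repsPerCondition),
        names(repsPerCondition)),
      baseReadsPerFeature = baseReadsPerFeature,
      uorfAllocation = uorfAllocation,
      nPlantedEffects = as.integer(nPlantedEffects),
      effectLog2 = effectLog2, nbDispersion = nbDispersion,
      readLen = as.integer(readLen), seed = as.integer(seed))
}

.BASES <- c("A", "C", "G", "T")
# codons over {C,T} only: cannot form ATG or a stop codon in any frame,
# in any juxtaposition; used for planted uORF interiors
.CT_CODONS <- c("CCC", "CCT", "CTC", "CTT", "TCC", "TCT", "TTC", "TTT")
.NONSTOP_CODONS <- setdiff(
  apply(expand.grid(.BASES, .BASES, .BASES), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

.randSeq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                              collapse = "")

# remove every ATG whose start is not in `keepStarts` (0-based) by mutating
# one of its bases lying outside all planted spans to C
.scrubAtg <- function(chars, keepStarts, plantedSpans) {
  inPlanted <- rep(FALSE, length(chars))
  if (nrow(plantedSpans))
    for (i in seq_len(nrow(plantedSpans)))
      inPlanted[(plantedSpans$t_start[i] + 1L):plantedSpans$t_end[i]] <- TRUE
  repeat {
    hits <- which(chars[-c(length(chars) - 0:1)] == "A" &
                    chars[-c(1L, length(chars))] == "T" &
                    chars[-(1:2)] == "G")
    hits <- setdiff(hits - 1L, keepStarts)  # 0-based ATG starts
    if (!length(hits)) break
    for (h in hits) {
      cand <- (h + 1L):(h + 3L)             # 1-based positions of the codon
      cand <- cand[!inPlanted[cand]]
      chars[cand[1]] <- "C"
    }
  }
  chars
}

# one gene in transcript space: sequence, structure, planted uORFs
.makeGene <- function(spec, geneIdx) {
  nU <- if (spec@plantedUorfsPerGene[1] == spec@plantedUorfsPerGene[2])
    spec@plantedUorfsPerGene[1] else
      sample(spec@plantedUorfsPerGene[1]:spec@plantedUorfsPerGene[2], 1L)
  L <- sample(spec@tlsLen[1]:spec@tlsLen[2], 1L)
  # uORF spans must fit after a 15-nt cap margin with >=4-nt spacers
  budget <- L - 15L - 4L * nU
  if (budget < 9L * nU)
    .configError("infeasible SyntheticSpec: TLS of %d nt cannot hold %d uORF(s)",
                 L, nU)
  lens <- integer(0)
  if (nU > 0L) {
    maxAa <- pmin(25L, (budget %/% nU) %/% 3L - 2L)
    lens <- 3L * (sample(1:23, nU, replace = TRUE) %% pmax(1L, maxAa - 2L) +
                    3L)
    lens <- pmin(lens, 3L * (maxAa + 2L))
  }
  slack <- L - 15L - sum(lens)
  gaps <- if (nU > 0L) {
    cuts <- sort(sample.int(slack - 4L * nU + 1L, nU, replace = TRUE)) +
      4L * (seq_len(nU) - 1L)
    diff(c(0L, cuts))
  } else integer(0)
  tStarts <- integer(nU); tEnds <- integer(nU)
  cursor <- 15L
  uorfSeqs <- character(nU)
  for (i in seq_len(nU)) {
    cursor <- cursor + gaps[i]
    tStarts[i] <- cursor
    tEnds[i] <- cursor + lens[i]
    nCod <- lens[i] %/% 3L - 2L
    uorfSeqs[i] <- paste0("ATG",
                          paste(sample(.CT_CODONS, nCod, replace = TRUE),
                                collapse = ""), "TAA")
    cursor <- tEnds[i]
  }
  tls <- strsplit(.randSeq(L), "")[[1]]
  for (i in seq_len(nU))
    tls[(tStarts[i] + 1L):tEnds[i]] <- strsplit(uorfSeqs[i], "")[[1]]
  tls <- .scrubAtg(tls, keepStarts = tStarts,
                   plantedSpans = data.frame(t_start = tStarts,
                                             t_end = tEnds))
  nCodCds <- sample(100:200, 1L)
  cds <- paste0("ATG", paste(sample(.NONSTOP_CODONS, nCodCds,
                                    replace = TRUE), collapse = ""),
                sample(.STOP_CODONS, 1L))
  utr3 <- .randSeq(sample(50:100, 1L))
  txSeq <- paste0(paste(tls, collapse = ""), cds, utr3)
  list(tlsLen = L, cdsLen = nchar(cds), txSeq = txSeq,
       uorf = data.frame(t_start = tStarts, t_end = tEnds,
                         length_nt = lens,
                         start_codon = rep("ATG", nU)))
}

#' Generate a synthetic test world
#'
#' Creates a toy genome FASTA, a Gencode-style GTF and a ground-truth table
#' from a [SyntheticSpec-class]. Leader backgrounds are scrubbed of spurious
#' ATGs so the set of discoverable uORFs equals the planted set exactly.
#' Each gene carries, besides its main transcript (confidence level 1 or 2),
#' a shorter protein-coding decoy transcript (level 2) and, for every fifth
#' gene, a longer level-3 transcript, so annotation reduction is genuinely
#' exercised. Generation is fully deterministic in `spec@seed`: the same
#' spec produces byte-identical files.
#'
#' @param spec a [SyntheticSpec-class].
#' @param dir output directory (created if needed).
#'
#' @return (invisibly printable) list of class `UorfWorld`: `genomeFasta`,
#'   `gtf`, `truthCsv`, `manifest` (file paths), `genome`
#'   ([Biostrings::DNAStringSet]), `models` (main [TranscriptModel-class]
#'   per gene), `truth` (planted uORFs with expected `uorf_id`),
#'   `effects` (named per-gene log2 allocation shifts) and `spec`.
#' @export
makeWorld <- function(spec, dir = tempfile("uorf_world_")) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec@seed)
  chromNames <- c("chrS1", "chrS2")
  chromParts <- list(character(0), character(0))
  cursors <- c(0L, 0L)
  models <- list()
  gtfRows <- list()
  truthRows <- list()

  addGtf <- function(chrom, start, end, strand, type, gid, tid, level,
                     phase = NA_integer_) {
    data.frame(chrom = chrom, start = start, end = end, strand = strand,
               type = type, gene_id = gid, transcript_id = tid,
               level = level, phase = phase, stringsAsFactors = FALSE)
  }

  for (g in seq_len(spec@nGenes)) {
    gid <- sprintf("SYNG%04d", g)
    tid <- sprintf("SYNT%04d.1", g)
    gene <- .makeGene(spec, g)
    M <- nchar(gene$txSeq)
    k <- sample(spec@exonsPerGene[1]:spec@exonsPerGene[2], 1L)
    k <- min(k, M %/% 60L)
    tCuts <- if (k > 1L) sort(sample(seq(30L, M - 30L, by = 1L), k - 1L))
      else integer(0)
    tLens <- diff(c(0L, tCuts, M))               # exon lengths, 5'->3'
    introns <- if (k > 1L) sample(60:200, k - 1L, replace = TRUE)
      else integer(0)
    strand <- if (stats::runif(1) < spec@strandMix) "-" else "+"
    ci <- (g - 1L) %% 2L + 1L
    chrom <- chromNames[ci]
    gap <- sample(250:500, 1L)
    gStart <- cursors[ci] + gap + 1L             # 1-based genomic start
    # genomic-ascending exon lengths / intron lengths
    aLens <- if (strand == "+") tLens else rev(tLens)
    aIntrons <- if (strand == "+") introns else rev(introns)
    exStart <- integer(k); exEnd <- integer(k)
    pos <- gStart
    for (i in seq_len(k)) {
      exStart[i] <- pos
      exEnd[i] <- pos + aLens[i] - 1L
      pos <- exEnd[i] + 1L + if (i < k) aIntrons[i] else 0L
    }
    gEnd <- exEnd[k]
    # genomic sequence of the locus
    txPieces <- substring(gene$txSeq, cumsum(tLens) - tLens + 1L,
                          cumsum(tLens))
    aPieces <- if (strand == "+") txPieces else
      vapply(rev(txPieces), function(p)
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(p))),
        character(1))
    locus <- character(0)
    for (i in seq_len(k)) {
      locus <- c(locus, aPieces[i])
      if (i < k) locus <- c(locus, .randSeq(aIntrons[i]))
    }
    chromParts[[ci]] <- c(chromParts[[ci]], .randSeq(gap),
                          paste(locus, collapse = ""))
    cursors[ci] <- gEnd

    level <- sample(1:2, 1L)
    tm <- transcriptModel(tid, gid, chrom, strand,
                          IRanges::IRanges(exStart, exEnd),
                          gene$tlsLen, gene$tlsLen + gene$cdsLen,
                          level = level)
    models[[gid]] <- tm

    # GTF rows for the main transcript (CDS rows exclude the stop codon)
    cdsBlocks <- transcriptToGenome(tm, tm@cdsStartT, tm@cdsEndT - 3L)
    cdsW <- GenomicRanges::width(cdsBlocks)
    phases <- (3L - (cumsum(cdsW) - cdsW) %% 3L) %% 3L
    gtfRows[[length(gtfRows) + 1L]] <- rbind(
      addGtf(chrom, gStart, gEnd, strand, "gene", gid, NA, level),
      addGtf(chrom, gStart, gEnd, strand, "transcript", gid, tid, level),
      addGtf(chrom, exStart, exEnd, strand, "exon", gid, tid, level),
      addGtf(chrom, GenomicRanges::start(cdsBlocks),
             GenomicRanges::end(cdsBlocks), strand, "CDS", gid, tid, level,
             phases))

    # shorter protein-coding decoy (level 2): 5' exon trimmed
    tid2 <- sprintf("SYNT%04d.2", g)
    d <- min(40L, tLens[1] - 10L)
    if (d > 0L) {
      dStart <- exStart; dEnd <- exEnd
      if (strand == "+") dStart[1] <- dStart[1] + d else
        dEnd[k] <- dEnd[k] - d
      gtfRows[[length(gtfRows) + 1L]] <- rbind(
        addGtf(chrom, min(dStart), max(dEnd), strand, "transcript", gid,
               tid2, 2L),
        addGtf(chrom, dStart, dEnd, strand, "exon", gid, tid2, 2L),
        addGtf(chrom, GenomicRanges::start(cdsBlocks),
               GenomicRanges::end(cdsBlocks), strand, "CDS", gid, tid2, 2L,
               phases))
    }
    # longer low-confidence decoy (level 3) on every 5th gene
    if (g %% 5L == 0L) {
      tid3 <- sprintf("SYNT%04d.3", g)
      eStart <- exStart; eEnd <- exEnd
      if (strand == "+") eStart[1] <- eStart[1] - 20L else
        eEnd[k] <- eEnd[k] + 20L
      gtfRows[[length(gtfRows) + 1L]] <- rbind(
        addGtf(chrom, min(eStart), max(eEnd), strand, "transcript", gid,
               tid3, 3L),
        addGtf(chrom, eStart, eEnd, strand, "exon", gid, tid3, 3L),
        addGtf(chrom, GenomicRanges::start(cdsBlocks),
               GenomicRanges::end(cdsBlocks), strand, "CDS", gid, tid3, 3L,
               phases))
    }

    if (nrow(gene$uorf)) {
      ord <- order(gene$uorf$t_start)
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        gene_id = gid, transcript_id = tid,
        uorf_id = sprintf("%s.u%d", tid, seq_len(nrow(gene$uorf))),
        gene$uorf[ord, , drop = FALSE], stringsAsFactors = FALSE)
    }
  }

  # planted condition effects: half up, half down
  effects <- stats::setNames(rep(0, spec@nGenes), names(models))
  if (spec@nPlantedEffects > 0L) {
    chosen <- sample(names(models), spec@nPlantedEffects)
    nUp <- ceiling(spec@nPlantedEffects / 2)
    effects[chosen] <- c(rep(spec@effectLog2, nUp),
                         rep(-spec@effectLog2,
                             spec@nPlantedEffects - nUp))
  }

  genome <- Biostrings::DNAStringSet(vapply(chromParts, paste, character(1),
                                            collapse = ""))
  names(genome) <- chromNames
  genome <- genome[Biostrings::width(genome) > 0L]

  genomeFasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, genomeFasta, width = 70L)
  gtfPath <- file.path(dir, "annotation.gtf")
  .writeSyntheticGtf(do.call(rbind, gtfRows), gtfPath)
  truth <- if (length(truthRows)) do.call(rbind, truthRows) else
    data.frame(gene_id = character(), transcript_id = character(),
               uorf_id = character(), t_start = integer(),
               t_end = integer(), length_nt = integer(),
               start_codon = character())
  truth$effect_log2 <- effects[truth$gene_id]
  rownames(truth) <- NULL
  truthCsv <- file.path(dir, "truth.csv")
  utils::write.csv(truth, truthCsv, row.names = FALSE, quote = FALSE)
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(
    generator = "riboUORF makeWorld",
    seed = spec@seed,
    n_genes = spec@nGenes,
    files = list(genome = basename(genomeFasta), gtf = basename(gtfPath),
                 truth = basename(truthCsv)),
    md5 = as.list(tools::md5sum(c(genomeFasta, gtfPath, truthCsv)))),
    manifest)
  structure(list(genomeFasta = genomeFasta, gtf = gtfPath,
                 truthCsv = truthCsv, manifest = manifest, genome = genome,
                 models = models, truth = truth, effects = effects,
                 spec = spec, dir = dir),
            class = "UorfWorld")
}

#' @export
print.UorfWorld <- function(x, ...) {
  cat(sprintf("UorfWorld: %d gene(s), %d planted uORF(s), seed %d\n  dir: %s\n",
              length(x$models), nrow(x$truth), x$spec@seed, x$dir))
  invisible(x)
}

.writeSyntheticGtf <- function(rows, path) {
  attr9 <- function(i) {
    r <- rows[i, ]
    a <- sprintf('gene_id "%s"; gene_type "protein_coding";', r$gene_id)
    if (!is.na(r$transcript_id))
      a <- paste(a, sprintf('transcript_id "%s"; transcript_type "protein_coding";',
                            r$transcript_id))
    paste(a, sprintf('level %d;', r$level))
  }
  lines <- sprintf("%s\triboUORF_sim\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                   rows$chrom, rows$type, rows$start, rows$end, rows$strand,
                   ifelse(is.na(rows$phase), ".", as.character(rows$phase)),
                   vapply(seq_len(nrow(rows)), attr9, character(1)))
  writeLines(c("##description: synthetic annotation (riboUORF)", lines),
             path)
}

# exon structure arrays for fast read placement (no S4 in the hot path)
.exonStruct <- function(tm) {
  ord <- .txExonOrder(tm)
  w <- IRanges::width(tm@exons)[ord]
  list(offStart = cumsum(w) - w, w = w,
       gs = IRanges::start(tm@exons)[ord], ge = IRanges::end(tm@exons)[ord],
       plus = tm@strand == "+", chrom = tm@chrom, M = sum(w))
}

# alignment POS (1-based, leftmost) and CIGAR for a transcript span
.spanToAlignment <- function(es, tstart, tend) {
  i1 <- findInterval(tstart, es$offStart)
  i2 <- findInterval(tend - 1L, es$offStart)
  blocks <- lapply(i1:i2, function(i) {
    o1 <- max(tstart, es$offStart[i]) - es$offStart[i]
    o2 <- min(tend, es$offStart[i] + es$w[i]) - es$offStart[i]
    if (es$plus) c(es$gs[i] + o1, es$gs[i] + o2 - 1L)
    else c(es$ge[i] - o2 + 1L, es$ge[i] - o1)
  })
  m <- do.call(rbind, blocks)
  m <- m[order(m[, 1]), , drop = FALSE]          # genomic ascending
  widths <- m[, 2] - m[, 1] + 1L
  cig <- sprintf("%dM", widths[1])
  if (nrow(m) > 1L)
    for (i in 2:nrow(m))
      cig <- paste0(cig, sprintf("%dN%dM", m[i, 1] - m[i - 1L, 2] - 1L,
                                 widths[i]))
  list(pos = m[1, 1], cigar = cig)
}

# simulate reads for one feature of one transcript; returns SAM line fields
.featureReads <- function(es, fs, fe, n, readLens, offset, prefix) {
  if (n == 0L) return(NULL)
  lens <- sample(readLens, n, replace = TRUE)
  lo <- max(fs, offset)
  hi <- pmin(fe - 1L, es$M - lens + offset)
  ok <- hi >= lo
  lens <- lens[ok]; hi <- hi[ok]
  n <- length(lens)
  if (n == 0L) return(NULL)
  p <- lo + floor(stats::runif(n) * (hi - lo + 1L))
  tstart <- p - offset
  tend <- tstart + lens
  i1 <- findInterval(tstart, es$offStart)
  i2 <- findInterval(tend - 1L, es$offStart)
  pos <- integer(n); cigar <- character(n)
  simple <- i1 == i2
  if (any(simple)) {
    o1 <- tstart[simple] - es$offStart[i1[simple]]
    if (es$plus) pos[simple] <- es$gs[i1[simple]] + o1
    else pos[simple] <- es$ge[i1[simple]] - o1 - lens[simple] + 1L
    cigar[simple] <- sprintf("%dM", lens[simple])
  }
  for (i in which(!simple)) {
    al <- .spanToAlignment(es, tstart[i], tend[i])
    pos[i] <- al$pos
    cigar[i] <- al$cigar
  }
  flag <- if (es$plus) 0L else 16L
  sprintf("%s_%d\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
          prefix, seq_len(n), flag, es$chrom, pos, cigar)
}

#' Simulate RPF libraries for a synthetic world
#'
#' Draws, per library and transcript, a negative-binomial read total (mean
#' `baseReadsPerFeature`, dispersion `nbDispersion`) and allocates it
#' between the transcript's uORFs and its CDS. In treatment libraries the
#' CDS:uORF allocation odds of genes with a planted effect are multiplied by
#' `2^effect`. Read 5' ends are placed so the default P-site offset (12 nt)
#' lands uniformly inside the intended feature; reads crossing exon
#' junctions are written with `N` gaps. Output SAM files are converted to
#' sorted, indexed BAM.
#'
#' @param world a `UorfWorld` from [makeWorld()].
#' @param dir output directory (default: the world's directory).
#' @param psiteOffset offset used to position reads (default 12; keep equal
#'   to the counting offset).
#'
#' @return list: `bamPaths` (named by sample), `samPaths`, `design`
#'   (a [ConditionDesign-class]), `manifest`.
#' @export
simulateRpfs <- function(world, dir = world$dir, psiteOffset = 12L) {
  spec <- world$spec
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec@seed + 7L)
  reps <- spec@repsPerCondition
  sampleIds <- c(sprintf("ctrl_%d", seq_len(reps["control"])),
                 sprintf("tx_%d", seq_len(reps["treatment"])))
  condition <- c(rep("ctrl", reps["control"]),
                 rep("tx", reps["treatment"]))
  readLens <- spec@readLen[1]:spec@readLen[2]
  disp <- spec@nbDispersion
  truthByTx <- split(world$truth, world$truth$transcript_id)
  sq <- sprintf("@SQ\tSN:%s\tLN:%d", names(world$genome),
                Biostrings::width(world$genome))
  samPaths <- character(length(sampleIds))
  bamPaths <- character(length(sampleIds))
  for (j in seq_along(sampleIds)) {
    isTx <- condition[j] == "tx"
    lines <- vector("list", length(world$models))
    li <- 0L
    for (gid in names(world$models)) {
      tm <- world$models[[gid]]
      es <- .exonStruct(tm)
      N <- if (disp > 0)
        stats::rnbinom(1L, mu = spec@baseReadsPerFeature, size = 1 / disp)
      else stats::rpois(1L, spec@baseReadsPerFeature)
      if (N == 0L) { li <- li + 1L; next }
      u <- spec@uorfAllocation
      eff <- if (isTx) world$effects[[gid]] else 0
      uEff <- u / (u + 2^eff * (1 - u))
      tru <- truthByTx[[tm@txId]]
      nUorfs <- if (is.null(tru)) 0L else nrow(tru)
      nU <- if (nUorfs > 0L) stats::rbinom(1L, N, uEff) else 0L
      nCds <- N - nU
      prefix <- sprintf("%s_%s", sampleIds[j], gid)
      out <- list(.featureReads(es, tm@cdsStartT, tm@cdsEndT, nCds,
                                readLens, psiteOffset,
                                paste0(prefix, "_cds")))
      if (nU > 0L) {
        alloc <- stats::rmultinom(1L, nU, rep(1 / nUorfs, nUorfs))[, 1]
        for (q in seq_len(nUorfs)) {
          out[[q + 1L]] <- .featureReads(es, tru$t_start[q], tru$t_end[q],
                                         alloc[q], readLens, psiteOffset,
                                         sprintf("%s_u%d", prefix, q))
        }
      }
      li <- li + 1L
      lines[[li]] <- unlist(out)
    }
    samPaths[j] <- file.path(dir, sprintf("%s.sam", sampleIds[j]))
    writeLines(c("@HD\tVN:1.6\tSO:unknown", sq, unlist(lines)),
               samPaths[j])
    bamPaths[j] <- Rsamtools::asBam(samPaths[j],
                                    destination = file.path(
                                      dir, sampleIds[j]),
                                    overwrite = TRUE,
                                    indexDestination = TRUE)
  }
  names(bamPaths) <- sampleIds
  names(samPaths) <- sampleIds
  design <- conditionDesign(sampleIds, condition, control = "ctrl")
  manifest <- file.path(dir, "rpf_manifest.yaml")
  yaml::write_yaml(list(
    generator = "riboUORF simulateRpfs",
    seed = spec@seed,
    psite_offset = psiteOffset,
    samples = as.list(stats::setNames(condition, sampleIds)),
    bam = as.list(stats::setNames(basename(bamPaths), sampleIds))),
    manifest)
  list(bamPaths = bamPaths, samPaths = samPaths, design = design,
       manifest = manifest)
}
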