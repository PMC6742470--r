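#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay
NULL

#' TranscriptModel: one gene model with a transcript/genome coordinate map
#'
#' Holds the exon structure of a single transcript together with the span of
#' its coding sequence (CDS) in transcript coordinates. Exons are stored as an
#' [IRanges::IRanges] in genomic order (1-based, closed, the Bioconductor
#' convention); all transcript-space coordinates in this package are 0-based
#' half-open and run 5' to 3' along the transcript, so that on the minus
#' strand transcript position 0 corresponds to the highest genomic coordinate.
#'
#' @slot txId transcript identifier.
#' @slot geneId gene identifier.
#' @slot chrom chromosome / sequence name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons [IRanges::IRanges] of exon blocks, sorted, non-overlapping.
#' @slot cdsStartT,cdsEndT CDS span in transcript coordinates
#'   (0-based half-open). `cdsStartT` is the length of the transcript leader
#'   sequence (TLS, the 5'UTR).
#' @slot level annotation confidence level (Gencode `level` attribute;
#'   1 = validated, 2 = manually annotated). Missing levels are coded 3.
#' @slot txType transcript biotype, e.g. `"protein_coding"`.
#'
#' @aliases TranscriptModel-class
#' @export
setClass("TranscriptModel",
  representation(
    txId = "character",
    geneId = "character",
    chrom = "character",
    strand = "character",
    exons = "IRanges",
    cdsStartT = "integer",
    cdsEndT = "integer",
    level = "integer",
    txType = "character"
  )
)

setValidity("TranscriptModel", function(object) {
  msgs <- character()
  if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) == 0L) {
    msgs <- c(msgs, "transcript must have at least one exon")
  } else {
    if (is.unsorted(IRanges::start(ex), strictly = FALSE))
      msgs <- c(msgs, "exons must be sorted in genomic order")
    if (length(ex) > 1L &&
        any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
      msgs <- c(msgs, "exons must be non-overlapping")
    ml <- sum(IRanges::width(ex))
    if (!(object@cdsStartT >= 0L && object@cdsStartT < object@cdsEndT &&
          object@cdsEndT <= ml))
      msgs <- c(msgs, "CDS span must satisfy 0 <= cdsStartT < cdsEndT <= mature length")
  }
  if (length(msgs)) msgs else TRUE
})

#' ReducedAnnotation: one longest high-confidence transcript per gene
#'
#' The result of [reduceAnnotation()]: a mapping `gene_id ->`
#' [TranscriptModel], holding exactly one protein-coding transcript per gene,
#' plus provenance describing the source file and filter settings.
#'
#' @slot transcripts named list of [TranscriptModel] (names are gene ids).
#' @slot provenance list: source, accepted levels, counts of dropped genes.
#'
#' @aliases ReducedAnnotation-class
#' @export
setClass("ReducedAnnotation",
  representation(transcripts = "list", provenance = "list")
)

setValidity("ReducedAnnotation", function(object) {
  txs <- object@transcripts
  if (length(txs) == 0L) return(TRUE)
  if (is.null(names(txs)) || anyDuplicated(names(txs)))
    return("transcripts must be uniquely named by gene id")
  if (!all(vapply(txs, is, logical(1), class2 = "TranscriptModel")))
    return("all elements must be TranscriptModel objects")
  gids <- vapply(txs, function(t) t@geneId, character(1))
  if (!identical(unname(gids), names(txs)))
    return("list names must equal the gene ids of the models")
  TRUE
})

#' UorfScanParam: rules for uORF discovery in transcript leaders
#'
#' Parameters of the open-reading-frame scan over transcript leader sequences.
#' Lengths are in nucleotides and include the stop codon, so the smallest
#' admissible uORF (start codon + one codon + stop codon) is 9 nt.
#'
#' @slot startCodons candidate start codons (default `"ATG"` only; near-
#'   cognate starts such as CTG/GTG can be added for exploratory scans).
#' @slot minLen,maxLen admissible span length in nt, stop codon included
#'   (defaults 9 and 400).
#' @slot requireContained if `TRUE` (default) a uORF must end at or before
#'   the main-ORF start codon, i.e. lie fully within the leader.
#'
#' @aliases UorfScanParam-class
#' @export
setClass("UorfScanParam",
  representation(
    startCodons = "character",
    minLen = "integer",
    maxLen = "integer",
    requireContained = "logical"
  ),
  prototype(startCodons = "ATG", minLen = 9L, maxLen = 400L,
            requireContained = TRUE)
)

setValidity("UorfScanParam", function(object) {
  msgs <- character()
  if (!length(object@startCodons) ||
      !all(grepl("^[ACGT]{3}$", object@startCodons)))
    msgs <- c(msgs, "startCodons must be trinucleotides over A/C/G/T")
  if (object@minLen < 3L || object@minLen > object@maxLen)
    msgs <- c(msgs, "need 3 <= minLen <= maxLen")
  if (length(msgs)) msgs else TRUE
})

#' UorfAnnotation: a validated table of upstream open reading frames
#'
#' Wraps a data.frame with one row per uORF and a fixed column set (see
#' [writeUorfAnnotation()] for the on-disk layout). Transcript-space spans are
#' 0-based half-open and include the stop codon; `genome_blocks` serializes
#' the spliced genomic footprint as `start1-end1;start2-end2` (0-based
#' half-open, blocks 5'->3' along the transcript).
#'
#' @slot table data.frame with columns `uorf_id`, `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `genome_blocks`, `t_start`, `t_end`, `length_nt`,
#'   `peptide_len_aa`, `start_codon`.
#'
#' @aliases UorfAnnotation-class
#' @export
setClass("UorfAnnotation", representation(table = "data.frame"))

.UORF_COLUMNS <- c("uorf_id", "transcript_id", "gene_id", "chrom", "strand",
                   "genome_blocks", "t_start", "t_end", "length_nt",
                   "peptide_len_aa", "start_codon")

setValidity("UorfAnnotation", function(object) {
  tab <- object@table
  msgs <- character()
  if (!identical(colnames(tab), .UORF_COLUMNS))
    return(paste("table must have columns:", paste(.UORF_COLUMNS, collapse = ",")))
  if (nrow(tab) == 0L) return(TRUE)
  if (anyDuplicated(tab$uorf_id))
    msgs <- c(msgs, "duplicate uorf_id")
  if (any(tab$length_nt %% 3L != 0L))
    msgs <- c(msgs, "length_nt must be divisible by 3")
  if (any(tab$length_nt != tab$t_end - tab$t_start))
    msgs <- c(msgs, "length_nt must equal t_end - t_start")
  if (any(tab$peptide_len_aa != tab$length_nt %/% 3L - 1L))
    msgs <- c(msgs, "peptide_len_aa must equal length_nt/3 - 1")
  if (!all(tab$strand %in% c("+", "-")))
    msgs <- c(msgs, "strand must be '+' or '-'")
  if (length(msgs)) msgs else TRUE
})

#' RpfCounts: ribosome-protected-fragment counts per feature and sample
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] carrying
#' an integer `counts` assay (features x samples) and a tag saying whether
#' the features are main-ORF coding sequences or uORFs.
#'
#' @slot featureKind `"CDS"` or `"uORF"`.
#'
#' @aliases RpfCounts-class
#' @export
setClass("RpfCounts",
  contains = "SummarizedExperiment",
  representation(featureKind = "character")
)

setValidity("RpfCounts", function(object) {
  msgs <- character()
  if (length(object@featureKind) != 1L ||
      !object@featureKind %in% c("CDS", "uORF"))
    msgs <- c(msgs, "featureKind must be 'CDS' or 'uORF'")
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "must carry a 'counts' assay")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(m < 0) || any(m != round(m)))
      msgs <- c(msgs, "counts must be non-negative integers")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
      msgs <- c(msgs, "feature ids (rownames) must be present and unique")
  }
  if (length(msgs)) msgs else TRUE
})

#' ConditionDesign: two-condition sample layout
#'
#' Maps each counted sample to one of exactly two condition labels and
#' designates which label is the control. Ratio changes are reported as
#' treatment over control.
#'
#' @slot samples sample identifiers.
#' @slot condition condition label per sample.
#' @slot control the control condition label.
#' @slot treatment the treatment condition label.
#'
#' @aliases ConditionDesign-class
#' @export
setClass("ConditionDesign",
  representation(samples = "character", condition = "character",
                 control = "character", treatment = "character")
)

setValidity("ConditionDesign", function(object) {
  msgs <- character()
  if (length(object@samples) != length(object@condition))
    msgs <- c(msgs, "samples and condition must have equal length")
  if (anyDuplicated(object@samples))
    msgs <- c(msgs, "duplicate sample ids")
  lv <- unique(object@condition)
  if (length(lv) != 2L)
    msgs <- c(msgs, "exactly two conditions are required")
  if (!(object@control %in% lv))
    msgs <- c(msgs, "control label not among condition labels")
  if (length(lv) == 2L && !identical(object@treatment,
                                     setdiff(lv, object@control)))
    msgs <- c(msgs, "treatment label must be the non-control condition")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticSpec: full description of a simulated ribosome-profiling study
#'
#' Parameters of the synthetic test world: a toy genome, Gencode-style gene
#' models with planted uORFs, and simulated RPF libraries for a two-condition
#' design with condition-dependent shifts of the main-ORF-to-uORF read
#' allocation in selected genes. See [syntheticSpec()] for defaults and
#' units.
#'
#' @slot nGenes number of uORF-bearing genes.
#' @slot exonsPerGene integer range (min, max) of exons per transcript.
#' @slot tlsLen integer range of transcript-leader lengths (nt).
#' @slot plantedUorfsPerGene integer range of uORFs planted per gene.
#' @slot strandMix fraction of genes on the minus strand.
#' @slot repsPerCondition named integer vector `c(control=, treatment=)`.
#' @slot baseReadsPerFeature expected RPF count per transcript per library.
#' @slot uorfAllocation baseline fraction of a transcript's reads placed in
#'   its uORFs.
#' @slot nPlantedEffects number of genes receiving a ratio shift.
#' @slot effectLog2 magnitude of the planted log2 shift of the CDS:uORF
#'   allocation odds (applied +/- in equal numbers of genes).
#' @slot nbDispersion negative-binomial dispersion of per-library totals.
#' @slot readLen integer range of simulated read lengths (nt).
#' @slot seed integer seed; mandatory for any generation call.
#'
#' @aliases SyntheticSpec-class
#' @export
setClass("SyntheticSpec",
  representation(
    nGenes = "integer",
    exonsPerGene = "integer",
    tlsLen = "integer",
    plantedUorfsPerGene = "integer",
    strandMix = "numeric",
    repsPerCondition = "integer",
    baseReadsPerFeature = "numeric",
    uorfAllocation = "numeric",
    nPlantedEffects = "integer",
    effectLog2 = "numeric",
    nbDispersion = "numeric",
    readLen = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  rng <- function(x) length(x) == 2L && x[1] <= x[2] && x[1] >= 1L
  if (object@nGenes < 1L) msgs <- c(msgs, "nGenes must be >= 1")
  if (!rng(object@exonsPerGene)) msgs <- c(msgs, "exonsPerGene must be a valid range")
  if (!rng(object@tlsLen)) msgs <- c(msgs, "tlsLen must be a valid range")
  if (!(length(object@plantedUorfsPerGene) == 2L &&
        object@plantedUorfsPerGene[1] >= 0L &&
        object@plantedUorfsPerGene[1] <= object@plantedUorfsPerGene[2]))
    msgs <- c(msgs, "plantedUorfsPerGene must be a valid range")
  if (object@strandMix < 0 || object@strandMix > 1)
    msgs <- c(msgs, "strandMix must be in [0,1]")
  if (!identical(sort(names(object@repsPerCondition)),
                 c("control", "treatment")) ||
      any(object@repsPerCondition < 1L))
    msgs <- c(msgs, "repsPerCondition must be c(control=,treatment=) with >=1 each")
  if (object@uorfAllocation <= 0 || object@uorfAllocation >= 1)
    msgs <- c(msgs, "uorfAllocation must be in (0,1)")
  if (object@nPlantedEffects > object@nGenes)
    msgs <- c(msgs, "nPlantedEffects cannot exceed nGenes")
  if (object@nbDispersion < 0) msgs <- c(msgs, "nbDispersion must be >= 0")
  if (!rng(object@readLen)) msgs <- c(msgs, "readLen must be a valid range")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed is mandatory")
  if (length(msgs)) msgs else TRUE
})
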