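#' @importFrom BiocGenerics counts
NULL

#' @rdname TranscriptModel-class
#' @param object,x a package object.
#' @export
setGeneric("txId", function(x) standardGeneric("txId"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("matureLength", function(x) standardGeneric("matureLength"))

#' @rdname TranscriptModel-class
#' @export
setGeneric("tlsLength", function(x) standardGeneric("tlsLength"))

#' @rdname ReducedAnnotation-class
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))

#' @rdname ReducedAnnotation-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname RpfCounts-class
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))

setMethod("txId", "TranscriptModel", function(x) x@txId)
setMethod("geneId", "TranscriptModel", function(x) x@geneId)
setMethod("matureLength", "TranscriptModel",
          function(x) sum(IRanges::width(x@exons)))
setMethod("tlsLength", "TranscriptModel", function(x) x@cdsStartT)

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf(
    "TranscriptModel %s (gene %s) %s:%s, %d exon(s), mature %d nt, TLS %d nt, level %d\n",
    object@txId, object@geneId, object@chrom, object@strand,
    length(object@exons), matureLength(object), object@cdsStartT,
    object@level))
})

setMethod("transcripts", "ReducedAnnotation", function(x) x@transcripts)
setMethod("provenance", "ReducedAnnotation", function(x) x@provenance)

#' @rdname ReducedAnnotation-class
#' @export
setMethod("length", "ReducedAnnotation", function(x) length(x@transcripts))

#' @rdname ReducedAnnotation-class
#' @param i gene identifier or index.
#' @export
setMethod("[[", "ReducedAnnotation", function(x, i) x@transcripts[[i]])

setMethod("show", "ReducedAnnotation", function(object) {
  cat(sprintf("ReducedAnnotation with %d gene(s): one longest protein-coding transcript each\n",
              length(object)))
  pv <- object@provenance
  if (!is.null(pv$source))
    cat(sprintf("  source: %s\n", pv$source))
  if (!is.null(pv$accepted_levels))
    cat(sprintf("  accepted confidence levels: %s\n",
                paste(pv$accepted_levels, collapse = ",")))
  if (!is.null(pv$n_genes_dropped))
    cat(sprintf("  genes without qualifying transcript: %d\n",
                pv$n_genes_dropped))
})

setMethod("show", "UorfScanParam", function(object) {
  cat(sprintf("UorfScanParam: starts {%s}, span %d-%d nt (stop incl.), contained in TLS: %s\n",
              paste(object@startCodons, collapse = ","),
              object@minLen, object@maxLen, object@requireContained))
})

#' @rdname UorfAnnotation-class
#' @export
setMethod("length", "UorfAnnotation", function(x) nrow(x@table))

#' @rdname UorfAnnotation-class
#' @param row.names,optional,... passed on as in [base::as.data.frame].
#' @export
setMethod("as.data.frame", "UorfAnnotation",
          function(x, row.names = NULL, optional = FALSE, ...) {
            df <- x@table
            rownames(df) <- row.names
            df
          })

#' @rdname UorfAnnotation-class
#' @export
setMethod("[", "UorfAnnotation", function(x, i, j, ..., drop = TRUE) {
  initialize(x, table = x@table[i, , drop = FALSE])
})

setMethod("show", "UorfAnnotation", function(object) {
  tab <- object@table
  cat(sprintf("UorfAnnotation with %d uORF(s) on %d transcript(s)\n",
              nrow(tab), length(unique(tab$transcript_id))))
  if (nrow(tab))
    cat(sprintf("  length (nt, stop incl.): min %d, mean %.1f, max %d\n",
                min(tab$length_nt), mean(tab$length_nt), max(tab$length_nt)))
})

#' @rdname RpfCounts-class
#' @export
setMethod("featureKind", "RpfCounts", function(x) x@featureKind)

#' @rdname RpfCounts-class
#' @export
setMethod("counts", "RpfCounts",
          function(object) SummarizedExperiment::assay(object, "counts"))

setMethod("show", "ConditionDesign", function(object) {
  cat(sprintf("ConditionDesign: %d sample(s); control '%s' (n=%d) vs treatment '%s' (n=%d)\n",
              length(object@samples), object@control,
              sum(object@condition == object@control), object@treatment,
              sum(object@condition == object@treatment)))
})

#' @rdname ConditionDesign-class
#' @param x a `ConditionDesign`.
#' @export
setMethod("length", "ConditionDesign", function(x) length(x@samples))
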