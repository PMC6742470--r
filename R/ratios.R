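#' Construct a two-condition design
#'
#' @param samples sample ids (must match count-table columns).
#' @param condition condition label per sample (exactly two distinct labels).
#' @param control which label is the control; ratio changes are reported as
#'   treatment over control.
#'
#' @return a [ConditionDesign-class].
#' @examples
#' conditionDesign(paste0("s", 1:4), rep(c("ctrl", "tx"), each = 2), "ctrl")
#' @export
conditionDesign <- function(samples, condition, control) {
  lv <- unique(as.character(condition))
  new("ConditionDesign", samples = as.character(samples),
      condition = as.character(condition), control = as.character(control),
      treatment = setdiff(lv, as.character(control)))
}

#' Median-of-ratios size factors
#'
#' The standard library-size normalization for count data: per feature the
#' geometric mean across samples is taken as a pseudo-reference, and the size
#' factor of sample `j` is the median over features of `K_ij / g_i`,
#' restricted to features with strictly positive counts in every sample.
#' Identical libraries get size factor 1; scaling one library by `c` scales
#' its factor by `c` (up to the geometric-mean renormalization), which is
#' what makes downstream ratios scale invariant.
#'
#' @param counts an [RpfCounts-class] or a features x samples count matrix
#'   with at least two samples.
#'
#' @return named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
#' sizeFactorsMoR(m)   # ratio b/a = 2
#' @export
sizeFactorsMoR <- function(counts) {
  m <- if (is(counts, "RpfCounts")) counts(counts) else as.matrix(counts)
  if (ncol(m) < 2L)
    .dataError("size factors require at least two samples")
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    .dataError("no feature has nonzero counts in every sample; lower upstream filters or check library quality")
  mp <- m[pos, , drop = FALSE]
  g <- exp(rowMeans(log(mp)))
  sf <- apply(mp / g, 2L, stats::median)
  stats::setNames(as.numeric(sf), colnames(m))
}

#' Normalize a count table by size factors
#'
#' Divides each sample column by its size factor.
#'
#' @param counts [RpfCounts-class] or matrix.
#' @param sf named size-factor vector covering every sample.
#'
#' @return numeric matrix of normalized counts (same dimnames).
#' @export
normalizeCounts <- function(counts, sf) {
  m <- if (is(counts, "RpfCounts")) counts(counts) else as.matrix(counts)
  missing <- setdiff(colnames(m), names(sf))
  if (length(missing))
    .configError("no size factor for sample(s): %s",
                 paste(missing, collapse = ", "))
  sweep(m, 2L, sf[colnames(m)], "/")
}

#' Per-condition main-ORF-to-uORF ratios
#'
#' For each uORF, the relative translation of its main ORF in condition `c`
#' is `R_c = (mean normalized CDS count + pseudocount) /
#' (mean normalized uORF count + pseudocount)`, the means taken over the
#' replicates of `c`. The pseudocount keeps ratios defined for uORFs without
#' reads (which the comprehensive annotation deliberately retains); such
#' raw-zero uORFs are marked in `raw_uorf_zero` and later excluded from
#' quantile ranking. uORFs whose transcript has no CDS feature are skipped
#' with a message.
#'
#' @param cdsNorm normalized CDS matrix (rownames = transcript ids).
#' @param uorfNorm normalized uORF matrix (rownames = uORF ids).
#' @param uorfRaw raw uORF counts ([RpfCounts-class] or matrix), used only
#'   to mark all-zero uORFs.
#' @param uorfs a [UorfAnnotation-class] (or data.frame with `uorf_id`,
#'   `transcript_id`, `gene_id`) linking uORFs to their transcripts.
#' @param design a [ConditionDesign-class].
#' @param pseudocount added to both means (default 1).
#'
#' @return data.frame with one row per uORF: `uorf_id`, `transcript_id`,
#'   `gene_id`, `R_ctrl`, `R_tx`, `log2FC`, `raw_uorf_zero`, `flag`
#'   (initialized to `"none"`; see [flagQuantiles()]).
#' @export
conditionRatios <- function(cdsNorm, uorfNorm, uorfRaw, uorfs, design,
                            pseudocount = 1) {
  map <- if (is(uorfs, "UorfAnnotation")) as.data.frame(uorfs) else
    as.data.frame(uorfs)
  rawM <- if (is(uorfRaw, "RpfCounts")) counts(uorfRaw) else
    as.matrix(uorfRaw)
  if (pseudocount < 0) .configError("pseudocount must be >= 0")
  ctrlS <- design@samples[design@condition == design@control]
  txS <- design@samples[design@condition == design@treatment]
  for (s in c(ctrlS, txS)) {
    if (!s %in% colnames(cdsNorm) || !s %in% colnames(uorfNorm))
      .configError("sample '%s' missing from normalized tables", s)
  }
  keep <- map$uorf_id %in% rownames(uorfNorm)
  if (any(!keep))
    message(sprintf("conditionRatios: %d uORF(s) absent from the uORF count table; skipped",
                    sum(!keep)))
  map <- map[keep, , drop = FALSE]
  hasCds <- map$transcript_id %in% rownames(cdsNorm)
  if (any(!hasCds))
    message(sprintf("conditionRatios: %d uORF(s) whose transcript lacks a CDS feature; skipped",
                    sum(!hasCds)))
  map <- map[hasCds, , drop = FALSE]
  condMean <- function(m, rows, cols)
    rowMeans(m[rows, cols, drop = FALSE])
  cdsCtrl <- condMean(cdsNorm, map$transcript_id, ctrlS)
  cdsTx <- condMean(cdsNorm, map$transcript_id, txS)
  uCtrl <- condMean(uorfNorm, map$uorf_id, ctrlS)
  uTx <- condMean(uorfNorm, map$uorf_id, txS)
  rCtrl <- (cdsCtrl + pseudocount) / (uCtrl + pseudocount)
  rTx <- (cdsTx + pseudocount) / (uTx + pseudocount)
  rawZero <- rowSums(rawM[map$uorf_id, c(ctrlS, txS), drop = FALSE]) == 0
  data.frame(uorf_id = map$uorf_id, transcript_id = map$transcript_id,
             gene_id = map$gene_id,
             R_ctrl = unname(rCtrl), R_tx = unname(rTx),
             log2FC = log2FoldChange(unname(rTx), unname(rCtrl)),
             raw_uorf_zero = unname(rawZero),
             flag = "none", stringsAsFactors = FALSE)
}

#' Log2 fold change of the main-ORF-to-uORF ratio
#'
#' `log2(R_tx / R_ctrl)`: positive values indicate a treatment-induced shift
#' of ribosome occupancy towards the main ORF, i.e. relieved uORF
#' repression; negative values an inhibitory uORF becoming more active.
#'
#' @param rTx,rCtrl per-condition ratios, strictly positive.
#' @return numeric vector.
#' @examples
#' log2FoldChange(4, 2)    # 1
#' log2FoldChange(21.61, 5.51)
#' @export
log2FoldChange <- function(rTx, rCtrl) {
  if (any(rTx <= 0) || any(rCtrl <= 0))
    .dataError("ratios must be strictly positive")
  log2(rTx) - log2(rCtrl)
}

#' Flag the quantiles of strongest and least ratio changes
#'
#' Ranks records by absolute log2 fold change (two-sided, since both relief
#' and strengthening of uORF repression are of interest). The top
#' `round(q * N)` eligible records are flagged `strongest_change`, the
#' bottom `round(q * N)` `least_change` (round half up; with the default
#' `q = 0.05`, 939 eligible records give 47 and 1878 give 94). uORFs with
#' zero raw counts in every sample are not eligible and keep flag `"none"`.
#' Ties in `|log2FC|` are broken by `uorf_id` so the flag set is
#' deterministic.
#'
#' @param records data.frame from [conditionRatios()].
#' @param q quantile fraction, `0 < q < 0.5` (default 0.05).
#'
#' @return the records with the `flag` column filled in.
#' @export
flagQuantiles <- function(records, q = 0.05) {
  if (q <= 0 || q >= 0.5) .configError("q must satisfy 0 < q < 0.5")
  records$flag <- "none"
  elig <- which(!records$raw_uorf_zero & is.finite(records$log2FC))
  nE <- length(elig)
  if (nE == 0L) {
    warning("flagQuantiles: no eligible records")
    return(records)
  }
  k <- .roundHalfUp(q * nE)
  if (k < 1L) return(records)
  a <- abs(records$log2FC[elig])
  ids <- records$uorf_id[elig]
  byStrongest <- elig[order(-a, ids)]
  strongest <- byStrongest[seq_len(min(k, nE))]
  byLeast <- elig[order(a, ids)]
  byLeast <- setdiff(byLeast, strongest)
  least <- byLeast[seq_len(min(k, length(byLeast)))]
  records$flag[strongest] <- "strongest_change"
  records$flag[least] <- "least_change"
  records
}

#' Summarize a set of ratio records
#'
#' @param records flagged data.frame from [flagQuantiles()].
#' @return a list: counts of records with log2FC below 0, below -1, above 0,
#'   above 1; the means of the negative and of the positive log2FC; and the
#'   number of `strongest_change` records with negative log2FC.
#' @export
summarizeRegulation <- function(records) {
  if (!nrow(records)) .dataError("summarizeRegulation: no records")
  fc <- records$log2FC
  list(
    n_total = length(fc),
    n_negative = sum(fc < 0),
    n_below_minus1 = sum(fc < -1),
    n_positive = sum(fc > 0),
    n_above_1 = sum(fc > 1),
    mean_negative = if (any(fc < 0)) mean(fc[fc < 0]) else NA_real_,
    mean_positive = if (any(fc > 0)) mean(fc[fc > 0]) else NA_real_,
    n_strongest_negative = sum(records$flag == "strongest_change" & fc < 0)
  )
}

#' Write the analysis output files
#'
#' Writes the two normalized count tables, `ribo_norm_CDS_reads.csv` and
#' `ribo_norm_uORFs_reads.csv`, and the regulation table
#' `uORF_regulation.csv` (columns
#' `uorf_id,transcript_id,gene_id,R_ctrl,R_tx,log2FC,flag`) into `outdir`.
#'
#' @param records flagged data.frame from [flagQuantiles()] (may have zero
#'   rows; a header-only file is then written).
#' @param cdsNorm,uorfNorm normalized matrices.
#' @param outdir output directory (created if needed).
#' @return named vector of the three file paths, invisibly.
#' @export
writeRatioOutputs <- function(records, cdsNorm, uorfNorm, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) .configError("cannot create directory %s", outdir)
  paths <- c(
    cds = file.path(outdir, "ribo_norm_CDS_reads.csv"),
    uorf = file.path(outdir, "ribo_norm_uORFs_reads.csv"),
    regulation = file.path(outdir, "uORF_regulation.csv"))
  writeNorm <- function(m, path) {
    df <- data.frame(feature_id = rownames(m), round(m, 6),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  writeNorm(cdsNorm, paths["cds"])
  writeNorm(uorfNorm, paths["uorf"])
  reg <- records[, c("uorf_id", "transcript_id", "gene_id", "R_ctrl",
                     "R_tx", "log2FC", "flag"), drop = FALSE]
  utils::write.csv(reg, paths["regulation"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' End-to-end ratio analysis from raw count tables
#'
#' Convenience wrapper: size factors are computed from the CDS table
#' (main-ORF features are long and stable) and applied to both tables; the
#' per-condition ratios, log2 fold changes and quantile flags are then
#' computed in one call.
#'
#' @param cdsCounts,uorfCounts [RpfCounts-class] objects (or matrices).
#' @param uorfs a [UorfAnnotation-class] linking uORFs to transcripts.
#' @param design a [ConditionDesign-class].
#' @param q quantile fraction (default 0.05).
#' @param pseudocount ratio pseudocount (default 1).
#'
#' @return list with `records` (flagged data.frame), `summary`,
#'   `sizeFactors`, `cdsNorm`, `uorfNorm`.
#' @export
analyzeRatios <- function(cdsCounts, uorfCounts, uorfs, design, q = 0.05,
                          pseudocount = 1) {
  sf <- sizeFactorsMoR(cdsCounts)
  cdsNorm <- normalizeCounts(cdsCounts, sf)
  uorfNorm <- normalizeCounts(uorfCounts, sf)
  records <- conditionRatios(cdsNorm, uorfNorm, uorfCounts, uorfs, design,
                             pseudocount = pseudocount)
  records <- flagQuantiles(records, q = q)
  list(records = records,
       summary = if (nrow(records)) summarizeRegulation(records) else NULL,
       sizeFactors = sf, cdsNorm = cdsNorm, uorfNorm = uorfNorm)
}
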