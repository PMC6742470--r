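.CONFIG_KEYS <- list(
  top = c("genome", "gtf", "bams", "samples", "control", "uorf_annotation",
          "discover", "scan", "counting", "analysis", "outdir", "seed",
          "accepted_levels", "verbose"),
  scan = c("start_codons", "min_len_nt", "max_len_nt",
           "require_contained_in_tls"),
  counting = c("psite_offset_nt", "strandedness", "primary_only",
               "min_read_len", "max_read_len"),
  analysis = c("q", "pseudocount", "min_total_reads"))

#' Validate a YAML run configuration
#'
#' Reads and validates the YAML configuration of an end-to-end run, fills in
#' defaults, and aggregates every problem into a single error report.
#' Unknown keys are rejected. Exactly one of the two annotation modes must
#' be active: discovery (the default) or comprehensive mode (activated by
#' the `uorf_annotation` path; setting `discover: true` alongside it is an
#' error).
#'
#' Recognized keys: `genome`, `gtf` (paths), `bams` (map sample id -> BAM
#' path), `samples` (map sample id -> condition label), `control`
#' (the control condition label), `outdir`, optional `uorf_annotation`,
#' `discover`, `accepted_levels`, `seed`, `verbose`, and the nested blocks
#' `scan` (`start_codons`, `min_len_nt`, `max_len_nt`,
#' `require_contained_in_tls`), `counting` (`psite_offset_nt`,
#' `strandedness`, `primary_only`, `min_read_len`, `max_read_len`) and
#' `analysis` (`q`, `pseudocount`, `min_total_reads`).
#'
#' @param path YAML file path.
#'
#' @return a fully resolved configuration list (class `RunConfig`).
#' @export
validateConfig <- function(path) {
  if (!file.exists(path)) .configError("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  errs <- character()
  note <- function(fmt, ...) errs <<- c(errs, sprintf(fmt, ...))

  unknown <- setdiff(names(cfg), .CONFIG_KEYS$top)
  if (length(unknown)) note("unknown key(s): %s", paste(unknown, collapse = ", "))
  for (blk in c("scan", "counting", "analysis")) {
    if (!is.null(cfg[[blk]])) {
      u <- setdiff(names(cfg[[blk]]), .CONFIG_KEYS[[blk]])
      if (length(u)) note("unknown key(s) in %s: %s", blk,
                          paste(u, collapse = ", "))
    }
  }
  for (k in c("genome", "gtf", "bams", "samples", "control", "outdir")) {
    if (is.null(cfg[[k]])) note("missing required key: %s", k)
  }
  for (k in c("genome", "gtf")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      note("%s file not found: %s", k, cfg[[k]])
  }
  if (!is.null(cfg$bams)) {
    if (is.null(names(cfg$bams)))
      note("bams must be a map of sample id -> file path")
    else for (s in names(cfg$bams))
      if (!file.exists(cfg$bams[[s]]))
        note("bam for sample %s not found: %s", s, cfg$bams[[s]])
  }
  if (!is.null(cfg$samples) && !is.null(cfg$bams) &&
      !is.null(names(cfg$bams))) {
    if (!setequal(names(cfg$samples), names(cfg$bams)))
      note("sample ids in 'samples' and 'bams' differ")
    if (!is.null(cfg$control)) {
      lv <- unique(unlist(cfg$samples))
      if (length(lv) != 2L)
        note("exactly two conditions required, found: %s",
             paste(lv, collapse = ", "))
      else if (!cfg$control %in% lv)
        note("control '%s' is not a condition label", cfg$control)
    }
  }
  comprehensive <- !is.null(cfg$uorf_annotation)
  if (comprehensive && isTRUE(cfg$discover))
    note("both discovery and comprehensive-annotation modes requested; choose one")
  if (comprehensive && !file.exists(cfg$uorf_annotation))
    note("uorf_annotation file not found: %s", cfg$uorf_annotation)
  if (length(errs))
    .configError("invalid configuration:\n  - %s",
                 paste(errs, collapse = "\n  - "))

  scan <- cfg$scan
  counting <- cfg$counting
  analysis <- cfg$analysis
  resolved <- list(
    genome = cfg$genome, gtf = cfg$gtf,
    bams = unlist(cfg$bams), samples = unlist(cfg$samples),
    control = cfg$control, outdir = cfg$outdir,
    mode = if (comprehensive) "comprehensive" else "discover",
    uorf_annotation = cfg$uorf_annotation,
    accepted_levels = if (is.null(cfg$accepted_levels)) c(1L, 2L)
      else as.integer(cfg$accepted_levels),
    seed = if (is.null(cfg$seed)) NA_integer_ else as.integer(cfg$seed),
    verbose = isTRUE(cfg$verbose),
    scanParam = uorfScanParam(
      startCodons = if (is.null(scan$start_codons)) "ATG"
        else unlist(scan$start_codons),
      minLen = if (is.null(scan$min_len_nt)) 9L else scan$min_len_nt,
      maxLen = if (is.null(scan$max_len_nt)) 400L else scan$max_len_nt,
      requireContained = if (is.null(scan$require_contained_in_tls)) TRUE
        else scan$require_contained_in_tls),
    countParam = rpfCountParam(
      psiteOffset = if (is.null(counting$psite_offset_nt)) 12L
        else counting$psite_offset_nt,
      strandedness = if (is.null(counting$strandedness)) "forward"
        else counting$strandedness,
      primaryOnly = if (is.null(counting$primary_only)) TRUE
        else counting$primary_only,
      minReadLen = if (is.null(counting$min_read_len)) 25L
        else counting$min_read_len,
      maxReadLen = if (is.null(counting$max_read_len)) 35L
        else counting$max_read_len),
    q = if (is.null(analysis$q)) 0.05 else analysis$q,
    pseudocount = if (is.null(analysis$pseudocount)) 1
      else analysis$pseudocount,
    minTotalReads = if (is.null(analysis$min_total_reads)) 1L
      else as.integer(analysis$min_total_reads))
  structure(resolved, class = "RunConfig")
}

#' Run the full uORF analysis pipeline
#'
#' Executes annotation reduction, uORF discovery (or loading of a
#' pre-built comprehensive annotation), P-site counting of CDS and uORF
#' features, normalization, ratio analysis and quantile flagging, and writes
#' all output files plus a machine-readable run manifest (package version,
#' config hash, input checksums) into the configured output directory.
#' Inputs are validated before any counting starts.
#'
#' @param config a `RunConfig` from [validateConfig()] or a YAML path.
#'
#' @return (invisibly) a list with `records`, `summary`, `sizeFactors`,
#'   `uorfs`, `reduced`, and the output `paths`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- validateConfig(config)
  if (!inherits(config, "RunConfig"))
    .configError("config must be a RunConfig or a YAML path")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(outdir, "run.log")
  logCon <- file(logFile, "w")
  on.exit(close(logCon), add = TRUE)
  stage <- "setup"
  log <- function(fmt, ...) {
    line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"), stage,
                    sprintf(fmt, ...))
    writeLines(line, logCon)
    if (config$verbose) message(line)
  }
  runStage <- function(name, expr) {
    stage <<- name
    log("start")
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        log("FAILED: %s", conditionMessage(e))
        stop(errorCondition(
          sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          class = class(e)[class(e) != "simpleError"]))
      }),
      warning = function(w) log("warning: %s", conditionMessage(w)),
      message = function(m) log("%s", sub("\n$", "", conditionMessage(m))))
  }
  if (!is.na(config$seed)) set.seed(config$seed)

  genome <- runStage("load-genome", .asGenome(config$genome))
  reduced <- runStage("reduce-annotation", {
    txs <- readGtf(config$gtf)
    red <- reduceAnnotation(txs, acceptedLevels = config$accepted_levels,
                            source = config$gtf)
    writeReducedGtf(red, config$gtf,
                    file.path(outdir, "longest_protein_coding.gtf"))
    red
  })

  cds <- runStage("count-cds", {
    countFeatures(unname(config$bams), cdsFeatures(reduced), "CDS",
                  param = config$countParam,
                  sampleIds = names(config$bams))
  })

  uorfs <- if (config$mode == "comprehensive") {
    runStage("load-comprehensive-annotation", {
      log("discovery stage skipped: comprehensive annotation %s",
          config$uorf_annotation)
      readUorfAnnotation(config$uorf_annotation)
    })
  } else {
    runStage("discover-uorfs",
             buildUorfAnnotation(reduced, genome, config$scanParam))
  }

  uorfCounts <- runStage("count-uorfs", {
    countFeatures(unname(config$bams), uorfFeatures(uorfs), "uORF",
                  param = config$countParam,
                  sampleIds = names(config$bams))
  })
  if (config$mode == "discover") {
    uorfs <- runStage("evidence-filter", {
      kept <- filterByEvidence(uorfs, uorfCounts,
                               minTotalReads = config$minTotalReads)
      log("%d of %d candidate uORF(s) kept", length(kept), length(uorfs))
      kept
    })
    uorfCounts <- uorfCounts[as.data.frame(uorfs)$uorf_id, ]
  }

  res <- runStage("ratio-analysis", {
    design <- conditionDesign(names(config$samples),
                              unname(config$samples), config$control)
    analyzeRatios(cds, uorfCounts, uorfs, design, q = config$q,
                  pseudocount = config$pseudocount)
  })

  paths <- runStage("write-outputs", {
    p <- writeRatioOutputs(res$records, res$cdsNorm, res$uorfNorm, outdir)
    writeUorfAnnotation(uorfs, file.path(outdir, "uORF_annotation.csv"))
    writeUorfBed(uorfs, file.path(outdir, "uORFs.bed"))
    writeCountTable(cds, file.path(outdir, "ribo_raw_CDS_reads.csv"))
    writeCountTable(uorfCounts, file.path(outdir, "ribo_raw_uORFs_reads.csv"))
    inputs <- c(config$genome, config$gtf, unname(config$bams))
    yaml::write_yaml(list(
      tool = "riboUORF",
      version = as.character(utils::packageVersion("riboUORF")),
      mode = config$mode,
      seed = if (is.na(config$seed)) NULL else config$seed,
      n_genes = length(reduced),
      n_uorfs = length(uorfs),
      input_md5 = as.list(tools::md5sum(inputs))),
      file.path(outdir, "run_manifest.yaml"))
    p
  })
  stage <- "done"
  log("pipeline complete: %d uORF(s), %d record(s)", length(uorfs),
      nrow(res$records))
  invisible(list(records = res$records, summary = res$summary,
                 sizeFactors = res$sizeFactors, uorfs = uorfs,
                 reduced = reduced, paths = paths))
}
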