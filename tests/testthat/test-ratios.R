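# small helper: a ratio-record frame with the columns flagQuantiles expects
mkRecords <- function(log2FC, rawZero = rep(FALSE, length(log2FC))) {
  n <- length(log2FC)
  data.frame(uorf_id = sprintf("u%04d", seq_len(n)),
             transcript_id = sprintf("t%04d", seq_len(n)),
             gene_id = sprintf("g%04d", seq_len(n)),
             R_ctrl = 1, R_tx = 2^log2FC, log2FC = log2FC,
             raw_uorf_zero = rawZero, flag = "none",
             stringsAsFactors = FALSE)
}

test_that("median-of-ratios size factors match hand computation", {
  # identical libraries
  m <- cbind(s1 = c(5L, 9L, 30L), s2 = c(5L, 9L, 30L))
  expect_equal(sizeFactorsMoR(m), c(s1 = 1, s2 = 1))
  # sample B = 2 x sample A: factors 1/sqrt(2) and sqrt(2)
  a <- c(10L, 20L, 40L)
  m2 <- cbind(A = a, B = 2L * a)
  expect_equal(sizeFactorsMoR(m2), c(A = 1 / sqrt(2), B = sqrt(2)))
  # features with a zero anywhere are excluded from the median
  m3 <- rbind(m2, c(0L, 100L))
  expect_equal(sizeFactorsMoR(m3), sizeFactorsMoR(m2))
  expect_error(sizeFactorsMoR(rbind(c(0L, 1L), c(1L, 0L))),
               "no feature has nonzero counts")
  expect_error(sizeFactorsMoR(m2[, 1, drop = FALSE]), "two samples")
})

test_that("size factors agree with an independent implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(13)
  # odd number of all-positive features: plain median and exp(median(log))
  # coincide, so the two routes must agree exactly
  m <- matrix(rnbinom(35 * 6, mu = 100, size = 5) + 1L, ncol = 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  expect_equal(unname(sizeFactorsMoR(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
})

test_that("normalization divides by size factors and is scale invariant", {
  m <- cbind(s1 = c(10L, 4L), s2 = c(10L, 4L))
  expect_equal(normalizeCounts(m, c(s1 = 2, s2 = 1))[, "s1"], c(5, 2))
  expect_equal(normalizeCounts(m, c(s1 = 1, s2 = 1)), m + 0)
  set.seed(3)
  raw <- matrix(rnbinom(40, mu = 80, size = 5) + 1L, ncol = 4,
                dimnames = list(NULL, paste0("s", 1:4)))
  scaled <- raw
  scaled[, 2] <- scaled[, 2] * 7L
  n1 <- normalizeCounts(raw, sizeFactorsMoR(raw))
  n2 <- normalizeCounts(scaled, sizeFactorsMoR(scaled))
  expect_equal(n1 / n2, matrix(rep(n1[1, 1] / n2[1, 1], 40), ncol = 4,
                               dimnames = dimnames(n1)),
               tolerance = 1e-9)
})

test_that("per-condition ratios follow the pseudocounted mean-of-replicates rule", {
  design <- conditionDesign(c("c1", "c2", "t1", "t2"),
                            c("ctrl", "ctrl", "tx", "tx"), "ctrl")
  cdsN <- matrix(c(100, 100, 400, 400), nrow = 1,
                 dimnames = list("TX1", c("c1", "c2", "t1", "t2")))
  uN <- matrix(c(10, 10, 10, 10), nrow = 1,
               dimnames = list("TX1.u1", c("c1", "c2", "t1", "t2")))
  raw <- uN
  map <- data.frame(uorf_id = "TX1.u1", transcript_id = "TX1",
                    gene_id = "G1", stringsAsFactors = FALSE)
  r0 <- conditionRatios(cdsN, uN, raw, map, design, pseudocount = 0)
  expect_equal(r0$R_ctrl, 10)
  expect_equal(r0$R_tx, 40)
  expect_equal(r0$log2FC, 2)
  # zero uORF counts stay defined through the pseudocount
  uZ <- uN * 0
  rz <- conditionRatios(cdsN, uZ, uZ, map, design, pseudocount = 1)
  expect_equal(rz$R_ctrl, 101)
  expect_true(rz$raw_uorf_zero)
  # equal means give ratio 1
  re <- conditionRatios(uN, uN, raw,
                        transform(map, transcript_id = "TX1.u1"),
                        design, pseudocount = 0)
  expect_equal(re$R_ctrl, 1)
  expect_equal(re$log2FC, 0)
  # a uORF whose transcript lacks a CDS feature is skipped with a message
  map2 <- rbind(map, data.frame(uorf_id = "TX9.u1", transcript_id = "TX9",
                                gene_id = "G9"))
  uN2 <- rbind(uN, "TX9.u1" = c(1, 1, 1, 1))
  expect_message(r2 <- conditionRatios(cdsN, uN2, uN2, map2, design),
                 "lacks a CDS feature")
  expect_equal(r2$uorf_id, "TX1.u1")
})

test_that("log2 fold change is log2 of the ratio of ratios", {
  expect_equal(log2FoldChange(4, 2), 1)
  expect_equal(log2FoldChange(7.3, 7.3), 0)
  expect_equal(log2FoldChange(21.61, 5.51), 1.9715750, tolerance = 1e-6)
  expect_error(log2FoldChange(-1, 2), "strictly positive")
})

test_that("condition swap negates every log2 fold change", {
  set.seed(21)
  design <- conditionDesign(paste0("s", 1:6),
                            rep(c("ctrl", "tx"), each = 3), "ctrl")
  designSwap <- conditionDesign(paste0("s", 1:6),
                                rep(c("ctrl", "tx"), each = 3), "tx")
  cdsN <- matrix(runif(60, 50, 500), nrow = 10,
                 dimnames = list(paste0("T", 1:10), paste0("s", 1:6)))
  uN <- matrix(runif(60, 1, 50), nrow = 10,
               dimnames = list(paste0("T", 1:10, ".u1"), paste0("s", 1:6)))
  map <- data.frame(uorf_id = rownames(uN), transcript_id = rownames(cdsN),
                    gene_id = paste0("G", 1:10), stringsAsFactors = FALSE)
  f <- conditionRatios(cdsN, uN, uN, map, design)
  b <- conditionRatios(cdsN, uN, uN, map, designSwap)
  expect_equal(f$log2FC, -b$log2FC)
  expect_equal(f$R_ctrl, b$R_tx)
})

test_that("quantile flags use round-half-up and exclude raw-zero uORFs", {
  set.seed(33)
  rec <- mkRecords(rnorm(939))
  fl <- flagQuantiles(rec, 0.05)
  expect_equal(sum(fl$flag == "strongest_change"), 47L)
  expect_equal(sum(fl$flag == "least_change"), 47L)
  # the flagged sets are the extremes of |log2FC|
  expect_gte(min(abs(fl$log2FC[fl$flag == "strongest_change"])),
             max(abs(fl$log2FC[fl$flag == "none"])))
  expect_lte(max(abs(fl$log2FC[fl$flag == "least_change"])),
             min(abs(fl$log2FC[fl$flag == "none"])))
  # raw-zero records are ineligible and unflagged
  rec2 <- mkRecords(rnorm(1000), rawZero = rep(c(TRUE, FALSE), c(61, 939)))
  fl2 <- flagQuantiles(rec2, 0.05)
  expect_equal(sum(fl2$flag == "strongest_change"), 47L)
  expect_true(all(fl2$flag[rec2$raw_uorf_zero] == "none"))
})

test_that("tied fold changes flag deterministically by uORF id", {
  rec <- mkRecords(rep(1, 40))
  f1 <- flagQuantiles(rec, 0.05)
  f2 <- flagQuantiles(rec[sample(40), ], 0.05)
  expect_equal(sort(f1$uorf_id[f1$flag == "strongest_change"]),
               sort(f2$uorf_id[f2$flag == "strongest_change"]))
  expect_equal(f1$uorf_id[f1$flag == "strongest_change"],
               c("u0001", "u0002"))
})

test_that("regulation summary matches direct recomputation", {
  set.seed(44)
  rec <- flagQuantiles(mkRecords(rnorm(200, sd = 1.2)))
  s <- summarizeRegulation(rec)
  fc <- rec$log2FC
  expect_equal(s$n_negative, sum(fc < 0))
  expect_equal(s$n_below_minus1, sum(fc < -1))
  expect_equal(s$n_above_1, sum(fc > 1))
  expect_equal(s$mean_negative, mean(fc[fc < 0]))
  expect_equal(s$mean_positive, mean(fc[fc > 0]))
  expect_equal(s$n_strongest_negative,
               sum(fc < 0 & rec$flag == "strongest_change"))
  # symmetric set: means are -a and +a
  sym <- summarizeRegulation(mkRecords(c(-2, -2, 2, 2)))
  expect_equal(sym$mean_negative, -2)
  expect_equal(sym$mean_positive, 2)
})

test_that("output files round-trip and survive empty record sets", {
  set.seed(5)
  outdir <- tempfile("ratio_out_")
  cdsN <- matrix(runif(8, 1, 100), nrow = 2,
                 dimnames = list(c("T1", "T2"), paste0("s", 1:4)))
  uN <- matrix(runif(8, 1, 30), nrow = 2,
               dimnames = list(c("T1.u1", "T2.u1"), paste0("s", 1:4)))
  rec <- flagQuantiles(mkRecords(c(0.5, -0.2)))
  paths <- writeRatioOutputs(rec, cdsN, uN, outdir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[["cds"]], row.names = 1, check.names = FALSE)
  expect_equal(as.matrix(back), cdsN, tolerance = 1e-6)
  reg <- read.csv(paths[["regulation"]])
  expect_equal(reg$log2FC, rec$log2FC)
  # empty records: header-only regulation table
  empty <- writeRatioOutputs(rec[0, ], cdsN, uN, tempfile("ratio_empty_"))
  regEmpty <- read.csv(empty[["regulation"]])
  expect_equal(nrow(regEmpty), 0L)
  expect_equal(colnames(regEmpty),
               c("uorf_id", "transcript_id", "gene_id", "R_ctrl", "R_tx",
                 "log2FC", "flag"))
})
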