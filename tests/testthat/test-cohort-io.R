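writeToyTable <- function(lines, sep = "\t") {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

test_that("alteration tables are read with case-folded vocabularies", {
  tf <- writeToyTable(c(
    "patient_id\tgene\talteration_class\tsignificance",
    "P1\tBRCA1\tFrameshift\tunclassified",
    "P2\t brca2 \tmissense\tVUS",
    "P3\tTP53\tnonsense\tPathogenic"))
  rec <- readAlterationTable(tf)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$alteration_class, c("frameshift", "missense", "nonsense"))
  expect_equal(rec$significance, c("unclassified", "vus", "pathogenic"))
  expect_equal(rec$gene, c("BRCA1", "BRCA2", "TP53"))
})

test_that("unknown vocabulary strings map to fallbacks with a warning", {
  tf <- writeToyTable(c(
    "patient_id\tgene\talteration_class\tsignificance",
    "P1\tATM\tweird_class\tmaybe_bad"))
  expect_warning(expect_warning(rec <- readAlterationTable(tf),
                                "alteration_class"), "significance")
  expect_equal(rec$alteration_class, "other")
  expect_equal(rec$significance, "unclassified")
})

test_that("missing mapped columns and empty tables are hard errors", {
  tf <- writeToyTable(c("patient_id\tgene\tsignificance",
                        "P1\tATM\tvus"))
  expect_error(readAlterationTable(tf), "alteration_class")
  tf2 <- writeToyTable("patient_id\tgene\talteration_class\tsignificance")
  expect_error(readAlterationTable(tf2), "empty")
})

test_that("column mapping and CSV dialect are honored", {
  tf <- writeToyTable(c("pt,symbol,class,sig", "P1,EGFR,missense,pathogenic"),
                      sep = ",")
  rec <- readAlterationTable(tf, sep = ",",
                             columnMap = c(patient_id = "pt", gene = "symbol",
                                           alteration_class = "class",
                                           significance = "sig"))
  expect_equal(rec$gene, "EGFR")
})

test_that("record write-then-read round trip is lossless", {
  rec <- data.frame(patient_id = c("P1", "P2", "P3"),
                    gene = c("BRCA1", "BRCA2", "ATM"),
                    alteration_class = c("frameshift", "missense", "splice"),
                    significance = c("unclassified", "pathogenic", "vus"),
                    stringsAsFactors = FALSE)
  tf <- tempfile()
  writeAlterationTable(rec, tf)
  expect_identical(readAlterationTable(tf), rec)
})

test_that("pathogenicity filter follows the stated rules and is idempotent", {
  rec <- data.frame(
    patient_id = sprintf("P%d", 1:6), gene = rep("ATM", 6),
    alteration_class = c("frameshift", "nonsense", "missense", "missense",
                         "splice", "missense"),
    significance = c("unclassified", "vus", "vus", "pathogenic", "benign",
                     "likely_pathogenic"),
    stringsAsFactors = FALSE)
  out <- filterPathogenic(rec)
  # frameshift/nonsense kept regardless of annotation; VUS/benign otherwise out
  expect_equal(out$patient_id, c("P1", "P2", "P4", "P6"))
  expect_identical(filterPathogenic(out), out)
  empty <- rec[0, ]
  expect_equal(nrow(filterPathogenic(empty)), 0L)
})

test_that("binarize collapses duplicates, honors the universe and excludes CNVs", {
  rec <- data.frame(
    patient_id = c("P1", "P1", "P2", "P3"),
    gene = c("BRCA1", "BRCA1", "TP53", "ERBB2"),
    alteration_class = c("frameshift", "nonsense", "missense", "amplification"),
    significance = rep("pathogenic", 4), stringsAsFactors = FALSE)
  mm <- binarize(rec, patientUniverse = c("P0", "P1", "P2", "P3"))
  expect_equal(patientIds(mm), c("P0", "P1", "P2", "P3"))
  expect_equal(unname(mutationCalls(mm)["P1", "BRCA1"]), 1L)  # idempotent collapse
  expect_equal(sum(mutationCalls(mm)["P0", ]), 0L)            # zero row
  expect_false("ERBB2" %in% panelGenes(mm))                   # amplification out
  mm2 <- binarize(rec, includeCopyNumber = TRUE)
  expect_equal(unname(mutationCalls(mm2)["P3", "ERBB2"]), 1L)
  # record order invariance
  mm3 <- binarize(rec[4:1, ], patientUniverse = c("P0", "P1", "P2", "P3"))
  expect_identical(mutationCalls(mm3), mutationCalls(mm))
})

test_that("binarize matches a hand-built truth table", {
  rec <- data.frame(patient_id = c("P1", "P2", "P2"),
                    gene = c("A", "A", "B"),
                    alteration_class = rep("missense", 3),
                    significance = rep("pathogenic", 3),
                    stringsAsFactors = FALSE)
  mm <- binarize(rec, patientUniverse = c("P1", "P2", "P3"))
  truth <- matrix(c(1L, 1L, 0L, 0L, 1L, 0L), 3, 2,
                  dimnames = list(c("P1", "P2", "P3"), c("A", "B")))
  expect_identical(mutationCalls(mm), truth)
})

test_that("landscape thresholds at the stated boundary and orders by frequency", {
  mat <- matrix(0L, 614, 3, dimnames = list(sprintf("P%03d", 1:614),
                                            c("LOW", "MID", "TOP")))
  mat[1:30, "LOW"] <- 1L   # 30/614 = 0.0489 < 0.05
  mat[1:31, "MID"] <- 1L   # 31/614 = 0.0505 >= 0.05
  mat[1:200, "TOP"] <- 1L
  ls <- landscape(MutationMatrix(mat), minFreq = 0.05)
  expect_equal(retainedGenes(ls), c("TOP", "MID"))
  expect_false("LOW" %in% retainedGenes(ls))
  # frequency * n recovers the integer column sums
  expect_equal(ls$frequency * 614, as.numeric(ls$count))
  # min_freq = 0 retains everything
  expect_equal(sort(retainedGenes(landscape(MutationMatrix(mat), 0))),
               c("LOW", "MID", "TOP"))
  expect_error(landscape(MutationMatrix(mat[0, , drop = FALSE])), "empty")
})

test_that("mutation matrix write-then-read round trip is lossless", {
  mm <- toyMatrix()
  tf <- tempfile()
  writeMutationMatrix(mm, tf)
  back <- readMutationMatrix(tf)
  expect_identical(mutationCalls(back), mutationCalls(mm))
})

test_that("MutationMatrix validity rejects malformed input", {
  expect_error(MutationMatrix(matrix(c(0L, 2L), 1, 2,
                                     dimnames = list("P1", c("A", "B")))),
               "0 or 1")
  expect_error(MutationMatrix(matrix(0L, 2, 1,
                                     dimnames = list(c("P1", "P1"), "A"))),
               "duplicate")
})
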