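#' @name cohort-io
#' @title Alteration-call input/output and the pathogenicity filter
#'
#' @description
#' A cohort arrives as a long-format alteration-call table: one row per
#' reported patient/gene/alteration with a functional class and a clinical
#' significance annotation. These functions read such tables, apply the
#' pathogenicity filter (variants of unknown significance and benign calls
#' are excluded; frameshift and nonsense changes count as pathogenic
#' regardless of annotation), collapse the retained calls into a binary
#' patient-by-gene [MutationMatrix-class], and summarize the alteration
#' landscape at a frequency threshold.
NULL

ALTERATION_CLASSES <- c("missense", "frameshift", "nonsense", "splice",
                        "synonymous", "amplification", "fusion", "other")
SIGNIFICANCE_LEVELS <- c("pathogenic", "likely_pathogenic", "vus", "benign",
                         "unclassified")

DEFAULT_COLUMN_MAP <- c(patient_id = "patient_id", gene = "gene",
                        alteration_class = "alteration_class",
                        significance = "significance")

normalizeVocab <- function(x, vocab, fallback, what) {
  y <- gsub("[ -]", "_", tolower(trimws(x)))
  bad <- !(y %in% vocab)
  if (any(bad)) {
    warning(sprintf("%d %s value(s) outside the known vocabulary mapped to '%s': %s",
                    sum(bad), what, fallback,
                    paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
    y[bad] <- fallback
  }
  y
}

#' Read an alteration-call table
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field delimiter; tab by default, use "," for CSV.
#' @param columnMap named character vector mapping the canonical record
#'   fields (`patient_id`, `gene`, `alteration_class`, `significance`) to
#'   the column names used in the file.
#' @return data frame of alteration records with canonical columns
#'   `patient_id`, `gene`, `alteration_class`, `significance`. Gene symbols
#'   are upper-cased and whitespace-stripped; class and significance are
#'   case-folded into their closed vocabularies, with unknown strings mapped
#'   to `other` / `unclassified` under a warning.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("patient_id\tgene\talteration_class\tsignificance",
#'              "P1\tBRCA1\tframeshift\tunclassified",
#'              "P2\ttp53\tMissense\tPathogenic"), tf)
#' readAlterationTable(tf)
#' @export
readAlterationTable <- function(path, sep = "\t",
                                columnMap = DEFAULT_COLUMN_MAP) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (nrow(df) == 0L) stop("empty alteration table: ", path)
  cm <- DEFAULT_COLUMN_MAP
  cm[names(columnMap)] <- columnMap
  for (field in names(cm))
    if (!cm[[field]] %in% names(df))
      stop(sprintf("mapped column '%s' (field %s) missing from header",
                   cm[[field]], field))
  rec <- data.frame(
    patient_id = as.character(df[[cm[["patient_id"]]]]),
    gene = toupper(gsub("\\s+", "", as.character(df[[cm[["gene"]]]]))),
    alteration_class = normalizeVocab(df[[cm[["alteration_class"]]]],
                                      ALTERATION_CLASSES, "other",
                                      "alteration_class"),
    significance = normalizeVocab(df[[cm[["significance"]]]],
                                  SIGNIFICANCE_LEVELS, "unclassified",
                                  "significance"),
    stringsAsFactors = FALSE)
  if (any(!nzchar(rec$gene))) stop("empty gene symbol in table")
  rec
}

#' Write an alteration-call table
#'
#' Inverse of [readAlterationTable()]: a write-then-read round trip
#' reproduces the records field-for-field.
#'
#' @param records record data frame as returned by [readAlterationTable()].
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
writeAlterationTable <- function(records, path, sep = "\t") {
  utils::write.table(records[, names(DEFAULT_COLUMN_MAP)], path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Retain pathogenic alteration calls
#'
#' Drops variants of unknown significance and benign calls; keeps calls
#' annotated pathogenic or likely pathogenic; frameshift and nonsense
#' alterations are kept as pathogenic regardless of their significance
#' annotation. Idempotent.
#'
#' @param records record data frame ([readAlterationTable()] layout).
#' @return the retained subset, same columns.
#' @examples
#' rec <- data.frame(patient_id = c("P1", "P2"), gene = c("BRCA1", "ATM"),
#'                   alteration_class = c("frameshift", "missense"),
#'                   significance = c("unclassified", "vus"))
#' filterPathogenic(rec)  # keeps the frameshift, drops the VUS
#' @export
filterPathogenic <- function(records) {
  keep <- records$alteration_class %in% c("frameshift", "nonsense") |
    records$significance %in% c("pathogenic", "likely_pathogenic")
  records[keep, , drop = FALSE]
}

#' Collapse filtered records into a binary mutation matrix
#'
#' Entry (patient, gene) is 1 when the patient has at least one retained
#' record for the gene. Copy-number amplifications and fusions do not
#' confer mutation-positive status unless `includeCopyNumber = TRUE`.
#'
#' @param records filtered record data frame.
#' @param patientUniverse optional ordered patient identifiers; patients
#'   with no records appear as all-zero rows.
#' @param panelGenes optional gene symbols guaranteed to appear as columns
#'   even when never altered.
#' @param includeCopyNumber logical; count `amplification`/`fusion` records
#'   toward mutation-positive status.
#' @return A [MutationMatrix-class]; rows follow `patientUniverse` order
#'   (then any additional observed patients), columns are alphabetical.
#' @export
binarize <- function(records, patientUniverse = NULL, panelGenes = NULL,
                     includeCopyNumber = FALSE) {
  if (!includeCopyNumber)
    records <- records[!records$alteration_class %in%
                         c("amplification", "fusion"), , drop = FALSE]
  patients <- unique(c(as.character(patientUniverse), records$patient_id))
  genes <- sort(unique(c(toupper(as.character(panelGenes)), records$gene)))
  mat <- matrix(0L, length(patients), length(genes),
                dimnames = list(patients, genes))
  if (nrow(records))
    mat[cbind(match(records$patient_id, patients),
              match(records$gene, genes))] <- 1L
  MutationMatrix(mat)
}

#' Alteration landscape at a frequency threshold
#'
#' Per-gene alteration frequency (column mean of the mutation matrix) and
#' the genes retained at a minimum frequency, ordered by descending
#' frequency with alphabetical tie-break.
#'
#' @param mm A [MutationMatrix-class].
#' @param minFreq minimum frequency in `[0, 1]` for a gene to be retained.
#' @return data frame with columns `gene`, `count`, `frequency`,
#'   `retained`, ordered by descending frequency; `retainedGenes()` of the
#'   result is `gene[retained]`.
#' @export
landscape <- function(mm, minFreq = 0.05) {
  stopifnot(is(mm, "MutationMatrix"))
  if (nPatients(mm) == 0L || nGenes(mm) == 0L) stop("empty mutation matrix")
  if (minFreq < 0 || minFreq > 1) stop("minFreq must be in [0, 1]")
  counts <- colSums(mutationCalls(mm))
  freq <- counts / nPatients(mm)
  ord <- order(-freq, names(freq))
  data.frame(gene = names(freq)[ord], count = as.integer(counts[ord]),
             frequency = as.numeric(freq[ord]),
             retained = as.numeric(freq[ord]) >= minFreq,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genes retained by a landscape summary
#'
#' @param ls landscape data frame from [landscape()].
#' @return character vector of retained genes in landscape order.
#' @export
retainedGenes <- function(ls) ls$gene[ls$retained]

#' Read / write a binary mutation matrix
#'
#' Delimited text with a header; first column `patient_id`, remaining
#' columns gene symbols, cells 0/1. A write-then-read round trip is
#' lossless.
#'
#' @param path file path.
#' @param mm A [MutationMatrix-class] (for writing).
#' @param sep field delimiter.
#' @return `readMutationMatrix` a [MutationMatrix-class];
#'   `writeMutationMatrix` the path, invisibly.
#' @export
readMutationMatrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "patient_id") stop("first column must be patient_id")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df$patient_id)
  MutationMatrix(mat)
}

#' @rdname readMutationMatrix
#' @export
writeMutationMatrix <- function(mm, path, sep = "\t") {
  stopifnot(is(mm, "MutationMatrix"))
  df <- data.frame(patient_id = patientIds(mm), mutationCalls(mm),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readMutationMatrix
#' @param ls landscape data frame (for `writeLandscape`).
#' @export
writeLandscape <- function(ls, path, sep = "\t") {
  utils::write.table(ls, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
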