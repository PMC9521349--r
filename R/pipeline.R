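#' @name pipeline
#' @title End-to-end co-mutation analysis pipeline
#'
#' @description
#' Orchestrates the full chain on one cohort: pathogenicity filter and
#' binarization (when the input is a long alteration table), landscape
#' summary, per-anchor Fisher/FDR screening, approximate neighbor
#' discovery, exact structure search over anchors plus neighbors,
#' CPT fitting, and the relative-risk report. Every stage writes a
#' self-describing delimited file into the output directory and the run
#' is fully determined by the configuration plus one integer seed.
NULL

#' Run the full analysis pipeline
#'
#' @param input path to a mutation-matrix TSV ([readMutationMatrix()]
#'   layout) or a long alteration table; or a [MutationMatrix-class]
#'   directly.
#' @param outputDir directory for result files (created if needed).
#' @param anchors anchor genes (default BRCA1 and BRCA2); all must be on
#'   the panel.
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param minFreq landscape retention threshold (default 0.05).
#' @param candidateMinFreq minimum alteration frequency for screen
#'   candidates (default 0 = no filter).
#' @param k neighbor count cap for the approximate stage (default 15).
#' @param score,ess,maxParents structure-learning score settings (see
#'   [localScores()]).
#' @param restarts,maxMoves hill-climbing settings (see [hillClimb()]).
#' @param pseudoCount CPT smoothing pseudo-count (default 1).
#' @param seed integer seed for every stochastic stage.
#' @param cohort `"all"` (default) or `"anchor-positive"`, restricting
#'   the model-based stages to patients mutated in at least one anchor.
#' @param direction RR conditioning direction (see [relativeRisk()]).
#' @param multiGeneQueries list of condition gene sets for multi-gene RR
#'   queries, in addition to the automatic single-gene queries for every
#'   network gene.
#' @param inputType `"auto"` (sniff the header), `"matrix"`, or
#'   `"alterations"`.
#' @param sep input field delimiter.
#' @param includeCopyNumber passed to [binarize()].
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(input, outputDir,
                        anchors = c("BRCA1", "BRCA2"), alpha = 0.05,
                        minFreq = 0.05, candidateMinFreq = 0,
                        k = 15L, score = "bdeu", ess = 1,
                        maxParents = 4L, restarts = 10L, maxMoves = 500L,
                        pseudoCount = 1, seed = 1L,
                        cohort = c("all", "anchor-positive"),
                        direction = "anchor_given_genes",
                        multiGeneQueries = list(c("NOTCH1"),
                                                c("NOTCH1", "ARID1A", "MTOR")),
                        inputType = c("auto", "matrix", "alterations"),
                        sep = "\t", includeCopyNumber = FALSE) {
  cohort <- match.arg(cohort)
  inputType <- match.arg(inputType)
  stopifnot(alpha > 0, alpha < 1, minFreq >= 0, minFreq <= 1, k >= 1)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = list(
    anchors = anchors, alpha = alpha, min_freq = minFreq,
    candidate_min_freq = candidateMinFreq, k = k, score = score,
    ess = ess, max_parents = maxParents, restarts = restarts,
    max_moves = maxMoves, pseudo_count = pseudoCount, seed = seed,
    cohort = cohort, direction = direction,
    multi_gene_queries = multiGeneQueries),
    version = as.character(utils::packageVersion("comutnet")),
    stages = list())
  tic <- function() proc.time()[["elapsed"]]
  addStage <- function(name, t0, ...) {
    manifest$stages[[name]] <<- c(list(seconds = round(tic() - t0, 3)),
                                  list(...))
  }

  t0 <- tic()
  mm <- if (is(input, "MutationMatrix")) input
  else {
    if (inputType == "auto") {
      hdr <- strsplit(readLines(input, n = 1L), sep, fixed = TRUE)[[1]]
      inputType <- if (identical(hdr[1], "patient_id") &&
                       !"gene" %in% hdr) "matrix" else "alterations"
    }
    if (inputType == "matrix") readMutationMatrix(input, sep = sep)
    else binarize(filterPathogenic(readAlterationTable(input, sep = sep)),
                  includeCopyNumber = includeCopyNumber)
  }
  missingAnchor <- setdiff(anchors, panelGenes(mm))
  if (length(missingAnchor))
    stop("anchor gene(s) absent from the panel: ",
         paste(missingAnchor, collapse = ", "))
  if (cohort == "anchor-positive") {
    keep <- rowSums(mutationCalls(mm)[, anchors, drop = FALSE]) > 0L
    mm <- MutationMatrix(mutationCalls(mm)[keep, , drop = FALSE])
  }
  addStage("load", t0, patients = nPatients(mm), genes = nGenes(mm))
  stageLog("load", "%d patients x %d genes (%s cohort)",
           nPatients(mm), nGenes(mm), cohort)

  t0 <- tic()
  ls <- landscape(mm, minFreq)
  writeLandscape(ls, file.path(outputDir, "landscape.tsv"))
  addStage("landscape", t0, retained = sum(ls$retained))
  stageLog("landscape", "%d of %d genes at frequency >= %.3f",
           sum(ls$retained), nrow(ls), minFreq)

  t0 <- tic()
  freqs <- setNames(ls$frequency, ls$gene)
  candidates <- setdiff(names(freqs)[freqs >= candidateMinFreq], anchors)
  assoc <- list()
  for (a in anchors) {
    res <- screenAssociations(mm, a, candidates, alpha = alpha)
    writeAssociations(res, file.path(outputDir,
                                     sprintf("assoc_%s.tsv", a)))
    assoc[[a]] <- res
    stageLog("screen", "%s: %d of %d candidates significant at FDR %.2f",
             a, sum(res$significant), nrow(res), alpha)
  }
  addStage("screen", t0,
           significant = vapply(assoc, function(r) sum(r$significant),
                                numeric(1)))

  t0 <- tic()
  neighbors <- approximateNeighbors(mm, anchors, k = k, score = score,
                                    ess = ess, maxParents = maxParents,
                                    restarts = restarts,
                                    maxMoves = maxMoves, seed = seed)
  writeLines(neighbors, file.path(outputDir, "neighbors.txt"))
  addStage("neighbors", t0, count = length(neighbors))
  stageLog("neighbors", "%d candidate genes: %s", length(neighbors),
           paste(neighbors, collapse = ", "))

  t0 <- tic()
  netNodes <- c(anchors, neighbors)
  tab <- localScores(mm, netNodes, score = score, ess = ess,
                     maxParents = maxParents)
  writeScoreTable(tab, file.path(outputDir, "local_scores.tsv"))
  sr <- exactSearch(tab)
  exportNetwork(sr$dag, dotPath = file.path(outputDir, "network.dot"),
                graphmlPath = file.path(outputDir, "network.graphml"),
                frequencies = freqs[netNodes])
  addStage("structure", t0, nodes = length(netNodes),
           edges = sum(lengths(sr$dag@parents)),
           total_score = sr$totalScore, expansions = sr$expansions)
  stageLog("structure", "optimal network: %d edges, score %.3f (%d expansions)",
           sum(lengths(sr$dag@parents)), sr$totalScore, sr$expansions)

  t0 <- tic()
  cpts <- fitCpts(mm, sr$dag, pseudoCount = pseudoCount)
  writeCpts(cpts, file.path(outputDir, "cpts.tsv"))
  addStage("fit", t0)

  t0 <- tic()
  singles <- lapply(setdiff(netNodes, anchors), function(g) g)
  rr <- riskReport(sr$dag, cpts, anchors,
                   c(singles, multiGeneQueries), direction = direction)
  utils::write.table(rr, file.path(outputDir, "rr_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  addStage("risk", t0, queries = nrow(rr))
  stageLog("risk", "%d relative-risk queries answered", nrow(rr))

  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a simulated cohort with its ground-truth sidecar
#'
#' Draws a cohort from a planted model (object or YAML config path) and
#' writes the binary matrix in the standard layout plus a JSON sidecar of
#' model-implied relative risks for downstream comparison.
#'
#' @param model A [PlantedModel-class] or path to a model config
#'   ([readModelConfig()]).
#' @param outputDir output directory.
#' @param seed optional seed overriding the model's.
#' @return invisibly, list of the written paths.
#' @export
writeSimulatedCohort <- function(model, outputDir, seed = NULL) {
  if (is.character(model)) model <- readModelConfig(model)
  stopifnot(is(model, "PlantedModel"))
  if (!is.null(seed)) model@seed <- as.integer(seed)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  real <- sampleCohort(model)
  matPath <- file.path(outputDir, "cohort.tsv")
  writeMutationMatrix(real$matrix, matPath)
  truthPath <- file.path(outputDir, "truth.json")
  jsonlite::write_json(list(seed = model@seed,
                            n_patients = model@nPatients,
                            true_rr = as.list(real$trueRR)),
                       truthPath, auto_unbox = TRUE, digits = NA)
  stageLog("simulate", "%d x %d cohort written to %s",
           nPatients(real$matrix), nGenes(real$matrix), matPath)
  invisible(list(matrix = matPath, truth = truthPath))
}

#' One-page summary of a pipeline run
#'
#' Re-reads the result files in a run directory and prints cohort size,
#' anchor prevalences, significant genes per anchor, the learned edge
#' list, and the strongest relative risks. Missing stage files are listed
#' as absent rather than raising an error.
#'
#' @param runDir directory written by [runPipeline()].
#' @return invisibly, the summary lines.
#' @export
reportRun <- function(runDir) {
  manifestPath <- file.path(runDir, "manifest.json")
  if (!file.exists(manifestPath)) stop("no manifest.json in ", runDir)
  man <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  out <- c(sprintf("comutnet run summary: %s", runDir),
           sprintf("cohort: %s patients, %s genes",
                   man$stages$load$patients, man$stages$load$genes))
  anchors <- man$config$anchors
  lsPath <- file.path(runDir, "landscape.tsv")
  if (file.exists(lsPath)) {
    ls <- utils::read.table(lsPath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    for (a in anchors) {
      fr <- ls$frequency[ls$gene == a]
      if (length(fr))
        out <- c(out, sprintf("prevalence %s: %.2f%%", a, 100 * fr))
    }
  } else out <- c(out, "landscape.tsv: absent")
  for (a in anchors) {
    ap <- file.path(runDir, sprintf("assoc_%s.tsv", a))
    if (file.exists(ap)) {
      res <- utils::read.table(ap, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      sig <- res$gene[res$significant]
      out <- c(out, sprintf("%s significant co-mutated genes (%d): %s", a,
                            length(sig),
                            if (length(sig)) paste(sig, collapse = ", ")
                            else "none"))
    } else out <- c(out, sprintf("assoc_%s.tsv: absent", a))
  }
  dotPath <- file.path(runDir, "network.dot")
  if (file.exists(dotPath)) {
    edges <- grep("->", readLines(dotPath), value = TRUE)
    out <- c(out, sprintf("learned network edges (%d):", length(edges)),
             paste0("  ", trimws(sub(";$", "", edges))))
  } else out <- c(out, "network.dot: absent")
  rrPath <- file.path(runDir, "rr_report.tsv")
  if (file.exists(rrPath)) {
    rr <- utils::read.table(rrPath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    rr <- rr[order(-rr$rr), ]
    top <- utils::head(rr, 5)
    out <- c(out, "top relative risks:",
             sprintf("  RR(%s; %s) = %.3g", top$anchor, top$condition,
                     top$rr))
  } else out <- c(out, "rr_report.tsv: absent")
  cat(paste(out, collapse = "\n"), "\n")
  invisible(out)
}
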