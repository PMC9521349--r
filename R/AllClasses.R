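#' @import methods
#' @importFrom stats setNames
NULL

#' Binary patient-by-gene mutation matrix
#'
#' Core container for a liquid-biopsy cohort: one row per patient, one
#' column per panel gene, entries 1 if the patient carries at least one
#' retained pathogenic alteration in that gene and 0 otherwise.
#'
#' @slot calls integer matrix with dimnames; rows are patient identifiers,
#'   columns are HGNC-style gene symbols; all entries 0 or 1.
#'
#' @seealso [binarize()], [readMutationMatrix()], [landscape()]
#' @export
setClass("MutationMatrix", representation(calls = "matrix"))

setValidity("MutationMatrix", function(object) {
  m <- object@calls
  msg <- character(0)
  if ((nrow(m) > 0L && is.null(rownames(m))) || is.null(colnames(m)))
    msg <- c(msg, "calls must have patient row names and gene column names")
  else {
    if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate patient_ids")
    if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate genes")
    if (any(!nzchar(colnames(m)))) msg <- c(msg, "empty gene symbol")
  }
  if (!all(m %in% c(0L, 1L))) msg <- c(msg, "entries must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Construct a MutationMatrix
#'
#' @param calls numeric or integer matrix of 0/1 calls with patient row
#'   names and gene column names.
#' @return A [MutationMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("BRCA1", "TP53")))
#' MutationMatrix(m)
#' @export
MutationMatrix <- function(calls) {
  storage.mode(calls) <- "integer"
  new("MutationMatrix", calls = calls)
}

#' Directed acyclic graph over panel genes
#'
#' @slot nodes character vector of gene symbols (the variable order used
#'   for display only; edges are given by `parents`).
#' @slot parents named list, one character vector of parent genes per node.
#' @export
setClass("GeneDag", representation(nodes = "character", parents = "list"))

setValidity("GeneDag", function(object) {
  nd <- object@nodes; pa <- object@parents
  if (anyDuplicated(nd)) return("duplicate nodes")
  if (!identical(sort(names(pa)), sort(nd))) return("parents must be named by nodes")
  for (v in nd) {
    if (v %in% pa[[v]]) return(sprintf("self-parent at %s", v))
    if (!all(pa[[v]] %in% nd)) return(sprintf("unknown parent of %s", v))
  }
  if (is.null(topoSortOrNull(nd, pa))) return("graph contains a cycle")
  TRUE
})

#' Construct a GeneDag
#'
#' @param nodes character vector of gene symbols.
#' @param parents named list mapping each node to a character vector of
#'   parent nodes; nodes absent from the list get no parents.
#' @return A [GeneDag-class].
#' @examples
#' GeneDag(c("A", "B"), list(B = "A"))
#' @export
GeneDag <- function(nodes, parents = list()) {
  full <- setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) full[[v]] <- as.character(if (v %in% names(parents)) parents[[v]] else character(0))
  new("GeneDag", nodes = nodes, parents = full)
}

#' Conditional probability tables for a binary Bayesian network
#'
#' For every node the table stores P(node = 1 | parent configuration).
#' Parent configurations are indexed with the first listed parent as the
#' least-significant bit: row j (1-based) encodes configuration j - 1.
#'
#' @slot cpts named list; each element has `parents` (character) and `p1`
#'   (numeric of length 2^length(parents), all in (0, 1)).
#' @slot pseudoCount the Dirichlet pseudo-count used at fitting time
#'   (NA_real_ for hand-specified tables).
#' @export
setClass("CptSet", representation(cpts = "list", pseudoCount = "numeric"))

setValidity("CptSet", function(object) {
  for (v in names(object@cpts)) {
    e <- object@cpts[[v]]
    if (!is.numeric(e$p1) || length(e$p1) != 2^length(e$parents))
      return(sprintf("CPT for %s has wrong length", v))
    if (any(e$p1 <= 0 | e$p1 >= 1))
      return(sprintf("CPT for %s has probabilities outside (0,1)", v))
  }
  TRUE
})

#' Construct a CptSet
#'
#' @param cpts named list of `list(parents =, p1 =)` entries (see
#'   [CptSet-class] for the row indexing convention).
#' @param pseudoCount Dirichlet pseudo-count associated with the tables.
#' @return A [CptSet-class].
#' @export
CptSet <- function(cpts, pseudoCount = NA_real_) {
  new("CptSet", cpts = cpts, pseudoCount = pseudoCount)
}

#' Ground-truth generative model for synthetic cohorts
#'
#' A binary Bayesian network plus cohort size and seed; realizations drawn
#' from it stand in for a clinical cohort in tests and benchmarks.
#'
#' @slot dag [GeneDag-class] ground-truth structure.
#' @slot cpts [CptSet-class] ground-truth conditional probabilities.
#' @slot nPatients cohort size to sample.
#' @slot seed integer seed governing the realization.
#' @export
setClass("PlantedModel", representation(
  dag = "GeneDag", cpts = "CptSet", nPatients = "integer", seed = "integer"))

setValidity("PlantedModel", function(object) {
  if (!identical(sort(names(object@cpts@cpts)), sort(object@dag@nodes)))
    return("cpts must cover exactly the dag nodes")
  for (v in object@dag@nodes)
    if (!identical(object@cpts@cpts[[v]]$parents, object@dag@parents[[v]]))
      return(sprintf("CPT parents for %s disagree with dag", v))
  if (object@nPatients < 1L) return("nPatients must be positive")
  TRUE
})

#' Construct a PlantedModel
#'
#' @param dag [GeneDag-class].
#' @param cpts [CptSet-class] whose parent sets match `dag`.
#' @param nPatients number of patients a realization will contain.
#' @param seed integer seed.
#' @return A [PlantedModel-class].
#' @export
PlantedModel <- function(dag, cpts, nPatients = 7707L, seed = 1L) {
  new("PlantedModel", dag = dag, cpts = cpts,
      nPatients = as.integer(nPatients), seed = as.integer(seed))
}

#' Decomposable local score table
#'
#' Per-node scores for every candidate parent set up to the cap, the input
#' to both hill climbing and the exact order-lattice search.
#'
#' @slot nodes character vector of scored nodes.
#' @slot scores named list (per node) of named numeric vectors; names are
#'   parent-set keys (`parentSetKey()`), values the local score.
#' @slot maxParents integer parent-set size cap.
#' @slot scoreType "bdeu" or "bic".
#' @export
setClass("LocalScoreTable", representation(
  nodes = "character", scores = "list", maxParents = "integer",
  scoreType = "character"))

setValidity("LocalScoreTable", function(object) {
  if (!identical(sort(names(object@scores)), sort(object@nodes)))
    return("scores must be named by nodes")
  for (v in object@nodes)
    if (any(!is.finite(object@scores[[v]])))
      return(sprintf("non-finite score for %s", v))
  TRUE
})

#' Bipartite factor graph for sum-product message passing
#'
#' @slot vars character vector of variable names.
#' @slot factors list; each element has `name`, `vars` (scope, child plus
#'   parents) and `table` (numeric of length 2^|scope|, first scope
#'   variable = least-significant bit).
#' @export
setClass("FactorGraph", representation(vars = "character", factors = "list"))

#' Relative risk of co-segregation
#'
#' Result of a conditional query RR = numerator / denominator, where the
#' two probabilities condition on the gene set being fully mutated versus
#' fully unmutated (direction `anchor_given_genes`) or on the anchor state
#' (direction `genes_given_anchor`).
#'
#' @slot anchor anchor gene.
#' @slot condition conditioning gene set.
#' @slot direction "anchor_given_genes" or "genes_given_anchor".
#' @slot rr the relative risk (may be `Inf` when the denominator is 0).
#' @slot numerator,denominator the two conditional probabilities.
#' @slot method "exact", "bp" or "empirical".
#' @slot converged logical; belief-propagation convergence (TRUE for exact
#'   and empirical estimates).
#' @slot flag character; "" or a note such as "zero_denominator" /
#'   "continuity_corrected".
#' @export
setClass("RiskEstimate", representation(
  anchor = "character", condition = "character", direction = "character",
  rr = "numeric", numerator = "numeric", denominator = "numeric",
  method = "character", converged = "logical", flag = "character"))

RiskEstimate <- function(anchor, condition, direction, rr, numerator,
                         denominator, method, converged = TRUE, flag = "") {
  new("RiskEstimate", anchor = anchor, condition = condition,
      direction = direction, rr = rr, numerator = numerator,
      denominator = denominator, method = method, converged = converged,
      flag = flag)
}

setMethod("show", "MutationMatrix", function(object) {
  m <- object@calls
  cat(sprintf("MutationMatrix: %d patients x %d genes (%.3g%% positive entries)\n",
              nrow(m), ncol(m), 100 * mean(m)))
  top <- sort(colMeans(m), decreasing = TRUE)
  top <- utils::head(top, 5)
  cat("  top genes:", paste(sprintf("%s (%.1f%%)", names(top), 100 * top),
                            collapse = ", "), "\n")
})

setMethod("show", "GeneDag", function(object) {
  ne <- sum(lengths(object@parents))
  cat(sprintf("GeneDag: %d nodes, %d edges\n", length(object@nodes), ne))
  for (v in object@nodes) {
    pa <- object@parents[[v]]
    if (length(pa)) cat(sprintf("  %s <- {%s}\n", v, paste(pa, collapse = ", ")))
  }
})

setMethod("show", "PlantedModel", function(object) {
  cat(sprintf("PlantedModel: %d genes, %d planted edges, n = %d, seed = %d\n",
              length(object@dag@nodes), sum(lengths(object@dag@parents)),
              object@nPatients, object@seed))
})

setMethod("show", "RiskEstimate", function(object) {
  cat(sprintf("RiskEstimate [%s]: RR(%s; {%s}) = %.4g  (%.4g / %.4g, %s%s)\n",
              object@direction, object@anchor,
              paste(object@condition, collapse = ", "),
              object@rr, object@numerator, object@denominator, object@method,
              if (nzchar(object@flag)) paste0(", ", object@flag) else ""))
})

setMethod("show", "LocalScoreTable", function(object) {
  cat(sprintf("LocalScoreTable (%s): %d nodes, max %d parents, %d stored sets\n",
              object@scoreType, length(object@nodes), object@maxParents,
              sum(lengths(object@scores))))
})
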