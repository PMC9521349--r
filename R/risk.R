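#' @name relative-risk
#' @title Relative risk of co-segregation
#'
#' @description
#' The headline query of the analysis: how much more (or less) likely is
#' an anchor gene's pathogenic mutation when a given gene set is fully
#' mutated than when it is fully unmutated? Both conditioning directions
#' are first-class, because the field's usage varies:
#' `anchor_given_genes` computes
#' P(anchor = 1 | genes = 1) / P(anchor = 1 | genes = 0) and
#' `genes_given_anchor` computes
#' P(genes = 1 | anchor = 1) / P(genes = 1 | anchor = 0).
#' Model-based estimates come from inference on a fitted network;
#' a count-based empirical estimator provides a cross-check.
NULL

#' Model-based relative risk
#'
#' Probabilities are computed on the subnetwork relevant to the query
#' (ancestral closure of anchor and condition genes) by exact variable
#' elimination when that subnetwork has at most 20 nodes, otherwise by
#' loopy belief propagation with a logged approximation notice.
#'
#' @param dag A [GeneDag-class] (fitted structure).
#' @param cpts A [CptSet-class] (fitted parameters).
#' @param anchor anchor gene; must not appear in `condition`.
#' @param condition character vector of conditioning genes.
#' @param direction `"anchor_given_genes"` (default) or
#'   `"genes_given_anchor"`.
#' @param exactLimit subnetwork size up to which exact inference is used
#'   (default 20).
#' @return A [RiskEstimate-class]; `rr` is `Inf` with flag
#'   `"zero_denominator"` when the denominator probability is 0.
#' @export
relativeRisk <- function(dag, cpts, anchor, condition,
                         direction = c("anchor_given_genes",
                                       "genes_given_anchor"),
                         exactLimit = 20L) {
  direction <- match.arg(direction)
  condition <- as.character(condition)
  stopifnot(!(anchor %in% condition),
            all(c(anchor, condition) %in% dag@nodes))
  sub <- ancestralClosure(dag, c(anchor, condition))
  useExact <- length(sub) <= exactLimit
  if (!useExact)
    stageLog("infer", "subnetwork of %d nodes exceeds exact limit %d; using loopy BP (approximate)",
             length(sub), exactLimit)
  converged <- TRUE
  condQuery <- function(evidence, query) {
    if (useExact) return(variableElimination(dag, cpts, evidence, query))
    bp <- loopyBP(buildFactorGraph(dag, cpts), evidence)
    converged <<- converged && bp$converged
    bp$beliefs[query, "p1"]
  }
  if (direction == "anchor_given_genes") {
    on <- setNames(rep(1L, length(condition)), condition)
    off <- setNames(rep(0L, length(condition)), condition)
    num <- condQuery(on, anchor)
    den <- condQuery(off, anchor)
  } else {
    jointAll <- function(aVal) {
      ev <- setNames(c(rep(1L, length(condition)), aVal),
                     c(condition, anchor))
      if (useExact) {
        pa <- jointProbEvidence(dag, cpts,
                                setNames(aVal, anchor))
        jointProbEvidence(dag, cpts, ev) / pa
      } else {
        # chain rule, each conditional from BP with accumulated evidence
        ev0 <- setNames(aVal, anchor)
        p <- 1
        for (g in condition) {
          p <- p * condQuery(ev0, g)
          ev0 <- c(ev0, setNames(1L, g))
        }
        p
      }
    }
    num <- jointAll(1L)
    den <- jointAll(0L)
  }
  if (den == 0)
    return(RiskEstimate(anchor, condition, direction, Inf, num, den,
                        if (useExact) "exact" else "bp", converged,
                        "zero_denominator"))
  RiskEstimate(anchor, condition, direction, num / den, num, den,
               if (useExact) "exact" else "bp", converged, "")
}

#' Count-based empirical relative risk
#'
#' The same ratio computed from raw cohort counts; when any stratum cell
#' is empty a 0.5 continuity correction is applied to both strata and the
#' estimate is flagged `"continuity_corrected"`.
#'
#' @param mm A [MutationMatrix-class].
#' @inheritParams relativeRisk
#' @return A [RiskEstimate-class] with method `"empirical"`.
#' @export
empiricalRelativeRisk <- function(mm, anchor, condition,
                                  direction = c("anchor_given_genes",
                                                "genes_given_anchor")) {
  direction <- match.arg(direction)
  condition <- as.character(condition)
  stopifnot(!(anchor %in% condition),
            all(c(anchor, condition) %in% panelGenes(mm)))
  mat <- mutationCalls(mm)
  condOn <- rowSums(mat[, condition, drop = FALSE]) == length(condition)
  condOff <- rowSums(mat[, condition, drop = FALSE]) == 0L
  aOn <- mat[, anchor] == 1L
  if (direction == "anchor_given_genes") {
    n1 <- sum(condOn); k1 <- sum(condOn & aOn)
    n0 <- sum(condOff); k0 <- sum(condOff & aOn)
  } else {
    n1 <- sum(aOn); k1 <- sum(aOn & condOn)
    n0 <- sum(!aOn); k0 <- sum(!aOn & condOn)
  }
  corrected <- n1 == 0L || n0 == 0L || k1 == 0L || k0 == 0L ||
    k1 == n1 || k0 == n0
  if (corrected) {
    num <- (k1 + 0.5) / (n1 + 1); den <- (k0 + 0.5) / (n0 + 1)
  } else {
    num <- k1 / n1; den <- k0 / n0
  }
  RiskEstimate(anchor, condition, direction, num / den, num, den,
               "empirical", TRUE,
               if (corrected) "continuity_corrected" else "")
}

#' Batch RR report
#'
#' Computes model-based relative risks for a list of condition sets
#' against one or more anchors and stacks them into the report layout
#' written by the pipeline.
#'
#' @param dag,cpts fitted network.
#' @param anchors character vector of anchor genes.
#' @param conditionSets list of character vectors; each is queried against
#'   every anchor that is not a member of the set.
#' @param direction conditioning direction (see [relativeRisk()]).
#' @return data frame, one row per (anchor, condition set).
#' @export
riskReport <- function(dag, cpts, anchors, conditionSets,
                       direction = "anchor_given_genes") {
  rows <- list()
  for (a in anchors) for (cs in conditionSets) {
    cs <- as.character(cs)
    if (a %in% cs || !all(c(a, cs) %in% dag@nodes)) next
    rows[[length(rows) + 1L]] <-
      as.data.frame(relativeRisk(dag, cpts, a, cs, direction))
  }
  do.call(rbind, rows)
}
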