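#' @name structure-scores
#' @title Decomposable network scores for binary data
#'
#' @description
#' Discrete Bayesian-network structure learning optimizes a decomposable
#' score: a sum of per-node local scores, each a function of the
#' sufficient statistics (counts of every parent configuration crossed
#' with the child state). Two families are provided: BDeu (Bayesian
#' Dirichlet equivalent uniform marginal likelihood with an equivalent
#' sample size, equal for Markov-equivalent structures) and BIC
#' (log-likelihood minus `(log n / 2)` times the number of free
#' parameters, `2^|parents|` for a binary child).
NULL

# counts matrix 2 x 2^k for child state (rows 0/1) by parent config.
familyCounts <- function(mat, child, parents) {
  cfg <- encodeConfigs(mat, parents)
  y <- mat[, child]
  q <- 2L^length(parents)
  tab <- tabulate((cfg - 1L) * 2L + y + 1L, nbins = 2L * q)
  matrix(tab, nrow = 2L)  # [y + 1, cfg]
}

bdeuLocal <- function(counts, ess) {
  q <- ncol(counts)
  aj <- ess / q; ajk <- ess / (2 * q)
  nj <- colSums(counts)
  sum(lgamma(aj) - lgamma(aj + nj)) +
    sum(lgamma(ajk + counts) - lgamma(ajk))
}

bicLocal <- function(counts, n) {
  q <- ncol(counts)
  nj <- colSums(counts)
  nz <- counts > 0
  ll <- sum(counts[nz] * log(counts[nz] /
                               rep(nj, each = 2)[as.vector(nz)]))
  ll - log(n) / 2 * q
}

localScoreOf <- function(mat, child, parents, score, ess) {
  counts <- familyCounts(mat, child, parents)
  if (score == "bdeu") bdeuLocal(counts, ess) else bicLocal(counts, nrow(mat))
}

# Memoized family scorer over a fixed data matrix.
makeFamilyScorer <- function(mat, score, ess) {
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  function(child, parents) {
    key <- paste0(child, "|", parentSetKey(parents))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- localScoreOf(mat, child, parents, score, ess)
    cache[[key]] <- val
    val
  }
}

#' Exhaustive local-score table
#'
#' Scores every candidate parent set of size at most `maxParents` for
#' every node, from the cohort's sufficient statistics. This table is the
#' sole input of [exactSearch()].
#'
#' @param mm A [MutationMatrix-class].
#' @param nodes genes to score (subset of the panel).
#' @param score `"bdeu"` (default) or `"bic"`.
#' @param ess equivalent sample size of the BDeu prior (default 1, with a
#'   uniform structure prior).
#' @param maxParents parent-set size cap (default 4); values at or above
#'   the node count are capped at `length(nodes) - 1` with a warning.
#' @return A [LocalScoreTable-class].
#' @export
localScores <- function(mm, nodes = panelGenes(mm),
                        score = c("bdeu", "bic"), ess = 1,
                        maxParents = 4L) {
  score <- match.arg(score)
  stopifnot(all(nodes %in% panelGenes(mm)), maxParents >= 0)
  if (maxParents >= length(nodes)) {
    warning("maxParents capped at |nodes| - 1")
    maxParents <- length(nodes) - 1L
  }
  mat <- mutationCalls(mm)
  tabs <- setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) {
    sets <- subsetsUpTo(setdiff(nodes, v), maxParents)
    vals <- vapply(sets, function(pa) localScoreOf(mat, v, pa, score, ess),
                   numeric(1))
    names(vals) <- vapply(sets, parentSetKey, character(1))
    tabs[[v]] <- vals
  }
  new("LocalScoreTable", nodes = nodes, scores = tabs,
      maxParents = as.integer(maxParents), scoreType = score)
}

#' Total score of a DAG under a local-score table
#'
#' @param table A [LocalScoreTable-class].
#' @param dag A [GeneDag-class] whose nodes and parent sets are covered by
#'   the table.
#' @return the summed local score.
#' @export
scoreDag <- function(table, dag) {
  tot <- 0
  for (v in dag@nodes) {
    key <- parentSetKey(dag@parents[[v]])
    val <- table@scores[[v]][key]
    if (is.na(val)) stop("parent set not in score table for ", v)
    tot <- tot + unname(val)
  }
  tot
}

#' Dump a local-score table as TSV
#'
#' Debugging aid: one row per (node, parent set, score).
#'
#' @param table A [LocalScoreTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScoreTable <- function(table, path) {
  rows <- do.call(rbind, lapply(table@nodes, function(v)
    data.frame(node = v, parent_set = names(table@scores[[v]]),
               score = unname(table@scores[[v]]),
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
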