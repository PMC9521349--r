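#' @name hill-climbing
#' @title Approximate structure search and neighbor discovery
#'
#' @description
#' Greedy score-based hill climbing over DAGs (add / delete / reverse
#' moves, random restarts) provides the cheap first pass of structure
#' discovery. Its role in the pipeline is Markov-blanket extraction: the
#' genes adjacent to the anchors (parents, children, co-parents) in the
#' best climbed network become the candidate set handed to the exact
#' search.
NULL

randomStartDag <- function(nodes, maxParents) {
  ord <- sample(nodes)
  parents <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(ord)) {
    prev <- ord[seq_len(i - 1L)]
    k <- min(length(prev), maxParents)
    if (k > 0L) {
      take <- prev[stats::runif(length(prev)) < 1.5 / length(nodes)]
      if (length(take) > k) take <- take[seq_len(k)]
      parents[[ord[i]]] <- take
    } else parents[[ord[i]]] <- character(0)
  }
  parents
}

# One greedy climb from `parents`; returns list(parents, score, moves).
greedyClimb <- function(nodes, parents, scorer, maxParents, maxMoves) {
  locScore <- vapply(nodes, function(v) scorer(v, parents[[v]]), numeric(1))
  moves <- 0L
  repeat {
    if (moves >= maxMoves) break
    best <- NULL; bestDelta <- 1e-10  # strictly improving moves only
    for (y in nodes) {
      pay <- parents[[y]]
      # deletions
      for (x in pay) {
        d <- scorer(y, setdiff(pay, x)) - locScore[[y]]
        if (d > bestDelta) { bestDelta <- d; best <- list("del", x, y) }
      }
      # additions
      if (length(pay) < maxParents) {
        for (x in setdiff(nodes, c(y, pay))) {
          if (hasPath(y, x, parents)) next  # x -> y would close a cycle
          d <- scorer(y, c(pay, x)) - locScore[[y]]
          if (d > bestDelta) { bestDelta <- d; best <- list("add", x, y) }
        }
      }
      # reversals of x -> y into y -> x
      for (x in pay) {
        pax <- parents[[x]]
        if (length(pax) >= maxParents) next
        tmp <- parents; tmp[[y]] <- setdiff(pay, x)
        if (hasPath(x, y, tmp)) next  # another x ~> y path remains
        d <- (scorer(y, setdiff(pay, x)) - locScore[[y]]) +
          (scorer(x, c(pax, y)) - locScore[[x]])
        if (d > bestDelta) { bestDelta <- d; best <- list("rev", x, y) }
      }
    }
    if (is.null(best)) break
    x <- best[[2]]; y <- best[[3]]
    if (best[[1]] == "del") {
      parents[[y]] <- setdiff(parents[[y]], x)
    } else if (best[[1]] == "add") {
      parents[[y]] <- c(parents[[y]], x)
    } else {
      parents[[y]] <- setdiff(parents[[y]], x)
      parents[[x]] <- c(parents[[x]], y)
      locScore[[x]] <- scorer(x, parents[[x]])
    }
    locScore[[y]] <- scorer(y, parents[[y]])
    moves <- moves + 1L
  }
  list(parents = parents, score = sum(locScore), moves = moves)
}

#' Score-based hill climbing over DAGs
#'
#' Greedy search with add/delete/reverse moves and seeded random
#' restarts; the first restart always starts from the empty graph. Local
#' scores are computed lazily and memoized, so only visited families are
#' ever scored.
#'
#' @param mm A [MutationMatrix-class].
#' @param nodes genes to search over (default: whole panel).
#' @param score,ess score family and BDeu equivalent sample size (see
#'   [localScores()]).
#' @param maxParents in-degree cap applied during the climb (default 4).
#' @param restarts number of restarts (default 10).
#' @param maxMoves move cap per restart (default 500).
#' @param seed integer seed; restart r uses `seed + r - 1`.
#' @return list with `dag` ([GeneDag-class]), `totalScore`, and
#'   `restartScores` (per-restart best scores).
#' @export
hillClimb <- function(mm, nodes = panelGenes(mm), score = c("bdeu", "bic"),
                      ess = 1, maxParents = 4L, restarts = 10L,
                      maxMoves = 500L, seed = 1L) {
  score <- match.arg(score)
  scorer <- makeFamilyScorer(mutationCalls(mm)[, nodes, drop = FALSE],
                             score, ess)
  bestParents <- NULL; bestScore <- -Inf
  restartScores <- numeric(restarts)
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    start <- if (r == 1L)
      setNames(rep(list(character(0)), length(nodes)), nodes)
    else randomStartDag(nodes, maxParents)
    res <- greedyClimb(nodes, start, scorer, maxParents, maxMoves)
    restartScores[r] <- res$score
    if (res$score > bestScore + 1e-12 ||
        (is.null(bestParents) && is.finite(res$score))) {
      bestScore <- res$score; bestParents <- res$parents
    }
  }
  list(dag = GeneDag(nodes, bestParents), totalScore = bestScore,
       restartScores = restartScores)
}

markovBlanket <- function(dag, node) {
  pa <- dag@parents[[node]]
  ch <- names(dag@parents)[vapply(dag@parents, function(p) node %in% p,
                                  logical(1))]
  cop <- unlist(dag@parents[ch], use.names = FALSE)
  setdiff(unique(c(pa, ch, cop)), node)
}

#' Candidate neighbor genes of the anchors
#'
#' Runs [hillClimb()] on the full gene set and extracts the union of the
#' anchors' Markov blankets (parents, children, co-parents). If that
#' union exceeds `k`, the `k` genes with the largest single-gene score
#' improvement when linked to an anchor (`score(g | anchor) -
#' score(g | {})`, maximized over anchors) are kept. Anchors never count
#' against `k`.
#'
#' @inheritParams hillClimb
#' @param anchors anchor genes (e.g. `c("BRCA1", "BRCA2")`).
#' @param k maximum number of neighbors returned (default 15).
#' @return character vector of at most `k` genes, ordered by decreasing
#'   anchor-linkage score improvement (ties alphabetical), anchors
#'   excluded.
#' @export
approximateNeighbors <- function(mm, anchors, k = 15L,
                                 score = c("bdeu", "bic"), ess = 1,
                                 maxParents = 4L, restarts = 10L,
                                 maxMoves = 500L, seed = 1L) {
  score <- match.arg(score)
  stopifnot(k >= 1L, all(anchors %in% panelGenes(mm)))
  nodes <- panelGenes(mm)
  if (length(setdiff(nodes, anchors)) <= k)
    return(sort(setdiff(nodes, anchors)))
  hc <- hillClimb(mm, nodes, score = score, ess = ess,
                  maxParents = maxParents, restarts = restarts,
                  maxMoves = maxMoves, seed = seed)
  mb <- unique(unlist(lapply(anchors, function(a) markovBlanket(hc$dag, a))))
  mb <- setdiff(mb, anchors)
  scorer <- makeFamilyScorer(mutationCalls(mm), score, ess)
  gain <- vapply(mb, function(g)
    max(vapply(anchors, function(a) scorer(g, a) - scorer(g, character(0)),
               numeric(1))), numeric(1))
  ord <- order(-gain, mb)
  utils::head(mb[ord], k)
}
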