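#' @name exact-search
#' @title Globally optimal structure search over the order lattice
#'
#' @description
#' Finding the DAG that maximizes a decomposable score can be posed as a
#' shortest-path problem on the lattice of variable subsets: a state is
#' the set S of variables already placed in the topological order, and
#' appending variable v costs the best local score of v with parents
#' restricted to S. A* traversal with the admissible heuristic
#' h(S) = sum over v not in S of v's unconstrained best parent-set score
#' returns a globally score-optimal network for the supplied
#' [LocalScoreTable-class]. A brute-force labeled-DAG enumerator serves as
#' the correctness oracle at small node counts.
NULL

# --- binary max-heap keyed by (f desc, mask asc), preallocated ----------
heapNew <- function() {
  h <- new.env(parent = emptyenv())
  h$f <- numeric(1024); h$mask <- numeric(1024); h$g <- numeric(1024)
  h$n <- 0L
  h
}

heapLess <- function(h, i, j) {  # TRUE when i has strictly higher priority
  h$f[i] > h$f[j] || (h$f[i] == h$f[j] && h$mask[i] < h$mask[j])
}

heapSwap <- function(h, i, j) {
  tf <- h$f[i]; tm <- h$mask[i]; tg <- h$g[i]
  h$f[i] <- h$f[j]; h$mask[i] <- h$mask[j]; h$g[i] <- h$g[j]
  h$f[j] <- tf; h$mask[j] <- tm; h$g[j] <- tg
}

heapPush <- function(h, f, mask, g) {
  if (h$n + 1L > length(h$f)) {
    grow <- length(h$f)
    h$f <- c(h$f, numeric(grow)); h$mask <- c(h$mask, numeric(grow))
    h$g <- c(h$g, numeric(grow))
  }
  i <- h$n <- h$n + 1L
  h$f[i] <- f; h$mask[i] <- mask; h$g[i] <- g
  while (i > 1L) {
    p <- i %/% 2L
    if (heapLess(h, i, p)) { heapSwap(h, i, p); i <- p } else break
  }
}

heapPop <- function(h) {
  out <- c(h$f[1], h$mask[1], h$g[1])
  heapSwap(h, 1L, h$n)
  h$n <- h$n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L; m <- i
    if (l <= h$n && heapLess(h, l, m)) m <- l
    if (r <= h$n && heapLess(h, r, m)) m <- r
    if (m == i) break
    heapSwap(h, i, m)
    i <- m
  }
  out
}

# Best score of node v over all parent sets contained in each subset mask,
# by subset-lattice dynamic programming over the stored sets.
bestInSubsetArray <- function(stored) {
  nStates <- length(stored)
  m <- as.integer(round(log2(nStates)))
  bs <- stored
  for (i in seq_len(m) - 1L) {
    half <- bitwAnd(0:(nStates - 1L), bitwShiftL(1L, i)) > 0L
    withI <- which(half)
    bs[withI] <- pmax(bs[withI], bs[withI - bitwShiftL(1L, i)])
  }
  bs
}

# Deterministic reconstruction: smallest parent set (then lexicographic by
# bit order) achieving bs[mask + 1].
reconstructParentMask <- function(bs, mask) {
  repeat {
    target <- bs[mask + 1]
    dropped <- FALSE
    i <- 0L
    while (bitwShiftL(1L, i) <= mask) {
      bit <- bitwShiftL(1L, i)
      if (bitwAnd(mask, bit) > 0L && bs[mask - bit + 1] == target) {
        mask <- mask - bit; dropped <- TRUE; break
      }
      i <- i + 1L
    }
    if (!dropped) return(mask)
  }
}

#' Exact structure search (A* over the order lattice)
#'
#' Returns a DAG maximizing the total decomposable score of the supplied
#' table, with an optimality guarantee. States with equal f-value are
#' expanded in ascending subset order; among tied optimal parent sets the
#' smallest, then lexicographically first, is kept.
#'
#' @param table A [LocalScoreTable-class] covering all nodes (at most 25,
#'   the guard beyond which the subset lattice is impractical; use
#'   [approximateNeighbors()] first to shrink the problem).
#' @return list with `dag` ([GeneDag-class]), `totalScore`, and
#'   `expansions` (number of lattice states expanded, a diagnostic).
#' @examples
#' m <- defaultPlantedModel(seed = 3, nPatients = 600)
#' mm <- sampleCohort(m)$matrix
#' tab <- localScores(mm, c("BRCA1", "BRCA2", "NOTCH1"), maxParents = 2)
#' exactSearch(tab)$totalScore
#' @export
exactSearch <- function(table) {
  nodes <- table@nodes
  m <- length(nodes)
  if (m > 25L) stop("exact search guarded at 25 nodes; got ", m,
                    " - use approximate neighbor discovery first")
  nStates <- 2L^m
  full <- nStates - 1L
  # stored scores as arrays over parent-set masks
  keyMask <- function(key) {
    if (identical(key, "{}")) return(0L)
    sum(bitwShiftL(1L, match(strsplit(key, ";", fixed = TRUE)[[1]], nodes) - 1L))
  }
  bs <- vector("list", m)
  for (vi in seq_len(m)) {
    stored <- rep(-Inf, nStates)
    sv <- table@scores[[nodes[vi]]]
    masks <- vapply(names(sv), keyMask, integer(1))
    stored[masks + 1L] <- unname(sv)
    bs[[vi]] <- bestInSubsetArray(stored)
  }
  hBest <- vapply(seq_len(m), function(vi)
    bs[[vi]][full - bitwShiftL(1L, vi - 1L) + 1L], numeric(1))
  hOf <- function(mask) {
    out <- 0
    for (vi in seq_len(m))
      if (bitwAnd(mask, bitwShiftL(1L, vi - 1L)) == 0L) out <- out + hBest[vi]
    out
  }
  g <- rep(-Inf, nStates); g[1] <- 0
  pred <- rep(NA_integer_, nStates)
  closed <- rep(FALSE, nStates)
  h <- heapNew()
  heapPush(h, hOf(0L), 0L, 0)
  expansions <- 0L
  while (h$n > 0L) {
    top <- heapPop(h)
    mask <- as.integer(top[2])
    if (closed[mask + 1L] || top[3] < g[mask + 1L]) next
    closed[mask + 1L] <- TRUE
    if (mask == full) break
    expansions <- expansions + 1L
    for (vi in seq_len(m)) {
      bit <- bitwShiftL(1L, vi - 1L)
      if (bitwAnd(mask, bit) > 0L) next
      g2 <- g[mask + 1L] + bs[[vi]][mask + 1L]
      nmask <- mask + bit
      if (g2 > g[nmask + 1L]) {
        g[nmask + 1L] <- g2
        pred[nmask + 1L] <- vi
        heapPush(h, g2 + hOf(nmask), nmask, g2)
      }
    }
  }
  if (!is.finite(g[full + 1L])) stop("search failed: incomplete score table")
  # walk back the optimal insertion order, recovering parent sets
  parents <- setNames(rep(list(character(0)), m), nodes)
  mask <- full
  while (mask > 0L) {
    vi <- pred[mask + 1L]
    prev <- mask - bitwShiftL(1L, vi - 1L)
    pmask <- reconstructParentMask(bs[[vi]], prev)
    parents[[nodes[vi]]] <- nodes[which(bitwAnd(pmask,
                                                bitwShiftL(1L, seq_len(m) - 1L)) > 0L)]
    mask <- prev
  }
  list(dag = GeneDag(nodes, parents), totalScore = g[full + 1L],
       expansions = expansions)
}

#' Enumerate every labeled DAG on a small node set
#'
#' Brute-force generator used as the optimality oracle for
#' [exactSearch()]: all directed edge subsets are generated and the
#' acyclic ones kept (3 DAGs on 2 nodes, 25 on 3, 543 on 4).
#'
#' @param nodes character vector of at most 5 node names.
#' @return list of [GeneDag-class] objects, each labeled DAG exactly once.
#' @export
enumerateAllDags <- function(nodes) {
  m <- length(nodes)
  if (m > 5L) stop("enumeration limited to 5 nodes")
  if (m == 0L) return(list())
  pairs <- which(matrix(TRUE, m, m) & !diag(m), arr.ind = TRUE)
  ne <- nrow(pairs)
  out <- list()
  for (code in 0:(2^ne - 1)) {
    sel <- bitwAnd(code, bitwShiftL(1L, seq_len(ne) - 1L)) > 0L
    parents <- setNames(rep(list(character(0)), m), nodes)
    for (e in which(sel))
      parents[[nodes[pairs[e, 2]]]] <-
        c(parents[[nodes[pairs[e, 2]]]], nodes[pairs[e, 1]])
    if (!is.null(topoSortOrNull(nodes, parents)))
      out[[length(out) + 1L]] <- new("GeneDag", nodes = nodes,
                                     parents = parents)
  }
  out
}
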