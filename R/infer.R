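#' @name inference
#' @title Parameter fitting and probabilistic inference
#'
#' @description
#' Given a learned structure, conditional probability tables are fitted by
#' Dirichlet-smoothed frequencies (pseudo-count 1 by default, so no factor
#' is ever exactly 0 or 1). Queries are answered either exactly, by
#' sum-product variable elimination in a min-degree order, or by loopy
#' belief propagation on the network's factor graph (synchronous flooding
#' schedule with message damping) - the latter exact on trees and
#' approximate in the presence of cycles.
NULL

#' Fit conditional probability tables
#'
#' P(node = 1 | config) = (count(node = 1, config) + pseudo) /
#' (count(config) + 2 pseudo); parent configurations never observed get
#' the pure prior 0.5.
#'
#' @param mm A [MutationMatrix-class].
#' @param dag A [GeneDag-class] over matrix genes.
#' @param pseudoCount positive Dirichlet pseudo-count (default 1).
#' @return A [CptSet-class].
#' @export
fitCpts <- function(mm, dag, pseudoCount = 1) {
  stopifnot(pseudoCount > 0, all(dag@nodes %in% panelGenes(mm)))
  mat <- mutationCalls(mm)
  cpts <- setNames(vector("list", length(dag@nodes)), dag@nodes)
  for (v in dag@nodes) {
    pa <- dag@parents[[v]]
    counts <- familyCounts(mat, v, pa)
    p1 <- (counts[2, ] + pseudoCount) / (colSums(counts) + 2 * pseudoCount)
    cpts[[v]] <- list(parents = pa, p1 = as.numeric(p1))
  }
  CptSet(cpts, pseudoCount = pseudoCount)
}

# ---- factor algebra (tables over binary variables, vars[1] = LSB) ------

factorNew <- function(vars, table) list(vars = vars, table = table)

cptFactor <- function(node, entry) {
  vars <- c(node, entry$parents)
  k <- length(entry$parents)
  tab <- numeric(2^(k + 1))
  for (cfg in 0:(2^k - 1)) {
    tab[2 * cfg + 1] <- 1 - entry$p1[cfg + 1]   # node = 0
    tab[2 * cfg + 2] <- entry$p1[cfg + 1]       # node = 1
  }
  factorNew(vars, tab)
}

factorBits <- function(f, var) {
  pos <- match(var, f$vars)
  states <- 0:(length(f$table) - 1)
  states %/% 2^(pos - 1) %% 2
}

factorReduce <- function(f, var, val) {
  keep <- factorBits(f, var) == val
  pos <- match(var, f$vars)
  factorNew(f$vars[-pos], reindexDrop(f$table[keep], length(f$vars), pos))
}

# After subsetting the table rows where `pos` has a fixed value, the
# remaining entries are already in the induced order; identity reindex.
reindexDrop <- function(table, nvars, pos) table

factorMarginalize <- function(f, var) {
  pos <- match(var, f$vars)
  bits <- factorBits(f, var)
  factorNew(f$vars[-pos], f$table[bits == 0] + f$table[bits == 1])
}

factorProduct <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  m <- length(vars)
  states <- 0:(2^m - 1)
  idxOf <- function(f) {
    idx <- rep.int(0, length(states))
    for (j in seq_along(f$vars)) {
      pos <- match(f$vars[j], vars)
      idx <- idx + (states %/% 2^(pos - 1) %% 2) * 2^(j - 1)
    }
    idx + 1
  }
  factorNew(vars, f1$table[idxOf(f1)] * f2$table[idxOf(f2)])
}

# Sum-product elimination of `elim` variables from a factor list; returns
# the reduced factor list (evidence must already be absorbed).
eliminateVars <- function(factors, elim) {
  for (step in seq_along(elim)) {
    # min-degree: pick the variable whose elimination touches the
    # smallest combined scope
    degrees <- vapply(elim, function(v) {
      sc <- unique(unlist(lapply(factors,
                                 function(f) if (v %in% f$vars) f$vars),
                          use.names = FALSE))
      length(sc)
    }, numeric(1))
    v <- elim[order(degrees, elim)[1]]
    elim <- setdiff(elim, v)
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod <- Reduce(factorProduct, factors[touch])
    factors <- c(factors[!touch], list(factorMarginalize(prod, v)))
    if (!length(elim)) break
  }
  factors
}

collapseFactors <- function(factors) Reduce(factorProduct, factors)

#' Exact conditional probability by variable elimination
#'
#' @param dag A [GeneDag-class].
#' @param cpts A [CptSet-class] matching `dag`.
#' @param evidence named vector of observed 0/1 states (may be empty).
#' @param query gene whose marginal P(query = 1 | evidence) is wanted;
#'   must not itself be in the evidence.
#' @return the conditional probability, a single numeric.
#' @export
variableElimination <- function(dag, cpts, evidence = integer(0), query) {
  ev <- evidence
  if (query %in% names(ev)) stop("query gene appears in the evidence")
  stopifnot(query %in% dag@nodes, all(names(ev) %in% dag@nodes))
  nodes <- ancestralClosure(dag, c(query, names(ev)))
  factors <- lapply(nodes, function(v) cptFactor(v, cpts@cpts[[v]]))
  for (e in names(ev)) {
    factors <- lapply(factors, function(f)
      if (e %in% f$vars) factorReduce(f, e, ev[[e]]) else f)
  }
  factors <- factors[vapply(factors, function(f) length(f$table) > 0,
                            logical(1))]
  elim <- setdiff(nodes, c(query, names(ev)))
  factors <- eliminateVars(factors, elim)
  out <- collapseFactors(factors)
  # scalar factors (fully reduced) multiply into the normalization
  if (length(out$vars) == 0)
    stop("evidence event has probability 0 or query eliminated")
  z <- sum(out$table)
  if (z <= 0) stop("evidence event has probability 0")
  pos <- match(query, out$vars)
  bits <- factorBits(out, query)
  sum(out$table[bits == 1]) / z
}

# P(evidence) under the network, by eliminating everything else.
jointProbEvidence <- function(dag, cpts, evidence) {
  stopifnot(length(evidence) >= 1, all(names(evidence) %in% dag@nodes))
  nodes <- ancestralClosure(dag, names(evidence))
  factors <- lapply(nodes, function(v) cptFactor(v, cpts@cpts[[v]]))
  for (e in names(evidence))
    factors <- lapply(factors, function(f)
      if (e %in% f$vars) factorReduce(f, e, evidence[[e]]) else f)
  elim <- setdiff(nodes, names(evidence))
  factors <- eliminateVars(factors, elim)
  prod(vapply(factors, function(f) sum(f$table), numeric(1)))
}

#' Build the factor graph of a fitted network
#'
#' One variable vertex per gene and one factor per node family (child
#' plus parents), the structure on which [loopyBP()] passes messages.
#'
#' @param dag A [GeneDag-class].
#' @param cpts A [CptSet-class] matching `dag`.
#' @return A [FactorGraph-class].
#' @export
buildFactorGraph <- function(dag, cpts) {
  factors <- lapply(dag@nodes, function(v) {
    f <- cptFactor(v, cpts@cpts[[v]])
    f$name <- paste0("phi_", v)
    f
  })
  new("FactorGraph", vars = dag@nodes, factors = factors)
}

#' Loopy belief propagation (synchronous flooding sum-product)
#'
#' Damped synchronous message passing until the largest absolute message
#' change falls below `tol` or `maxIters` is reached. Exact on
#' tree-structured graphs; approximate when the factor graph has cycles.
#' Evidence is absorbed by zeroing inconsistent factor entries; evidence
#' that contradicts a zero-probability configuration raises an error
#' naming the factor.
#'
#' @param graph A [FactorGraph-class].
#' @param evidence named vector of observed 0/1 states.
#' @param maxIters iteration cap (default 200).
#' @param tol convergence tolerance on message change (default 1e-8).
#' @param damping fraction of the old message retained (default 0.5).
#' @return list with `beliefs` (matrix, one row per variable, columns
#'   `p0`/`p1`), `converged` (logical) and `iters`.
#' @export
loopyBP <- function(graph, evidence = integer(0), maxIters = 200L,
                    tol = 1e-8, damping = 0.5) {
  vars <- graph@vars
  stopifnot(all(names(evidence) %in% vars))
  factors <- graph@factors
  for (e in names(evidence)) {
    for (i in seq_along(factors)) {
      f <- factors[[i]]
      if (e %in% f$vars) {
        f$table[factorBits(f, e) != evidence[[e]]] <- 0
        if (all(f$table == 0))
          stop("evidence contradicts factor ", f$name)
        factors[[i]] <- f
      }
    }
  }
  # message containers: per factor, per scope variable, both directions
  fv <- lapply(factors, function(f)
    matrix(0.5, length(f$vars), 2, dimnames = list(f$vars, NULL)))
  vf <- fv
  touching <- lapply(vars, function(v)
    which(vapply(factors, function(f) v %in% f$vars, logical(1))))
  names(touching) <- vars
  converged <- FALSE; iter <- 0L
  while (iter < maxIters) {
    iter <- iter + 1L
    delta <- 0
    # factor -> variable, from last iteration's variable -> factor
    newFv <- fv
    for (i in seq_along(factors)) {
      f <- factors[[i]]
      for (v in f$vars) {
        w <- f$table
        for (u in setdiff(f$vars, v)) {
          bits <- factorBits(f, u)
          w <- w * vf[[i]][u, bits + 1]
        }
        bits <- factorBits(f, v)
        msg <- c(sum(w[bits == 0]), sum(w[bits == 1]))
        s <- sum(msg)
        msg <- if (s > 0) msg / s else c(0.5, 0.5)
        msg <- damping * fv[[i]][v, ] + (1 - damping) * msg
        msg <- msg / sum(msg)
        delta <- max(delta, max(abs(msg - fv[[i]][v, ])))
        newFv[[i]][v, ] <- msg
      }
    }
    # variable -> factor, from the just-computed factor -> variable
    newVf <- vf
    for (v in vars) {
      ids <- touching[[v]]
      for (i in ids) {
        msg <- c(1, 1)
        for (j in setdiff(ids, i)) msg <- msg * newFv[[j]][v, ]
        s <- sum(msg)
        msg <- if (s > 0) msg / s else c(0.5, 0.5)
        msg <- damping * vf[[i]][v, ] + (1 - damping) * msg
        msg <- msg / sum(msg)
        delta <- max(delta, max(abs(msg - vf[[i]][v, ])))
        newVf[[i]][v, ] <- msg
      }
    }
    fv <- newFv; vf <- newVf
    if (delta < tol) { converged <- TRUE; break }
  }
  beliefs <- t(vapply(vars, function(v) {
    b <- c(1, 1)
    for (i in touching[[v]]) b <- b * fv[[i]][v, ]
    b / sum(b)
  }, numeric(2)))
  dimnames(beliefs) <- list(vars, c("p0", "p1"))
  list(beliefs = beliefs, converged = converged, iters = iter)
}
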