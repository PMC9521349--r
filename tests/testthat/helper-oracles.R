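# Independent oracles and small fixtures, written without reference to the
# package's internal code paths.

# --- brute-force joint distribution of a binary Bayesian network --------
# cpts: named list of list(parents =, p1 =) with first parent = LSB.
# Returns a data.frame of all assignments plus their probability, by
# plain per-assignment looping.
bruteForceJoint <- function(nodes, cpts) {
  m <- length(nodes)
  grid <- as.matrix(expand.grid(rep(list(0:1), m)))
  colnames(grid) <- nodes
  probs <- apply(grid, 1, function(a) {
    p <- 1
    for (v in nodes) {
      e <- cpts[[v]]
      cfg <- 0
      for (j in seq_along(e$parents))
        cfg <- cfg + a[[e$parents[j]]] * 2^(j - 1)
      pv <- e$p1[cfg + 1]
      p <- p * if (a[[v]] == 1) pv else 1 - pv
    }
    p
  })
  cbind(as.data.frame(grid), prob = probs)
}

# Exact P(query = 1 | evidence) from the brute-force joint.
bruteForceConditional <- function(nodes, cpts, evidence, query) {
  jt <- bruteForceJoint(nodes, cpts)
  keep <- rep(TRUE, nrow(jt))
  for (e in names(evidence)) keep <- keep & jt[[e]] == evidence[[e]]
  sum(jt$prob[keep & jt[[query]] == 1]) / sum(jt$prob[keep])
}

# --- two-sided Fisher p by explicit hypergeometric enumeration ----------
# Point probabilities from binomial coefficients (lchoose), not dhyper.
fisherOracle <- function(a, b, c, d) {
  m1 <- a + b; n <- a + b + c + d; k <- a + c
  if (m1 == 0 || k == 0 || m1 == n || k == n) return(1)
  lo <- max(0, k - (n - m1)); hi <- min(m1, k)
  logp <- vapply(lo:hi, function(x)
    lchoose(m1, x) + lchoose(n - m1, k - x) - lchoose(n, k), numeric(1))
  p <- exp(logp)
  pObs <- exp(lchoose(m1, a) + lchoose(n - m1, k - a) - lchoose(n, k))
  min(1, sum(p[p <= pObs * (1 + 1e-7)]))
}

# --- random model generators -------------------------------------------
# Random DAG over nNodes with expected extra edges; CPT probabilities
# drawn uniformly inside [lo, hi] to avoid near-deterministic factors.
randomDagModel <- function(nNodes, maxParents = 3, edgeProb = 2 / nNodes,
                           lo = 0.1, hi = 0.9) {
  nodes <- sprintf("G%02d", seq_len(nNodes))
  parents <- setNames(rep(list(character(0)), nNodes), nodes)
  for (i in seq_len(nNodes)[-1]) {
    prev <- nodes[seq_len(i - 1)]
    pick <- prev[stats::runif(length(prev)) < edgeProb]
    if (length(pick) > maxParents) pick <- sample(pick, maxParents)
    parents[[nodes[i]]] <- pick
  }
  cpts <- lapply(nodes, function(v) {
    k <- length(parents[[v]])
    list(parents = parents[[v]], p1 = stats::runif(2^k, lo, hi))
  })
  names(cpts) <- nodes
  list(nodes = nodes, parents = parents, cpts = cpts)
}

# Random polytree: random undirected tree, edges oriented by a random
# node permutation (guaranteeing acyclicity and singly connected factor
# graph).
randomPolytreeModel <- function(nNodes, lo = 0.1, hi = 0.9) {
  nodes <- sprintf("G%02d", seq_len(nNodes))
  ord <- sample(nodes)
  parents <- setNames(rep(list(character(0)), nNodes), nodes)
  if (nNodes > 1) for (i in 2:nNodes) {
    j <- sample(i - 1, 1)  # attach to an earlier node in the permutation
    parents[[ord[i]]] <- ord[j]
  }
  cpts <- lapply(nodes, function(v) {
    k <- length(parents[[v]])
    list(parents = parents[[v]], p1 = stats::runif(2^k, lo, hi))
  })
  names(cpts) <- nodes
  list(nodes = nodes, parents = parents, cpts = cpts)
}

asPlanted <- function(model, n = 1000L, seed = 1L)
  PlantedModel(GeneDag(model$nodes, model$parents), CptSet(model$cpts),
               nPatients = n, seed = seed)

# Random binary data matrix with independent columns (for score tests).
randomBinaryMatrix <- function(n, genes, p = 0.4) {
  mat <- matrix(stats::rbinom(n * length(genes), 1L, p), n, length(genes),
                dimnames = list(sprintf("P%04d", seq_len(n)), genes))
  MutationMatrix(mat)
}

# Six-patient toy matrix used in hand-count tests.
toyMatrix <- function() {
  mat <- matrix(c(1, 1, 0, 0, 1, 0,
                  1, 0, 1, 0, 0, 0,
                  0, 1, 1, 1, 0, 0), 6, 3,
                dimnames = list(sprintf("P%d", 1:6), c("A", "B", "C")))
  MutationMatrix(mat)
}

plantedPartners <- c("ERBB2", "NOTCH1", "AKT1", "MTOR", "ARID1A", "EGFR")

# Sparse loopy model: random polytree plus `extra` additional edges that
# keep the graph acyclic (each closes at least one factor-graph loop).
sparseLoopyModel <- function(nNodes, extra = 1, lo = 0.15, hi = 0.85) {
  model <- randomPolytreeModel(nNodes, lo, hi)
  nodes <- model$nodes
  isAcyclic <- function(parents) {
    indeg <- vapply(nodes, function(v) length(parents[[v]]), integer(1))
    done <- character(0); q <- nodes[indeg == 0]
    while (length(q)) {
      v <- q[1]; q <- q[-1]; done <- c(done, v)
      for (w in nodes) if (v %in% parents[[w]]) {
        indeg[[w]] <- indeg[[w]] - 1L
        if (indeg[[w]] == 0L) q <- c(q, w)
      }
    }
    length(done) == length(nodes)
  }
  for (e in seq_len(extra)) {
    repeat {
      fr <- sample(nodes, 1); to <- sample(setdiff(nodes, fr), 1)
      if (fr %in% model$parents[[to]]) next
      p <- model$parents; p[[to]] <- c(p[[to]], fr)
      if (length(p[[to]]) <= 3 && isAcyclic(p)) { model$parents <- p; break }
    }
  }
  model$cpts <- lapply(nodes, function(v) {
    k <- length(model$parents[[v]])
    list(parents = model$parents[[v]], p1 = stats::runif(2^k, lo, hi))
  })
  names(model$cpts) <- nodes
  model
}

# Independent textbook sum-product implementation (array-based sweep/apply
# message passer, fixed iteration count); used to cross-check the
# package's belief-propagation fixed point on loopy graphs.
referenceBP <- function(dag, cpts, iters = 400) {
  nodes <- dagNodes(dag)
  facs <- lapply(nodes, function(v) {
    e <- cpts@cpts[[v]]; vars <- c(v, e$parents); k <- length(vars)
    tab <- array(0, rep(2, k))
    idx <- as.matrix(expand.grid(rep(list(1:2), k)))
    for (r in seq_len(nrow(idx))) {
      cfg <- sum((idx[r, -1, drop = FALSE] - 1) * 2^(seq_len(k - 1) - 1))
      p1 <- e$p1[cfg + 1]
      tab[matrix(idx[r, ], 1)] <- if (idx[r, 1] == 2) p1 else 1 - p1
    }
    list(vars = vars, tab = tab)
  })
  mfv <- list(); mvf <- list()
  for (i in seq_along(facs)) for (v in facs[[i]]$vars) {
    mfv[[paste(i, v)]] <- c(0.5, 0.5); mvf[[paste(v, i)]] <- c(0.5, 0.5)
  }
  touch <- lapply(nodes, function(v)
    which(vapply(facs, function(f) v %in% f$vars, TRUE)))
  names(touch) <- nodes
  for (it in seq_len(iters)) {
    for (i in seq_along(facs)) {
      f <- facs[[i]]
      for (v in f$vars) {
        t <- f$tab
        for (u in f$vars) if (u != v)
          t <- sweep(t, match(u, f$vars), mvf[[paste(u, i)]], "*")
        out <- apply(t, match(v, f$vars), sum)
        mfv[[paste(i, v)]] <- out / sum(out)
      }
    }
    for (v in nodes) for (i in touch[[v]]) {
      msg <- c(1, 1)
      for (j in setdiff(touch[[v]], i)) msg <- msg * mfv[[paste(j, v)]]
      mvf[[paste(v, i)]] <- msg / sum(msg)
    }
  }
  sapply(nodes, function(v) {
    b <- c(1, 1)
    for (i in touch[[v]]) b <- b * mfv[[paste(i, v)]]
    (b / sum(b))[2]
  })
}
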