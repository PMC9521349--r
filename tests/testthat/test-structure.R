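test_that("BIC local scores match the closed form for root nodes", {
  set.seed(42)
  n <- 500; k <- 120
  col <- c(rep(1L, k), rep(0L, n - k))
  mat <- cbind(X = sample(col), Y = rbinom(n, 1, 0.5))
  rownames(mat) <- sprintf("P%03d", seq_len(n))
  mm <- MutationMatrix(mat)
  tab <- localScores(mm, c("X", "Y"), score = "bic", maxParents = 1)
  p <- k / n
  expect_equal(unname(tab@scores$X["{}"]),
               n * (p * log(p) + (1 - p) * log(1 - p)) - log(n) / 2,
               tolerance = 1e-10)
  # duplicating every row doubles the likelihood term and swaps the penalty
  mat2 <- rbind(mat, mat)
  rownames(mat2) <- sprintf("Q%04d", seq_len(2 * n))
  mm2 <- MutationMatrix(mat2)
  tab2 <- localScores(mm2, c("X", "Y"), score = "bic", maxParents = 1)
  ll <- unname(tab@scores$X["{}"]) + log(n) / 2
  expect_equal(unname(tab2@scores$X["{}"]), 2 * ll - log(2 * n) / 2,
               tolerance = 1e-8)
})

test_that("a constant parent adds only the BIC parameter penalty", {
  set.seed(7)
  mat <- cbind(V = rbinom(300, 1, 0.3), CONST = 0L)
  rownames(mat) <- sprintf("P%03d", 1:300)
  mm <- MutationMatrix(mat)
  tab <- localScores(mm, c("V", "CONST"), score = "bic", maxParents = 1)
  expect_equal(unname(tab@scores$V["CONST"]),
               unname(tab@scores$V["{}"]) - log(300) / 2, tolerance = 1e-10)
})

test_that("BDeu scores are equal across Markov-equivalent structures", {
  set.seed(11)
  m <- plantedModelFromMarginals(c(X = 0.3, Y = 0.4), nPatients = 400,
                                 seed = 11)
  mm <- sampleCohort(m, trueRRQueries = list())$matrix
  tab <- localScores(mm, c("X", "Y"), score = "bdeu", ess = 1, maxParents = 1)
  sXY <- scoreDag(tab, GeneDag(c("X", "Y"), list(Y = "X")))
  sYX <- scoreDag(tab, GeneDag(c("X", "Y"), list(X = "Y")))
  expect_equal(sXY, sYX, tolerance = 1e-9)
})

test_that("maxParents is capped at the node count with a warning", {
  mm <- randomBinaryMatrix(50, c("A", "B", "C"))
  expect_warning(tab <- localScores(mm, score = "bdeu", maxParents = 5),
                 "capped")
  expect_equal(tab@maxParents, 2L)
})

test_that("the labeled-DAG enumerator produces the known counts", {
  expect_equal(length(enumerateAllDags(c("A", "B"))), 3L)
  d3 <- enumerateAllDags(c("A", "B", "C"))
  expect_equal(length(d3), 25L)
  expect_equal(length(enumerateAllDags(c("A", "B", "C", "D"))), 543L)
  # the edgeless DAG is present exactly once, and all DAGs are distinct
  keys <- vapply(d3, function(d)
    paste(vapply(dagNodes(d), function(v)
      paste0(v, "<", parentSetKey(dagParents(d)[[v]])), character(1)),
      collapse = "|"), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_equal(sum(vapply(d3, function(d) sum(lengths(dagParents(d))) == 0,
                          logical(1))), 1L)
  expect_error(enumerateAllDags(sprintf("N%d", 1:6)), "5 nodes")
})

test_that("exact search equals exhaustive enumeration on small problems", {
  # single node: empty DAG, empty-parent score
  mm1 <- randomBinaryMatrix(60, "solo")
  tab1 <- localScores(mm1, "solo", maxParents = 0)
  sr1 <- exactSearch(tab1)
  expect_equal(sr1$totalScore, unname(tab1@scores$solo["{}"]))
  expect_equal(lengths(dagParents(sr1$dag))[["solo"]], 0L)
  # planted 3-node dependency
  set.seed(5)
  cpts <- list(X = list(parents = character(0), p1 = 0.5),
               Y = list(parents = "X", p1 = c(0.15, 0.85)),
               Z = list(parents = character(0), p1 = 0.3))
  m <- PlantedModel(GeneDag(c("X", "Y", "Z"), list(Y = "X")), CptSet(cpts),
                    nPatients = 200L, seed = 5L)
  mm <- sampleCohort(m, trueRRQueries = list())$matrix
  tab <- localScores(mm, c("X", "Y", "Z"), maxParents = 2)
  sr <- exactSearch(tab)
  best <- max(vapply(enumerateAllDags(c("X", "Y", "Z")),
                     function(d) scoreDag(tab, d), numeric(1)))
  expect_equal(sr$totalScore, best, tolerance = 1e-9)
  expect_equal(scoreDag(tab, sr$dag), sr$totalScore, tolerance = 1e-9)
  # learned structure links X and Y (either orientation)
  expect_true("X" %in% dagParents(sr$dag)$Y || "Y" %in% dagParents(sr$dag)$X)
})

test_that("exact search is never beaten by hill climbing", {
  set.seed(19)
  for (rep in 1:3) {
    model <- randomDagModel(5, maxParents = 2)
    mm <- sampleCohort(asPlanted(model, n = 300, seed = rep),
                       trueRRQueries = list())$matrix
    tab <- localScores(mm, model$nodes, maxParents = 3)
    sr <- exactSearch(tab)
    hc <- hillClimb(mm, model$nodes, maxParents = 3, restarts = 4,
                    seed = rep)
    expect_gte(sr$totalScore + 1e-9, hc$totalScore)
    # and the exact optimum matches exhaustive enumeration on 4 of 5 nodes
    sub <- model$nodes[1:4]
    tab4 <- localScores(mm, sub, maxParents = 3)
    best4 <- max(vapply(enumerateAllDags(sub),
                        function(d) scoreDag(tab4, d), numeric(1)))
    expect_equal(exactSearch(tab4)$totalScore, best4, tolerance = 1e-9)
  }
})

test_that("hill climbing is deterministic under a fixed seed", {
  m <- defaultPlantedModel(seed = 13, nPatients = 1200)
  mm <- sampleCohort(m)$matrix
  nodes <- c("BRCA1", "BRCA2", "NOTCH1", "ARID1A", "TP53", "AR")
  h1 <- hillClimb(mm, nodes, restarts = 3, seed = 99)
  h2 <- hillClimb(mm, nodes, restarts = 3, seed = 99)
  expect_identical(dagParents(h1$dag), dagParents(h2$dag))
  expect_identical(h1$totalScore, h2$totalScore)
})

test_that("a single dominant partner is found at k = 1", {
  cpts <- list(ANCHOR = list(parents = character(0), p1 = 0.3),
               STRONG = list(parents = "ANCHOR", p1 = c(0.05, 0.5)),
               NOISE1 = list(parents = character(0), p1 = 0.2),
               NOISE2 = list(parents = character(0), p1 = 0.1))
  m <- PlantedModel(GeneDag(names(cpts), list(STRONG = "ANCHOR")),
                    CptSet(cpts), nPatients = 3000L, seed = 21L)
  mm <- sampleCohort(m, trueRRQueries = list())$matrix
  nb <- approximateNeighbors(mm, "ANCHOR", k = 1, seed = 21)
  expect_identical(nb, "STRONG")
})

test_that("independent anchors yield no screen-significant neighbors", {
  m <- plantedModelFromMarginals(
    c(BRCA1 = 0.05, BRCA2 = 0.08, G1 = 0.1, G2 = 0.2, G3 = 0.15,
      G4 = 0.3, G5 = 0.12, G6 = 0.07), nPatients = 4000, seed = 17)
  mm <- sampleCohort(m, trueRRQueries = list())$matrix
  nb <- approximateNeighbors(mm, c("BRCA1", "BRCA2"), k = 3, seed = 17)
  if (length(nb)) {
    scr <- screenAssociations(mm, "BRCA1",
                              setdiff(panelGenes(mm), c("BRCA1", "BRCA2")))
    expect_false(any(scr$significant[scr$gene %in% nb]))
  }
  succeed()
})

test_that("the learned skeleton connects the hub to its planted partners", {
  m <- defaultPlantedModel(seed = 23, nPatients = 7707)
  mm <- sampleCohort(m)$matrix
  nb <- approximateNeighbors(mm, c("BRCA1", "BRCA2"), k = 15, seed = 23)
  tab <- localScores(mm, c("BRCA1", "BRCA2", nb))
  sr <- exactSearch(tab)
  adj <- moralizedSkeleton(sr$dag)
  linked <- intersect(plantedPartners, colnames(adj))
  expect_gte(sum(adj["BRCA1", linked]), 5L)
})
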