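test_that("CPT fitting applies Dirichlet smoothing as stated", {
  set.seed(3)
  col <- sample(c(rep(1L, 46), rep(0L, 954)))
  mat <- cbind(G = col, H = rbinom(1000, 1, 0.5))
  rownames(mat) <- sprintf("P%04d", 1:1000)
  mm <- MutationMatrix(mat)
  cpts <- fitCpts(mm, GeneDag(c("G", "H")), pseudoCount = 1)
  expect_equal(cpts@cpts$G$p1, 47 / 1002, tolerance = 1e-12)
  # unseen parent configuration falls back to the pure prior 0.5
  mat2 <- cbind(PA = 0L, CH = rbinom(1000, 1, 0.3))
  rownames(mat2) <- rownames(mat)
  cpts2 <- fitCpts(MutationMatrix(mat2), GeneDag(c("PA", "CH"),
                                                 list(CH = "PA")))
  expect_equal(cpts2@cpts$CH$p1[2], 0.5)
  # vanishing pseudo-count recovers the empirical frequency
  cpts3 <- fitCpts(mm, GeneDag(c("G", "H")), pseudoCount = 1e-9)
  expect_equal(cpts3@cpts$G$p1, 0.046, tolerance = 1e-9)
})

test_that("variable elimination equals full joint enumeration", {
  set.seed(29)
  for (rep in 1:8) {
    model <- randomDagModel(sample(4:9, 1))
    dag <- GeneDag(model$nodes, model$parents)
    cpts <- CptSet(model$cpts)
    q <- sample(model$nodes, 1)
    evGenes <- sample(setdiff(model$nodes, q), sample(0:2, 1))
    ev <- setNames(sample(0:1, length(evGenes), replace = TRUE), evGenes)
    expect_equal(variableElimination(dag, cpts, ev, q),
                 bruteForceConditional(model$nodes, model$cpts, ev, q),
                 tolerance = 1e-12)
  }
  # independent nodes: evidence elsewhere never moves the prior
  m <- plantedModelFromMarginals(c(A = 0.2, B = 0.7))
  expect_equal(variableElimination(m@dag, m@cpts, c(B = 1), "A"), 0.2,
               tolerance = 1e-12)
  # degenerate self-query is rejected
  expect_error(variableElimination(m@dag, m@cpts, c(A = 1), "A"), "evidence")
})

test_that("belief propagation is exact on edgeless and chain networks", {
  m <- plantedModelFromMarginals(c(A = 0.2, B = 0.7, C = 0.45))
  bp <- loopyBP(buildFactorGraph(m@dag, m@cpts))
  expect_true(bp$converged)
  expect_equal(unname(bp$beliefs[, "p1"]), c(0.2, 0.7, 0.45),
               tolerance = 1e-7)
  # chain A -> B -> C with evidence A = 1
  cpts <- list(A = list(parents = character(0), p1 = 0.3),
               B = list(parents = "A", p1 = c(0.2, 0.7)),
               C = list(parents = "B", p1 = c(0.1, 0.6)))
  dag <- GeneDag(c("A", "B", "C"), list(B = "A", C = "B"))
  cs <- CptSet(cpts)
  bp2 <- loopyBP(buildFactorGraph(dag, cs), evidence = c(A = 1L),
                 tol = 1e-12, maxIters = 500)
  expect_true(bp2$converged)
  expect_equal(unname(bp2$beliefs["C", "p1"]),
               variableElimination(dag, cs, c(A = 1L), "C"),
               tolerance = 1e-8)
  # beliefs are normalized
  expect_equal(unname(rowSums(bp2$beliefs)), rep(1, 3), tolerance = 1e-12)
})

test_that("belief propagation matches exact inference on random polytrees", {
  set.seed(31)
  for (rep in 1:10) {
    model <- randomPolytreeModel(sample(4:8, 1))
    dag <- GeneDag(model$nodes, model$parents)
    cpts <- CptSet(model$cpts)
    bp <- loopyBP(buildFactorGraph(dag, cpts), tol = 1e-12, maxIters = 500)
    expect_true(bp$converged)
    for (v in model$nodes)
      expect_equal(unname(bp$beliefs[v, "p1"]),
                   variableElimination(dag, cpts, integer(0), v),
                   tolerance = 1e-8)
  }
})

test_that("BP reaches the same fixed point as an independent message passer", {
  set.seed(61)
  for (rep in 1:3) {
    model <- sparseLoopyModel(7, extra = 2)
    dag <- GeneDag(model$nodes, model$parents)
    cpts <- CptSet(model$cpts)
    bp <- loopyBP(buildFactorGraph(dag, cpts), tol = 1e-12, maxIters = 2000)
    expect_true(bp$converged)
    ref <- referenceBP(dag, cpts, iters = 400)
    expect_equal(unname(bp$beliefs[model$nodes, "p1"]),
                 unname(ref[model$nodes]), tolerance = 1e-9)
  }
})

test_that("contradictory evidence names the offending factor", {
  cpts <- list(A = list(parents = character(0), p1 = 0.5),
               B = list(parents = "A", p1 = c(0.2, 1 - 1e-12)))
  dag <- GeneDag(c("A", "B"), list(B = "A"))
  fg <- buildFactorGraph(dag, CptSet(cpts))
  # make the near-deterministic entries exactly zero
  fg@factors[[2]]$table[fg@factors[[2]]$table < 1e-6] <- 0
  expect_error(loopyBP(fg, evidence = c(A = 1L, B = 0L)), "phi_B")
})

test_that("model-based relative risk has the stated limiting behavior", {
  # independence: RR exactly 1 in both directions
  m <- plantedModelFromMarginals(c(A = 0.2, B = 0.7, C = 0.1))
  for (dir in c("anchor_given_genes", "genes_given_anchor"))
    expect_equal(riskRatio(relativeRisk(m@dag, m@cpts, "A", c("B", "C"),
                                        direction = dir)), 1,
                 tolerance = 1e-9)
  # near-deterministic mutual exclusivity drives RR to 0
  eps <- 1e-12
  cpts <- list(A = list(parents = character(0), p1 = 0.3),
               X = list(parents = "A", p1 = c(0.2, eps)))
  dag <- GeneDag(c("A", "X"), list(X = "A"))
  rr <- relativeRisk(dag, CptSet(cpts), "X", "A")
  expect_lt(riskRatio(rr), 1e-6)
  # condition-set order invariance
  md <- defaultPlantedModel(seed = 3)
  r1 <- relativeRisk(md@dag, md@cpts, "BRCA1", c("NOTCH1", "MTOR"))
  r2 <- relativeRisk(md@dag, md@cpts, "BRCA1", c("MTOR", "NOTCH1"))
  expect_equal(riskRatio(r1), riskRatio(r2), tolerance = 1e-12)
  # on the generator's own tables the query reproduces the exact truth
  expect_equal(riskRatio(relativeRisk(md@dag, md@cpts, "BRCA2", "BRCA1")),
               trueRelativeRisk(md, "BRCA2", "BRCA1"), tolerance = 1e-9)
})

test_that("relative risk directions condition the intended way", {
  cpts <- list(A = list(parents = character(0), p1 = 0.3),
               B = list(parents = "A", p1 = c(0.2, 0.7)),
               C = list(parents = "B", p1 = c(0.1, 0.6)))
  dag <- GeneDag(c("A", "B", "C"), list(B = "A", C = "B"))
  cs <- CptSet(cpts)
  fwd <- relativeRisk(dag, cs, "C", c("A", "B"))
  num <- bruteForceConditional(c("A", "B", "C"), cpts, c(A = 1, B = 1), "C")
  den <- bruteForceConditional(c("A", "B", "C"), cpts, c(A = 0, B = 0), "C")
  expect_equal(riskRatio(fwd), num / den, tolerance = 1e-10)
  rev <- relativeRisk(dag, cs, "A", c("B", "C"),
                      direction = "genes_given_anchor")
  jt <- bruteForceJoint(c("A", "B", "C"), cpts)
  pn <- sum(jt$prob[jt$A == 1 & jt$B == 1 & jt$C == 1]) /
    sum(jt$prob[jt$A == 1])
  pd <- sum(jt$prob[jt$A == 0 & jt$B == 1 & jt$C == 1]) /
    sum(jt$prob[jt$A == 0])
  expect_equal(riskRatio(rev), pn / pd, tolerance = 1e-10)
})

test_that("empirical relative risk matches hand counts and flags corrections", {
  mat <- matrix(c(1, 1, 1, 0, 0, 0, 0, 0,   # ANCH
                  1, 1, 0, 1, 1, 0, 0, 0),  # COND
                8, 2, dimnames = list(sprintf("P%d", 1:8), c("ANCH", "COND")))
  mm <- MutationMatrix(mat)
  est <- empiricalRelativeRisk(mm, "ANCH", "COND")
  # P(ANCH|COND=1) = 2/4, P(ANCH|COND=0) = 1/4
  expect_equal(riskRatio(est), (2 / 4) / (1 / 4), tolerance = 1e-12)
  expect_equal(est@flag, "")
  # empty stratum triggers the continuity correction
  mat2 <- mat; mat2[, "COND"] <- 1L
  est2 <- empiricalRelativeRisk(MutationMatrix(mat2), "ANCH", "COND")
  expect_equal(est2@flag, "continuity_corrected")
  expect_true(is.finite(riskRatio(est2)))
})

test_that("model-based and empirical RR agree on a large planted sample", {
  cpts <- list(A = list(parents = character(0), p1 = 0.25),
               P = list(parents = "A", p1 = c(0.1, 0.4)))
  m <- PlantedModel(GeneDag(c("A", "P"), list(P = "A")), CptSet(cpts),
                    nPatients = 100000L, seed = 37L)
  mm <- sampleCohort(m, trueRRQueries = list())$matrix
  dag <- m@dag
  fit <- fitCpts(mm, dag)
  modelRR <- riskRatio(relativeRisk(dag, fit, "A", "P"))
  empRR <- riskRatio(empiricalRelativeRisk(mm, "A", "P"))
  expect_equal(modelRR, empRR, tolerance = 0.02)
  expect_equal(modelRR, trueRelativeRisk(m, "A", "P"), tolerance = 0.1)
})
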