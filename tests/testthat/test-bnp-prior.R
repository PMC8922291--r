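# The knowledge prior: GI labeling, BNP learning, cross-validation,
# per-pair priors, graph log-prior.

test_that("GI labeling follows the two-or-more rule and is idempotent", {
  pairs <- cbind(a = c("a", "a", "b"), b = c("b", "c", "c"))
  types <- matrix(c(1L, 0L, 0L,
                    0L, 1L, 0L,
                    1L, 0L, 0L), ncol = 3,
                  dimnames = list(NULL, c("t1", "t2", "t3")))
  E <- new("EvidenceSet", pairs = pairs, types = types,
           experimentalTypes = character(0), gi = integer(0))
  lab <- labelGI(E)
  # rows: (1,0,1) -> 2 ones -> 1; (0,1,0) -> 0; (0,0,0) -> 0
  expect_equal(giLabels(lab), c(1L, 0L, 0L))
  expect_equal(giLabels(labelGI(lab)), giLabels(lab))
  # experimental columns never count toward the rule
  E2 <- new("EvidenceSet", pairs = pairs, types = types,
            experimentalTypes = "t3", gi = integer(0))
  expect_equal(giLabels(labelGI(E2)), c(0L, 0L, 0L))
})

test_that("perfectly informative evidence ties every type to GI", {
  at <- generateAtlas(nPathways = 4L, meanPathwaySize = 15L, seed = 6)
  E <- labelGI(generateEvidence(at, nTypes = 4L, sensitivity = 1, fpr = 0,
                                seed = 6))
  bnp <- learnBNP(E, B = 25L, seed = 6)
  # evidence == GI indicator everywhere: every type must connect to GI,
  # directly or through another type, in the consensus
  g <- igraph::graph_from_edgelist(dagArcs(bnp@dag), directed = FALSE)
  for (v in setdiff(dagNodes(bnp@dag), "GI"))
    expect_true(v %in% igraph::V(g)$name &&
                  !is.infinite(igraph::distances(g, v, "GI")[1]))
  # determinism
  bnp2 <- learnBNP(E, B = 25L, seed = 6)
  expect_equal(dagArcs(bnp2@dag), dagArcs(bnp@dag))
  expect_equal(bnp2@strengths@strength, bnp@strengths@strength)
})

test_that("independent evidence gives GI no reliable support", {
  # with evidence independent of GI, no GI pair should accumulate anything
  # close to the bootstrap support a real dependence produces (compare the
  # strength-1 arcs of the perfectly informative case above)
  set.seed(44)
  for (seed in 1:5) {
    n <- 400
    types <- matrix(rbinom(n * 3, 1, 0.4), ncol = 3,
                    dimnames = list(NULL, c("t1", "t2", "t3")))
    pairs <- cbind(a = sprintf("a%03d", 1:n), b = sprintf("b%03d", 1:n))
    E <- new("EvidenceSet", pairs = pairs, types = types,
             experimentalTypes = character(0),
             gi = rbinom(n, 1, 0.3))
    bnp <- learnBNP(E, B = 20L, seed = seed)
    tab <- strengthTable(bnp@strengths)
    giStrength <- tab$strength[tab$a == "GI" | tab$b == "GI"]
    expect_lt(max(giStrength), 0.5)
  }
})

test_that("cross-validated AUROC separates informative from shuffled evidence", {
  at <- generateAtlas(nPathways = 5L, meanPathwaySize = 20L, seed = 12)
  E <- labelGI(generateEvidence(at, nTypes = 6L, sensitivity = 0.9,
                                fpr = 0.05, seed = 12))
  auc <- crossValidateGI(E, folds = 3L, B = 20L, seed = 12)
  expect_gt(auc, 0.85)
  # shuffling labels against evidence collapses the AUROC toward 1/2
  set.seed(1)
  Esh <- initialize(E, gi = sample(giLabels(E)))
  aucSh <- crossValidateGI(Esh, folds = 3L, B = 20L, seed = 12)
  expect_lt(abs(aucSh - 0.5), 0.12)
})

test_that("pair priors are monotone in the evidence and clamped", {
  # hand-built 2-node BNP: GI -> E
  h <- handBnp()
  st <- new("StrengthTable", pairs = cbind("E", "GI"), strength = 1,
            fwdFraction = 0, B = 1L)
  bnp <- new("BNPModel", dag = h$dag, cpts = h$cpts, strengths = st,
             threshold = 0.5, experimentalTypes = character(0))
  # evidence set containing one strongly supported pair
  pairs <- cbind(a = "g1", b = "g2")
  types <- matrix(1L, 1, 1, dimnames = list(NULL, "E"))
  E <- new("EvidenceSet", pairs = pairs, types = types,
           experimentalTypes = character(0), gi = integer(0))
  at <- tinyAtlas()
  genes <- c("g1", "g2", "g3")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = matrix(runif(12, 1, 2), 3, 4,
                                     dimnames = list(genes, paste0("s", 1:4)))),
    colData = S4Vectors::DataFrame(
      condition = factor(c("test", "test", "control", "control"),
                         levels = c("test", "control"))))
  pm <- pairPriorMatrix(bnp, E, se, genes)
  # supported pair: P(GI=1|E=1) = 0.27/0.34; unsupported: P(GI=1|E=0)
  expect_equal(pm["g1", "g2"], 0.27 / 0.34)
  expect_equal(pm["g1", "g3"], 0.03 / 0.66)
  expect_gt(pm["g1", "g2"], pm["g1", "g3"])
  expect_true(all(is.na(diag(pm))))
  expect_true(isSymmetric(pm))

  # clamping: a degenerate CPT cannot push the prior to exactly 1
  cptE <- h$cpts$E
  cptE[, 1] <- c(1, 0); cptE[, 2] <- c(0, 1)   # E == GI deterministically
  bnp2 <- initialize(bnp, cpts = list(GI = h$cpts$GI, E = cptE))
  pm2 <- pairPriorMatrix(bnp2, E, se, genes, eps = 1e-3)
  expect_equal(pm2["g1", "g2"], 1 - 1e-3)
  expect_equal(pm2["g1", "g3"], 1e-3)
})

test_that("true edges receive higher mean prior than non-edges", {
  for (seed in 1:5) {
    at <- generateAtlas(nPathways = 2L, meanPathwaySize = 10L,
                        overlapFraction = 0, seed = seed)
    se <- simulateExpression(at, seed = seed)
    E <- generateEvidence(at, nTypes = 5L, sensitivity = 0.9, fpr = 0.05,
                          seed = seed)
    E2 <- labelGI(addCoexpressionEvidence(E, se))
    bnp <- learnBNP(E2, B = 25L, seed = seed)
    pm <- pairPriorMatrix(bnp, E, se, atlasNodes(at))
    ek <- atlasEdges(at)
    isEdge <- matrix(FALSE, nrow(pm), ncol(pm), dimnames = dimnames(pm))
    isEdge[ek] <- TRUE
    isEdge <- isEdge | t(isEdge)
    up <- upper.tri(pm)
    expect_gt(mean(pm[up & isEdge]), mean(pm[up & !isEdge]))
  }
})

test_that("the graph log-prior is edge-decomposable", {
  genes <- c("a", "b", "c")
  pm <- matrix(0.5, 3, 3, dimnames = list(genes, genes))
  pm["a", "b"] <- pm["b", "a"] <- 0.9
  pm["a", "c"] <- pm["c", "a"] <- 0.2
  diag(pm) <- NA
  empty <- dag(genes)
  withAB <- dag(genes, cbind("a", "b"))
  # uniform prior: every DAG on the same nodes scores kappa * P * log 0.5
  unif <- matrix(0.5, 3, 3, dimnames = list(genes, genes))
  expect_equal(graphLogPrior(empty, unif, kappa = 2), 2 * 3 * log(0.5))
  expect_equal(graphLogPrior(withAB, unif, kappa = 2), 2 * 3 * log(0.5))
  # toggling one pair with pi = 0.9 changes the prior by kappa*log(.9/.1)
  expect_equal(graphLogPrior(withAB, pm) - graphLogPrior(empty, pm),
               log(0.9 / 0.1))
  # direction does not matter
  expect_equal(graphLogPrior(dag(genes, cbind("b", "a")), pm),
               graphLogPrior(withAB, pm))
  # small-pi expansion: empty graph under pi == eps
  eps <- 1e-6
  tiny <- matrix(eps, 3, 3, dimnames = list(genes, genes))
  expect_equal(graphLogPrior(empty, tiny), 3 * log1p(-eps))
  expect_equal(graphLogPrior(empty, tiny), -3 * eps, tolerance = 1e-5)
  # out-of-range probabilities are rejected
  bad <- matrix(1, 3, 3, dimnames = list(genes, genes))
  expect_error(graphLogPrior(empty, bad), "strictly inside")
})
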