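# Fold-change observations, discretization and MAP network learning.

test_that("pairwise fold changes enumerate test x control sample pairs", {
  at <- tinyAtlas()
  se <- simulateExpression(at, nTest = 4, nControl = 5, seed = 2)
  obs <- pairwiseFoldChanges(se)
  expect_equal(nrow(obs), 20L)
  expect_equal(colnames(obs), rownames(SummarizedExperiment::assay(se)))
  # spot value: log2 ratio of the underlying abundances
  x <- SummarizedExperiment::assay(se)
  g <- rownames(x)[1]
  expect_equal(obs[1, g], log2(x[g, "T01"] / x[g, "C01"]),
               ignore_attr = TRUE)
  # constant gene: all-zero observations; 8 vs 2 gives +2 (log2 of 4)
  xx <- rbind(flat = c(8, 8, 8, 8), up = c(8, 2, 2, 8))
  colnames(xx) <- paste0("s", 1:4)
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = xx),
    colData = S4Vectors::DataFrame(
      condition = factor(c("test", "control", "test", "control"),
                         levels = c("test", "control"))))
  obs2 <- pairwiseFoldChanges(se2)
  expect_true(all(obs2[, "flat"] == 0))
  expect_equal(sort(unique(obs2[, "up"])), c(-2, 0, 2))
})

test_that("discretization thresholds at +/- tau", {
  obs <- matrix(c(-2, 0, 2, -0.5, 1, -1), ncol = 2,
                dimnames = list(NULL, c("g1", "g2")))
  d <- discretizeFoldChanges(obs, tau = 1)
  expect_equal(as.integer(d@values[, "g1"]), c(0L, 1L, 2L))
  expect_equal(as.integer(d@values[, "g2"]), c(1L, 2L, 0L))
  expect_equal(unname(d@arity), c(3L, 3L))
  # tau larger than any |value|: everything unchanged
  d2 <- discretizeFoldChanges(obs, tau = 10)
  expect_true(all(d2@values == 1L))
})

# deterministic coupled-pair expression fixture: two genes moving together
coupledSE <- function(nTest = 10, nControl = 10, seed = 3) {
  set.seed(seed)
  n <- nTest + nControl
  base <- exp(rnorm(n, 0, 1.2))
  x <- rbind(gA = 100 * base * exp(rnorm(n, 0, 0.05)),
             gB = 50 * base * exp(rnorm(n, 0, 0.05)),
             gC = exp(rnorm(n, log(80), 1.2)))
  colnames(x) <- c(sprintf("T%02d", 1:nTest), sprintf("C%02d", 1:nControl))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = x),
    colData = S4Vectors::DataFrame(
      condition = factor(rep(c("test", "control"), c(nTest, nControl)),
                         levels = c("test", "control")),
      row.names = colnames(x)))
}

flatBnp <- function() {
  # BNP whose GI node is disconnected: constant prior for every pair
  g <- dag(c("GI", "E"))
  d <- discreteDataset(cbind(GI = c(0L, 1L), E = c(0L, 1L)),
                       arity = c(2L, 2L))
  cpts <- fitCPTs(g, d, pseudo = 1)
  st <- new("StrengthTable", pairs = cbind("E", "GI"), strength = 0,
            fwdFraction = NA_real_, B = 1L)
  new("BNPModel", dag = g, cpts = cpts, strengths = st, threshold = 0.5,
      experimentalTypes = character(0))
}

emptyEvidence <- function() {
  new("EvidenceSet",
      pairs = matrix(character(0), 0, 2,
                     dimnames = list(NULL, c("a", "b"))),
      types = matrix(integer(0), 0, 1, dimnames = list(NULL, "E")),
      experimentalTypes = character(0), gi = integer(0))
}

test_that("strongly coupled genes are recovered; kappa = 0 disables the prior", {
  se <- coupledSE()
  net <- learnNetwork(se, c("gA", "gB", "gC"), flatBnp(), emptyEvidence(),
                      kappa = 0, B = 25L, seed = 2)
  keys <- pairKey(networkEdges(net)[, 1], networkEdges(net)[, 2])
  expect_true("gA|gB" %in% keys)
  tab <- strengthTable(networkStrengths(net))
  expect_gt(tab$strength[tab$a == "gA" & tab$b == "gB"],
            tab$strength[tab$a == "gA" & tab$b == "gC"])
  # strength keys are exactly the unordered pairs over the gene set
  expect_setequal(pairKey(tab$a, tab$b), c("gA|gB", "gA|gC", "gB|gC"))
  # kappa = 0 equals prior-free learning with the same seed regardless of pi
  pm <- matrix(1e-3, 3, 3, dimnames = list(c("gA", "gB", "gC"),
                                           c("gA", "gB", "gC")))
  net2 <- learnNetwork(se, c("gA", "gB", "gC"), flatBnp(), emptyEvidence(),
                       kappa = 0, B = 25L, seed = 2, priorMatrix = pm)
  expect_equal(strengthTable(networkStrengths(net2)), tab)
})

test_that("a dominant prior can force or fail to suppress an edge", {
  se <- coupledSE()
  genes <- c("gA", "gB", "gC")
  # two independent genes but near-one prior with large kappa: edge forced
  pm <- matrix(1e-3, 3, 3, dimnames = list(genes, genes))
  pm["gA", "gC"] <- pm["gC", "gA"] <- 1 - 1e-3
  netF <- learnNetwork(se, genes, flatBnp(), emptyEvidence(), kappa = 30,
                       B = 20L, seed = 4, priorMatrix = pm)
  expect_true("gA|gC" %in% pairKey(networkEdges(netF)[, 1],
                                   networkEdges(netF)[, 2]))
  # deterministically coupled pair survives a hostile prior at kappa = 1
  netH <- learnNetwork(se, genes, flatBnp(), emptyEvidence(), kappa = 1,
                       B = 20L, seed = 4, priorMatrix = pm)
  tab <- strengthTable(networkStrengths(netH))
  expect_equal(tab$strength[tab$a == "gA" & tab$b == "gB"], 1)
})

test_that("singleton gene sets yield an empty network", {
  se <- coupledSE()
  net <- learnNetwork(se, "gA", flatBnp(), emptyEvidence(), B = 5L)
  expect_length(net@strengths@strength, 0L)
  expect_equal(nrow(networkEdges(net)), 0L)
})

test_that("kappa = 0 consensus matches the enumeration MAP skeleton", {
  se <- coupledSE(seed = 9)
  genes <- c("gA", "gB", "gC")
  obs <- pairwiseFoldChanges(se, genes)
  d <- discretizeFoldChanges(obs, tau = 1)
  oracle <- bruteForceBest(d)
  net <- learnNetwork(se, genes, flatBnp(), emptyEvidence(), kappa = 0,
                      B = 40L, seed = 3)
  keys <- pairKey(networkEdges(net)[, 1], networkEdges(net)[, 2])
  expect_true(list(sort(keys)) %in% oracle$skeletons)
})

test_that("network TSV writer emits strengths and significance flags", {
  se <- coupledSE()
  net <- learnNetwork(se, c("gA", "gB", "gC"), flatBnp(), emptyEvidence(),
                      kappa = 0, B = 10L, seed = 2)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeNetwork(net, tmp)
  lines <- readLines(tmp)
  expect_match(lines[1], "^# threshold")
  df <- utils::read.table(tmp, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(nrow(df), 3L)
  expect_true(all(df$significant %in% 0:1))
})
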