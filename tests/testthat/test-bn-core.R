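# Discrete BN machinery: scoring, search, bootstrap averaging, threshold,
# CPTs and inference.

test_that("BIC score matches closed forms", {
  # one binary variable, half 0 half 1, N = 4
  d1 <- discreteDataset(matrix(c(0L, 0L, 1L, 1L), ncol = 1,
                               dimnames = list(NULL, "x")))
  expect_equal(bicScore(dag("x"), d1), 4 * log(0.5) - log(4) / 2)

  # y = x exactly, N = 100: arc model beats empty model
  x <- rep(c(0L, 1L), 50)
  d2 <- discreteDataset(cbind(x = x, y = x))
  sEdge <- bicScore(dag(c("x", "y"), cbind("x", "y")), d2)
  sEmpty <- bicScore(dag(c("x", "y")), d2)
  # closed forms: empty = 2*(100 log .5) - 2*(log100)/2;
  # edge adds zero conditional entropy for y but one extra parameter
  expect_equal(sEmpty, 200 * log(0.5) - log(100))
  expect_equal(sEdge, 100 * log(0.5) - 3 * log(100) / 2)
  expect_gt(sEdge, sEmpty)
})

test_that("adding an uninformative parent never raises BIC", {
  # exactly independent counts: all four (x, y) combinations equally often
  d <- discreteDataset(cbind(x = rep(c(0L, 1L), each = 10),
                             y = rep(c(0L, 1L), 10)))
  expect_lt(bicScore(dag(c("x", "y"), cbind("x", "y")), d),
            bicScore(dag(c("x", "y")), d))
})

test_that("hill climbing recovers the expected structures", {
  # independent variables -> empty DAG
  dInd <- discreteDataset(cbind(x = rep(c(0L, 1L), each = 10),
                                y = rep(c(0L, 1L), 10)))
  expect_equal(nrow(dagArcs(hillClimb(dInd, seed = 1))), 0L)

  # deterministic y = x, N = 400 -> a single arc either direction
  x <- rep(c(0L, 1L), 200)
  dDet <- discreteDataset(cbind(x = x, y = x))
  g <- hillClimb(dDet, seed = 1)
  expect_equal(skeletonKeys(dagArcs(g)), "x|y")

  # noisy chain x -> y -> z, N = 500: skeleton {x-y, y-z}, no x-z
  set.seed(42)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  y <- ifelse(runif(n) < 0.9, x, 1 - x)
  z <- ifelse(runif(n) < 0.9, y, 1 - y)
  dChain <- discreteDataset(cbind(x = as.integer(x), y = as.integer(y),
                                  z = as.integer(z)))
  g <- hillClimb(dChain, seed = 1)
  expect_setequal(skeletonKeys(dagArcs(g)), c("x|y", "y|z"))
})

test_that("hill climbing attains the brute-force optimum on <=3 variables", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 120
    x <- rbinom(n, 1, 0.5)
    y <- ifelse(runif(n) < 0.75, x, rbinom(n, 1, 0.5))
    z <- rbinom(n, 1, 0.4)
    d <- discreteDataset(cbind(x = as.integer(x), y = as.integer(y),
                               z = as.integer(z)))
    oracle <- bruteForceBest(d)
    g <- hillClimb(d, restarts = 5L, seed = rep)
    expect_equal(attr(g, "score"), oracle$score, tolerance = 1e-9)
    expect_true(list(skeletonKeys(dagArcs(g))) %in% oracle$skeletons)
  }
})

test_that("hill climbing result is a local optimum", {
  set.seed(99)
  n <- 200
  vals <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5))
  vals <- cbind(vals, c = as.integer(xor(vals[, 1], vals[, 2])))
  d <- discreteDataset(vals)
  g <- hillClimb(d, restarts = 3L, seed = 5)
  base <- bicScore(g, d)
  nodes <- dagNodes(g)
  arcs <- dagArcs(g)
  key <- function(m) paste(m[, 1], m[, 2], collapse = ";")
  # every legal single-arc neighbor scores no better
  for (u in nodes) for (v in nodes) {
    if (u == v) next
    present <- any(arcs[, 1] == u & arcs[, 2] == v)
    if (present) {
      del <- arcs[!(arcs[, 1] == u & arcs[, 2] == v), , drop = FALSE]
      expect_lte(bicScore(dag(nodes, del), d), base + 1e-9)
      rev <- rbind(del, c(v, u))
      ok <- tryCatch({ dag(nodes, rev); TRUE }, error = function(e) FALSE)
      if (ok) expect_lte(bicScore(dag(nodes, rev), d), base + 1e-9)
    } else if (!any(arcs[, 1] == v & arcs[, 2] == u)) {
      add <- rbind(arcs, c(u, v))
      ok <- tryCatch({ dag(nodes, add); TRUE }, error = function(e) FALSE)
      if (ok) expect_lte(bicScore(dag(nodes, add), d), base + 1e-9)
    }
  }
})

test_that("bootstrap strengths behave as model averaging", {
  x <- rep(c(0L, 1L), 100)
  d <- discreteDataset(cbind(x = x, y = x))
  # deterministic dependence survives every resample
  st <- bootstrapStrengths(d, B = 7L, seed = 3)
  tab <- strengthTable(st)
  expect_equal(tab$strength[tab$a == "x" & tab$b == "y"], 1)
  # B = 1 gives 0/1 strengths
  st1 <- bootstrapStrengths(d, B = 1L, seed = 3)
  expect_true(all(strengthTable(st1)$strength %in% c(0, 1)))
})

test_that("bootstrap strengths are invariant to input row order", {
  set.seed(21)
  n <- 80
  x <- rbinom(n, 1, 0.5)
  y <- ifelse(runif(n) < 0.8, x, 1 - x)
  vals <- cbind(x = as.integer(x), y = as.integer(y),
                z = rbinom(n, 1, 0.5))
  d1 <- discreteDataset(vals)
  d2 <- discreteDataset(vals[sample(n), ])
  s1 <- bootstrapStrengths(d1, B = 10L, seed = 5)
  s2 <- bootstrapStrengths(d2, B = 10L, seed = 5)
  expect_equal(strengthTable(s1), strengthTable(s2))
})

test_that("significance threshold minimizes the CDF gap", {
  # {0,0,1,1}: threshold strictly inside (0,1); the two 1s significant
  t1 <- significanceThreshold(c(0, 0, 1, 1))
  expect_gt(t1, 0); expect_lt(t1, 1)
  expect_equal(sum(c(0, 0, 1, 1) > t1), 2L)
  # {0.05, 0.1, 0.9, 0.95}: the two high values significant
  s <- c(0.05, 0.1, 0.9, 0.95)
  t2 <- significanceThreshold(s)
  expect_setequal(s[s > t2], c(0.9, 0.95))
  # degenerate single value: threshold just below, one significant edge
  expect_warning(t3 <- significanceThreshold(0.7), "identical")
  expect_lt(t3, 0.7)
  expect_equal(sum(0.7 > t3), 1L)
})

test_that("CPT fitting applies pseudo-counts correctly", {
  d <- discreteDataset(matrix(c(0L, 0L, 0L, 1L), ncol = 1,
                              dimnames = list(NULL, "x")))
  cpts <- fitCPTs(dag("x"), d, pseudo = 1)
  expect_equal(as.numeric(cpts$x), c(4 / 6, 2 / 6))
  # pseudo = 0 with one observed state: degenerate CPT
  d2 <- discreteDataset(matrix(c(0L, 0L), ncol = 1,
                               dimnames = list(NULL, "x")), arity = 2L)
  expect_equal(as.numeric(fitCPTs(dag("x"), d2, pseudo = 0)$x), c(1, 0))
  # unseen parent configuration with pseudo = 1: uniform row
  d3 <- discreteDataset(cbind(p = c(0L, 0L, 0L), c = c(0L, 1L, 0L)),
                        arity = c(2L, 2L))
  cpt <- fitCPTs(dag(c("p", "c"), cbind("p", "c")), d3, pseudo = 1)$c
  expect_equal(as.numeric(as.array(cpt)[, 2L]), c(0.5, 0.5))
})

test_that("posterior inference matches Bayes rule on the 2-node model", {
  h <- handBnp()
  post <- inferPosterior(h$dag, h$cpts, evidence = c(E = 1L), query = "GI")
  expect_equal(post[[2]], 0.27 / 0.34)
  # no evidence: prior marginal
  expect_equal(inferPosterior(h$dag, h$cpts, query = "GI")[[2]], 0.3)
  # contradictory evidence errors
  cptE <- h$cpts$E
  cptE[, 1] <- c(1, 0); cptE[, 2] <- c(1, 0)  # E always 0
  h$cpts$E <- cptE
  expect_error(inferPosterior(h$dag, h$cpts, evidence = c(E = 1L),
                              query = "GI"),
               "zero probability")
})

test_that("variable elimination matches joint-table enumeration", {
  set.seed(13)
  for (rep in 1:6) {
    nNodes <- sample(3:6, 1)
    nodes <- paste0("v", seq_len(nNodes))
    # random DAG over a random order
    ord <- sample(nodes)
    arcs <- NULL
    for (i in seq_len(nNodes - 1)) for (j in seq.int(i + 1, nNodes))
      if (runif(1) < 0.4) arcs <- rbind(arcs, c(ord[i], ord[j]))
    g <- dag(nodes, arcs)
    vals <- matrix(sample(0:1, 30 * nNodes, replace = TRUE), ncol = nNodes,
                   dimnames = list(NULL, nodes))
    d <- discreteDataset(vals, arity = rep(2L, nNodes))
    cpts <- fitCPTs(g, d, pseudo = 1)
    q <- sample(nodes, 1)
    evNodes <- sample(setdiff(nodes, q), sample(0:(nNodes - 2), 1))
    ev <- stats::setNames(sample(0:1, length(evNodes), replace = TRUE),
                          evNodes)
    expect_equal(inferPosterior(g, cpts, ev, q),
                 jointEnumPosterior(g, cpts, ev, q),
                 tolerance = 1e-10)
  }
})
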