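# Clustering and the validation indices.

test_that("cluster count follows the expected-size rule", {
  expect_equal(nClusters(11454, 34), 337L)
  expect_equal(nClusters(10, 25), 1L)
  expect_equal(nClusters(100, 25), 4L)
})

planted <- function(seed = 31L) {
  # two blocks of strongly correlated genes
  set.seed(seed)
  base1 <- rnorm(60); base2 <- rnorm(60)
  obs <- cbind(
    sapply(1:5, function(i) base1 + rnorm(60, sd = 0.05)),
    sapply(1:5, function(i) base2 + rnorm(60, sd = 0.05)))
  colnames(obs) <- sprintf("g%02d", 1:10)
  list(obs = obs,
       truth = stats::setNames(rep(1:2, each = 5), colnames(obs)))
}

test_that("both methods recover a planted two-block structure exactly", {
  p <- planted()
  for (m in c("hierarchical", "kmeans")) {
    lab <- clusterGenes(p$obs, m, K = 2, seed = 7)
    expect_equal(ariScore(lab, p$truth), 1)
    expect_equal(vMeasure(lab, p$truth), 1)
  }
})

test_that("clustering degenerate cases behave", {
  p <- planted()
  # K = number of genes: all singletons
  lab <- clusterGenes(p$obs, "hierarchical", K = 10)
  expect_equal(sort(unique(lab)), 1:10)
  # determinism of kmeans under a fixed seed
  l1 <- clusterGenes(p$obs, "kmeans", K = 3, seed = 4)
  l2 <- clusterGenes(p$obs, "kmeans", K = 3, seed = 4)
  expect_identical(l1, l2)
  # labels contiguous from 1, every gene labeled
  expect_setequal(names(l1), colnames(p$obs))
  expect_equal(sort(unique(as.integer(l1))), 1:3)
})

test_that("V-measure matches direct entropy computation", {
  genes <- paste0("g", 1:4)
  lab <- stats::setNames(c(1L, 1L, 2L, 2L), genes)
  # identical partitions
  expect_equal(vMeasure(lab, lab), 1)
  # single cluster vs two balanced classes -> homogeneity 0 -> v = 0
  one <- stats::setNames(rep(1L, 4), genes)
  expect_equal(vMeasure(one, lab), 0)
  # hand-computed 4-gene contingency: labels {g1,g2 | g3,g4},
  # truth {g1,g3 | g2,g4}: H(T|L) = H(T) = log 2 -> h = 0 -> v = 0
  cross <- stats::setNames(c(1L, 2L, 1L, 2L), genes)
  expect_equal(vMeasure(lab, cross), 0)
  # asymmetric case: labels {g1 | g2 g3 g4}, truth {g1 g2 | g3 g4}
  la <- stats::setNames(c(1L, 2L, 2L, 2L), genes)
  tr <- stats::setNames(c(1L, 1L, 2L, 2L), genes)
  hTgivenL <- (3 / 4) * (-(1 / 3) * log(1 / 3) - (2 / 3) * log(2 / 3))
  hT <- log(2)
  hLgivenT <- (1 / 2) * (-2 * 0.5 * log(0.5))
  hL <- -(1 / 4) * log(1 / 4) - (3 / 4) * log(3 / 4)
  h <- 1 - hTgivenL / hT; c <- 1 - hLgivenT / hL
  expect_equal(vMeasure(la, tr), 2 * h * c / (h + c))
})

test_that("ARI matches the pair-counting formula", {
  genes <- paste0("g", 1:4)
  lab <- stats::setNames(c(1L, 1L, 2L, 2L), genes)
  expect_equal(ariScore(lab, lab), 1)
  # {a,b | c,d} vs {a,b,c | d}: index equals expected index -> ARI 0
  tr <- stats::setNames(c(1L, 1L, 1L, 2L), genes)
  expect_equal(ariScore(lab, tr), 0)
  # independent random labelings center on 0
  set.seed(2)
  vals <- replicate(20, {
    a <- stats::setNames(sample(1:3, 30, replace = TRUE), paste0("g", 1:30))
    b <- stats::setNames(sample(1:3, 30, replace = TRUE), paste0("g", 1:30))
    ariScore(a, b)
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("ARI agrees with a hand pair-counting oracle", {
  # independent oracle: direct pair counting over all gene pairs
  ariOracle <- function(a, b) {
    n <- length(a)
    s11 <- s00 <- s10 <- s01 <- 0
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      sameA <- a[i] == a[j]; sameB <- b[i] == b[j]
      if (sameA && sameB) s11 <- s11 + 1
      else if (!sameA && !sameB) s00 <- s00 + 1
      else if (sameA) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
    idx <- s11
    total <- s11 + s10 + s01 + s00
    expIdx <- (s11 + s10) * (s11 + s01) / total
    maxIdx <- ((s11 + s10) + (s11 + s01)) / 2
    (idx - expIdx) / (maxIdx - expIdx)
  }
  set.seed(5)
  for (rep in 1:5) {
    a <- stats::setNames(sample(1:4, 25, replace = TRUE), paste0("g", 1:25))
    b <- stats::setNames(sample(1:3, 25, replace = TRUE), paste0("g", 1:25))
    expect_equal(ariScore(a, b), ariOracle(unname(a), unname(b)),
                 tolerance = 1e-10)
  }
})

test_that("metrics are invariant to cluster-id permutation", {
  set.seed(8)
  genes <- paste0("g", 1:20)
  lab <- stats::setNames(sample(1:4, 20, replace = TRUE), genes)
  tr <- stats::setNames(sample(1:3, 20, replace = TRUE), genes)
  perm <- stats::setNames(sample(1:4), 1:4)
  lab2 <- stats::setNames(perm[as.character(lab)], genes)
  expect_equal(vMeasure(lab, tr), vMeasure(lab2, tr))
  expect_equal(ariScore(lab, tr), ariScore(lab2, tr))
  classes <- stats::setNames(
    lapply(genes, function(g) sample(LETTERS[1:3], sample(0:2, 1))), genes)
  expect_equal(bhi(lab, classes), bhi(lab2, classes))
})

test_that("BHI counts shared-class pairs per cluster", {
  genes <- paste0("g", 1:3)
  lab <- stats::setNames(rep(1L, 3), genes)
  # pairs (g1,g2) share A, (g1,g3) share nothing, (g2,g3) share B: 2/3
  classes <- list(g1 = c("A"), g2 = c("A", "B"), g3 = c("B"))
  expect_equal(bhi(lab, classes), 2 / 3)
  # all genes share one pathway -> 1
  expect_equal(bhi(lab, list(g1 = "A", g2 = "A", g3 = "A")), 1)
  # no shared classes -> 0
  expect_equal(bhi(lab, list(g1 = "A", g2 = "B", g3 = "C")), 0)
  # tiny clusters contribute 1 (with a message)
  lab2 <- stats::setNames(c(1L, 1L, 2L), genes)
  expect_message(v <- bhi(lab2, list(g1 = "A", g2 = "A", g3 = "B")),
                 "contributed 1")
  expect_equal(v, 1)
})
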