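# Synthetic study systems: a multi-pathway sparse truth atlas, two-condition
# expression data driven by the atlas topology, and a binary evidence matrix
# with per-type sensitivity / false-positive rates. Everything is
# deterministic given its seed, so every downstream stage is testable
# without external downloads.

#' Generate a synthetic multi-pathway interaction atlas
#'
#' Pathway sizes are drawn from a rounded lognormal with the requested mean;
#' after the first pathway, a fraction of each pathway's genes is reused
#' from earlier pathways (overlap); within each pathway,
#' \code{round(size * meanDegree / 2)} edges are laid down by preferential
#' attachment (endpoint probability proportional to degree + 1).
#'
#' @param nPathways number of pathways (default 10, the desk scale).
#' @param meanPathwaySize mean genes per pathway (default 30).
#' @param sizeDispersion lognormal sd of log-size (default 0.25).
#' @param overlapFraction fraction of a pathway's genes reused from earlier
#'   pathways (default 0.1).
#' @param meanDegree target mean degree within a pathway (default 3).
#' @param seed integer seed.
#' @return an \code{\link{Atlas-class}}.
#' @export
generateAtlas <- function(nPathways = 10L, meanPathwaySize = 30L,
                          sizeDispersion = 0.25, overlapFraction = 0.1,
                          meanDegree = 3, seed = 1L) {
  stopifnot(nPathways >= 1L, meanPathwaySize >= 2L,
            overlapFraction >= 0, overlapFraction < 1, sizeDispersion >= 0)
  if (meanDegree >= meanPathwaySize)
    stop("infeasible density: meanDegree (", meanDegree,
         ") must be below the mean pathway size (", meanPathwaySize, ")")
  set.seed(seed)
  sizes <- round(stats::rlnorm(nPathways,
                               meanlog = log(meanPathwaySize) -
                                 sizeDispersion^2 / 2,
                               sdlog = sizeDispersion))
  sizes <- pmax(sizes, max(3, ceiling(meanDegree) + 1))
  total <- sum(sizes)
  geneName <- function(i) sprintf("g%0*d", nchar(total), i)
  nextGene <- 1L
  pids <- sprintf("P%0*d", nchar(nPathways), seq_len(nPathways))
  membership <- list()
  edgeList <- list()
  pool <- character(0)
  for (p in seq_len(nPathways)) {
    sz <- sizes[p]
    nShared <- if (p == 1L) 0L else min(round(overlapFraction * sz),
                                        length(pool))
    shared <- if (nShared > 0L) sample(pool, nShared) else character(0)
    fresh <- geneName(seq.int(nextGene, length.out = sz - nShared))
    nextGene <- nextGene + sz - nShared
    genes <- c(shared, fresh)
    pool <- c(pool, fresh)
    for (g in genes) membership[[g]] <- c(membership[[g]], pids[p])
    # preferential attachment within the pathway
    m <- round(sz * meanDegree / 2)
    deg <- stats::setNames(rep(0L, sz), genes)
    seenKey <- character(0)
    edges <- matrix(character(0), ncol = 2L)
    tries <- 0L
    while (nrow(edges) < m && tries < 50L * m) {
      tries <- tries + 1L
      u <- sample(genes, 1L, prob = deg + 1)
      v <- sample(setdiff(genes, u), 1L,
                  prob = (deg[setdiff(genes, u)] + 1))
      key <- pairKey(u, v)
      if (key %in% seenKey) next
      seenKey <- c(seenKey, key)
      edges <- rbind(edges, c(u, v))
      deg[u] <- deg[u] + 1L
      deg[v] <- deg[v] + 1L
    }
    edgeList[[p]] <- edges
  }
  nodes <- sort(names(membership))
  membership <- lapply(membership, function(v) sort(unique(v)))
  new("Atlas", nodes = nodes,
      edges = canonicalPairs(do.call(rbind, edgeList)),
      membership = membership[nodes])
}

#' Simulate two-condition expression data from an atlas
#'
#' Each connected component of the (undirected) atlas is oriented by
#' breadth-first search from a random root; orientation is used only for
#' simulation and never alters the truth graph. Roots receive a basal
#' abundance; in the test condition a fraction of roots get a shifted basal
#' level. Every non-root's mean is the basal level times a saturating
#' Hill-type term per parent,
#' \eqn{(v/K)^h / (1 + (v/K)^h)} for activators and
#' \eqn{1 / (1 + (v/K)^h)} for repressors with \eqn{h = 2} and \eqn{K} the
#' parent's noiseless reference value, with random activation/repression
#' signs per edge. A small constitutive leak keeps every gene expressed (and
#' the cascade numerically stable). Multiplicative lognormal biological
#' noise is applied per gene and sample during propagation and experimental
#' noise last; all outputs are positive.
#'
#' @param atlas an \code{\link{Atlas-class}}.
#' @param nTest,nControl sample counts per group (default 20 each).
#' @param noiseBio sd of the lognormal biological noise (default 0.3).
#' @param noiseExp sd of the lognormal experimental noise (default 0.1).
#' @param perturbFraction fraction of roots whose basal level is shifted in
#'   the test condition (default 0.3).
#' @param basal basal abundance of root genes (default 100).
#' @param leak constitutive leak fraction of the basal level (default 0.01).
#' @param perturbShift log2 shift applied to perturbed roots (default 2).
#' @param seed integer seed.
#' @return a \code{SummarizedExperiment} with assay \code{"abundance"}
#'   (genes x samples, all positive) and \code{colData(x)$condition} a
#'   factor with levels \code{"test"} and \code{"control"}.
#' @export
simulateExpression <- function(atlas, nTest = 20L, nControl = 20L,
                               noiseBio = 0.3, noiseExp = 0.1,
                               perturbFraction = 0.3, basal = 100,
                               leak = 0.01, perturbShift = 2, seed = 1L) {
  if (nTest < 1L || nControl < 1L)
    stop("both groups need at least one sample")
  genes <- atlas@nodes
  if (length(genes) == 0L) stop("atlas has no nodes")
  set.seed(seed)
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(atlas@edges), directed = FALSE,
    vertices = data.frame(name = genes))
  comp <- igraph::components(g)
  parentsOf <- stats::setNames(vector("list", length(genes)), genes)
  topo <- character(0)
  roots <- character(0)
  for (ci in seq_len(comp$no)) {
    members <- genes[comp$membership == ci]
    root <- sample(members, 1L)
    roots <- c(roots, root)
    bfs <- igraph::bfs(g, root = root, unreachable = FALSE)
    rank <- match(genes, names(bfs$order))
    members <- members[order(rank[match(members, genes)])]
    topo <- c(topo, members)
    for (v in members) {
      nb <- names(igraph::neighbors(g, v))
      parentsOf[[v]] <- nb[rank[match(nb, genes)] < rank[match(v, genes)]]
    }
  }
  # activation (+1) / repression (-1) sign per (parent, child)
  signs <- new.env(parent = emptyenv())
  for (v in topo)
    for (p in parentsOf[[v]])
      assign(paste(p, v, sep = "->"), sample(c(1, -1), 1L), envir = signs)
  nPerturb <- round(perturbFraction * length(roots))
  perturbed <- if (nPerturb > 0L) sample(roots, nPerturb) else character(0)

  hill <- function(v, K, s) {
    x <- (v / K)^2
    ifelse(s > 0, x / (1 + x), 1 / (1 + x))
  }
  # noiseless reference pass (control condition): defines K per gene
  ref <- stats::setNames(numeric(length(genes)), genes)
  for (v in topo) {
    ps <- parentsOf[[v]]
    if (length(ps) == 0L) ref[v] <- basal
    else {
      term <- 1
      for (p in ps)
        term <- term * hill(ref[p], ref[p],
                            get(paste(p, v, sep = "->"), envir = signs))
      ref[v] <- basal * (leak + (1 - leak) * term)
    }
  }
  samples <- c(sprintf("T%02d", seq_len(nTest)),
               sprintf("C%02d", seq_len(nControl)))
  condition <- factor(rep(c("test", "control"), c(nTest, nControl)),
                      levels = c("test", "control"))
  x <- matrix(0, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  for (s in seq_along(samples)) {
    isTest <- condition[s] == "test"
    val <- stats::setNames(numeric(length(genes)), genes)
    for (v in topo) {
      ps <- parentsOf[[v]]
      mu <- if (length(ps) == 0L) {
        b <- basal
        if (isTest && v %in% perturbed) b <- basal * 2^perturbShift
        b
      } else {
        term <- 1
        for (p in ps)
          term <- term * hill(val[p], ref[p],
                              get(paste(p, v, sep = "->"), envir = signs))
        basal * (leak + (1 - leak) * term)
      }
      noise <- if (noiseBio > 0) stats::rlnorm(1L, 0, noiseBio) else 1
      val[v] <- mu * noise
    }
    x[, s] <- val
  }
  if (noiseExp > 0)
    x <- x * matrix(stats::rlnorm(length(x), 0, noiseExp), nrow = nrow(x))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = x),
    colData = S4Vectors::DataFrame(condition = condition,
                                   row.names = samples))
}

#' Generate a synthetic evidence matrix from an atlas
#'
#' Rows are all true edges plus \code{nonedgeFactor} times as many non-edges
#' sampled uniformly without replacement (self-pairs excluded). Each
#' evidence column is set to 1 with probability \code{sensitivity} on edge
#' rows and \code{fpr} on non-edge rows, independently.
#'
#' @param atlas an \code{\link{Atlas-class}}.
#' @param nTypes number of evidence types (default 8).
#' @param sensitivity per-type probability of a 1 on a true edge (scalar or
#'   length-\code{nTypes}; default 0.8).
#' @param fpr per-type probability of a 1 on a non-edge (default 0.05).
#' @param nonedgeFactor non-edges sampled per true edge (default 3).
#' @param seed integer seed.
#' @return an \code{\link{EvidenceSet-class}} (no GI labels yet); attribute
#'   \code{"isEdge"} records which rows are true edges (for validation
#'   studies only -- the workflow itself never reads it).
#' @export
generateEvidence <- function(atlas, nTypes = 8L, sensitivity = 0.8,
                             fpr = 0.05, nonedgeFactor = 3, seed = 1L) {
  sens <- rep_len(sensitivity, nTypes)
  fprv <- rep_len(fpr, nTypes)
  stopifnot(all(fprv >= 0), all(fprv < sens), all(sens <= 1))
  set.seed(seed)
  genes <- atlas@nodes
  n <- length(genes)
  edges <- atlas@edges
  nEdges <- nrow(edges)
  nNon <- round(nonedgeFactor * nEdges)
  totalPairs <- nGenePairs(n)
  if (nNon > totalPairs - nEdges)
    stop("not enough non-edges to sample: need ", nNon, ", have ",
         totalPairs - nEdges)
  edgeKeys <- pairKey(edges[, 1L], edges[, 2L])
  if (totalPairs <= 2e6) {
    univ <- allPairs(genes)
    keys <- pairKey(univ[, 1L], univ[, 2L])
    nonIdx <- which(!keys %in% edgeKeys)
    pick <- sample(nonIdx, nNon)
    non <- univ[pick, , drop = FALSE]
  } else {
    # rejection sampling for very large gene universes
    chosen <- character(0)
    non <- matrix(character(0), ncol = 2L)
    while (nrow(non) < nNon) {
      i <- sample.int(n, 2L * (nNon - nrow(non)) + 10L, replace = TRUE)
      j <- sample.int(n, length(i), replace = TRUE)
      ok <- i != j
      a <- pmin(genes[i[ok]], genes[j[ok]])
      b <- pmax(genes[i[ok]], genes[j[ok]])
      key <- paste(a, b, sep = "|")
      keep <- !key %in% edgeKeys & !key %in% chosen & !duplicated(key)
      take <- utils::head(which(keep), nNon - nrow(non))
      non <- rbind(non, cbind(a[take], b[take]))
      chosen <- c(chosen, key[take])
    }
  }
  pairs <- rbind(edges, non)
  isEdge <- rep(c(TRUE, FALSE), c(nEdges, nrow(non)))
  ord <- order(pairKey(pairs[, 1L], pairs[, 2L]))
  pairs <- pairs[ord, , drop = FALSE]
  isEdge <- isEdge[ord]
  types <- matrix(0L, nrow(pairs), nTypes,
                  dimnames = list(NULL, sprintf("ev%d", seq_len(nTypes))))
  for (t in seq_len(nTypes)) {
    pr <- ifelse(isEdge, sens[t], fprv[t])
    types[, t] <- as.integer(stats::runif(nrow(pairs)) < pr)
  }
  colnames(pairs) <- c("a", "b")
  out <- new("EvidenceSet", pairs = pairs, types = types,
             experimentalTypes = character(0), gi = integer(0))
  attr(out, "isEdge") <- isEdge
  out
}

#' Planted cluster labels from pathway membership
#'
#' Assigns every gene to the first (lexicographically smallest) pathway it
#' belongs to, yielding the "perfect clustering" partition used when
#' benchmarking clustering quality against the truth.
#'
#' @param atlas an \code{\link{Atlas-class}}.
#' @return named integer vector of contiguous cluster ids (1..K).
#' @export
plantedClusters <- function(atlas) {
  first <- vapply(atlas@membership[atlas@nodes], function(v) v[[1L]],
                  character(1))
  ids <- as.integer(factor(first, levels = sort(unique(first))))
  # relabel by decreasing cluster size for consistency with clusterGenes
  relabelBySize(stats::setNames(ids, atlas@nodes))
}

#' Write an expression matrix and its design as TSV
#'
#' @param se a \code{SummarizedExperiment} from
#'   \code{\link{simulateExpression}}.
#' @param exprFile path for the expression TSV (genes in rows, header of
#'   sample ids).
#' @param designFile path for the design TSV (sample, group).
#' @return the input, invisibly.
#' @export
writeExpression <- function(se, exprFile, designFile) {
  x <- SummarizedExperiment::assay(se)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  utils::write.table(df, exprFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(x),
               group = as.character(se$condition)),
    designFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(se)
}

#' @rdname writeExpression
#' @export
readExpression <- function(exprFile, designFile) {
  df <- utils::read.table(exprFile, sep = "\t", header = TRUE,
                          check.names = FALSE)
  x <- as.matrix(df[, -1L, drop = FALSE])
  rownames(x) <- df[[1L]]
  des <- utils::read.table(designFile, sep = "\t", header = TRUE,
                           colClasses = "character")
  cond <- factor(des$group[match(colnames(x), des$sample)],
                 levels = c("test", "control"))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = x),
    colData = S4Vectors::DataFrame(condition = cond,
                                   row.names = colnames(x)))
}

#' Write / read an evidence matrix as TSV
#'
#' Columns: gene_a, gene_b, one 0/1 column per evidence type, and GI when
#' labeled.
#'
#' @param E an \code{\link{EvidenceSet-class}}.
#' @param path file path.
#' @return \code{writeEvidence} returns the input invisibly.
#' @export
writeEvidence <- function(E, path) {
  df <- data.frame(gene_a = E@pairs[, 1L], gene_b = E@pairs[, 2L],
                   E@types, check.names = FALSE)
  if (length(E@gi)) df$GI <- E@gi
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(E)
}

#' @rdname writeEvidence
#' @param experimentalTypes type columns to flag as expression-derived.
#' @export
readEvidence <- function(path, experimentalTypes = character(0)) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  df$gene_a <- as.character(df$gene_a)
  df$gene_b <- as.character(df$gene_b)
  gi <- integer(0)
  typeCols <- setdiff(names(df), c("gene_a", "gene_b", "GI"))
  if ("GI" %in% names(df)) gi <- as.integer(df$GI)
  types <- as.matrix(df[, typeCols, drop = FALSE])
  storage.mode(types) <- "integer"
  new("EvidenceSet",
      pairs = cbind(a = df$gene_a, b = df$gene_b),
      types = types, experimentalTypes = experimentalTypes, gi = gi)
}
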