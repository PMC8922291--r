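# Representative-gene selection: a fixed battery of centrality measures on
# the cluster's consensus network, PCA-based selection of the most
# informative measure, and declared fallbacks for degenerate networks.

batteryMeasures <- c("degree", "betweenness", "closeness", "harmonic",
                     "eigenvector", "pagerank")

#' Centrality battery on a gene network
#'
#' Computes degree, betweenness, closeness, harmonic closeness, eigenvector
#' centrality and PageRank on the consensus-edge graph restricted to its
#' largest connected component. Measures that come back undefined (any
#' NA/NaN) on the component are dropped.
#'
#' @param net a \code{\link{GeneNetwork-class}} with at least one
#'   significant edge.
#' @return list with \code{nodes} (component members) and \code{values}
#'   (node x measure matrix), or \code{NULL} when the network has no edges
#'   (the "no-network" condition; \code{\link{selectRepresentative}} falls
#'   back to correlations).
#' @export
centralityBattery <- function(net) {
  if (nrow(net@consensusEdges) == 0L) return(NULL)
  g <- igraph::graph_from_edgelist(net@consensusEdges, directed = FALSE)
  comp <- igraph::components(g)
  keepComp <- which.max(comp$csize)
  g <- igraph::induced_subgraph(
    g, igraph::V(g)[comp$membership == keepComp])
  nodes <- igraph::V(g)$name
  vals <- cbind(
    degree = igraph::degree(g),
    betweenness = igraph::betweenness(g),
    closeness = suppressWarnings(igraph::closeness(g)),
    harmonic = igraph::harmonic_centrality(g),
    eigenvector = suppressWarnings(igraph::eigen_centrality(g)$vector),
    pagerank = igraph::page_rank(g)$vector)
  rownames(vals) <- nodes
  ok <- apply(vals, 2L, function(v) all(is.finite(v)))
  list(nodes = nodes, values = vals[, ok, drop = FALSE])
}

#' Most informative centrality measure via PCA
#'
#' Columns are standardized (constant columns dropped) and the measure with
#' the largest absolute loading on the first principal component is
#' returned; ties resolve in battery order. When every column is constant
#' the degree measure is the fallback.
#'
#' @param profile list from \code{\link{centralityBattery}}.
#' @return a measure name.
#' @export
mostInformativeMeasure <- function(profile) {
  stopifnot(!is.null(profile), length(profile$nodes) >= 2L)
  v <- profile$values
  sds <- apply(v, 2L, stats::sd)
  keep <- which(sds > 0)
  if (length(keep) == 0L) return("degree")
  z <- scale(v[, keep, drop = FALSE])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  loadings <- stats::setNames(abs(pc$rotation[, 1L]),
                              rownames(pc$rotation))
  names(loadings)[which.max(loadings)]
}

#' Select a cluster's representative gene
#'
#' The most central node of the cluster's consensus network under the
#' PCA-selected measure, restricted to the largest connected component;
#' ties resolve by higher degree, then lexicographically. Degenerate
#' cases: an edgeless network falls back to the gene with the highest total
#' absolute correlation to the cluster's other members, and a singleton
#' cluster returns its only gene.
#'
#' @param net a \code{\link{GeneNetwork-class}}.
#' @param obs fold-change observations for (at least) the cluster's genes,
#'   used by the correlation fallback.
#' @return a gene identifier.
#' @export
selectRepresentative <- function(net, obs) {
  genes <- net@genes
  stopifnot(length(genes) >= 1L)
  if (length(genes) == 1L) return(genes)
  profile <- centralityBattery(net)
  if (is.null(profile) || length(profile$nodes) < 2L) {
    cc <- abs(suppressWarnings(stats::cor(obs[, genes, drop = FALSE])))
    cc[is.na(cc)] <- 0
    diag(cc) <- 0
    tot <- colSums(cc)
    return(sort(names(tot)[tot == max(tot)])[1L])
  }
  measure <- mostInformativeMeasure(profile)
  vals <- profile$values[, measure]
  top <- profile$nodes[vals == max(vals)]
  if (length(top) > 1L) {
    deg <- profile$values[top, "degree"]
    top <- top[deg == max(deg)]
  }
  sort(top)[1L]
}

#' Write the representative table as TSV (cluster_id, gene, chosen measure)
#'
#' @param reps named character vector (names = cluster ids).
#' @param measures named character vector of chosen measures (optional).
#' @param path file path.
#' @export
writeRepresentatives <- function(reps, path, measures = NULL) {
  df <- data.frame(cluster_id = names(reps), gene = unname(reps))
  if (!is.null(measures)) df$chosen_measure <- measures[names(reps)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(reps)
}
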