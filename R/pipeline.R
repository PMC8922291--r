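# Full workflow orchestration: cluster, learn within-cluster networks,
# build the network of clusters from representative genes, merge linked
# clusters, collect the per-pair strength lists, aggregate, and emit the
# final atlas.

#' One-step Tukey biweight location estimate
#'
#' Robust average around the median with weights \eqn{(1-u^2)^2} for
#' \eqn{|u| < 1}, \eqn{u = (x - M) / (c\,\mathrm{MAD} + \epsilon)}.
#'
#' @param x numeric vector.
#' @param c tuning constant (default 5).
#' @param eps guard against zero MAD (default 1e-4).
#' @return a single value.
#' @export
tukeyBiweight <- function(x, c = 5, eps = 1e-4) {
  m <- stats::median(x)
  s <- stats::median(abs(x - m))
  u <- (x - m) / (c * s + eps)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  if (sum(w) == 0) return(m)
  sum(w * x) / sum(w)
}

#' Aggregate per-pair strength lists
#'
#' Each pair accumulated one strength per network it was examined in (the
#' within-cluster run first, then one per merge its cluster joined).
#' \code{first} keeps the first value; \code{min}, \code{max}, \code{mean},
#' \code{median} are as named; \code{tukey} is the one-step Tukey biweight.
#'
#' @param strengthLists named list (names = \code{\link{pairKey}}s) of
#'   nonempty numeric vectors.
#' @param method one of first, min, max, mean, median, tukey (default mean,
#'   the best-performing rule).
#' @return data.frame with columns a, b, nStrengths, score.
#' @export
aggregateStrengths <- function(strengthLists,
                               method = c("mean", "first", "min", "max",
                                          "median", "tukey")) {
  method <- match.arg(method)
  stopifnot(all(lengths(strengthLists) > 0))
  fn <- switch(method,
               first = function(x) x[[1L]],
               min = min, max = max, mean = mean,
               median = stats::median, tukey = tukeyBiweight)
  score <- vapply(strengthLists, fn, numeric(1))
  parts <- strsplit(names(strengthLists), "|", fixed = TRUE)
  data.frame(a = vapply(parts, `[[`, character(1), 1L),
             b = vapply(parts, `[[`, character(1), 2L),
             nStrengths = unname(lengths(strengthLists)),
             score = unname(score))
}

#' Build the merge plan from the network of representative genes
#'
#' Learns an interaction network over the representative genes (one per
#' cluster); every significant edge between two representatives schedules a
#' merge of their clusters. \code{kPerCluster} counts how many merges each
#' cluster participates in.
#'
#' @param expr a \code{SummarizedExperiment}.
#' @param representatives named character vector, cluster id -> gene.
#' @param bnp,E,kappa,B,tau,rho0,seed as in \code{\link{learnNetwork}}.
#' @return list with \code{repNetwork} (a \code{GeneNetwork}),
#'   \code{mergePairs} (m x 2 character matrix of cluster-id pairs) and
#'   \code{kPerCluster} (named integer vector).
#' @export
buildMergePlan <- function(expr, representatives, bnp, E, kappa = 1,
                           B = 100L, tau = 1, rho0 = 0.5, seed = 1L) {
  clusters <- names(representatives)
  empty <- list(repNetwork = NULL,
                mergePairs = matrix(character(0), ncol = 2L),
                kPerCluster = stats::setNames(rep(0L, length(clusters)),
                                              clusters))
  if (length(clusters) < 2L) return(empty)
  repNet <- learnNetwork(expr, unname(representatives), bnp, E,
                         kappa = kappa, B = B, tau = tau, rho0 = rho0,
                         seed = seed)
  edges <- repNet@consensusEdges
  if (nrow(edges) == 0L) {
    empty$repNetwork <- repNet
    return(empty)
  }
  geneToCluster <- stats::setNames(clusters, representatives)
  ca <- geneToCluster[edges[, 1L]]
  cb <- geneToCluster[edges[, 2L]]
  mp <- canonicalPairs(cbind(ca, cb))
  k <- stats::setNames(rep(0L, length(clusters)), clusters)
  tab <- table(c(mp))
  k[names(tab)] <- as.integer(tab)
  list(repNetwork = repNet, mergePairs = mp, kPerCluster = k)
}

#' Learn a network over the union of two clusters
#'
#' @param expr a \code{SummarizedExperiment}.
#' @param genesA,genesB the two clusters' (disjoint) gene sets.
#' @param bnp,E,kappa,B,tau,rho0,seed as in \code{\link{learnNetwork}}.
#' @return the union network's \code{\link{StrengthTable-class}} (within-A,
#'   within-B and cross pairs).
#' @export
mergeAndLearn <- function(expr, genesA, genesB, bnp, E, kappa = 1,
                          B = 100L, tau = 1, rho0 = 0.5, seed = 1L) {
  stopifnot(length(intersect(genesA, genesB)) == 0L)
  net <- learnNetwork(expr, c(genesA, genesB), bnp, E, kappa = kappa,
                      B = B, tau = tau, rho0 = rho0, seed = seed)
  net@strengths
}

#' Default workflow configuration
#'
#' @return named list of tunable parameters: \code{expectedSize} (genes per
#'   cluster, default 25), \code{clusterMethod} ("hierarchical" or
#'   "kmeans"), \code{aggregation} (default "mean"), \code{kappa} (prior
#'   weight, 1), \code{B} (bootstraps per network, 100), \code{bnpB}
#'   (bootstraps for BNP learning, 200), \code{tau} (discretization
#'   threshold, 1), \code{rho0} (coexpression cutoff, 0.5).
#' @export
defaultConfig <- function() {
  list(expectedSize = 25L, clusterMethod = "hierarchical",
       aggregation = "mean", kappa = 1, B = 100L, bnpB = 200L,
       tau = 1, rho0 = 0.5)
}

validateConfig <- function(config) {
  cfg <- utils::modifyList(defaultConfig(), config)
  stopifnot(cfg$expectedSize >= 1,
            cfg$clusterMethod %in% c("hierarchical", "kmeans"),
            cfg$aggregation %in% c("mean", "first", "min", "max",
                                   "median", "tukey"),
            cfg$kappa >= 0, cfg$B >= 1, cfg$bnpB >= 1,
            cfg$tau > 0, cfg$rho0 >= 0, cfg$rho0 <= 1)
  cfg
}

#' Run the full atlas-reconstruction workflow
#'
#' Pipeline: pairwise fold changes, gene clustering, per-cluster network
#' learning under the BNP prior (recording each within-cluster pair's
#' "first" strength), representative selection, the network of clusters,
#' one merge pass over linked clusters (each merge appends one strength per
#' pair in the union), aggregation of the per-pair strength lists, and a
#' final thresholded edge set. Pairs never co-examined carry no score and
#' count as 0 at evaluation time. Fully deterministic given the seed: every
#' stage consumes a child seed derived from it.
#'
#' @param expr a \code{SummarizedExperiment} (two-group design).
#' @param E the knowledge \code{\link{EvidenceSet-class}} (no GI label
#'   needed; labeling happens internally after the coexpression column is
#'   appended).
#' @param config list of parameters overriding \code{\link{defaultConfig}};
#'   the optional entry \code{labels} supplies a precomputed clustering
#'   (named integer vector) and skips the clustering stage.
#' @param seed master seed.
#' @return list of class \code{"atlasBuild"}: \code{scores} (data.frame a,
#'   b, nStrengths, score, significant), \code{atlas} (thresholded
#'   \code{Atlas}), \code{clustering}, \code{representatives},
#'   \code{plan}, \code{bnp}, \code{threshold}, \code{config}, plus
#'   per-stage provenance in \code{log}.
#' @export
buildAtlas <- function(expr, E, config = list(), seed = 1L) {
  labels <- config$labels
  config$labels <- NULL
  cfg <- validateConfig(config)
  genes <- rownames(SummarizedExperiment::assay(expr))

  # knowledge prior
  E2 <- addCoexpressionEvidence(E, expr, rho0 = cfg$rho0)
  E2 <- labelGI(E2)
  bnp <- learnBNP(E2, B = cfg$bnpB, seed = childSeed(seed, 10L))

  obs <- pairwiseFoldChanges(expr)
  if (is.null(labels)) {
    K <- nClusters(length(genes), cfg$expectedSize)
    labels <- clusterGenes(obs, cfg$clusterMethod, K,
                           seed = childSeed(seed, 20L))
  } else {
    stopifnot(setequal(names(labels), genes))
  }
  K <- max(labels)

  strengthEnv <- new.env(parent = emptyenv())
  record <- function(st) {
    if (length(st@strength) == 0L) return(invisible())
    keys <- pairKey(st@pairs[, 1L], st@pairs[, 2L])
    for (i in seq_along(keys))
      strengthEnv[[keys[i]]] <- c(strengthEnv[[keys[i]]], st@strength[i])
  }

  # per-cluster networks and representatives
  nets <- vector("list", K)
  reps <- character(K)
  measures <- character(K)
  for (k in seq_len(K)) {
    ck <- names(labels)[labels == k]
    nets[[k]] <- learnNetwork(expr, ck, bnp, E, kappa = cfg$kappa,
                              B = cfg$B, tau = cfg$tau, rho0 = cfg$rho0,
                              seed = childSeed(seed, 30L, k))
    record(nets[[k]]@strengths)
    reps[k] <- selectRepresentative(nets[[k]], obs)
    prof <- centralityBattery(nets[[k]])
    measures[k] <- if (is.null(prof) || length(prof$nodes) < 2L)
      "correlation-fallback" else mostInformativeMeasure(prof)
  }
  names(reps) <- as.character(seq_len(K))
  names(measures) <- names(reps)

  # network of clusters and merge pass
  plan <- buildMergePlan(expr, reps, bnp, E, kappa = cfg$kappa, B = cfg$B,
                         tau = cfg$tau, rho0 = cfg$rho0,
                         seed = childSeed(seed, 40L))
  if (nrow(plan$mergePairs) > 0L) {
    for (i in seq_len(nrow(plan$mergePairs))) {
      ca <- as.integer(plan$mergePairs[i, 1L])
      cb <- as.integer(plan$mergePairs[i, 2L])
      st <- mergeAndLearn(expr, names(labels)[labels == ca],
                          names(labels)[labels == cb], bnp, E,
                          kappa = cfg$kappa, B = cfg$B, tau = cfg$tau,
                          rho0 = cfg$rho0, seed = childSeed(seed, 50L, i))
      record(st)
    }
  }

  keys <- ls(strengthEnv, sorted = TRUE)
  lists <- stats::setNames(lapply(keys, function(k) strengthEnv[[k]]), keys)
  scores <- aggregateStrengths(lists, cfg$aggregation)
  thr <- significanceThreshold(scores$score)
  scores$significant <- as.integer(scores$score > thr)
  sig <- scores$significant == 1L
  membership <- stats::setNames(
    lapply(genes, function(g) as.character(labels[[g]])), genes)
  atlas <- new("Atlas", nodes = sort(genes),
               edges = canonicalPairs(as.matrix(scores[sig, c("a", "b")])),
               membership = membership[sort(genes)])
  structure(list(scores = scores, atlas = atlas, clustering = labels,
                 representatives = reps, chosenMeasures = measures,
                 plan = plan, bnp = bnp, threshold = thr, config = cfg,
                 log = list(
                   clusterSizes = as.integer(table(labels)),
                   kPerCluster = plan$kPerCluster,
                   nMerges = nrow(plan$mergePairs),
                   seed = seed)),
            class = "atlasBuild")
}

#' @export
print.atlasBuild <- function(x, ...) {
  cat("Atlas reconstruction run\n",
      "  genes: ", length(x$clustering),
      "   clusters: ", length(x$representatives),
      "   merges: ", x$log$nMerges, "\n",
      "  scored pairs: ", nrow(x$scores),
      "   significant edges: ", sum(x$scores$significant),
      " (threshold ", signif(x$threshold, 3), ")\n", sep = "")
  invisible(x)
}

#' Write the aggregated score table as TSV
#'
#' Columns gene_a, gene_b, n_strengths, aggregated_score, significant.
#'
#' @param result an \code{"atlasBuild"} list from \code{\link{buildAtlas}}.
#' @param path file path.
#' @export
writeScores <- function(result, path) {
  df <- data.frame(gene_a = result$scores$a, gene_b = result$scores$b,
                   n_strengths = result$scores$nStrengths,
                   aggregated_score = result$scores$score,
                   significant = result$scores$significant)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(result)
}

#' Write the run manifest (all parameters and seeds) as YAML
#'
#' @inheritParams writeScores
#' @export
writeManifest <- function(result, path) {
  yaml::write_yaml(list(
    config = result$config,
    seed = result$log$seed,
    clusters = length(result$representatives),
    cluster_sizes = result$log$clusterSizes,
    merges = result$log$nMerges,
    k_per_cluster = as.list(result$log$kPerCluster),
    threshold = result$threshold,
    representatives = as.list(result$representatives)), path)
  invisible(result)
}
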