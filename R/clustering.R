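# Gene clustering on fold-change observation vectors, plus the validation
# indices used to compare partitions: V-measure, ARI and the biological
# homogeneity index.

# relabel cluster ids by decreasing size (ties: first occurrence), 1..K
relabelBySize <- function(labels) {
  sizes <- table(labels)
  ord <- order(-as.integer(sizes), match(names(sizes), names(sizes)))
  newId <- stats::setNames(seq_along(ord), names(sizes)[ord])
  stats::setNames(as.integer(newId[as.character(labels)]), names(labels))
}

#' Cluster count from an expected cluster size
#'
#' @param nGenes number of genes.
#' @param expectedSize expected genes per cluster.
#' @return \code{max(1, round(nGenes / expectedSize))}.
#' @export
nClusters <- function(nGenes, expectedSize) {
  stopifnot(nGenes >= 1, expectedSize >= 1)
  max(1L, as.integer(round(nGenes / expectedSize)))
}

#' Cluster genes by their fold-change observation vectors
#'
#' Hierarchical clustering uses distance \code{1 - Pearson r} between gene
#' observation vectors with average linkage and cuts the tree at \code{K}
#' groups; k-means standardizes each gene vector, seeds centers k-means++
#' style and runs \code{stats::kmeans}. Cluster ids are relabeled by
#' decreasing cluster size. Genes with constant observation vectors have
#' undefined correlations; they are assigned via a zero-correlation
#' convention with a warning.
#'
#' @param obs fold-change observation matrix (rows = observations, columns
#'   = genes), see \code{\link{pairwiseFoldChanges}}.
#' @param method \code{"hierarchical"} or \code{"kmeans"}.
#' @param K number of clusters (at most the number of genes).
#' @param seed integer seed (used by k-means).
#' @return named integer vector of cluster labels (1..K, contiguous).
#' @export
clusterGenes <- function(obs, method = c("hierarchical", "kmeans"), K,
                         seed = 1L) {
  method <- match.arg(method)
  genes <- colnames(obs)
  stopifnot(K >= 1L, K <= length(genes))
  if (K == length(genes))
    return(stats::setNames(seq_along(genes), genes))
  if (method == "hierarchical") {
    cc <- suppressWarnings(stats::cor(obs))
    if (anyNA(cc)) {
      warning("constant gene vector(s): using zero-correlation convention")
      cc[is.na(cc)] <- 0
      diag(cc) <- 1
    }
    d <- stats::as.dist(1 - cc)
    labels <- stats::cutree(stats::hclust(d, method = "average"), k = K)
  } else {
    set.seed(seed)
    v <- t(obs)
    sds <- apply(v, 1L, stats::sd)
    if (any(sds == 0)) {
      warning("constant gene vector(s): standardized to zero")
      sds[sds == 0] <- 1
    }
    v <- (v - rowMeans(v)) / sds
    centers <- kmeansPlusPlusCenters(v, K)
    km <- stats::kmeans(v, centers = v[centers, , drop = FALSE],
                        iter.max = 100L)
    labels <- stats::setNames(km$cluster, genes)
  }
  relabelBySize(stats::setNames(as.integer(labels), genes))
}

# k-means++ seeding: returns K row indices of x
kmeansPlusPlusCenters <- function(x, K) {
  n <- nrow(x)
  centers <- sample.int(n, 1L)
  if (K > 1L) {
    d2 <- rowSums((x - matrix(x[centers, ], n, ncol(x), byrow = TRUE))^2)
    for (k in 2:K) {
      prob <- if (sum(d2) > 0) d2 else rep(1, n)
      cand <- sample.int(n, 1L, prob = prob)
      centers <- c(centers, cand)
      nd <- rowSums((x - matrix(x[cand, ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, nd)
    }
  }
  centers
}

#' V-measure of a clustering against a reference partition
#'
#' Harmonic mean of homogeneity \eqn{1 - H(T|L)/H(T)} and completeness
#' \eqn{1 - H(L|T)/H(L)}, with entropies from the label contingency table
#' (natural log) and 0/0 terms taken as 1.
#'
#' @param labels,truth named integer/character vectors over the same genes.
#' @return a value in [0, 1].
#' @export
vMeasure <- function(labels, truth) {
  stopifnot(setequal(names(labels), names(truth)))
  truth <- truth[names(labels)]
  ct <- table(labels, truth)
  n <- sum(ct)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  hT <- ent(colSums(ct) / n)
  hL <- ent(rowSums(ct) / n)
  # conditional entropies
  hTgL <- 0
  for (i in seq_len(nrow(ct))) {
    ni <- sum(ct[i, ])
    if (ni > 0) hTgL <- hTgL + (ni / n) * ent(ct[i, ] / ni)
  }
  hLgT <- 0
  for (j in seq_len(ncol(ct))) {
    nj <- sum(ct[, j])
    if (nj > 0) hLgT <- hLgT + (nj / n) * ent(ct[, j] / nj)
  }
  h <- if (hT == 0) 1 else 1 - hTgL / hT
  c <- if (hL == 0) 1 else 1 - hLgT / hL
  if (h + c == 0) 0 else 2 * h * c / (h + c)
}

#' Adjusted Rand index
#'
#' Chance-adjusted pair-counting agreement between two partitions
#' (delegates to \code{mclust::adjustedRandIndex}).
#'
#' @inheritParams vMeasure
#' @return a value \eqn{\le 1}; 0 expected for random labelings.
#' @export
ariScore <- function(labels, truth) {
  stopifnot(setequal(names(labels), names(truth)))
  mclust::adjustedRandIndex(labels, truth[names(labels)])
}

#' Biological homogeneity index
#'
#' Average over clusters of the fraction of distinct annotated gene pairs in
#' the cluster that share at least one functional class. Clusters with fewer
#' than two annotated genes contribute 1 by convention (their count is
#' reported via \code{message}).
#'
#' @param labels named integer vector of cluster labels.
#' @param functionalClasses named list mapping each gene to a character
#'   vector of class (pathway) ids; genes may have zero classes.
#' @return a value in [0, 1].
#' @export
bhi <- function(labels, functionalClasses) {
  ks <- sort(unique(labels))
  tiny <- 0L
  terms <- numeric(length(ks))
  for (i in seq_along(ks)) {
    genes <- names(labels)[labels == ks[i]]
    ann <- genes[vapply(genes, function(g)
      length(functionalClasses[[g]]) > 0, logical(1))]
    if (length(ann) < 2L) {
      tiny <- tiny + 1L
      terms[i] <- 1
      next
    }
    share <- 0L
    tot <- 0L
    for (a in seq_len(length(ann) - 1L))
      for (b in seq.int(a + 1L, length(ann))) {
        tot <- tot + 1L
        if (length(intersect(functionalClasses[[ann[a]]],
                             functionalClasses[[ann[b]]])) > 0)
          share <- share + 1L
      }
    terms[i] <- share / tot
  }
  if (tiny > 0L)
    message(tiny, " cluster(s) with <2 annotated genes contributed 1")
  mean(terms)
}

#' Write cluster labels as TSV (gene, cluster_id)
#'
#' @param labels named integer vector.
#' @param path file path.
#' @export
writeClustering <- function(labels, path) {
  utils::write.table(
    data.frame(gene = names(labels), cluster_id = as.integer(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(labels)
}
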