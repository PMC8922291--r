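# Evaluation of a reconstructed atlas against the truth: baseline
# prevalence, precision-recall curve with tie-group handling, AUC of the
# PR curve (average precision), and confusion counts.

#' Baseline prevalence of the true class
#'
#' The AUC of the precision-recall curve attained by a random (constant)
#' classifier equals the fraction of candidate pairs that are true edges.
#'
#' @param nNodes number of genes (>= 2).
#' @param nTrueEdges number of true edges (in \code{1 ..} \code{C(nNodes, 2)}).
#' @return \code{nTrueEdges / (nNodes * (nNodes - 1) / 2)}.
#' @export
baselinePrevalence <- function(nNodes, nTrueEdges) {
  if (nNodes < 2) stop("need at least two nodes")
  total <- nGenePairs(nNodes)
  if (nTrueEdges <= 0 || nTrueEdges > total)
    stop("nTrueEdges must lie in 1 .. ", total)
  nTrueEdges / total
}

#' AUC of the precision-recall curve over all candidate pairs
#'
#' Ranks all \eqn{n(n-1)/2} candidate pairs by score (pairs absent from
#' \code{scores} count as score 0). Equal scores form one threshold group
#' processed as a block: every true pair in a group contributes the group's
#' final (cumulative) precision, so the dominant all-zero group is never
#' ordered arbitrarily, and a constant scorer attains exactly the baseline
#' prevalence. Evaluation is on undirected skeletons.
#'
#' @param scores data.frame with columns \code{a}, \code{b}, \code{score}
#'   (unordered pairs; duplicates not allowed), or a named numeric vector
#'   keyed by \code{\link{pairKey}}.
#' @param truth an \code{\link{Atlas-class}}; all scored pairs must be over
#'   its nodes.
#' @return list with \code{points} (data.frame recall, precision per
#'   threshold group), \code{auc}, \code{baseline}, \code{nPairs},
#'   \code{nTrue}.
#' @export
aucPRC <- function(scores, truth) {
  nodes <- truth@nodes
  if (nrow(truth@edges) == 0L) stop("truth atlas has no edges")
  if (is.data.frame(scores)) {
    keys <- pairKey(scores$a, scores$b)
    val <- scores$score
  } else {
    keys <- names(scores)
    val <- as.numeric(scores)
  }
  if (anyDuplicated(keys)) stop("duplicate scored pairs")
  parts <- strsplit(keys, "|", fixed = TRUE)
  known <- unique(unlist(parts))
  if (length(known) && !all(known %in% nodes))
    stop("scored pairs reference nodes outside the truth atlas")
  trueKeys <- pairKey(truth@edges[, 1L], truth@edges[, 2L])
  nPairs <- nGenePairs(length(nodes))
  nTrue <- length(trueKeys)
  isTrue <- keys %in% trueKeys
  # fold explicit zero scores into the implicit zero group
  nz <- val > 0
  keys <- keys[nz]; val <- val[nz]; isTrue <- isTrue[nz]
  ord <- order(-val)
  val <- val[ord]; isTrue <- isTrue[ord]
  grp <- cumsum(!duplicated(val))
  sizes <- as.numeric(tapply(rep(1, length(val)), grp, sum))
  tps <- as.numeric(tapply(as.numeric(isTrue), grp, sum))
  # implicit zero group holds everything unscored
  sizes <- c(sizes, nPairs - length(val))
  tps <- c(tps, nTrue - sum(isTrue))
  cumN <- cumsum(sizes)
  cumTP <- cumsum(tps)
  precision <- cumTP / cumN
  recall <- cumTP / nTrue
  auc <- sum(tps * precision) / nTrue
  list(points = data.frame(recall = recall, precision = precision),
       auc = auc, baseline = nTrue / nPairs,
       nPairs = nPairs, nTrue = nTrue)
}

#' Confusion counts between a predicted and a true atlas
#'
#' @param predicted,truth \code{\link{Atlas-class}} objects over the same
#'   node universe.
#' @return named integer vector (TP, FP, FN) from set operations on the
#'   undirected edge sets.
#' @export
confusionCounts <- function(predicted, truth) {
  pk <- pairKey(predicted@edges[, 1L], predicted@edges[, 2L])
  tk <- pairKey(truth@edges[, 1L], truth@edges[, 2L])
  c(TP = length(intersect(pk, tk)),
    FP = length(setdiff(pk, tk)),
    FN = length(setdiff(tk, pk)))
}

#' Write an evaluation report as YAML
#'
#' @param pr result of \code{\link{aucPRC}}.
#' @param confusion optional result of \code{\link{confusionCounts}}.
#' @param path file path.
#' @export
writeEvaluation <- function(pr, path, confusion = NULL) {
  rep <- list(auc_prc = pr$auc, baseline = pr$baseline,
              fold_over_baseline = pr$auc / pr$baseline,
              n_pairs = pr$nPairs, n_true = pr$nTrue)
  if (!is.null(confusion)) rep <- c(rep, as.list(confusion))
  yaml::write_yaml(rep, path)
  invisible(pr)
}
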