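# The Bayesian Network Prior (BNP): a discrete BN over evidence types plus
# one "GI" node, learned from the evidence matrix by bootstrap model
# averaging. It supplies per-pair interaction probabilities and the graph
# log-prior used by the MAP structure search.

#' Label gene pairs as interacting (GI) from their evidence vectors
#'
#' A pair is labeled GI = 1 when two or more knowledge-base evidence types
#' flag it, else 0. Expression-derived (experimental) columns do not count
#' toward the rule. Idempotent.
#'
#' @param E an \code{\link{EvidenceSet-class}}.
#' @return the EvidenceSet with its \code{gi} slot filled.
#' @export
labelGI <- function(E) {
  knowledge <- setdiff(colnames(E@types), E@experimentalTypes)
  gi <- as.integer(rowSums(E@types[, knowledge, drop = FALSE]) >= 2L)
  initialize(E, gi = gi)
}

#' Append an expression-derived coexpression evidence type
#'
#' Adds a binary "coexpression" column: 1 when the absolute Pearson
#' correlation of the two genes' expression profiles is at least
#' \code{rho0}. This is the channel through which expression profiles enter
#' BNP inference; the column is flagged experimental so it never counts
#' toward the GI label.
#'
#' @param E an \code{\link{EvidenceSet-class}} whose pairs are all present
#'   in the expression data.
#' @param expr a \code{SummarizedExperiment} (see
#'   \code{\link{simulateExpression}}).
#' @param rho0 absolute-correlation threshold (default 0.5).
#' @param name column name (default "coexpression").
#' @return the EvidenceSet with one extra experimental column.
#' @export
addCoexpressionEvidence <- function(E, expr, rho0 = 0.5,
                                    name = "coexpression") {
  x <- SummarizedExperiment::assay(expr)
  missing <- setdiff(unique(c(E@pairs)), rownames(x))
  if (length(missing))
    stop("gene(s) missing from expression data: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  co <- integer(nrow(E@pairs))
  for (i in seq_len(nrow(E@pairs))) {
    r <- suppressWarnings(stats::cor(x[E@pairs[i, 1L], ],
                                     x[E@pairs[i, 2L], ]))
    co[i] <- as.integer(!is.na(r) && abs(r) >= rho0)
  }
  types <- cbind(E@types, co)
  colnames(types) <- c(colnames(E@types), name)
  initialize(E, types = types,
             experimentalTypes = union(E@experimentalTypes, name))
}

#' Learn the Bayesian Network Prior
#'
#' Runs bootstrap model averaging over the evidence + GI dataset, keeps the
#' arcs whose strength exceeds the data-driven significance threshold,
#' fixes consensus directions by the majority direction among the bootstrap
#' networks containing each arc (ties resolve toward the lexicographically
#' smaller endpoint as source; arcs that would close a cycle are dropped in
#' decreasing-strength order), and fits CPTs on the full dataset with one
#' pseudo-count.
#'
#' @param E a GI-labeled \code{\link{EvidenceSet-class}} with at least two
#'   evidence types.
#' @param B bootstrap replicate count (default 1000; desk-scale runs use
#'   less).
#' @param seed integer seed.
#' @return a \code{\link{BNPModel-class}}.
#' @export
learnBNP <- function(E, B = 1000L, seed = 1L) {
  if (length(E@gi) == 0L) stop("label the evidence set with labelGI() first")
  if (ncol(E@types) < 2L) stop("need at least two evidence types")
  values <- cbind(E@types, GI = E@gi)
  data <- discreteDataset(values, arity = rep(2L, ncol(values)))
  st <- bootstrapStrengths(data, B = B, seed = seed)
  thr <- significanceThreshold(st@strength)
  consensus <- consensusDag(st, thr, colnames(values))
  cpts <- fitCPTs(consensus, data, pseudo = 1)
  new("BNPModel", dag = consensus, cpts = cpts, strengths = st,
      threshold = thr, experimentalTypes = E@experimentalTypes)
}

# consensus DAG from a strength table: arcs with strength > threshold,
# majority direction, added in decreasing strength, skipping cycle-closers
consensusDag <- function(st, threshold, nodes) {
  keep <- which(st@strength > threshold)
  keep <- keep[order(-st@strength[keep])]
  arcs <- matrix(character(0), ncol = 2L)
  g <- dag(nodes)
  for (k in keep) {
    a <- st@pairs[k, 1L]; b <- st@pairs[k, 2L]
    arc <- if (!is.na(st@fwdFraction[k]) && st@fwdFraction[k] < 0.5)
      c(b, a) else c(a, b)
    cand <- rbind(arcs, arc)
    ok <- tryCatch({
      validObject(dag(nodes, cand)); TRUE
    }, error = function(e) FALSE)
    if (ok) arcs <- cand
    else warning("dropping consensus arc ", arc[1L], "->", arc[2L],
                 " (would close a cycle)")
  }
  dag(nodes, arcs)
}

#' Cross-validated AUROC of GI prediction
#'
#' Splits the evidence rows into folds; for each fold, learns a BNP on the
#' remaining rows, infers P(GI = 1 | evidence vector) for the held-out
#' rows, pools the scores and returns the AUROC against the GI labels.
#' Folds whose training data contain a single GI class are skipped with a
#' warning.
#'
#' @param E a GI-labeled \code{\link{EvidenceSet-class}}.
#' @param folds number of folds (default 5).
#' @param B bootstrap replicates per fold (default 100).
#' @param seed integer seed.
#' @return the AUROC in [0, 1].
#' @export
crossValidateGI <- function(E, folds = 5L, B = 100L, seed = 1L) {
  stopifnot(folds >= 2L)
  if (length(E@gi) == 0L) stop("label the evidence set with labelGI() first")
  n <- nrow(E@pairs)
  set.seed(seed)
  foldId <- sample(rep_len(seq_len(folds), n))
  scores <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    test <- which(foldId == f)
    train <- which(foldId != f)
    if (length(unique(E@gi[train])) < 2L ||
        length(unique(E@gi[test])) < 2L) {
      warning("fold ", f, " has a single GI class; skipped")
      next
    }
    Etr <- initialize(E, pairs = E@pairs[train, , drop = FALSE],
                      types = E@types[train, , drop = FALSE],
                      gi = E@gi[train])
    bnp <- learnBNP(Etr, B = B, seed = childSeed(seed, 2L, f))
    evNodes <- colnames(E@types)
    memo <- new.env(parent = emptyenv())
    for (i in test) {
      vec <- E@types[i, ]
      key <- paste(vec, collapse = "")
      if (is.null(memo[[key]])) {
        post <- inferPosterior(bnp@dag, bnp@cpts,
                               evidence = stats::setNames(as.integer(vec),
                                                          evNodes),
                               query = "GI")
        memo[[key]] <- post[[2L]]
      }
      scores[i] <- memo[[key]]
    }
  }
  ok <- !is.na(scores)
  if (!any(ok)) stop("no fold produced predictions")
  as.numeric(pROC::auc(pROC::roc(response = E@gi[ok],
                                 predictor = scores[ok],
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Per-pair interaction prior from a BNP
#'
#' For every unordered pair of \code{genes}: the knowledge-base evidence
#' types are instantiated from \code{E} (pairs absent from \code{E} get
#' all-zero knowledge evidence), any expression-derived types are computed
#' from \code{expr} (coexpression: 1 iff |Pearson r| of the two profiles is
#' at least \code{rho0}), and the posterior P(GI = 1 | evidence) is read
#' off the BNP. Values are clamped to \code{[eps, 1 - eps]}.
#'
#' @param bnp a \code{\link{BNPModel-class}}.
#' @param E the knowledge \code{\link{EvidenceSet-class}}.
#' @param expr a \code{SummarizedExperiment} containing all \code{genes}.
#' @param genes character vector of gene identifiers.
#' @param rho0 coexpression threshold (default 0.5).
#' @param eps clamp width (default 1e-3).
#' @return a symmetric genes x genes matrix of interaction probabilities
#'   (diagonal NA).
#' @export
pairPriorMatrix <- function(bnp, E, expr, genes, rho0 = 0.5, eps = 1e-3) {
  x <- SummarizedExperiment::assay(expr)
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("gene(s) missing from expression data: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  knowledge <- setdiff(colnames(E@types), bnp@experimentalTypes)
  expTypes <- intersect(bnp@experimentalTypes, bnp@dag@nodes)
  evKeys <- pairKey(E@pairs[, 1L], E@pairs[, 2L])
  corMat <- if (length(expTypes))
    suppressWarnings(stats::cor(t(x[genes, , drop = FALSE]))) else NULL
  n <- length(genes)
  pi <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  memo <- new.env(parent = emptyenv())
  evNodes <- c(knowledge, expTypes)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      key <- pairKey(genes[i], genes[j])
      row <- match(key, evKeys)
      kn <- if (is.na(row)) rep(0L, length(knowledge))
      else as.integer(E@types[row, knowledge])
      ex <- integer(0)
      if (length(expTypes)) {
        r <- corMat[genes[i], genes[j]]
        ex <- rep(as.integer(!is.na(r) && abs(r) >= rho0), length(expTypes))
      }
      patt <- paste(c(kn, ex), collapse = "")
      if (is.null(memo[[patt]])) {
        post <- inferPosterior(bnp@dag, bnp@cpts,
                               evidence = stats::setNames(c(kn, ex), evNodes),
                               query = "GI")
        memo[[patt]] <- min(max(post[[2L]], eps), 1 - eps)
      }
      pi[i, j] <- pi[j, i] <- memo[[patt]]
    }
  }
  pi
}

#' Graph log-prior from per-pair interaction probabilities
#'
#' \eqn{\kappa \sum_{u<v} [\log \pi_{uv}] } over pairs joined by an arc in
#' either direction plus \eqn{\kappa \sum [\log(1 - \pi_{uv})]} over pairs
#' that are not. Edge-decomposable, so structure search can score moves
#' incrementally.
#'
#' @param x a \code{\link{DAG-class}} whose nodes appear in \code{pi}.
#' @param pi symmetric matrix of pair probabilities in (0, 1) (see
#'   \code{\link{pairPriorMatrix}}).
#' @param kappa nonnegative prior weight (default 1).
#' @return the log-prior (a single real).
#' @export
graphLogPrior <- function(x, pi, kappa = 1) {
  nodes <- x@nodes
  stopifnot(all(nodes %in% rownames(pi)), kappa >= 0)
  p <- pi[nodes, nodes, drop = FALSE]
  vals <- p[upper.tri(p)]
  if (any(vals <= 0 | vals >= 1))
    stop("pair probabilities must lie strictly inside (0, 1); clamp upstream")
  adj <- dagAdjacency(x, nodes)
  skel <- (adj + t(adj))[upper.tri(adj)] > 0
  kappa * sum(ifelse(skel, log(vals), log1p(-vals)))
}
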