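# Discrete Bayesian-network machinery: BIC scoring, MAP hill climbing,
# bootstrap model averaging, significance thresholding, CPT fitting and
# exact inference. Shared by the knowledge prior (BNP) and the gene-network
# learner.

#' Construct a DiscreteDataset
#'
#' @param values integer matrix (rows = observations, columns = variables,
#'   states coded 0 .. arity-1) or a data.frame coercible to one.
#' @param arity optional integer vector of state counts per variable; by
#'   default inferred as \code{max + 1} per column.
#' @return a \code{\link{DiscreteDataset-class}} object.
#' @export
discreteDataset <- function(values, arity = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(colnames(values)))
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  if (is.null(arity)) {
    arity <- pmax(apply(values, 2L, max) + 1L, 2L)
  }
  arity <- as.integer(arity)
  names(arity) <- colnames(values)
  new("DiscreteDataset", values = values, arity = arity)
}

#' Construct a DAG from an arc list
#'
#' @param nodes character vector of node names.
#' @param arcs m x 2 character matrix (from, to); may have zero rows.
#' @return a \code{\link{DAG-class}} object (validity enforces acyclicity).
#' @export
dag <- function(nodes, arcs = NULL) {
  if (is.null(arcs) || length(arcs) == 0L)
    arcs <- matrix(character(0), ncol = 2L)
  arcs <- matrix(as.character(arcs), ncol = 2L,
                 dimnames = list(NULL, c("from", "to")))
  new("DAG", nodes = as.character(nodes), arcs = arcs)
}

# adjacency matrix (nodes in `variables` order) from a DAG
dagAdjacency <- function(x, variables = x@nodes) {
  n <- length(variables)
  adj <- matrix(0L, n, n, dimnames = list(variables, variables))
  if (nrow(x@arcs) > 0L) adj[x@arcs] <- 1L
  adj
}

dagFromAdjacency <- function(adj) {
  idx <- which(adj == 1L, arr.ind = TRUE)
  vars <- colnames(adj)
  dag(vars, cbind(vars[idx[, 1L]], vars[idx[, 2L]]))
}

# parents of `v` in a DAG
dagParents <- function(x, v) {
  if (nrow(x@arcs) == 0L) return(character(0))
  x@arcs[x@arcs[, 2L] == v, 1L]
}

# log-likelihood (MLE, natural log) and free-parameter count of one family
familyTerms <- function(values, arity, v, parents) {
  r <- arity[[v]]
  child <- values[, v]
  if (length(parents) == 0L) {
    cfg <- rep.int(0L, nrow(values))
    q <- 1L
  } else {
    cfg <- rep.int(0L, nrow(values))
    mult <- 1L
    for (p in parents) {
      cfg <- cfg + mult * values[, p]
      mult <- mult * arity[[p]]
    }
    q <- prod(arity[parents])
  }
  counts <- table(factor(cfg, levels = 0:(q - 1L)),
                  factor(child, levels = 0:(r - 1L)))
  nj <- rowSums(counts)
  nz <- counts > 0
  ll <- sum(counts[nz] * log(counts[nz] / nj[row(counts)[nz]]))
  list(loglik = ll, nparams = (r - 1L) * q)
}

#' BIC network score
#'
#' Decomposable score \eqn{\sum_v [\log L_v - (\log N / 2)\, k_v]} where
#' \eqn{\log L_v} is the maximum-likelihood multinomial log-likelihood of
#' node \eqn{v} given its parents and \eqn{k_v} its free-parameter count.
#' Natural logarithms throughout.
#'
#' @param x a \code{\link{DAG-class}}.
#' @param data a \code{\link{DiscreteDataset-class}} whose variables are
#'   exactly the DAG's nodes.
#' @return the BIC score (a single real; larger is better).
#' @export
bicScore <- function(x, data) {
  stopifnot(setequal(x@nodes, colnames(data@values)))
  N <- nrow(data@values)
  pen <- log(N) / 2
  score <- 0
  for (v in colnames(data@values)) {
    ft <- familyTerms(data@values, data@arity, v, dagParents(x, v))
    score <- score + ft$loglik - pen * ft$nparams
  }
  score
}

# symmetric log-odds matrix in the data's variable order; zero if prior NULL
priorLogOddsMatrix <- function(data, priorLogOdds) {
  vars <- colnames(data@values)
  n <- length(vars)
  if (is.null(priorLogOdds))
    return(matrix(0, n, n, dimnames = list(vars, vars)))
  stopifnot(all(vars %in% colnames(priorLogOdds)))
  m <- priorLogOdds[vars, vars, drop = FALSE]
  diag(m) <- 0
  m
}

#' Hill-climbing structure search
#'
#' Steepest-ascent search over single-arc add/delete/reverse moves that
#' preserve acyclicity, maximizing the BIC score plus, optionally, an
#' edge-decomposable graph log-prior supplied as a symmetric matrix of
#' per-pair log-odds (\code{log(pi/(1-pi))}, already weighted). With
#' \code{restarts > 0}, additional searches start from random DAGs and the
#' best-scoring local optimum is returned. Among equal-gain moves the search
#' prefers delete over reverse over add, then the first arc in row-major
#' order of the variable ordering, so results are deterministic given the
#' seed.
#'
#' @param data a \code{\link{DiscreteDataset-class}}.
#' @param priorLogOdds optional symmetric numeric matrix (dimnames = the
#'   variables) of per-pair prior log-odds; \code{NULL} for pure BIC.
#' @param restarts number of random restarts (default 2).
#' @param maxIter move budget per search (default \code{10 * n^2}).
#' @param seed integer seed for the random restarts.
#' @return a \code{\link{DAG-class}}; attribute \code{"score"} holds the
#'   attained objective (BIC + prior log-odds of present skeleton edges).
#' @export
hillClimb <- function(data, priorLogOdds = NULL, restarts = 2L,
                      maxIter = NULL, seed = 1L) {
  vars <- colnames(data@values)
  n <- length(vars)
  if (is.null(maxIter)) maxIter <- 10L * n * n
  L <- priorLogOddsMatrix(data, priorLogOdds)
  empty <- matrix(0L, n, n)
  run <- .hc_search_cpp(data@values, data@arity, L, empty, maxIter)
  if (!run$converged)
    warning("hill climb stopped at the move budget (", maxIter,
            "); returning best-so-far")
  best <- run
  if (restarts > 0L) {
    set.seed(seed)
    for (r in seq_len(restarts)) {
      start <- randomDagAdjacency(n)
      cand <- .hc_search_cpp(data@values, data@arity, L, start, maxIter)
      if (cand$score > best$score + 1e-10) best <- cand
    }
  }
  adj <- best$adj
  dimnames(adj) <- list(vars, vars)
  out <- dagFromAdjacency(adj)
  attr(out, "score") <- best$score
  out
}

# random DAG via a random topological order and sparse forward arcs
randomDagAdjacency <- function(n) {
  ord <- sample.int(n)
  adj <- matrix(0L, n, n)
  if (n >= 2L) {
    p <- min(0.5, 2 / (n - 1))
    for (i in seq_len(n - 1L))
      for (j in seq.int(i + 1L, n))
        if (stats::runif(1) < p) adj[ord[i], ord[j]] <- 1L
  }
  adj
}

#' Bootstrap arc strengths (model averaging)
#'
#' Resamples the observations with replacement \code{B} times, runs the
#' hill-climbing search on each replicate, and reports for every unordered
#' variable pair the fraction of replicates whose network contains an arc
#' between the pair in either direction, plus the fraction of those arcs
#' oriented from the lexicographically smaller endpoint to the larger one.
#' Each replicate consumes its own child seed derived from \code{seed}, so
#' \code{B} can grow without reshuffling earlier replicates; rows are
#' canonicalized (sorted) before resampling, making the result invariant to
#' the row order of the input.
#'
#' @inheritParams hillClimb
#' @param B bootstrap replicate count (default 1000, the published setting;
#'   smaller values are appropriate at desk scale).
#' @param restarts random restarts per replicate (default 0; the averaging
#'   over replicates already explores the search space).
#' @return a \code{\link{StrengthTable-class}}.
#' @export
bootstrapStrengths <- function(data, priorLogOdds = NULL, B = 1000L,
                               seed = 1L, restarts = 0L, maxIter = NULL) {
  stopifnot(B >= 1L)
  vars <- colnames(data@values)
  n <- length(vars)
  if (is.null(maxIter)) maxIter <- 10L * n * n
  L <- priorLogOddsMatrix(data, priorLogOdds)
  # canonical row order: strengths independent of input row order
  ord <- do.call(order, split(data@values, col(data@values)))
  values <- data@values[ord, , drop = FALSE]
  N <- nrow(values)
  skel <- matrix(0, n, n)   # either-direction counts (upper triangle)
  fwd <- matrix(0, n, n)    # u -> v counts with u < v in column order
  for (b in seq_len(B)) {
    set.seed(childSeed(seed, 1L, b))
    rows <- sample.int(N, N, replace = TRUE)
    boot <- values[rows, , drop = FALSE]
    start <- matrix(0L, n, n)
    if (restarts > 0L) start <- randomDagAdjacency(n)
    run <- .hc_search_cpp(boot, data@arity, L, start, maxIter)
    adj <- run$adj
    if (restarts > 0L) {
      base <- .hc_search_cpp(boot, data@arity, L, matrix(0L, n, n), maxIter)
      if (base$score >= run$score) adj <- base$adj
    }
    up <- adj[upper.tri(adj)]
    lo <- t(adj)[upper.tri(adj)]
    skel[upper.tri(skel)] <- skel[upper.tri(skel)] + pmax(up, lo)
    fwd[upper.tri(fwd)] <- fwd[upper.tri(fwd)] + up
  }
  # map to lexicographic pair order over variable names
  pairs <- allPairs(vars)
  str <- numeric(nrow(pairs))
  fwdFrac <- rep(NA_real_, nrow(pairs))
  pos <- match(vars, vars) # identity; used for clarity below
  iu <- match(pairs[, 1L], vars)
  iv <- match(pairs[, 2L], vars)
  for (k in seq_len(nrow(pairs))) {
    i <- min(iu[k], iv[k]); j <- max(iu[k], iv[k])
    cnt <- skel[i, j]
    str[k] <- cnt / B
    if (cnt > 0) {
      f <- fwd[i, j] / cnt                 # fraction oriented vars[i]->vars[j]
      # express as smaller-name -> larger-name orientation
      fwdFrac[k] <- if (iu[k] == i) f else 1 - f
    }
  }
  new("StrengthTable", pairs = pairs, strength = str,
      fwdFraction = fwdFrac, B = as.integer(B))
}

#' Data-driven significance threshold for bootstrap strengths
#'
#' Finds the threshold \eqn{t} minimizing the L1 distance between the
#' empirical CDF of the strength values and the ideal one-step CDF that is 0
#' below \eqn{t} and 1 at or above it,
#' \eqn{g(t) = \int_0^t F(x)\,dx + \int_t^1 (1-F(x))\,dx}. The objective is
#' piecewise linear with knots at the observed values; the midpoint of the
#' minimizing interval is returned. Edges are "significant" when their
#' strength strictly exceeds the threshold.
#'
#' @param strengths numeric vector of strengths in [0, 1].
#' @return the threshold, a single value in [0, 1].
#' @export
significanceThreshold <- function(strengths) {
  stopifnot(length(strengths) >= 1L, all(strengths >= 0 & strengths <= 1))
  u <- sort(unique(strengths))
  if (length(u) == 1L) {
    warning("all strength values identical (", u,
            "); thresholding just below it retains every edge")
    return(u - .Machine$double.eps)
  }
  Fn <- stats::ecdf(strengths)
  knots <- unique(c(0, u, 1))
  g <- function(t) {
    # integral of F on [0, t] plus integral of (1 - F) on [t, 1]
    xs <- knots
    tot <- 0
    for (i in seq_len(length(xs) - 1L)) {
      lo <- xs[i]; hi <- xs[i + 1L]
      f <- Fn(lo)                      # F constant on [lo, hi)
      below <- max(0, min(hi, t) - lo)
      above <- max(0, hi - max(lo, t))
      tot <- tot + f * below + (1 - f) * above
    }
    tot
  }
  vals <- vapply(knots, g, numeric(1))
  minv <- min(vals)
  inRegion <- which(vals <= minv + 1e-12)
  (knots[min(inRegion)] + knots[max(inRegion)]) / 2
}

#' Fit conditional probability tables
#'
#' Multinomial maximum-a-posteriori estimates with an additive pseudo-count
#' per cell; every row of every CPT normalizes to one (unseen parent
#' configurations become uniform when \code{pseudo > 0}).
#'
#' @param x a \code{\link{DAG-class}}.
#' @param data a \code{\link{DiscreteDataset-class}} over the DAG's nodes.
#' @param pseudo nonnegative pseudo-count (default 1).
#' @return a named list; element \code{v} is an array with first dimension
#'   the states of \code{v} and one further dimension per parent (attribute
#'   \code{"parents"} gives their order).
#' @export
fitCPTs <- function(x, data, pseudo = 1) {
  stopifnot(pseudo >= 0)
  out <- list()
  for (v in x@nodes) {
    parents <- dagParents(x, v)
    r <- data@arity[[v]]
    if (length(parents) == 0L) {
      counts <- tabulate(data@values[, v] + 1L, nbins = r) + pseudo
      tab <- counts / sum(counts)
      dim(tab) <- r
      dimnames(tab) <- list(as.character(0:(r - 1L)))
    } else {
      dims <- c(r, unname(data@arity[parents]))
      tab <- array(pseudo, dim = dims,
                   dimnames = lapply(dims, function(d) as.character(0:(d - 1L))))
      idx <- cbind(data@values[, v] + 1L,
                   data@values[, parents, drop = FALSE] + 1L)
      for (i in seq_len(nrow(idx)))
        tab[matrix(idx[i, ], 1L)] <- tab[matrix(idx[i, ], 1L)] + 1
      # normalize over the child dimension
      norm <- apply(tab, seq_along(dims)[-1L], sum)
      tab <- sweep(tab, seq_along(dims)[-1L], norm, "/")
      tab[is.nan(tab)] <- 1 / r
    }
    attr(tab, "parents") <- parents
    out[[v]] <- tab
  }
  out
}

# ---------------------------------------------------------------------------
# Exact inference by variable elimination. Factors are lists with fields
# vars (character), card (integer) and val (numeric, column-major over vars).
# ---------------------------------------------------------------------------

factorFromCPT <- function(v, cpt) {
  parents <- attr(cpt, "parents")
  list(vars = c(v, parents), card = as.integer(dim(cpt)), val = as.numeric(cpt))
}

factorReduce <- function(f, var, state) {
  k <- match(var, f$vars)
  if (is.na(k)) return(f)
  arr <- array(f$val, dim = f$card)
  idx <- rep(list(quote(expr = )), length(f$card))
  idx[[k]] <- state + 1L
  arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), k)
  list(vars = f$vars[keep], card = f$card[keep], val = as.numeric(arr))
}

factorProduct <- function(f, g) {
  vars <- union(f$vars, g$vars)
  card <- integer(length(vars))
  card[match(f$vars, vars)] <- f$card
  card[match(g$vars, vars)] <- g$card
  n <- prod(card)
  # assignment matrix for the joint scope
  assign <- matrix(0L, n, length(vars))
  rep1 <- 1L
  for (j in seq_along(vars)) {
    assign[, j] <- rep(rep(0:(card[j] - 1L), each = rep1),
                       length.out = n)
    rep1 <- rep1 * card[j]
  }
  idxOf <- function(h) {
    cols <- match(h$vars, vars)
    if (length(cols) == 0L) return(rep(1L, n))
    mult <- cumprod(c(1L, h$card[-length(h$card)]))
    as.integer(assign[, cols, drop = FALSE] %*% mult) + 1L
  }
  list(vars = vars, card = card, val = f$val[idxOf(f)] * g$val[idxOf(g)])
}

factorMarginalize <- function(f, var) {
  k <- match(var, f$vars)
  if (is.na(k)) return(f)
  arr <- array(f$val, dim = f$card)
  keep <- seq_along(f$card)[-k]
  if (length(keep) == 0L)
    return(list(vars = character(0), card = integer(0), val = sum(arr)))
  val <- apply(arr, keep, sum)
  list(vars = f$vars[keep], card = f$card[keep], val = as.numeric(val))
}

#' Exact posterior by variable elimination
#'
#' @param x a \code{\link{DAG-class}}.
#' @param cpts conditional probability tables from \code{\link{fitCPTs}}.
#' @param evidence named integer vector of observed states (0-based); may be
#'   empty.
#' @param query the variable to query (not in the evidence).
#' @return numeric vector over the query's states, summing to one.
#' @export
inferPosterior <- function(x, cpts, evidence = integer(0), query) {
  stopifnot(query %in% x@nodes, !query %in% names(evidence),
            all(names(evidence) %in% x@nodes))
  factors <- lapply(names(cpts), function(v) factorFromCPT(v, cpts[[v]]))
  for (v in names(evidence))
    factors <- lapply(factors, factorReduce, var = v, state = evidence[[v]])
  elim <- setdiff(x@nodes, c(query, names(evidence)))
  # eliminate cheapest variable first (fewest touching factors)
  while (length(elim) > 0L) {
    touching <- vapply(elim, function(v)
      sum(vapply(factors, function(f) v %in% f$vars, logical(1))), integer(1))
    v <- elim[which.min(touching)]
    hit <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod <- Reduce(factorProduct, factors[hit])
    factors <- c(factors[!hit], list(factorMarginalize(prod, v)))
    elim <- setdiff(elim, v)
  }
  res <- Reduce(factorProduct, factors)
  if (!identical(res$vars, query)) {
    # reorder in case scalars multiplied in
    k <- match(query, res$vars)
    stopifnot(!is.na(k))
  }
  val <- res$val
  z <- sum(val)
  if (z <= 0)
    stop("evidence {", paste(names(evidence), evidence, sep = "=",
                             collapse = ", "),
         "} has zero probability under the model")
  val / z
}
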