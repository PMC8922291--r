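# Shared fixtures and independent oracles, built in code at test time.

# --- exhaustive DAG enumeration (oracle for hill climbing) -----------------

# all DAGs over the given nodes as a list of arc matrices
enumerateDags <- function(nodes) {
  n <- length(nodes)
  arcs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  arcs <- arcs[arcs$from != arcs$to, ]
  out <- list()
  for (mask in 0:(2^nrow(arcs) - 1)) {
    pick <- which(bitwAnd(mask, 2^(seq_len(nrow(arcs)) - 1L)) > 0)
    m <- as.matrix(arcs[pick, , drop = FALSE])
    ok <- tryCatch({ netatlas::dag(nodes, m); TRUE },
                   error = function(e) FALSE)
    if (ok) out[[length(out) + 1L]] <- m
  }
  out
}

# best score over all DAGs by brute force; returns list(score, skeletons)
bruteForceBest <- function(data, priorLogOdds = NULL, kappa = 1) {
  nodes <- colnames(data@values)
  best <- -Inf
  skeletons <- list()
  for (m in enumerateDags(nodes)) {
    g <- netatlas::dag(nodes, m)
    s <- netatlas::bicScore(g, data)
    if (!is.null(priorLogOdds)) {
      adj <- matrix(0L, length(nodes), length(nodes),
                    dimnames = list(nodes, nodes))
      if (nrow(m) > 0) adj[m] <- 1L
      skel <- (adj + t(adj))[upper.tri(adj)] > 0
      L <- priorLogOdds[nodes, nodes][upper.tri(adj)]
      s <- s + sum(ifelse(skel, L, 0))
    }
    if (s > best + 1e-9) {
      best <- s
      skeletons <- list(skeletonKeys(m))
    } else if (abs(s - best) <= 1e-9) {
      skeletons <- unique(c(skeletons, list(skeletonKeys(m))))
    }
  }
  list(score = best, skeletons = skeletons)
}

skeletonKeys <- function(arcs) {
  if (is.null(arcs) || nrow(arcs) == 0L) return(character(0))
  sort(unique(netatlas::pairKey(arcs[, 1L], arcs[, 2L])))
}

# --- joint-table enumeration (oracle for variable elimination) -------------

# posterior over `query` by enumerating all full assignments
jointEnumPosterior <- function(g, cpts, evidence, query) {
  nodes <- dagNodes(g)
  arity <- vapply(nodes, function(v) dim(as.array(cpts[[v]]))[1L], integer(1))
  grids <- lapply(arity, function(a) 0:(a - 1L))
  names(grids) <- nodes
  full <- expand.grid(grids)
  keep <- rep(TRUE, nrow(full))
  for (v in names(evidence)) keep <- keep & full[[v]] == evidence[[v]]
  full <- full[keep, , drop = FALSE]
  probs <- apply(full, 1L, function(row) {
    p <- 1
    for (v in nodes) {
      tab <- cpts[[v]]
      parents <- attr(tab, "parents")
      idx <- c(row[[v]] + 1L,
               if (length(parents)) as.integer(row[parents]) + 1L)
      p <- p * as.array(tab)[matrix(idx, 1L)]
    }
    p
  })
  qstates <- grids[[query]]
  post <- vapply(qstates, function(s) sum(probs[full[[query]] == s]),
                 numeric(1))
  post / sum(post)
}

# --- brute-force average precision (oracle for aucPRC) ---------------------

# direct computation over distinct thresholds with tie blocks
bruteForceAP <- function(scoreVec, truthVec) {
  ord <- order(-scoreVec)
  s <- scoreVec[ord]
  y <- truthVec[ord]
  thr <- unique(s)
  nTrue <- sum(y)
  ap <- 0
  for (t in thr) {
    sel <- s >= t
    prec <- sum(y[sel]) / sum(sel)
    inGroup <- s == t
    ap <- ap + sum(y[inGroup]) * prec
  }
  ap / nTrue
}

# --- small shared objects --------------------------------------------------

# tiny deterministic two-pathway system used across module tests
tinyAtlas <- function(seed = 11L) {
  generateAtlas(nPathways = 2L, meanPathwaySize = 8L, sizeDispersion = 0,
                overlapFraction = 0, meanDegree = 2, seed = seed)
}

# a hand-built BNP over one evidence node and GI: P(GI=1)=0.3,
# P(E=1|GI=1)=0.9, P(E=1|GI=0)=0.1
handBnp <- function() {
  g <- netatlas::dag(c("GI", "E"), cbind("GI", "E"))
  cptGI <- array(c(0.7, 0.3), dim = 2L, dimnames = list(c("0", "1")))
  attr(cptGI, "parents") <- character(0)
  cptE <- array(c(0.9, 0.1, 0.1, 0.9), dim = c(2L, 2L),
                dimnames = list(c("0", "1"), c("0", "1")))
  attr(cptE, "parents") <- "GI"
  list(dag = g, cpts = list(GI = cptGI, E = cptE))
}

# write a small KGML document; relations is a data.frame(e1, e2)
writeTestKGML <- function(path, entries, relations) {
  lines <- c('<?xml version="1.0"?>',
             '<pathway name="path:test01" org="test" number="01">')
  for (i in seq_len(nrow(entries)))
    lines <- c(lines, sprintf('  <entry id="%s" name="%s" type="%s"/>',
                              entries$id[i], entries$name[i],
                              entries$type[i]))
  for (i in seq_len(nrow(relations)))
    lines <- c(lines, sprintf(
      '  <relation entry1="%s" entry2="%s" type="PPrel"/>',
      relations$e1[i], relations$e2[i]))
  writeLines(c(lines, "</pathway>"), path)
  path
}
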