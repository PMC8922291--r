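# Within-cluster gene-network learning: pairwise fold-change observations,
# three-state discretization, MAP hill climbing under the BNP graph prior,
# bootstrap strengths and the significance consensus.

#' Pairwise fold-change observations between the two sample groups
#'
#' One observation per (test sample, control sample) pair: the log2 ratio
#' of each gene's abundance in the test sample over the control sample.
#' Rows are ordered test-major (all control partners of the first test
#' sample first).
#'
#' @param expr a \code{SummarizedExperiment} with
#'   \code{colData(expr)$condition} in \{test, control\} and positive
#'   abundances.
#' @param genes genes to include (default: all).
#' @return numeric matrix, \code{nTest * nControl} rows x genes columns,
#'   rownames \code{"<test>.<control>"}.
#' @export
pairwiseFoldChanges <- function(expr, genes = NULL) {
  x <- SummarizedExperiment::assay(expr)
  cond <- expr$condition
  testIdx <- which(cond == "test")
  ctrlIdx <- which(cond == "control")
  if (length(testIdx) == 0L || length(ctrlIdx) == 0L)
    stop("both sample groups must be nonempty")
  if (is.null(genes)) genes <- rownames(x)
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("gene(s) missing from expression data: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  if (any(x[genes, ] <= 0))
    stop("abundances must be strictly positive to form fold changes")
  lx <- log2(x[genes, , drop = FALSE])
  it <- rep(testIdx, each = length(ctrlIdx))
  ic <- rep(ctrlIdx, times = length(testIdx))
  obs <- t(lx[, it, drop = FALSE] - lx[, ic, drop = FALSE])
  rownames(obs) <- paste(colnames(x)[it], colnames(x)[ic], sep = ".")
  colnames(obs) <- genes
  obs
}

#' Discretize fold-change observations into down / unchanged / up
#'
#' States: 0 (down) when the value is \eqn{\le -\tau}, 2 (up) when
#' \eqn{\ge +\tau}, else 1 (unchanged). The default \eqn{\tau = 1} is the
#' conventional two-fold-change cutoff on the log2 scale.
#'
#' @param obs matrix from \code{\link{pairwiseFoldChanges}}.
#' @param tau positive threshold (default 1).
#' @return a \code{\link{DiscreteDataset-class}} with arity 3 everywhere.
#' @export
discretizeFoldChanges <- function(obs, tau = 1) {
  stopifnot(tau > 0)
  states <- matrix(1L, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  states[obs <= -tau] <- 0L
  states[obs >= tau] <- 2L
  discreteDataset(states, arity = rep(3L, ncol(obs)))
}

#' Learn a gene interaction network under the BNP prior
#'
#' MAP structure search: the objective is the BIC score of the discretized
#' fold-change dataset plus \eqn{\kappa} times the BNP graph log-prior.
#' Bootstrap model averaging (\code{B} replicates) yields per-pair
#' strengths; pairs whose strength exceeds the data-driven significance
#' threshold form the consensus edge set. With \code{kappa = 0} the prior
#' vanishes and the result equals prior-free learning under the same seed.
#'
#' @param expr a \code{SummarizedExperiment}.
#' @param genes the gene set to learn over (a singleton yields an empty
#'   network).
#' @param bnp a \code{\link{BNPModel-class}}.
#' @param E the knowledge \code{\link{EvidenceSet-class}}.
#' @param kappa prior weight (default 1).
#' @param B bootstrap replicates (default 100).
#' @param tau discretization threshold (default 1).
#' @param rho0 coexpression threshold for the prior (default 0.5).
#' @param seed integer seed.
#' @param priorMatrix optional precomputed \code{\link{pairPriorMatrix}}
#'   covering \code{genes} (computed when NULL).
#' @return a \code{\link{GeneNetwork-class}}.
#' @export
learnNetwork <- function(expr, genes, bnp, E, kappa = 1, B = 100L,
                         tau = 1, rho0 = 0.5, seed = 1L,
                         priorMatrix = NULL) {
  genes <- sort(unique(genes))
  if (length(genes) < 2L) {
    st <- new("StrengthTable",
              pairs = matrix(character(0), ncol = 2L),
              strength = numeric(0), fwdFraction = numeric(0), B = 1L)
    return(new("GeneNetwork", genes = genes, strengths = st,
               consensusEdges = matrix(character(0), ncol = 2L),
               threshold = 1))
  }
  obs <- pairwiseFoldChanges(expr, genes)
  data <- discretizeFoldChanges(obs, tau)
  L <- NULL
  if (kappa > 0) {
    if (is.null(priorMatrix))
      priorMatrix <- pairPriorMatrix(bnp, E, expr, genes, rho0 = rho0)
    p <- priorMatrix[genes, genes, drop = FALSE]
    L <- kappa * (log(p) - log1p(-p))
    diag(L) <- 0
  }
  st <- bootstrapStrengths(data, priorLogOdds = L, B = B, seed = seed)
  thr <- significanceThreshold(st@strength)
  sig <- st@strength > thr
  new("GeneNetwork", genes = genes, strengths = st,
      consensusEdges = st@pairs[sig, , drop = FALSE], threshold = thr)
}

#' Write a learned network as TSV
#'
#' Columns gene_a, gene_b, strength, significant; the significance
#' threshold is recorded in a header comment line.
#'
#' @param net a \code{\link{GeneNetwork-class}}.
#' @param path file path.
#' @export
writeNetwork <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# threshold\t%.6g", net@threshold), con)
  df <- data.frame(gene_a = net@strengths@pairs[, 1L],
                   gene_b = net@strengths@pairs[, 2L],
                   strength = net@strengths@strength,
                   significant = as.integer(net@strengths@strength >
                                              net@threshold))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(net)
}
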