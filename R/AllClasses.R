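#' @import methods
NULL

# ---------------------------------------------------------------------------
# Central S4 data containers. Edge matrices are always n x 2 character
# matrices with endpoints in lexicographic order within each row, so edge
# sets have well-defined set semantics.
# ---------------------------------------------------------------------------

#' PathwayGraph: one pathway's gene graph plus its cross-pathway references
#'
#' Gene nodes and gene--gene edges of one pathway, together with the "map"
#' entries (other pathways) it references and the genes linked, directly or
#' indirectly, to each referenced pathway.
#'
#' @slot pathwayId single pathway identifier.
#' @slot geneNodes character vector of gene identifiers.
#' @slot mapNodes character vector of referenced pathway identifiers.
#' @slot geneEdges n x 2 character matrix of unordered gene pairs.
#' @slot geneMapLinks data.frame with columns \code{gene}, \code{map},
#'   \code{direct} (logical): gene-to-referenced-pathway links.
#' @export
setClass("PathwayGraph",
  representation(pathwayId = "character", geneNodes = "character",
                 mapNodes = "character", geneEdges = "matrix",
                 geneMapLinks = "data.frame"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@pathwayId) != 1L)
      msg <- c(msg, "pathwayId must be a single identifier")
    e <- object@geneEdges
    if (ncol(e) != 2L) msg <- c(msg, "geneEdges must have 2 columns")
    if (nrow(e) > 0L) {
      if (!all(c(e) %in% object@geneNodes))
        msg <- c(msg, "every edge endpoint must be a declared gene node")
      if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
    }
    gml <- object@geneMapLinks
    if (!all(c("gene", "map", "direct") %in% names(gml)))
      msg <- c(msg, "geneMapLinks needs columns gene, map, direct")
    else if (nrow(gml) > 0L) {
      if (!all(gml$gene %in% object@geneNodes))
        msg <- c(msg, "geneMapLinks$gene must be declared gene nodes")
      if (!all(gml$map %in% object@mapNodes))
        msg <- c(msg, "geneMapLinks$map must be declared map nodes")
    }
    if (length(msg)) msg else TRUE
  })

#' Atlas: an undirected gene--gene interaction graph with pathway membership
#'
#' @slot nodes character vector of gene identifiers.
#' @slot edges n x 2 character matrix of unordered gene pairs
#'   (lexicographic endpoints, no self-loops, no duplicates).
#' @slot membership named list mapping each gene to the character vector of
#'   pathway identifiers it belongs to (every gene has at least one).
#' @export
setClass("Atlas",
  representation(nodes = "character", edges = "matrix",
                 membership = "list"),
  validity = function(object) {
    msg <- character(0)
    e <- object@edges
    if (ncol(e) != 2L) msg <- c(msg, "edges must have 2 columns")
    if (nrow(e) > 0L) {
      if (!all(c(e) %in% object@nodes))
        msg <- c(msg, "edge endpoints must be atlas nodes")
      if (any(e[, 1L] >= e[, 2L]))
        msg <- c(msg, "edge endpoints must be in lexicographic order (no self-loops)")
      if (anyDuplicated(paste(e[, 1L], e[, 2L])))
        msg <- c(msg, "duplicate edges")
    }
    if (!all(object@nodes %in% names(object@membership)) ||
        any(lengths(object@membership[object@nodes]) < 1L))
      msg <- c(msg, "every node needs at least one pathway membership")
    if (length(msg)) msg else TRUE
  })

#' DAG: a directed acyclic graph over named nodes
#'
#' @slot nodes character vector of node identifiers.
#' @slot arcs m x 2 character matrix of directed arcs (from, to).
#' @export
setClass("DAG",
  representation(nodes = "character", arcs = "matrix"),
  validity = function(object) {
    msg <- character(0)
    a <- object@arcs
    if (ncol(a) != 2L) msg <- c(msg, "arcs must have 2 columns")
    if (nrow(a) > 0L) {
      if (!all(c(a) %in% object@nodes))
        msg <- c(msg, "arcs must reference declared nodes")
      if (any(a[, 1L] == a[, 2L])) msg <- c(msg, "self-arcs are not allowed")
      g <- igraph::graph_from_edgelist(a, directed = TRUE)
      if (!igraph::is_dag(g)) msg <- c(msg, "graph contains a cycle")
    }
    if (length(msg)) msg else TRUE
  })

#' DiscreteDataset: complete discrete observations for network learning
#'
#' @slot values integer matrix, rows = observations, columns = variables;
#'   states are coded 0 .. arity-1.
#' @slot arity integer vector of per-variable state counts (named as the
#'   columns of \code{values}).
#' @export
setClass("DiscreteDataset",
  representation(values = "matrix", arity = "integer"),
  validity = function(object) {
    msg <- character(0)
    v <- object@values
    if (nrow(v) < 1L) msg <- c(msg, "need at least one observation")
    if (length(object@arity) != ncol(v))
      msg <- c(msg, "arity must have one entry per variable")
    else {
      if (any(object@arity < 2L)) msg <- c(msg, "arity must be >= 2")
      mx <- suppressWarnings(apply(v, 2L, max))
      if (nrow(v) >= 1L && any(mx >= object@arity | apply(v, 2L, min) < 0L))
        msg <- c(msg, "values must lie in 0 .. arity-1")
    }
    if (is.null(colnames(v))) msg <- c(msg, "variables must be named")
    if (length(msg)) msg else TRUE
  })

#' StrengthTable: bootstrap arc strengths over unordered node pairs
#'
#' \code{strength} is the fraction of bootstrap networks containing an arc
#' between the pair in either direction; \code{fwdFraction} is, among those,
#' the fraction oriented from the lexicographically smaller to the larger
#' endpoint (used to fix consensus directions).
#'
#' @slot pairs n x 2 character matrix (lexicographic endpoints).
#' @slot strength numeric vector in [0, 1], one per pair.
#' @slot fwdFraction numeric vector in [0, 1] (NA where strength is 0).
#' @slot B integer bootstrap replicate count.
#' @export
setClass("StrengthTable",
  representation(pairs = "matrix", strength = "numeric",
                 fwdFraction = "numeric", B = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@pairs) != length(object@strength))
      msg <- c(msg, "one strength per pair required")
    if (length(object@fwdFraction) != length(object@strength))
      msg <- c(msg, "one fwdFraction per pair required")
    if (length(object@strength) &&
        (min(object@strength) < 0 || max(object@strength) > 1))
      msg <- c(msg, "strengths must lie in [0, 1]")
    if (object@B < 1L) msg <- c(msg, "B must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' EvidenceSet: binary evidence-type vectors over unordered gene pairs
#'
#' @slot pairs n x 2 character matrix of unordered gene pairs
#'   (lexicographic endpoints, unique).
#' @slot types integer 0/1 matrix, one row per pair, one column per
#'   evidence type (column names are the type names).
#' @slot experimentalTypes character vector naming the columns that are
#'   computed from expression data at run time rather than taken from the
#'   knowledge base.
#' @slot gi integer vector of GI labels (length 0 until \code{labelGI} is
#'   called).
#' @export
setClass("EvidenceSet",
  representation(pairs = "matrix", types = "matrix",
                 experimentalTypes = "character", gi = "integer"),
  validity = function(object) {
    msg <- character(0)
    p <- object@pairs
    if (ncol(p) != 2L) msg <- c(msg, "pairs must have 2 columns")
    if (nrow(p) != nrow(object@types))
      msg <- c(msg, "one evidence row per pair required")
    if (nrow(p) > 0L) {
      if (any(p[, 1L] >= p[, 2L]))
        msg <- c(msg, "pair endpoints must be in lexicographic order")
      if (anyDuplicated(paste(p[, 1L], p[, 2L])))
        msg <- c(msg, "duplicate pair keys")
    }
    tv <- object@types
    if (length(tv) && !all(tv %in% c(0L, 1L)))
      msg <- c(msg, "evidence values must be 0/1")
    if (is.null(colnames(tv))) msg <- c(msg, "evidence types must be named")
    if (!all(object@experimentalTypes %in% colnames(tv)))
      msg <- c(msg, "experimentalTypes must be existing columns")
    if (length(object@gi) &&
        (length(object@gi) != nrow(p) || !all(object@gi %in% c(0L, 1L))))
      msg <- c(msg, "gi must be a 0/1 vector with one entry per pair")
    if (length(msg)) msg else TRUE
  })

#' BNPModel: a Bayesian network prior over evidence types and the GI node
#'
#' A discrete Bayesian network with one node per evidence type plus a "GI"
#' node; instantiating the evidence nodes and querying GI yields the prior
#' probability that a gene pair interacts.
#'
#' @slot dag consensus \code{DAG} over the evidence types and "GI".
#' @slot cpts named list of conditional probability tables (see
#'   \code{\link{fitCPTs}}).
#' @slot strengths the bootstrap \code{StrengthTable} behind the consensus.
#' @slot threshold the significance threshold applied to the strengths.
#' @slot experimentalTypes evidence types instantiated from expression data.
#' @export
setClass("BNPModel",
  representation(dag = "DAG", cpts = "list", strengths = "StrengthTable",
                 threshold = "numeric", experimentalTypes = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!"GI" %in% object@dag@nodes)
      msg <- c(msg, "the DAG must contain the GI node")
    if (length(object@threshold) != 1L)
      msg <- c(msg, "threshold must be a single value")
    if (length(msg)) msg else TRUE
  })

#' GeneNetwork: a learned within-cluster interaction network
#'
#' @slot genes the gene set the network was learned over.
#' @slot strengths \code{StrengthTable} over all unordered gene pairs.
#' @slot consensusEdges pairs whose strength exceeds the threshold.
#' @slot threshold the data-driven significance threshold.
#' @export
setClass("GeneNetwork",
  representation(genes = "character", strengths = "StrengthTable",
                 consensusEdges = "matrix", threshold = "numeric"),
  validity = function(object) {
    msg <- character(0)
    ce <- object@consensusEdges
    if (nrow(ce) > 0L) {
      have <- pairKey(object@strengths@pairs[, 1L], object@strengths@pairs[, 2L])
      want <- pairKey(ce[, 1L], ce[, 2L])
      if (!all(want %in% have))
        msg <- c(msg, "consensus edges must be scored pairs")
    }
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
# show() methods
# ---------------------------------------------------------------------------

setMethod("show", "PathwayGraph", function(object) {
  cat("PathwayGraph", object@pathwayId, "\n",
      " genes: ", length(object@geneNodes),
      "  edges: ", nrow(object@geneEdges),
      "  map refs: ", length(object@mapNodes),
      "  gene-map links: ", nrow(object@geneMapLinks), "\n", sep = "")
})

setMethod("show", "Atlas", function(object) {
  cat("Atlas with", length(object@nodes), "genes,",
      nrow(object@edges), "edges,",
      length(unique(unlist(object@membership))), "pathways\n")
})

setMethod("show", "DAG", function(object) {
  cat("DAG with", length(object@nodes), "nodes and",
      nrow(object@arcs), "arcs\n")
})

setMethod("show", "DiscreteDataset", function(object) {
  cat("DiscreteDataset:", nrow(object@values), "observations of",
      ncol(object@values), "variables (arity",
      paste(range(object@arity), collapse = "-"), ")\n")
})

setMethod("show", "StrengthTable", function(object) {
  cat("StrengthTable:", length(object@strength), "pairs from",
      object@B, "bootstrap replicates;",
      sum(object@strength > 0), "with nonzero strength\n")
})

setMethod("show", "EvidenceSet", function(object) {
  cat("EvidenceSet:", nrow(object@pairs), "gene pairs x",
      ncol(object@types), "evidence types",
      if (length(object@gi)) "(GI labeled)" else "(no GI labels)", "\n")
})

setMethod("show", "BNPModel", function(object) {
  cat("BNPModel over", length(object@dag@nodes) - 1L,
      "evidence types + GI;", nrow(object@dag@arcs),
      "consensus arcs (strength threshold",
      signif(object@threshold, 3), ")\n")
})

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork over", length(object@genes), "genes;",
      nrow(object@consensusEdges), "significant edges (threshold",
      signif(object@threshold, 3), ")\n")
})

# ---------------------------------------------------------------------------
# Accessors
# ---------------------------------------------------------------------------

#' @describeIn Atlas-class gene identifiers
#' @param x an \code{Atlas}.
#' @export
atlasNodes <- function(x) x@nodes

#' @describeIn Atlas-class edge matrix (n x 2, lexicographic)
#' @export
atlasEdges <- function(x) x@edges

#' @describeIn Atlas-class named list gene -> pathway ids
#' @export
atlasMembership <- function(x) x@membership

#' @describeIn DAG-class node identifiers
#' @param x a \code{DAG}.
#' @export
dagNodes <- function(x) x@nodes

#' @describeIn DAG-class arc matrix (from, to)
#' @export
dagArcs <- function(x) x@arcs

#' @describeIn StrengthTable-class data.frame view (a, b, strength, fwdFraction)
#' @param x a \code{StrengthTable}.
#' @export
strengthTable <- function(x) {
  data.frame(a = x@pairs[, 1L], b = x@pairs[, 2L],
             strength = x@strength, fwdFraction = x@fwdFraction,
             stringsAsFactors = FALSE)
}

#' @describeIn GeneNetwork-class significant (consensus) edges
#' @param x a \code{GeneNetwork}.
#' @export
networkEdges <- function(x) x@consensusEdges

#' @describeIn GeneNetwork-class the bootstrap strength table
#' @export
networkStrengths <- function(x) x@strengths

#' @describeIn GeneNetwork-class the significance threshold
#' @export
networkThreshold <- function(x) x@threshold

#' @describeIn EvidenceSet-class pair matrix
#' @param x an \code{EvidenceSet}.
#' @export
evidencePairs <- function(x) x@pairs

#' @describeIn EvidenceSet-class 0/1 evidence matrix
#' @export
evidenceTypes <- function(x) x@types

#' @describeIn EvidenceSet-class GI labels (integer 0/1, empty until labeled)
#' @export
giLabels <- function(x) x@gi
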