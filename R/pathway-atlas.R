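# Ground-truth atlas construction: merge per-pathway gene graphs through
# their reciprocal cross-pathway ("map") references, and read/write the
# pathway and atlas text formats.

#' Construct a PathwayGraph
#'
#' @param pathwayId single pathway identifier.
#' @param geneNodes character vector of gene identifiers.
#' @param mapNodes character vector of referenced pathway identifiers.
#' @param geneEdges n x 2 character matrix (or NULL) of gene pairs;
#'   canonicalized (lexicographic endpoints, self-loops dropped).
#' @param geneMapLinks data.frame with columns \code{gene}, \code{map} and
#'   optionally \code{direct} (logical; default TRUE).
#' @return a \code{\link{PathwayGraph-class}} object.
#' @export
pathwayGraph <- function(pathwayId, geneNodes, mapNodes = character(0),
                         geneEdges = NULL, geneMapLinks = NULL) {
  edges <- canonicalPairs(geneEdges)
  if (is.null(geneMapLinks))
    geneMapLinks <- data.frame(gene = character(0), map = character(0),
                               direct = logical(0))
  if (is.null(geneMapLinks$direct))
    geneMapLinks$direct <- rep(TRUE, nrow(geneMapLinks))
  geneMapLinks <- unique(geneMapLinks[, c("gene", "map", "direct")])
  new("PathwayGraph", pathwayId = as.character(pathwayId),
      geneNodes = unique(as.character(geneNodes)),
      mapNodes = unique(as.character(mapNodes)),
      geneEdges = edges, geneMapLinks = geneMapLinks)
}

#' Genes of a pathway linked to a referenced pathway
#'
#' Returns the gene set \eqn{G_{XY}}: all genes of pathway \code{p} with a
#' direct or indirect link to the referenced pathway \code{target}.
#'
#' @param p a \code{\link{PathwayGraph-class}}.
#' @param target a pathway identifier among \code{p}'s map nodes.
#' @return character vector of gene identifiers (possibly empty).
#' @export
linkedGeneSet <- function(p, target) {
  if (!target %in% p@mapNodes)
    stop("pathway ", p@pathwayId, " has no map reference to '", target, "'")
  sort(unique(p@geneMapLinks$gene[p@geneMapLinks$map == target]))
}

#' Merge pathway graphs into an interaction atlas
#'
#' The atlas nodes are the union of all pathway gene sets and its edges the
#' union of all within-pathway edges plus, for every pathway pair \{X, Y\}
#' that reference each other, all pairs \eqn{G_{XY} \times G_{YX}} (the
#' bipartite product of the genes each pathway links to the other).
#' One-sided references add no cross edges; self-pairs are excluded and
#' duplicates collapsed.
#'
#' @param pathways list of \code{\link{PathwayGraph-class}} objects with
#'   unique pathway ids.
#' @return an \code{\link{Atlas-class}}; membership records each gene's
#'   source pathways.
#' @export
mergePathways <- function(pathways) {
  if (length(pathways) == 0L) stop("need at least one pathway")
  ids <- vapply(pathways, function(p) p@pathwayId, character(1))
  if (anyDuplicated(ids)) stop("pathway ids must be unique")
  names(pathways) <- ids
  nodes <- sort(unique(unlist(lapply(pathways, function(p) p@geneNodes))))
  edgeList <- lapply(pathways, function(p) p@geneEdges)
  # cross edges for reciprocally referencing pathway pairs
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      X <- pathways[[i]]; Y <- pathways[[j]]
      if (Y@pathwayId %in% X@mapNodes && X@pathwayId %in% Y@mapNodes) {
        gxy <- linkedGeneSet(X, Y@pathwayId)
        gyx <- linkedGeneSet(Y, X@pathwayId)
        if (length(gxy) && length(gyx)) {
          cross <- cbind(rep(gxy, each = length(gyx)),
                         rep(gyx, times = length(gxy)))
          edgeList[[length(edgeList) + 1L]] <- cross
        }
      }
    }
  }
  edges <- canonicalPairs(do.call(rbind, edgeList))
  membership <- vector("list", length(nodes))
  names(membership) <- nodes
  for (p in pathways)
    for (g in p@geneNodes)
      membership[[g]] <- c(membership[[g]], p@pathwayId)
  membership <- lapply(membership, function(v) sort(unique(v)))
  new("Atlas", nodes = nodes, edges = edges, membership = membership)
}

#' Read a KGML pathway file
#'
#' Parses a KGML (KEGG Markup Language) document: entries of type
#' \code{gene} become gene nodes (whitespace-separated names yield one node
#' per identifier, taken verbatim), entries of type \code{map} become map
#' nodes, and \code{relation} elements between two gene entries become gene
#' edges. A gene acquires a link to map \code{M} when a relation connects
#' them directly, or indirectly through a chain of entries that are neither
#' genes nor maps (compounds, groups, ...).
#'
#' @param path path to a KGML file.
#' @return a \code{\link{PathwayGraph-class}}.
#' @export
readKGML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed KGML in '", path, "': ", conditionMessage(e)))
  root <- xml2::xml_find_first(doc, "/pathway")
  pid <- xml2::xml_attr(root, "name")
  if (is.na(pid)) pid <- basename(path)
  entries <- xml2::xml_find_all(doc, "//entry")
  eid <- xml2::xml_attr(entries, "id")
  etype <- xml2::xml_attr(entries, "type")
  ename <- xml2::xml_attr(entries, "name")
  genesOf <- function(k) strsplit(trimws(ename[k]), "\\s+")[[1]]
  geneIdx <- which(etype == "gene")
  mapIdx <- which(etype == "map")
  geneNodes <- sort(unique(unlist(lapply(geneIdx, genesOf))))
  mapNodes <- sort(unique(ename[mapIdx]))
  rels <- xml2::xml_find_all(doc, "//relation")
  r1 <- xml2::xml_attr(rels, "entry1")
  r2 <- xml2::xml_attr(rels, "entry2")
  k1 <- match(r1, eid); k2 <- match(r2, eid)
  ok <- !is.na(k1) & !is.na(k2)
  k1 <- k1[ok]; k2 <- k2[ok]
  # gene-gene edges: all cross pairs of the two entries' gene identifiers
  edges <- NULL
  gg <- which(etype[k1] == "gene" & etype[k2] == "gene")
  if (length(gg)) {
    edges <- do.call(rbind, lapply(gg, function(i) {
      ga <- genesOf(k1[i]); gb <- genesOf(k2[i])
      cbind(rep(ga, each = length(gb)), rep(gb, times = length(ga)))
    }))
  }
  # entry-level undirected relation graph for map-link chains
  n <- length(eid)
  adj <- vector("list", n)
  for (i in seq_along(k1)) {
    adj[[k1[i]]] <- c(adj[[k1[i]]], k2[i])
    adj[[k2[i]]] <- c(adj[[k2[i]]], k1[i])
  }
  links <- list()
  for (m in mapIdx) {
    # BFS from the map entry through non-gene, non-map intermediates
    direct <- intersect(adj[[m]], geneIdx)
    seen <- rep(FALSE, n); seen[m] <- TRUE
    queue <- setdiff(adj[[m]], c(geneIdx, mapIdx))
    reach <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      reach <- c(reach, v)
      queue <- c(queue, setdiff(adj[[v]], c(geneIdx, mapIdx)))
    }
    indirect <- setdiff(intersect(unique(unlist(adj[reach])), geneIdx), direct)
    for (k in direct)
      links[[length(links) + 1L]] <-
        data.frame(gene = genesOf(k), map = ename[m], direct = TRUE)
    for (k in indirect)
      links[[length(links) + 1L]] <-
        data.frame(gene = genesOf(k), map = ename[m], direct = FALSE)
  }
  gml <- if (length(links)) do.call(rbind, links) else NULL
  pathwayGraph(pid, geneNodes, mapNodes, edges, gml)
}

#' Write / read an atlas as tab-separated text
#'
#' \code{writeAtlas} emits a 2-column edge list (gene_a, gene_b,
#' lexicographic) and a membership table (gene, pathway_id);
#' \code{readAtlas} reads them back.
#'
#' @param atlas an \code{\link{Atlas-class}}.
#' @param edgeFile path for the edge-list TSV.
#' @param membershipFile path for the membership TSV.
#' @return \code{writeAtlas} returns the atlas invisibly; \code{readAtlas}
#'   returns an \code{Atlas}.
#' @export
writeAtlas <- function(atlas, edgeFile, membershipFile) {
  utils::write.table(
    data.frame(gene_a = atlas@edges[, 1L], gene_b = atlas@edges[, 2L]),
    edgeFile, sep = "\t", quote = FALSE, row.names = FALSE)
  mem <- data.frame(
    gene = rep(names(atlas@membership), lengths(atlas@membership)),
    pathway_id = unlist(atlas@membership, use.names = FALSE))
  utils::write.table(mem, membershipFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(atlas)
}

#' @rdname writeAtlas
#' @export
readAtlas <- function(edgeFile, membershipFile) {
  ed <- utils::read.table(edgeFile, sep = "\t", header = TRUE,
                          colClasses = "character")
  mem <- utils::read.table(membershipFile, sep = "\t", header = TRUE,
                           colClasses = "character")
  membership <- split(mem$pathway_id, mem$gene)
  membership <- lapply(membership, function(v) sort(unique(v)))
  nodes <- sort(names(membership))
  new("Atlas", nodes = nodes,
      edges = canonicalPairs(as.matrix(ed[, 1:2])),
      membership = membership[nodes])
}
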