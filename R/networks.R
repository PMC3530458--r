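# Community network models over the OTU matrix: sample-correlation network
# with maximum spanning tree backbone, bipartite sample-OTU probability
# network, and the combined mixed-model network pruned by a second
# spanning-tree pass.
#
# Graphs are igraph objects. Vertex attributes: kind ("sample"/"otu"),
# vineyard (samples), size (set at finalization). Edge attributes: weight
# (the exported weight, always the ORIGINAL quantity), original_weight,
# edge_kind ("correlation"/"probability").

#' @importFrom igraph graph_from_data_frame vertex_attr edge_attr V E
#'   as_data_frame ecount vcount components write_graph read_graph degree
#'   is_connected set_vertex_attr
NULL

#' All-against-all sample correlation network
#'
#' Complete graph on the samples of an \linkS4class{OTUMatrix}; each edge
#' is weighted with the Pearson correlation between the two samples' OTU
#' fluorescence vectors. Sample nodes carry their vineyard label.
#'
#' @param x an \linkS4class{OTUMatrix} with at least two samples
#' @return an igraph graph with edge attributes \code{weight},
#'   \code{original_weight} and \code{edge_kind = "correlation"}
#' @examples
#' m <- OTUMatrix(rbind(A = c(1, 2, 3), B = c(3, 2, 1), C = c(1, 3, 2)))
#' igraph::E(correlationNetwork(m))$weight
#' @export
correlationNetwork <- function(x) {
  stopifnot(is(x, "OTUMatrix"))
  m <- otuAbundance(x)
  if (nrow(m) < 2) stop("need at least 2 samples")
  sdv <- apply(m, 1, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance sample vector(s): ",
         paste(rownames(m)[sdv == 0], collapse = ", "))
  r <- stats::cor(t(m))
  pair <- utils::combn(nrow(m), 2)
  edges <- data.frame(
    from = rownames(m)[pair[1, ]], to = rownames(m)[pair[2, ]],
    weight = r[t(pair)]
  )
  edges$original_weight <- edges$weight
  edges$edge_kind <- "correlation"
  meta <- sampleData(x)
  verts <- data.frame(name = rownames(m), kind = "sample",
    vineyard = if ("vineyard" %in% names(meta))
      as.character(meta$vineyard) else NA_character_)
  graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

## Kruskal's algorithm with deterministic tie-breaking: edges are taken in
## order of (cost, lexicographic sorted endpoint pair). `preselect` indices
## are forced into the forest first (must be acyclic). Returns indices of
## the selected edges or errors if no spanning tree exists.
.kruskal <- function(vnames, from, to, cost, preselect = integer()) {
  n <- length(vnames)
  a <- pmin(from, to)
  b <- pmax(from, to)
  ord <- order(cost, a, b)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  chosen <- integer()
  take <- function(k) {
    ra <- find(match(a[k], vnames))
    rb <- find(match(b[k], vnames))
    if (ra != rb) {
      parent[ra] <<- rb
      chosen <<- c(chosen, k)
    }
  }
  for (k in preselect) take(k)
  for (k in ord) if (!(k %in% preselect)) take(k)
  if (length(chosen) != n - 1)
    stop("graph is not connected: spanning tree impossible")
  chosen
}

## rebuild a graph keeping only the selected edges (attributes preserved)
.edgeSubgraph <- function(edges, verts, keep) {
  graph_from_data_frame(edges[keep, , drop = FALSE], directed = FALSE,
                        vertices = verts)
}

.connectedOrStop <- function(g, what) {
  comp <- components(g)
  if (comp$no > 1) {
    sets <- split(V(g)$name, comp$membership)
    stop(what, " is disconnected; components: ",
         paste(vapply(sets, paste, "", collapse = ","), collapse = " | "))
  }
  invisible(g)
}

#' Maximum spanning tree of a correlation network
#'
#' Transforms each edge weight into an inverse correlation, 1 - |r|, and
#' runs a minimum spanning tree search on the transformed costs, which
#' selects the highest-correlation pairs connecting all nodes. Surviving
#' edges keep their original signed correlations as weights. Ties are
#' broken deterministically by the lexicographically sorted endpoint pair,
#' so the output is unique and input-order invariant.
#'
#' @param net an igraph graph with a \code{weight} edge attribute,
#'   connected
#' @return an igraph tree with \code{vcount - 1} edges; node attribute
#'   \code{degree} records each node's incident edge count in the tree
#' @export
maximumSpanningTree <- function(net) {
  .connectedOrStop(net, "input network")
  edges <- as_data_frame(net, what = "edges")
  verts <- as_data_frame(net, what = "vertices")
  keep <- .kruskal(verts$name, edges$from, edges$to,
                   cost = 1 - abs(edges$weight))
  tree <- .edgeSubgraph(edges, verts, keep)
  set_vertex_attr(tree, "degree", value = degree(tree))
}

#' OTU occurrence probabilities per sample
#'
#' Divides each element of a sample's OTU vector by the vector's total, so
#' each entry becomes the probability of that sample containing that OTU;
#' zeros are preserved and every sample row sums to 1.
#'
#' @param x an \linkS4class{OTUMatrix} with no all-zero sample
#' @return a \linkS4class{ProbabilityMatrix}
#' @examples
#' m <- OTUMatrix(rbind(A = c(2, 3, 5)))
#' otuAbundance(probabilityMatrix(m))
#' @export
probabilityMatrix <- function(x) {
  stopifnot(is(x, "OTUMatrix"))
  m <- otuAbundance(x)
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("all-zero sample vector(s): ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  p <- m / tot
  new("ProbabilityMatrix", OTUMatrix(p, sampleData(x)))
}

#' Bipartite sample-OTU probability network
#'
#' Creates an edge between a sample and an OTU exactly when the occurrence
#' probability is greater than zero, weighted with that probability. OTU
#' node names are prefixed \code{"OTU_"} so they never collide with sample
#' ids; sample nodes carry their vineyard label.
#'
#' @param pmat a \linkS4class{ProbabilityMatrix}
#' @return a bipartite igraph graph (\code{kind} is "sample" or "otu")
#' @export
probabilityNetwork <- function(pmat) {
  stopifnot(is(pmat, "ProbabilityMatrix"))
  p <- otuAbundance(pmat)
  otuNames <- paste0("OTU_", colnames(p))
  nz <- which(p > 0, arr.ind = TRUE)
  edges <- data.frame(
    from = rownames(p)[nz[, 1]], to = otuNames[nz[, 2]],
    weight = p[nz]
  )
  edges$original_weight <- edges$weight
  edges$edge_kind <- "probability"
  meta <- sampleData(pmat)
  verts <- rbind(
    data.frame(name = rownames(p), kind = "sample",
      vineyard = if ("vineyard" %in% names(meta))
        as.character(meta$vineyard) else NA_character_),
    data.frame(name = otuNames, kind = "otu", vineyard = NA_character_)
  )
  graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Mixed-model network: correlation backbone united with OTU probabilities
#'
#' Represents the most probable community structure of each sampling point
#' by combining the sample maximum-spanning-tree backbone with the
#' bipartite probability network, exactly in this order: (1) multiply the
#' backbone edge weights by \code{scale} (default 10); (2) union the two
#' edge sets, merging node attributes; (3) transform every edge weight w
#' into the inverse value |1 - w|; (4) minimum spanning tree on the
#' transformed costs with deterministic tie-breaking; (5) restore the
#' original, untransformed weights (unscaled correlation for backbone
#' edges, probability for sample-OTU edges) on the surviving edges;
#' (6) size sample nodes by degree and OTU nodes by the probability on
#' their surviving edge (the maximum when several survive).
#'
#' Taken literally, the |1 - scale*r| transform makes scaled backbone edges
#' costly next to probability edges (whose cost is below 1), so the pruned
#' tree tends to retain few backbone edges; \code{forceBackbone = TRUE}
#' instead pins every backbone edge into the tree before the remaining
#' edges compete.
#'
#' @param backbone the sample maximum spanning tree
#'   (\code{\link{maximumSpanningTree}} of \code{\link{correlationNetwork}})
#' @param probnet the \code{\link{probabilityNetwork}} over the same samples
#' @param scale multiplier applied to backbone weights before the union
#' @param forceBackbone keep all backbone edges in the final tree
#' @return an igraph tree; edge \code{weight} holds the original
#'   correlation or probability, \code{edge_kind} tells which
#' @export
mixedModelNetwork <- function(backbone, probnet, scale = 10,
                              forceBackbone = FALSE) {
  bSamples <- V(backbone)$name
  pVerts <- as_data_frame(probnet, what = "vertices")
  if (!all(bSamples %in% pVerts$name[pVerts$kind == "sample"]))
    stop("backbone sample nodes must all appear in the probability network")

  bE <- as_data_frame(backbone, what = "edges")
  pE <- as_data_frame(probnet, what = "edges")
  edges <- data.frame(
    from = c(bE$from, pE$from), to = c(bE$to, pE$to),
    original_weight = c(bE$original_weight, pE$original_weight),
    edge_kind = c(rep("correlation", nrow(bE)),
                  rep("probability", nrow(pE)))
  )
  scaled <- ifelse(edges$edge_kind == "correlation",
                   scale * edges$original_weight, edges$original_weight)
  edges$weight <- edges$original_weight

  bV <- as_data_frame(backbone, what = "vertices")
  verts <- pVerts[c("name", "kind", "vineyard")]
  extra <- setdiff(bV$name, verts$name)  # defensive; normally empty
  if (length(extra))
    verts <- rbind(verts, data.frame(name = extra, kind = "sample",
                                     vineyard = NA_character_))
  union <- graph_from_data_frame(edges, directed = FALSE, vertices = verts)
  .connectedOrStop(union, "union network")

  pre <- if (forceBackbone) seq_len(nrow(bE)) else integer()
  keep <- .kruskal(verts$name, edges$from, edges$to,
                   cost = abs(1 - scaled), preselect = pre)
  tree <- .edgeSubgraph(edges, verts, keep)
  tree <- set_vertex_attr(tree, "degree", value = degree(tree))
  size <- as.numeric(degree(tree))
  isOtu <- V(tree)$kind == "otu"
  size[isOtu] <- vapply(which(isOtu), function(v) {
    inc <- igraph::incident(tree, v)
    if (length(inc)) max(inc$weight) else 0
  }, 0)
  set_vertex_attr(tree, "size", value = size)
}

#' Same-vineyard adjacency enrichment in a sample tree
#'
#' Tests whether tree edges join samples from the same vineyard more often
#' than expected if vineyard labels were arbitrary: the observed count of
#' same-vineyard edges is compared against a null built by permuting the
#' vineyard labels across the nodes. The empirical p-value uses the
#' standard add-one correction, p = (1 + #\{null >= observed\}) / (nPerm + 1).
#' A small p is the graph analogue of farming systems being discriminable
#' from the community data.
#'
#' @param tree a sample tree with a \code{vineyard} vertex attribute
#' @param nPerm number of label permutations (default 200)
#' @param seed optional integer seed for the permutation draw
#' @return list with \code{observed}, \code{null} (vector of permuted
#'   counts) and \code{p_value}
#' @export
vineyardAdjacencyTest <- function(tree, nPerm = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lab <- V(tree)$vineyard
  ends <- as_data_frame(tree, what = "edges")
  i <- match(ends$from, V(tree)$name)
  j <- match(ends$to, V(tree)$name)
  same <- function(l) sum(l[i] == l[j])
  observed <- same(lab)
  null <- vapply(seq_len(nPerm), function(k) same(sample(lab)), 0L)
  list(observed = observed, null = null,
       p_value = (1 + sum(null >= observed)) / (nPerm + 1))
}

#' Export a network to SIF, GraphML or CSV edge list
#'
#' GraphML round-trips nodes, edges and attributes through any
#' GraphML-aware viewer (e.g. Cytoscape). SIF encodes \code{edge_kind} as
#' the interaction label (\code{source kind target} per line). The CSV edge
#' list has columns \code{source,target,edge_kind,weight,original_weight}.
#'
#' @param net an igraph graph
#' @param path output file path
#' @param format one of \code{"graphml"}, \code{"sif"}, \code{"csv"}
#' @return \code{path}, invisibly
#' @export
exportNetwork <- function(net, path, format = c("graphml", "sif", "csv")) {
  format <- match.arg(format)
  edges <- as_data_frame(net, what = "edges")
  if (format == "graphml") {
    write_graph(net, path, format = "graphml")
  } else if (format == "sif") {
    kind <- if ("edge_kind" %in% names(edges) && nrow(edges))
      edges$edge_kind else rep("link", nrow(edges))
    writeLines(if (nrow(edges))
      paste(edges$from, kind, edges$to) else character(), path)
  } else {
    out <- data.frame(
      source = edges$from, target = edges$to,
      edge_kind = if ("edge_kind" %in% names(edges)) edges$edge_kind
                  else NA_character_,
      weight = if ("weight" %in% names(edges)) edges$weight else NA_real_,
      original_weight = if ("original_weight" %in% names(edges))
        edges$original_weight else NA_real_
    )
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}
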