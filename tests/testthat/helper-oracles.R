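# Independent oracles used across tests: brute-force spanning-tree
# enumeration, a from-the-formula Pearson correlation, and small random
# instance generators.

## exhaustive minimum spanning tree: enumerate all (n-1)-edge subsets
bruteMST <- function(vnames, from, to, cost) {
  n <- length(vnames)
  m <- length(from)
  best <- NULL
  bestCost <- Inf
  for (idx in utils::combn(m, n - 1, simplify = FALSE)) {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    ok <- TRUE
    for (k in idx) {
      ra <- find(match(from[k], vnames))
      rb <- find(match(to[k], vnames))
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (!ok) next
    tc <- sum(cost[idx])
    if (tc < bestCost) { bestCost <- tc; best <- idx }
  }
  list(cost = bestCost, edges = best)
}

edgeKey <- function(from, to) {
  paste(pmin(from, to), pmax(from, to), sep = "|")
}

## Pearson correlation written out from its definition, independent of cor()
pearsonByFormula <- function(x, y) {
  n <- length(x)
  sum((x - sum(x) / n) * (y - sum(y) / n)) /
    sqrt(sum((x - sum(x) / n)^2) * sum((y - sum(y) / n)^2))
}

## random complete weighted graph on n nodes, weights in [-1, 1]
randomCorrGraph <- function(n) {
  verts <- data.frame(name = LETTERS[seq_len(n)], kind = "sample",
                      vineyard = NA_character_)
  pair <- utils::combn(n, 2)
  edges <- data.frame(
    from = verts$name[pair[1, ]], to = verts$name[pair[2, ]],
    weight = stats::runif(ncol(pair), -1, 1)
  )
  edges$original_weight <- edges$weight
  edges$edge_kind <- "correlation"
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

## random OTUMatrix with positive rows (no zero variance, no empty bins)
randomOTUMatrix <- function(nSamples = 5, nOtus = 8, vineyard = NULL) {
  m <- matrix(stats::rexp(nSamples * nOtus, rate = 1 / 1000),
              nrow = nSamples,
              dimnames = list(paste0("S", seq_len(nSamples)),
                              as.character(seq(300, by = 3,
                                               length.out = nOtus))))
  meta <- if (is.null(vineyard)) NULL else data.frame(vineyard = vineyard)
  OTUMatrix(m, meta)
}
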