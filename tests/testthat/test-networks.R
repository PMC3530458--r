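# Correlation, probability and mixed-model networks, spanning trees and
# exports.

test_that("correlationNetwork weights every sample pair by Pearson r", {
  m <- OTUMatrix(rbind(A = c(1, 2, 3), B = c(2, 4, 6)))
  g <- correlationNetwork(m)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 1)

  m2 <- OTUMatrix(rbind(A = c(1, 2, 3), B = c(3, 2, 1)))
  expect_equal(igraph::E(correlationNetwork(m2))$weight, -1)

  vals <- rbind(A = c(1, 2, 3), B = c(2, 4, 6.5),
                C = c(5, 1, 0.5), D = c(3, 3, 3.5))
  g4 <- correlationNetwork(OTUMatrix(vals, data.frame(vineyard = rep("BD", 4))))
  expect_equal(igraph::ecount(g4), 6)
  ed <- igraph::as_data_frame(g4)
  for (k in seq_len(nrow(ed)))  # from-the-formula oracle
    expect_equal(ed$weight[k],
                 pearsonByFormula(vals[ed$from[k], ], vals[ed$to[k], ]))
  expect_equal(unique(igraph::V(g4)$vineyard), "BD")
  expect_equal(unique(igraph::V(g4)$kind), "sample")

  flat <- rbind(A = c(1, 2, 3), B = c(4, 4, 4))
  expect_error(correlationNetwork(OTUMatrix(flat)), "zero-variance.*B")
  expect_error(correlationNetwork(OTUMatrix(vals[1, , drop = FALSE])),
               "at least 2")
})

test_that("maximumSpanningTree keeps the strongest |r| edges, original signs", {
  m <- OTUMatrix(rbind(A = c(1, 2, 3), B = c(2, 4, 6)))
  g <- correlationNetwork(m)
  t1 <- maximumSpanningTree(g)
  expect_equal(igraph::ecount(t1), 1)

  tri <- igraph::graph_from_data_frame(data.frame(
    from = c("A", "A", "B"), to = c("B", "C", "C"),
    weight = c(0.9, 0.8, 0.1)), directed = FALSE)
  tt <- maximumSpanningTree(tri)
  expect_setequal(edgeKey(igraph::as_data_frame(tt)$from,
                          igraph::as_data_frame(tt)$to),
                  c("A|B", "A|C"))

  # selection uses |r|; the exported weight keeps the sign
  tri2 <- igraph::graph_from_data_frame(data.frame(
    from = c("A", "A", "B"), to = c("B", "C", "C"),
    weight = c(-0.95, 0.5, 0.3)), directed = FALSE)
  tt2 <- igraph::as_data_frame(maximumSpanningTree(tri2))
  expect_setequal(tt2$weight, c(-0.95, 0.5))

  # deterministic lexicographic tie-break on equal weights
  tie <- igraph::graph_from_data_frame(data.frame(
    from = c("A", "A", "B"), to = c("B", "C", "C"),
    weight = rep(0.5, 3)), directed = FALSE)
  tb <- igraph::as_data_frame(maximumSpanningTree(tie))
  expect_equal(sort(edgeKey(tb$from, tb$to)), c("A|B", "A|C"))

  disc <- igraph::graph_from_data_frame(data.frame(
    from = c("A", "C"), to = c("B", "D"), weight = c(0.5, 0.5)),
    directed = FALSE)
  expect_error(maximumSpanningTree(disc), "disconnected")
})

test_that("maximumSpanningTree matches brute-force enumeration and igraph", {
  set.seed(101)
  for (k in 1:30) {
    n <- sample(3:6, 1)
    g <- randomCorrGraph(n)
    tree <- maximumSpanningTree(g)
    expect_equal(igraph::ecount(tree), n - 1)
    expect_true(igraph::is_connected(tree))
    ed <- igraph::as_data_frame(g)
    ref <- bruteMST(LETTERS[1:n], ed$from, ed$to, 1 - abs(ed$weight))
    td <- igraph::as_data_frame(tree)
    expect_equal(sum(1 - abs(td$weight)), ref$cost, tolerance = 1e-12)
    expect_setequal(edgeKey(td$from, td$to),
                    edgeKey(ed$from[ref$edges], ed$to[ref$edges]))
    # independent library cross-check (weights continuous, ties a.s. absent)
    ig <- igraph::mst(g, weights = 1 - abs(igraph::E(g)$weight))
    igd <- igraph::as_data_frame(ig)
    expect_setequal(edgeKey(td$from, td$to), edgeKey(igd$from, igd$to))
  }
})

test_that("probabilityMatrix row-normalizes and preserves zeros", {
  m <- OTUMatrix(rbind(A = c(2, 3, 5)))
  expect_equal(unname(otuAbundance(probabilityMatrix(m))[1, ]),
               c(0.2, 0.3, 0.5))

  vals <- rbind(A = c(1, 0, 3, 4), B = c(0, 5, 0, 5), C = c(2, 2, 2, 2))
  p <- otuAbundance(probabilityMatrix(OTUMatrix(vals)))
  expect_equal(p, vals / rowSums(vals),       # element-wise hand division
               ignore_attr = TRUE)
  expect_equal(unname(rowSums(p)), rep(1, 3))
  expect_equal(p[vals == 0], rep(0, sum(vals == 0)))

  zero <- suppressWarnings(OTUMatrix(rbind(A = c(1, 2), B = c(0, 0))))
  expect_error(probabilityMatrix(zero), "all-zero sample.*B")
})

test_that("probabilityNetwork links samples to OTUs with p > 0 only", {
  vals <- rbind(S1 = c(4, 0, 6), S2 = c(0, 10, 0))
  colnames(vals) <- c("518", "545", "700")
  pm <- probabilityMatrix(OTUMatrix(vals, data.frame(vineyard = c("BD", "IPW"))))
  g <- probabilityNetwork(pm)
  expect_equal(igraph::ecount(g), 3)          # one edge per nonzero entry
  ed <- igraph::as_data_frame(g)
  expect_setequal(ed$weight, c(0.4, 0.6, 1))
  expect_false(any(ed$from == "S1" & ed$to == "OTU_545"))  # p = 0: no edge
  expect_setequal(igraph::V(g)$kind[igraph::V(g)$name %in% c("S1", "S2")],
                  "sample")
  expect_equal(sum(igraph::V(g)$kind == "otu"), 3)

  single <- probabilityMatrix(OTUMatrix(rbind(S1 = 5)))
  g1 <- probabilityNetwork(single)
  expect_equal(igraph::ecount(g1), 1)
  expect_equal(igraph::E(g1)$weight, 1)
})

test_that("mixedModelNetwork follows the scale-union-invert-mst-restore pipeline", {
  # single sample with its OTU star is already a tree
  star <- probabilityNetwork(probabilityMatrix(
    OTUMatrix(rbind(S1 = c(2, 3, 5)))))
  backbone1 <- igraph::graph_from_data_frame(
    data.frame(from = character(), to = character(),
               weight = numeric(), original_weight = numeric(),
               edge_kind = character()),
    directed = FALSE, vertices = data.frame(name = "S1", kind = "sample",
                                            vineyard = NA_character_))
  mm1 <- mixedModelNetwork(backbone1, star)
  expect_equal(igraph::ecount(mm1), 3)
  expect_setequal(igraph::as_data_frame(mm1)$weight, c(0.2, 0.3, 0.5))

  # 2 samples x 3 OTUs: compare against brute force over the explicit union
  vals <- rbind(S1 = c(6, 3, 1), S2 = c(1, 0, 9))
  colnames(vals) <- c("400", "500", "600")
  m <- OTUMatrix(vals, data.frame(vineyard = c("BD", "BD")))
  backbone <- maximumSpanningTree(correlationNetwork(m))
  pn <- probabilityNetwork(probabilityMatrix(m))
  mm <- mixedModelNetwork(backbone, pn, scale = 10)

  bd <- igraph::as_data_frame(backbone)
  pd <- igraph::as_data_frame(pn)
  from <- c(bd$from, pd$from); to <- c(bd$to, pd$to)
  cost <- c(abs(1 - 10 * bd$weight), abs(1 - pd$weight))
  vn <- unique(c(from, to))
  ref <- bruteMST(vn, from, to, cost)
  md <- igraph::as_data_frame(mm)
  expect_equal(igraph::ecount(mm), length(vn) - 1)
  expect_setequal(edgeKey(md$from, md$to),
                  edgeKey(from[ref$edges], to[ref$edges]))
  # surviving edges carry original (unscaled) weights
  orig <- c(bd$weight, pd$weight)
  names(orig) <- edgeKey(from, to)
  expect_equal(md$weight, unname(orig[edgeKey(md$from, md$to)]))

  # node sizing: samples by degree, OTUs by surviving-edge probability
  deg <- igraph::degree(mm)
  isSample <- igraph::V(mm)$kind == "sample"
  expect_equal(igraph::V(mm)$size[isSample], unname(deg[isSample]))
  for (v in which(!isSample)) {
    inc <- igraph::incident(mm, v)
    expect_equal(igraph::V(mm)$size[v],
                 if (length(inc)) max(inc$weight) else 0)
  }
})

test_that("forceBackbone pins every backbone edge into the mixed tree", {
  set.seed(9)
  m <- randomOTUMatrix(nSamples = 4, nOtus = 6, vineyard = rep("BD", 4))
  backbone <- maximumSpanningTree(correlationNetwork(m))
  pn <- probabilityNetwork(probabilityMatrix(m))
  mm <- mixedModelNetwork(backbone, pn, forceBackbone = TRUE)
  bd <- igraph::as_data_frame(backbone)
  md <- igraph::as_data_frame(mm)
  expect_true(all(edgeKey(bd$from, bd$to) %in% edgeKey(md$from, md$to)))
  # literal transform instead tends to drop costly scaled backbone edges
  lit <- igraph::as_data_frame(mixedModelNetwork(backbone, pn))
  expect_lte(sum(lit$edge_kind == "correlation"),
             sum(md$edge_kind == "correlation"))
})

test_that("mixedModelNetwork is input-order invariant and checks its inputs", {
  set.seed(23)
  m <- randomOTUMatrix(nSamples = 5, nOtus = 7, vineyard = rep("BD", 5))
  backbone <- maximumSpanningTree(correlationNetwork(m))
  pn <- probabilityNetwork(probabilityMatrix(m))
  a <- igraph::as_data_frame(mixedModelNetwork(backbone, pn))

  perm <- c(3, 1, 5, 2, 4)
  m2 <- OTUMatrix(otuAbundance(m)[perm, ], sampleData(m)[perm, , drop = FALSE])
  b <- igraph::as_data_frame(mixedModelNetwork(
    maximumSpanningTree(correlationNetwork(m2)),
    probabilityNetwork(probabilityMatrix(m2))))
  expect_setequal(edgeKey(a$from, a$to), edgeKey(b$from, b$to))

  alien <- igraph::graph_from_data_frame(
    data.frame(from = "X1", to = "X2", weight = 0.5,
               original_weight = 0.5, edge_kind = "correlation"),
    directed = FALSE)
  expect_error(mixedModelNetwork(alien, pn), "must all appear")
})

test_that("exportNetwork writes SIF, GraphML and CSV; GraphML round-trips", {
  set.seed(31)
  m <- randomOTUMatrix(nSamples = 4, nOtus = 5, vineyard = rep("CONV", 4))
  mm <- mixedModelNetwork(maximumSpanningTree(correlationNetwork(m)),
                          probabilityNetwork(probabilityMatrix(m)))
  gml <- tempfile(fileext = ".graphml")
  exportNetwork(mm, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$name, igraph::V(mm)$name)
  a <- igraph::as_data_frame(mm); b <- igraph::as_data_frame(back)
  ord <- function(d) d[order(edgeKey(d$from, d$to)), ]
  expect_equal(ord(b)$weight, ord(a)$weight)
  expect_equal(ord(b)$edge_kind, ord(a)$edge_kind)
  expect_true(all(igraph::V(back)$kind %in% c("sample", "otu")))

  sif <- tempfile(fileext = ".sif")
  exportNetwork(mm, sif, "sif")
  lines <- readLines(sif)
  expect_equal(length(lines), igraph::ecount(mm))
  expect_true(all(grepl(" (correlation|probability) ", lines)))

  csv <- tempfile(fileext = ".csv")
  exportNetwork(mm, csv, "csv")
  tab <- read.csv(csv)
  expect_equal(names(tab),
               c("source", "target", "edge_kind", "weight", "original_weight"))
  expect_equal(nrow(tab), igraph::ecount(mm))

  emptyNet <- igraph::make_empty_graph(n = 0, directed = FALSE)
  exportNetwork(emptyNet, sif, "sif")
  expect_equal(length(readLines(sif)), 0)
  expect_error(exportNetwork(mm, csv, "gexf"), "arg")
})

test_that("same-vineyard adjacency enrichment is detected on clustered trees", {
  # path tree whose two halves are two vineyards: only one mixed edge
  ed <- data.frame(from = paste0("S", 1:7), to = paste0("S", 2:8))
  ed$weight <- 0.9
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
    vertices = data.frame(name = paste0("S", 1:8),
                          vineyard = rep(c("BD", "CONV"), each = 4)))
  res <- vineyardAdjacencyTest(g, nPerm = 200, seed = 1)
  expect_equal(res$observed, 6)
  expect_lt(res$p_value, 0.05)
  expect_length(res$null, 200)
})
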