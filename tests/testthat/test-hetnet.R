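test_that("edge-list parsing dedupes and resolves schema permutations", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(
    source_id = c("A", "A", "B", "B"), source_type = "Disease",
    edge_type = c("ASSOCIATES_DaG", "RESEMBLES_DrD", "ASSOCIATES_DaG",
                  "ASSOCIATES_DaG"),
    target_id = c("g1", "B", "g1", "g1"),
    target_type = c("Gene", "Disease", "Gene", "Gene"),
    stringsAsFactors = FALSE
  )
  write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- suppressMessages(readEdgeList(tmp))
  expect_equal(numNodes(g), 3L)
  expect_equal(numEdges(g), 3L)  # duplicated line collapsed

  # permuted, renamed columns resolved by schema give the identical graph
  tab2 <- tab[, c(4, 1, 3, 5, 2)]
  names(tab2) <- c("to", "from", "rel", "to_ty", "from_ty")
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab2, tmp2, sep = "\t", quote = FALSE, row.names = FALSE)
  g2 <- suppressMessages(readEdgeList(tmp2, schema = c(
    source_id = "from", source_type = "from_ty", edge_type = "rel",
    target_id = "to", target_type = "to_ty")))
  expect_identical(nodeTable(g), nodeTable(g2))
  expect_identical(edgeTable(g), edgeTable(g2))

  # unknown edge type rejected with the offending row
  expect_error(
    readEdgeList(tmp, edgeTypes = "ASSOCIATES_DaG"),
    "RESEMBLES_DrD")

  # round trip through the canonical TSV is bit-identical
  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(g, tmp3)
  g3 <- readEdgeList(tmp3)
  expect_identical(edgeTable(g), edgeTable(g3))
  expect_identical(nodeTable(g), nodeTable(g3))
})

test_that("node ordering is lexicographic by (type, id)", {
  g <- heteroGraph(edges = edgeRow(c("z", "a"), c("Gene", "Disease"), "E",
                                   c("a", "m"), c("Disease", "Symptom")))
  expect_identical(nodeKeys(g),
                   c("Disease:a", "Gene:z", "Symptom:m"))
})

test_that("transition operator normalises columns and flags dangling nodes", {
  g <- triangleGraph()
  op <- buildTransitionOperator(g, beta = 0.1)
  P <- as.matrix(transitionMatrix(op))
  expect_equal(unname(Matrix::colSums(transitionMatrix(op))), rep(1, 3))
  for (j in 1:3) expect_setequal(P[, j], c(0, 0.5, 0.5))

  # path graph a-b-c: column b splits, end columns put mass 1 on b
  gp <- pathGraph(c("a", "b", "c"))
  opp <- buildTransitionOperator(gp, beta = 0.1)
  Pp <- as.matrix(transitionMatrix(opp))
  expect_equal(unname(Pp[, 2]), c(0.5, 0, 0.5))
  expect_equal(unname(Pp[, 1]), c(0, 1, 0))
  expect_equal(unname(Pp[, 3]), c(0, 1, 0))

  # independent per-column normalisation oracle on a random graph
  gr <- randomGraph(20, seed = 7)
  opr <- buildTransitionOperator(gr, beta = 0.1)
  A <- as.matrix(adjacencyMatrix(gr))
  expect_true(isSymmetric(A))
  Pref <- apply(A, 2, function(col) if (sum(col) > 0) col / sum(col) else col)
  expect_equal(as.matrix(transitionMatrix(opr)), Pref,
               ignore_attr = TRUE, tolerance = 1e-14)

  # isolated node: dangling column all zero and flagged
  gi <- heteroGraph(nodes = data.frame(id = c("a", "b", "solo"), type = "N"),
                    edges = edgeRow("a", "N", "E", "b", "N"))
  opi <- buildTransitionOperator(gi, beta = 0.1)
  expect_identical(danglingMask(opi), c(FALSE, FALSE, TRUE))
  expect_equal(sum(transitionMatrix(opi)[, 3]), 0)

  expect_error(buildTransitionOperator(g, beta = 0), "beta")
  expect_error(buildTransitionOperator(g, beta = 1), "beta")
})

test_that("multi-edges sum in the adjacency unless binarized", {
  ed <- rbind(edgeRow("d", "Disease", "T1", "x", "Gene"),
              edgeRow("d", "Disease", "T2", "x", "Gene"))
  g <- heteroGraph(edges = ed)
  expect_equal(as.numeric(adjacencyMatrix(g)["Disease:d", "Gene:x"]), 2)
  expect_equal(as.numeric(adjacencyMatrix(g, binary = TRUE)["Disease:d",
                                                            "Gene:x"]), 1)
})

test_that("edge deletion holds out exactly the listed types", {
  ed <- rbind(edgeRow(c("d1", "d1", "d2"), "Disease", "ASSOCIATES_DaG",
                      c("g1", "g2", "g1"), "Gene"),
              edgeRow(c("d1", "d2"), "Disease", "RESEMBLES_DrD",
                      c("d2", "d3"), "Disease"),
              edgeRow("d1", "Disease", "LOCALIZES_DlA", "a1", "Anatomy"))
  g <- heteroGraph(edges = ed)
  del <- deleteEdgesByType(g, c("ASSOCIATES_DaG", "RESEMBLES_DrD"))
  expect_equal(nrow(del$gold), 5L)
  expect_false(any(edgeTable(del$graph)$type %in%
                     c("ASSOCIATES_DaG", "RESEMBLES_DrD")))
  expect_equal(numEdges(del$graph), 1L)
  expect_identical(nodeKeys(del$graph), nodeKeys(g))

  # deleting an absent type is a no-op with empty gold
  del2 <- deleteEdgesByType(del$graph, "ASSOCIATES_DaG")
  expect_equal(nrow(del2$gold), 0L)
  expect_identical(edgeTable(del2$graph), edgeTable(del$graph))

  # synthetic fixture: held-out count equals the manifest's planted count
  fx <- smallFixture(seed = 3)
  d3 <- deleteEdgesByType(fx$graph, "ASSOCIATES_DaG")
  expect_equal(nrow(d3$gold),
               sum(fx$manifest$planted$type == "ASSOCIATES_DaG"))
})

test_that("per-type shuffling preserves degree sequences and is seeded", {
  fx <- smallFixture(seed = 5)
  g <- fx$graph
  s1 <- shuffleEdgesByType(g, seed = 42)
  s2 <- shuffleEdgesByType(g, seed = 42)
  expect_identical(edgeTable(s1), edgeTable(s2))

  degByType <- function(gr) {
    ed <- edgeTable(gr)
    lapply(split(ed, ed$type), function(sub)
      sort(tabulate(c(sub$src, sub$dst), nbins = numNodes(gr))))
  }
  expect_identical(degByType(g), degByType(s1))
  expect_equal(table(edgeTable(g)$type), table(edgeTable(s1)$type))
  expect_identical(nodeKeys(g), nodeKeys(s1))

  # a type with a single edge is left untouched
  g1 <- heteroGraph(edges = rbind(
    edgeRow("a", "N", "ONLY", "b", "N"),
    edgeRow(c("a", "b", "c", "a"), "N", "E", c("c", "c", "d", "d"), "N")))
  expect_message(sh <- shuffleEdgesByType(g1, seed = 1), "ONLY")
  expect_identical(edgeTable(sh)[edgeTable(sh)$type == "ONLY", ],
                   edgeTable(g1)[edgeTable(g1)$type == "ONLY", ])

  # shuffling genuinely moves edges on a larger type
  ed <- edgeTable(g)
  eds <- edgeTable(s1)
  key <- function(e) paste(pmin(e$src, e$dst), pmax(e$src, e$dst), e$type)
  same <- mean(key(eds) %in% key(ed))
  expect_lt(same, 0.9)
})

test_that("add-back restores sampled fractions and inverts deletion", {
  fx <- smallFixture(seed = 2)
  del <- deleteEdgesByType(fx$graph, deletedTypes)
  n <- nrow(del$gold)

  ab0 <- addbackEdges(del$graph, del$gold, 0, seed = 1)
  expect_identical(edgeTable(ab0$graph), edgeTable(del$graph))
  expect_equal(nrow(ab0$heldOut), n)

  ab1 <- addbackEdges(del$graph, del$gold, 1, seed = 1)
  key <- function(e) sort(paste(pmin(e$src, e$dst), pmax(e$src, e$dst),
                                e$type))
  expect_identical(key(edgeTable(ab1$graph)), key(edgeTable(fx$graph)))
  expect_equal(nrow(ab1$heldOut), 0L)

  abHalf <- addbackEdges(del$graph, del$gold, 0.5, seed = 9)
  expect_equal(numEdges(abHalf$graph) - numEdges(del$graph), round(0.5 * n))

  # stratified add-back restores the right share of each stratum
  abStrat <- addbackEdges(del$graph, del$gold, 0.5, seed = 9,
                          stratifyBy = "type")
  restored <- table(edgeTable(abStrat$graph)$type)
  for (ty in intersect(names(restored), deletedTypes)) {
    expect_equal(as.integer(restored[[ty]]),
                 round(0.5 * sum(del$gold$type == ty)))
  }
})
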