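# Fixture builders shared across the suite. Everything is generated in code;
# no files are shipped.

edgeRow <- function(sid, sty, ety, tid, tty) {
  data.frame(source_id = sid, source_type = sty, edge_type = ety,
             target_id = tid, target_type = tty, stringsAsFactors = FALSE)
}

# undirected path graph over ids of a single node type
pathGraph <- function(ids, type = "N", edgeType = "E") {
  n <- length(ids)
  heteroGraph(edges = edgeRow(ids[-n], type, edgeType, ids[-1], type))
}

# triangle over three nodes
triangleGraph <- function(type = "N") {
  heteroGraph(edges = edgeRow(c("a", "b", "c"), type, "E",
                              c("b", "c", "a"), type))
}

# Erdos-Renyi-ish random typed graph; may contain dangling nodes
randomGraph <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[1] <- TRUE
  ids <- sprintf("n%02d", seq_len(n))
  nodes <- data.frame(id = ids, type = "N", stringsAsFactors = FALSE)
  heteroGraph(nodes = nodes,
              edges = edgeRow(ids[pairs[keep, 1]], "N", "E",
                              ids[pairs[keep, 2]], "N"))
}

# the 2-patient / 3-SEP worked example: P1 = {A, B}, P2 = {B, C}
sepExample <- function() {
  g <- pathGraph(c("A", "B", "C"), type = "Symptom")
  pats <- patientSet(
    list(P1 = c("Symptom:A", "Symptom:B"), P2 = c("Symptom:B", "Symptom:C")),
    graph = g)
  list(graph = g, patients = pats)
}

# dense linear-solve oracle for the restart walk fixed point:
# (I - (1-b) P - (1-b) v d^T) r = b v, d = dangling indicator
psevOracle <- function(op, v) {
  P <- as.matrix(transitionMatrix(op))
  b <- restartBeta(op)
  d <- as.numeric(danglingMask(op))
  n <- nrow(P)
  A <- diag(n) - (1 - b) * P - (1 - b) * outer(as.numeric(v), d)
  unname(solve(A, b * as.numeric(v)))
}

# hand-rolled BFS distances from one source (independent of igraph)
bfsDistances <- function(graph, from) {
  n <- numNodes(graph)
  ed <- edgeTable(graph)
  adj <- vector("list", n)
  for (i in seq_len(nrow(ed))) {
    adj[[ed$src[i]]] <- c(adj[[ed$src[i]]], ed$dst[i])
    adj[[ed$dst[i]]] <- c(adj[[ed$dst[i]]], ed$src[i])
  }
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    u <- queue[1]
    queue <- queue[-1]
    for (w in adj[[u]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[u] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# small planted fixture at reduced scale for unit tests (not the acceptance
# study conditions)
smallFixture <- function(seed = 1, theta = 0.8, nPatients = 300L) {
  cfg <- synthConfig(nDiseases = 3L, nGenes = 60L, nAnatomy = 8L,
                     nSymptoms = 8L, nCompounds = 8L, nPathways = 6L,
                     nPatients = nPatients, theta = theta, seed = seed)
  gg <- generateGraph(cfg)
  pp <- generatePatients(gg$graph, gg$manifest, cfg)
  list(cfg = cfg, graph = gg$graph, manifest = gg$manifest,
       patients = pp$patients, assignment = pp$assignment,
       conceptMap = pp$conceptMap)
}

# graph edges back in source/target row form (for rebuilding variants)
edgeTableToRows <- function(g) {
  nd <- nodeTable(g)
  ed <- edgeTable(g)
  edgeRow(nd$id[ed$src], nd$type[ed$src], ed$type,
          nd$id[ed$dst], nd$type[ed$dst])
}

deletedTypes <- c("ASSOCIATES_DaG", "UPREGULATES_DuG", "RESEMBLES_DrD")
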