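#' Construct a heterogeneous graph from node and edge tables
#'
#' Nodes are re-ordered lexicographically by (type, id); that ordering is the
#' canonical node index inherited by every derived matrix. Duplicate edges
#' (same unordered node pair and edge type) are collapsed.
#'
#' @param nodes data.frame with columns \code{id} and \code{type}. May be
#'   omitted, in which case the node set is taken from the edges.
#' @param edges data.frame with columns \code{source_id}, \code{source_type},
#'   \code{edge_type}, \code{target_id}, \code{target_type}.
#' @param nodeTypes,edgeTypes optional declared vocabularies; unknown types
#'   are rejected with the offending row numbers.
#' @return a \linkS4class{HeteroGraph}.
#' @examples
#' ed <- data.frame(source_id = "A", source_type = "Disease",
#'                  edge_type = "ASSOCIATES_DaG",
#'                  target_id = "g1", target_type = "Gene")
#' heteroGraph(edges = ed)
#' @export
heteroGraph <- function(nodes = NULL, edges,
                        nodeTypes = character(), edgeTypes = character()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  req <- c("source_id", "source_type", "edge_type", "target_id", "target_type")
  if (!all(req %in% names(edges)))
    stop("edges must have columns: ", paste(req, collapse = ", "))
  fromEdges <- data.frame(
    id = c(edges$source_id, edges$target_id),
    type = c(edges$source_type, edges$target_type),
    stringsAsFactors = FALSE
  )
  if (is.null(nodes)) nodes <- fromEdges else {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)[, c("id", "type")]
    nodes <- rbind(nodes, fromEdges)
  }
  nodes <- unique(nodes)
  if (length(nodeTypes)) {
    bad <- !nodes$type %in% nodeTypes
    if (any(bad))
      stop("unknown node type(s): ", paste(unique(nodes$type[bad]), collapse = ", "))
  }
  if (length(edgeTypes)) {
    bad <- which(!edges$edge_type %in% edgeTypes)
    if (length(bad))
      stop("unknown edge type(s) at edge row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), ": ",
           paste(unique(edges$edge_type[bad]), collapse = ", "))
  }
  nodes <- nodes[order(nodes$type, nodes$id, method = "radix"), , drop = FALSE]
  nodes$key <- paste(nodes$type, nodes$id, sep = ":")
  rownames(nodes) <- NULL
  idx <- structure(seq_len(nrow(nodes)), names = nodes$key)
  src <- idx[paste(edges$source_type, edges$source_id, sep = ":")]
  dst <- idx[paste(edges$target_type, edges$target_id, sep = ":")]
  if (any(src == dst))
    stop("self-loop(s) at edge row(s) ",
         paste(utils::head(which(src == dst), 5), collapse = ", "))
  ed <- data.frame(src = unname(src), dst = unname(dst),
                   type = edges$edge_type, stringsAsFactors = FALSE)
  pk <- paste(pmin(ed$src, ed$dst), pmax(ed$src, ed$dst), ed$type)
  dup <- duplicated(pk)
  if (any(dup))
    message(sum(dup), " duplicate edge(s) collapsed")
  ed <- ed[!dup, , drop = FALSE]
  ed <- ed[order(ed$type, pmin(ed$src, ed$dst), pmax(ed$src, ed$dst)), ,
           drop = FALSE]
  rownames(ed) <- NULL
  new("HeteroGraph", nodes = nodes, edges = ed,
      nodeTypes = if (length(nodeTypes)) nodeTypes else sort(unique(nodes$type)),
      edgeTypes = if (length(edgeTypes)) edgeTypes else sort(unique(ed$type)))
}

#' Read a typed edge list from a TSV file
#'
#' The file must be tab-separated with a header. Column names are resolved
#' through \code{schema}, a named map from the canonical names
#' (\code{source_id}, \code{source_type}, \code{edge_type}, \code{target_id},
#' \code{target_type}) to the names used in the file, so files with permuted
#' or renamed columns parse to the identical graph.
#'
#' @param path file path.
#' @param schema named character vector mapping canonical column names to
#'   file column names; defaults to the identity mapping.
#' @param nodeTypes,edgeTypes optional declared vocabularies.
#' @param nodesPath optional node-table TSV (columns \code{id}, \code{type})
#'   declaring the full node set, including nodes without edges.
#' @return a \linkS4class{HeteroGraph}.
#' @export
readEdgeList <- function(path, schema = NULL,
                         nodeTypes = character(), edgeTypes = character(),
                         nodesPath = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  canon <- c("source_id", "source_type", "edge_type", "target_id", "target_type")
  if (is.null(schema)) schema <- structure(canon, names = canon)
  missing <- setdiff(canon, names(schema))
  schema[missing] <- missing
  bad <- setdiff(unname(schema[canon]), names(tab))
  if (length(bad))
    stop("column(s) not found in ", path, ": ", paste(bad, collapse = ", "))
  edges <- tab[, unname(schema[canon])]
  names(edges) <- canon
  for (j in canon) edges[[j]] <- as.character(edges[[j]])
  nodes <- if (!is.null(nodesPath))
    utils::read.delim(nodesPath, stringsAsFactors = FALSE,
                      colClasses = "character") else NULL
  heteroGraph(nodes = nodes, edges = edges, nodeTypes = nodeTypes,
              edgeTypes = edgeTypes)
}

#' Write a graph back to the canonical edge-list TSV
#'
#' Edges are emitted in the graph's canonical order so that write/read
#' round-trips are bit-identical.
#'
#' @param graph a \linkS4class{HeteroGraph}.
#' @param path output file path.
#' @param nodesPath optional path for the node table (id, type); writing it
#'   preserves nodes that currently have no edges.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(graph, path, nodesPath = NULL) {
  nd <- nodeTable(graph)
  ed <- edgeTable(graph)
  out <- data.frame(
    source_id = nd$id[ed$src], source_type = nd$type[ed$src],
    edge_type = ed$type,
    target_id = nd$id[ed$dst], target_type = nd$type[ed$dst],
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(nodesPath))
    utils::write.table(nd[, c("id", "type")], nodesPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Symmetric adjacency matrix of a graph
#'
#' Multiple edge types between the same node pair each contribute weight 1
#' (summed) by default, because each typed edge is an independent assertion;
#' set \code{binary = TRUE} to collapse multiplicity to 0/1.
#'
#' @param graph a \linkS4class{HeteroGraph}.
#' @param binary collapse parallel typed edges to weight 1?
#' @return a symmetric sparse Matrix with node keys as dimnames.
#' @export
adjacencyMatrix <- function(graph, binary = FALSE) {
  n <- numNodes(graph)
  ed <- edgeTable(graph)
  keys <- nodeKeys(graph)
  if (nrow(ed) == 0L)
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n), dimnames = list(keys, keys)))
  A <- Matrix::sparseMatrix(
    i = c(ed$src, ed$dst), j = c(ed$dst, ed$src),
    x = 1, dims = c(n, n), dimnames = list(keys, keys)
  )
  if (binary) A@x[] <- 1
  A
}

#' Build the column-stochastic transition operator
#'
#' Each column of the adjacency is divided by its (weighted) degree, so
#' \code{P[i, j]} is the probability of stepping from node j to node i.
#' Zero-degree columns are left all-zero and flagged; during the walk their
#' mass is re-routed to the restart distribution.
#'
#' @param graph a \linkS4class{HeteroGraph}.
#' @param beta restart probability in (0, 1); the walk default is 0.1.
#' @param binary passed to \code{\link{adjacencyMatrix}}.
#' @return a \linkS4class{TransitionOperator}.
#' @export
buildTransitionOperator <- function(graph, beta = 0.1, binary = FALSE) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 1)
    stop("beta must be a single number strictly inside (0, 1)")
  if (numNodes(graph) == 0L) stop("graph has no nodes")
  A <- adjacencyMatrix(graph, binary = binary)
  deg <- Matrix::colSums(A)
  dangling <- deg == 0
  inv <- ifelse(dangling, 0, 1 / deg)
  P <- A %*% Matrix::Diagonal(x = inv)
  dimnames(P) <- dimnames(A)
  new("TransitionOperator", P = methods::as(P, "CsparseMatrix"), beta = beta,
      danglingMask = unname(dangling), nodeKeys = nodeKeys(graph))
}

#' Delete all edges of given types, keeping them as a gold standard
#'
#' Used to set up the recovery benchmark: the listed edge types (for example
#' all Disease-Gene and Disease-Disease edges) are removed before PSEV
#' computation and returned as the held-out gold standard. The returned graph
#' shares the node index of the input.
#'
#' @param graph a \linkS4class{HeteroGraph}.
#' @param edgeTypes character vector of edge-type names to remove.
#' @return list with elements \code{graph} (edges removed) and \code{gold}
#'   (data.frame of removed edges: \code{src}, \code{dst}, \code{type},
#'   \code{src_key}, \code{dst_key}).
#' @export
deleteEdgesByType <- function(graph, edgeTypes) {
  bad <- setdiff(edgeTypes, graph@edgeTypes)
  if (length(bad))
    stop("edge type(s) not in vocabulary: ", paste(bad, collapse = ", "))
  ed <- edgeTable(graph)
  hit <- ed$type %in% edgeTypes
  gold <- ed[hit, , drop = FALSE]
  keys <- nodeKeys(graph)
  gold$src_key <- keys[gold$src]
  gold$dst_key <- keys[gold$dst]
  rownames(gold) <- NULL
  g2 <- graph
  g2@edges <- ed[!hit, , drop = FALSE]
  rownames(g2@edges) <- NULL
  list(graph = g2, gold = gold)
}

#' Shuffle edges within each edge type
#'
#' The null used to test whether the network's internal wiring matters. By
#' default each edge type is rewired by degree-preserving double-edge swaps
#' (10 x the type's edge count attempted swaps), which destroys the pairing
#' of endpoints while preserving every node's per-type degree exactly. The
#' simpler endpoint-permutation null (\code{method = "permute"}) pairs each
#' source endpoint with a permuted target endpoint and is kept behind a flag;
#' it preserves per-type endpoint multisets but not simplicity guarantees, so
#' duplicates arising from it are collapsed.
#'
#' @param graph a \linkS4class{HeteroGraph}.
#' @param seed integer seed; the shuffle is fully reproducible.
#' @param method "swap" (degree-preserving, default) or "permute".
#' @param swapFactor attempted swaps per edge, default 10.
#' @return a \linkS4class{HeteroGraph} with the same node index.
#' @export
shuffleEdgesByType <- function(graph, seed, method = c("swap", "permute"),
                               swapFactor = 10) {
  method <- match.arg(method)
  ed <- edgeTable(graph)
  out <- vector("list", 0L)
  types <- sort(unique(ed$type))
  withSeed(seed, {
    for (ty in types) {
      sub <- ed[ed$type == ty, , drop = FALSE]
      if (nrow(sub) < 2L) {
        if (nrow(sub)) message("edge type ", ty, " has < 2 edges; left unshuffled")
        out[[ty]] <- sub
        next
      }
      if (method == "swap") {
        ig <- igraph::graph_from_edgelist(cbind(sub$src, sub$dst),
                                          directed = FALSE)
        ig <- igraph::rewire(
          ig, igraph::keeping_degseq(loops = FALSE,
                                     niter = swapFactor * nrow(sub)))
        el <- igraph::as_edgelist(ig, names = FALSE)
        sub$src <- as.integer(el[, 1])
        sub$dst <- as.integer(el[, 2])
      } else {
        sub$dst <- sub$dst[sample.int(nrow(sub))]
        keep <- sub$src != sub$dst
        sub <- sub[keep, , drop = FALSE]
        pk <- paste(pmin(sub$src, sub$dst), pmax(sub$src, sub$dst))
        sub <- sub[!duplicated(pk), , drop = FALSE]
      }
      out[[ty]] <- sub
    }
  })
  ed2 <- do.call(rbind, out[types])
  ed2 <- ed2[order(ed2$type, pmin(ed2$src, ed2$dst), pmax(ed2$src, ed2$dst)), ,
             drop = FALSE]
  rownames(ed2) <- NULL
  g2 <- graph
  g2@edges <- ed2
  g2
}

#' Restore a sampled fraction of held-out edges
#'
#' Emulates gradually returning knowledge to the network: a uniformly sampled
#' subset of the gold-standard edges of size \code{round(fraction * n)} is
#' restored. With \code{stratifyBy = "type"} the sampling is done within each
#' edge type separately, so strata of different fidelity can be compared.
#'
#' @param graphDeleted the graph returned by \code{\link{deleteEdgesByType}}.
#' @param gold the gold-standard edge data.frame from the same call.
#' @param fraction proportion of gold edges to restore, in [0, 1].
#' @param seed integer seed.
#' @param stratifyBy NULL (sample over all gold edges) or the name of a gold
#'   column (usually "type") to stratify by.
#' @return list with elements \code{graph} (edges restored) and
#'   \code{heldOut} (gold edges still absent).
#' @export
addbackEdges <- function(graphDeleted, gold, fraction, seed,
                         stratifyBy = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- nrow(gold)
  pick <- logical(n)
  withSeed(seed, {
    if (is.null(stratifyBy) || n == 0L) {
      k <- round(fraction * n)
      if (k > 0) pick[sample.int(n, k)] <- TRUE
    } else {
      for (lv in unique(gold[[stratifyBy]])) {
        rows <- which(gold[[stratifyBy]] == lv)
        k <- round(fraction * length(rows))
        if (k > 0) pick[rows[sample.int(length(rows), k)][seq_len(k)]] <- TRUE
      }
    }
  })
  g2 <- graphDeleted
  restored <- gold[pick, c("src", "dst", "type"), drop = FALSE]
  ed2 <- rbind(edgeTable(graphDeleted), restored)
  ed2 <- ed2[order(ed2$type, pmin(ed2$src, ed2$dst), pmax(ed2$src, ed2$dst)), ,
             drop = FALSE]
  rownames(ed2) <- NULL
  g2@edges <- ed2
  list(graph = g2, heldOut = gold[!pick, , drop = FALSE])
}

# Run expr under a local, restored RNG state with the given seed.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
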