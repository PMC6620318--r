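#' z-score normalise a PSEV matrix
#'
#' Raw walk mass is dominated by hub degree: the same high-degree nodes sit
#' at the top of every PSEV. Standardising each node (column) across PSEV
#' rows removes that shared component and leaves what is specific to each
#' concept, which is why the per-node axis is the default. Population
#' standard deviation (divisor n) is used. Zero-variance columns are set to
#' 0 with a message. The per-psev axis (standardise within each row) is
#' available for single-row matrices and sensitivity checks.
#'
#' @param M a \linkS4class{PsevMatrix}.
#' @param axis "node" (default; standardise each column across rows) or
#'   "psev" (standardise each row).
#' @return a \linkS4class{PsevMatrix} with \code{kind = "zscore"}.
#' @export
zscoreNormalize <- function(M, axis = c("node", "psev")) {
  axis <- match.arg(axis)
  X <- psevValues(M)
  if (axis == "node") {
    if (nrow(X) < 2L)
      stop("per-node z-scoring needs >= 2 PSEV rows; use axis = \"psev\"")
    mu <- colMeans(X)
    sd <- sqrt(colMeans(sweep(X, 2, mu)^2))
    zero <- sd == 0
    sd[zero] <- 1
    Z <- sweep(sweep(X, 2, mu), 2, sd, "/")
    if (any(zero)) {
      Z[, zero] <- 0
      message(sum(zero), " zero-variance node column(s) set to 0")
    }
  } else {
    mu <- rowMeans(X)
    sd <- sqrt(rowMeans(sweep(X, 1, mu)^2))
    zero <- sd == 0
    sd[zero] <- 1
    Z <- sweep(sweep(X, 1, mu), 1, sd, "/")
    if (any(zero)) Z[zero, ] <- 0
  }
  methods::initialize(M, values = Z, kind = "zscore")
}

#' Rank PSEV elements within one node type
#'
#' Restricts each PSEV row to the nodes of the given type and ranks them in
#' descending order of value: rank 1 is the most important node of that type
#' for that PSEV. Ties are broken deterministically by node key, so ranks
#' are always a permutation of 1..n_type.
#'
#' @param M a \linkS4class{PsevMatrix} (normally z-scored first).
#' @param graph the \linkS4class{HeteroGraph} supplying node types.
#' @param nodeType node type to rank (e.g. "Gene").
#' @param universe optional character vector of node keys restricting the
#'   candidate set (e.g. only genes with at least one known association).
#' @return integer matrix rows = PSEVs, cols = the ranked nodes (keys as
#'   colnames), entries = ranks 1..n.
#' @export
rankByType <- function(M, graph, nodeType, universe = NULL) {
  nd <- nodeTable(graph)
  if (!nodeType %in% nd$type) stop("unknown node type: ", nodeType)
  keys <- nd$key[nd$type == nodeType]
  if (!is.null(universe)) keys <- intersect(keys, universe)
  if (!length(keys)) stop("empty candidate set for type ", nodeType)
  cols <- match(keys, M@colKeys)
  if (anyNA(cols)) stop("node keys missing from PSEV columns")
  X <- psevValues(M)[, cols, drop = FALSE]
  ranks <- t(apply(X, 1, function(row) {
    ord <- order(-row, keys, method = "radix")
    r <- integer(length(row))
    r[ord] <- seq_along(row)
    r
  }))
  dimnames(ranks) <- list(M@rowKeys, keys)
  ranks
}

#' Export ranked PSEV elements as a long-format table
#'
#' @param M a z-scored \linkS4class{PsevMatrix}.
#' @param graph the \linkS4class{HeteroGraph}.
#' @param nodeTypes node types to include; default all.
#' @return data.frame (psev_id, node_type, node_id, zscore, rank).
#' @export
rankedTable <- function(M, graph, nodeTypes = NULL) {
  nd <- nodeTable(graph)
  if (is.null(nodeTypes)) nodeTypes <- sort(unique(nd$type))
  out <- lapply(nodeTypes, function(ty) {
    rk <- rankByType(M, graph, ty)
    cols <- match(colnames(rk), M@colKeys)
    do.call(rbind, lapply(seq_len(nrow(rk)), function(i) {
      data.frame(psev_id = M@rowKeys[i], node_type = ty,
                 node_id = nd$id[match(colnames(rk), nd$key)],
                 zscore = psevValues(M)[i, cols],
                 rank = rk[i, ], row.names = NULL,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}
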