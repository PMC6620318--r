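#' Per-SEP contributions to a target node
#'
#' Clear-box attribution of a PSEV element: for a given concept and target
#' node, the contribution of SEP j is the product of (a) the z-scored SEP
#' transition weight of j for the concept (how strongly the concept's
#' restart mass favours entering through j) and (b) the value that j's
#' single-SEP network-only PSEV assigns to the target (how much of a walk
#' started at j reaches the target). The network-only PSEVs are computed
#' with restart 0.33 on the benchmark (edge-deleted) graph.
#'
#' @param concept SEP key (column of the SEP transition matrix) to explain.
#' @param target node key or index of the downstream target.
#' @param Sz z-scored SEP transition matrix (matrix with SEP dimnames), from
#'   \code{\link{zscoreSepTransition}}.
#' @param spokeOnly \linkS4class{PsevMatrix} of single-SEP network-only
#'   PSEVs, rows named by SEP key (from \code{\link{spokeOnlyMatrix}}).
#' @return named numeric contribution vector over SEPs.
#' @export
sepContributions <- function(concept, target, Sz, spokeOnly) {
  seps <- rownames(Sz)
  if (is.null(seps)) stop("Sz must carry SEP dimnames")
  if (!concept %in% colnames(Sz)) stop("unknown concept: ", concept)
  if (!all(seps %in% spokeOnly@rowKeys))
    stop("spokeOnly matrix must have one row per SEP")
  tcol <- if (is.character(target)) match(target, spokeOnly@colKeys)
          else as.integer(target)
  if (is.na(tcol) || tcol < 1L || tcol > length(spokeOnly@colKeys))
    stop("target not in graph")
  mass <- psevValues(spokeOnly)[match(seps, spokeOnly@rowKeys), tcol]
  stats::setNames(Sz[, concept] * mass, seps)
}

#' z-score the SEP transition matrix
#'
#' Standardises each column (concept) of the SEP transition matrix to mean 0
#' and population sd 1, so a SEP's weight for a concept is measured relative
#' to the other SEPs of that concept before entering the contribution
#' product. Row-wise standardisation is available via \code{axis}.
#'
#' @param S a \linkS4class{SepTransitionMatrix}.
#' @param axis "column" (per concept, default) or "row".
#' @return matrix of z-scores with SEP dimnames.
#' @export
zscoreSepTransition <- function(S, axis = c("column", "row")) {
  axis <- match.arg(axis)
  X <- sepMatrix(S)
  if (axis == "row") X <- t(X)
  mu <- colMeans(X)
  sd <- sqrt(colMeans(sweep(X, 2, mu)^2))
  sd[sd == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd, "/")
  if (axis == "row") Z <- t(Z)
  Z
}

#' Top-contributing SEPs
#'
#' SEPs whose contribution reaches the (1 - percentile) empirical quantile;
#' the default keeps the top 0.1\% of contributors. Ties at the threshold are
#' all included, and at least one SEP (the argmax) is always returned; if
#' every contribution is equal the full set is returned with a warning.
#'
#' @param contributions named numeric vector from
#'   \code{\link{sepContributions}}.
#' @param percentile proportion of SEPs to keep, default 0.001.
#' @return character vector of SEP keys.
#' @export
topContributors <- function(contributions, percentile = 0.001) {
  stopifnot(percentile > 0, percentile < 1)
  if (length(unique(contributions)) == 1L) {
    warning("all contributions equal; returning every SEP")
    return(names(contributions))
  }
  thr <- stats::quantile(contributions, probs = 1 - percentile, names = FALSE,
                         type = 7)
  keep <- names(contributions)[contributions >= thr]
  if (!length(keep))
    keep <- names(contributions)[which.max(contributions)]
  keep
}

#' Shortest explanation paths from SEPs to a target
#'
#' Unweighted breadth-first shortest paths on the benchmark graph (the
#' held-out edge types are absent from it, so every path is an explanation
#' that does not use the deleted knowledge). All equally short paths are
#' retained up to \code{cap} per SEP, ordered deterministically by the node
#' keys along the path; unreachable SEPs are reported with length NA.
#'
#' @param graphDeleted the edge-deleted \linkS4class{HeteroGraph}.
#' @param seps character vector of SEP node keys (or integer indices).
#' @param target node key or index of the target.
#' @param cap maximum number of equally short paths kept per SEP.
#' @return data.frame (sep, length, path) with one row per retained path;
#'   \code{path} is the "key -> key" chain. A SEP equal to the target has a
#'   single length-0 path.
#' @export
shortestExplanationPaths <- function(graphDeleted, seps, target, cap = 10L) {
  keys <- nodeKeys(graphDeleted)
  ed <- edgeTable(graphDeleted)
  ig <- igraph::graph_from_edgelist(cbind(ed$src, ed$dst), directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, numNodes(graphDeleted) -
                                       igraph::vcount(ig)))
  tIdx <- resolveNode(graphDeleted, target)
  sIdx <- vapply(seps, function(s) resolveNode(graphDeleted, s), integer(1))
  out <- lapply(seq_along(sIdx), function(i) {
    s <- sIdx[i]
    if (s == tIdx)
      return(data.frame(sep = keys[s], length = 0L, path = keys[s],
                        stringsAsFactors = FALSE))
    ap <- suppressWarnings(
      igraph::all_shortest_paths(ig, from = s, to = tIdx))$vpath
    if (!length(ap))
      return(data.frame(sep = keys[s], length = NA_integer_,
                        path = NA_character_, stringsAsFactors = FALSE))
    chains <- vapply(ap, function(p)
      paste(keys[as.integer(p)], collapse = " -> "), character(1))
    chains <- sort(chains)
    chains <- chains[seq_len(min(cap, length(chains)))]
    data.frame(sep = keys[s],
               length = length(ap[[1]]) - 1L,
               path = chains, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (all(is.na(res$length)))
    message("target unreachable from every given SEP")
  res
}
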