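#' @import methods
#' @importFrom Matrix sparseMatrix colSums rowSums t Diagonal
#' @importClassesFrom Matrix Matrix
#' @importFrom stats setNames median pbinom pchisq quantile rnorm rpois runif
#' @importFrom utils read.delim write.table head combn
NULL

#' Typed heterogeneous knowledge graph
#'
#' Container for a typed heterogeneous network: an ordered node table and a
#' typed edge table. Nodes are ordered lexicographically by (type, id) and all
#' matrices derived from the graph inherit that ordering. The random walk
#' treats every edge as undirected, so the derived adjacency is symmetric.
#'
#' @slot nodes data.frame with columns \code{id}, \code{type}, \code{key}
#'   (\code{"type:id"}), sorted by (type, id); row number is the node index.
#' @slot edges data.frame with columns \code{src}, \code{dst} (integer node
#'   indices, oriented as given in the source data) and \code{type} (edge-type
#'   label); (unordered pair, type) is unique.
#' @slot nodeTypes declared node-type vocabulary.
#' @slot edgeTypes declared edge-type vocabulary.
#'
#' @export
setClass("HeteroGraph",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    nodeTypes = "character",
    edgeTypes = "character"
  )
)

setValidity("HeteroGraph", function(object) {
  nd <- object@nodes
  ed <- object@edges
  msg <- character()
  if (!all(c("id", "type", "key") %in% names(nd)))
    msg <- c(msg, "nodes must have columns id, type, key")
  if (!all(c("src", "dst", "type") %in% names(ed)))
    msg <- c(msg, "edges must have columns src, dst, type")
  if (anyDuplicated(nd$key))
    msg <- c(msg, "(type, id) must be unique across nodes")
  if (nrow(nd) > 1L) {
    ord <- order(nd$type, nd$id, method = "radix")
    if (!identical(ord, seq_len(nrow(nd))))
      msg <- c(msg, "nodes must be sorted by (type, id)")
  }
  if (nrow(ed) > 0L) {
    if (any(ed$src < 1L | ed$src > nrow(nd) | ed$dst < 1L | ed$dst > nrow(nd)))
      msg <- c(msg, "edge endpoints must be valid node indices")
    pk <- paste(pmin(ed$src, ed$dst), pmax(ed$src, ed$dst), ed$type)
    if (anyDuplicated(pk))
      msg <- c(msg, "(source, target, edge_type) must be unique")
    if (any(ed$src == ed$dst))
      msg <- c(msg, "self-loops are not allowed")
    if (length(object@edgeTypes) && !all(ed$type %in% object@edgeTypes))
      msg <- c(msg, "edge types outside declared vocabulary")
  }
  if (length(object@nodeTypes) && !all(nd$type %in% object@nodeTypes))
    msg <- c(msg, "node types outside declared vocabulary")
  if (length(msg)) msg else TRUE
})

#' Column-stochastic transition operator of the walk
#'
#' Out-edge-normalised adjacency of a \linkS4class{HeteroGraph} together with
#' the restart probability beta. Columns of \code{P} corresponding to
#' zero-degree (dangling) nodes are all-zero and flagged in
#' \code{danglingMask}; during the walk their mass is re-routed to the restart
#' distribution, which is the sparse equivalent of augmenting the matrix with
#' an extra restart row filled with beta.
#'
#' @slot P column-stochastic sparse matrix (dgCMatrix) over node indices.
#' @slot beta probability of a random jump per step, in (0, 1).
#' @slot danglingMask logical vector flagging zero-degree nodes.
#' @slot nodeKeys node keys in matrix order.
#'
#' @export
setClass("TransitionOperator",
  representation(
    P = "Matrix",
    beta = "numeric",
    danglingMask = "logical",
    nodeKeys = "character"
  )
)

setValidity("TransitionOperator", function(object) {
  msg <- character()
  n <- length(object@nodeKeys)
  if (!all(dim(object@P) == c(n, n)))
    msg <- c(msg, "P must be n x n with n = length(nodeKeys)")
  if (length(object@danglingMask) != n)
    msg <- c(msg, "danglingMask length must equal node count")
  if (object@beta <= 0 || object@beta >= 1)
    msg <- c(msg, "beta must lie strictly inside (0, 1)")
  cs <- Matrix::colSums(object@P)
  live <- !object@danglingMask
  if (any(abs(cs[live] - 1) > 1e-12))
    msg <- c(msg, "non-dangling columns of P must sum to 1 within 1e-12")
  if (any(cs[object@danglingMask] != 0))
    msg <- c(msg, "dangling columns of P must be all-zero")
  if (length(msg)) msg else TRUE
})

#' SEP transition matrix
#'
#' Column-stochastic matrix over entry-point (SEP) nodes encoding patient-level
#' SEP co-occurrence. Column j is the probability distribution with which a
#' walker restarting at SEP j re-enters the network through any SEP.
#'
#' @slot S dense n_SEP x n_SEP matrix, columns summing to 1.
#' @slot sepKeys ordered SEP node keys (dimnames of \code{S}).
#'
#' @export
setClass("SepTransitionMatrix",
  representation(S = "matrix", sepKeys = "character")
)

setValidity("SepTransitionMatrix", function(object) {
  msg <- character()
  n <- length(object@sepKeys)
  if (!all(dim(object@S) == c(n, n)))
    msg <- c(msg, "S must be square over sepKeys")
  if (any(object@S < 0))
    msg <- c(msg, "S entries must be nonnegative")
  cs <- colSums(object@S)
  nz <- cs > 0
  if (any(abs(cs[nz] - 1) > 1e-12))
    msg <- c(msg, "nonzero columns of S must sum to 1 within 1e-12")
  if (length(msg)) msg else TRUE
})

#' Matrix of propagated entry vectors
#'
#' Rows are PSEVs (one per EHR concept or cohort), columns are graph nodes in
#' the graph's canonical ordering. \code{kind} records whether the values are
#' raw walk mass (each row sums to 1), z-scores, or ranks.
#'
#' @slot values numeric matrix, rows = concepts/cohorts, cols = nodes.
#' @slot rowKeys concept/cohort identifiers.
#' @slot colKeys node keys (graph ordering).
#' @slot kind one of "raw", "zscore", "rank".
#' @slot provenance data.frame of per-row walk metadata (beta, alpha,
#'   iterations, restart description); zero rows when not applicable.
#'
#' @export
setClass("PsevMatrix",
  representation(
    values = "matrix",
    rowKeys = "character",
    colKeys = "character",
    kind = "character",
    provenance = "data.frame"
  )
)

setValidity("PsevMatrix", function(object) {
  msg <- character()
  if (!all(dim(object@values) ==
           c(length(object@rowKeys), length(object@colKeys))))
    msg <- c(msg, "values dimensions must match rowKeys x colKeys")
  if (!object@kind %in% c("raw", "zscore", "rank"))
    msg <- c(msg, "kind must be raw, zscore or rank")
  if (object@kind == "raw" && nrow(object@values) > 0) {
    rs <- rowSums(object@values)
    if (any(abs(rs - 1) > 1e-10))
      msg <- c(msg, "raw PSEV rows must sum to 1 within 1e-10")
    if (any(object@values < 0))
      msg <- c(msg, "raw PSEV values must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' Patient records mapped to entry-point nodes
#'
#' Per-patient sets of mapped concept nodes (binary incidence: a code occurring
#' many times in one patient counts once) plus optional continuous
#' measurements. The SEP universe is the union of entry points observed in at
#' least one patient.
#'
#' @slot records named list; one integer vector of graph node indices (the
#'   patient's SEPs) per patient.
#' @slot measurements data.frame with columns \code{patient_id}, \code{name},
#'   \code{value}.
#' @slot sepUniverse sorted integer node indices observed in >= 1 patient.
#' @slot nodeKeys node keys of the graph the indices refer to.
#'
#' @export
setClass("PatientSet",
  representation(
    records = "list",
    measurements = "data.frame",
    sepUniverse = "integer",
    nodeKeys = "character"
  )
)

setValidity("PatientSet", function(object) {
  msg <- character()
  if (is.null(names(object@records)) && length(object@records))
    msg <- c(msg, "records must be named by patient_id")
  if (anyDuplicated(names(object@records)))
    msg <- c(msg, "patient_id must be unique")
  if (length(object@records)) {
    rng <- range(unlist(object@records, use.names = FALSE))
    if (rng[1] < 1L || rng[2] > length(object@nodeKeys))
      msg <- c(msg, "record entries must be valid node indices")
  }
  if (length(msg)) msg else TRUE
})

#' Patient cohort
#'
#' A set of patient identifiers plus a provenance record describing how the
#' cohort was selected (by concept code or by an interval on a continuous
#' measurement).
#'
#' @slot patientIds character vector of member patient ids.
#' @slot definition one-row data.frame describing the selection rule.
#'
#' @export
setClass("Cohort",
  representation(patientIds = "character", definition = "data.frame")
)
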