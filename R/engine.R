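#' Compute one propagated entry vector (PSEV)
#'
#' Power iteration of the cohort-weighted restart walk
#' \deqn{r \leftarrow (1-\beta) P r + (\beta + (1-\beta) m_d(r)) v}
#' where \code{P} is the column-stochastic transition matrix, \code{v} the
#' restart distribution, and \code{m_d(r)} the mass currently sitting on
#' zero-degree nodes, which is re-routed to \code{v} (equivalent to the
#' extra restart row of the augmented-matrix formulation). Iteration starts
#' at \code{r0 = v} and stops when the L1 difference between consecutive
#' rank vectors is at most \code{alpha}. The fixed point is unique for
#' beta > 0, so the result does not depend on the start.
#'
#' @param op a \linkS4class{TransitionOperator} (records beta).
#' @param v restart distribution over graph nodes, summing to 1.
#' @param alpha L1 convergence threshold, default 1e-6.
#' @param maxIter iteration cap, default 1000.
#' @param checkConservation assert sum(r) == 1 at every iteration (used by
#'   the test suite).
#' @return numeric PSEV over graph nodes (names = node keys, sums to 1) with
#'   attributes \code{iterations} and \code{residual}.
#' @export
computePsev <- function(op, v, alpha = 1e-6, maxIter = 1000L,
                        checkConservation = FALSE) {
  P <- transitionMatrix(op)
  beta <- restartBeta(op)
  dang <- danglingMask(op)
  n <- length(nodeKeys(op))
  if (length(v) != n) stop("restart vector length must equal node count")
  if (abs(sum(v) - 1) > 1e-8) stop("restart vector must sum to 1")
  if (sum(v) <= 0 || any(v < 0)) stop("restart vector must be a distribution")
  r <- as.numeric(v)
  for (it in seq_len(maxIter)) {
    dmass <- if (any(dang)) sum(r[dang]) else 0
    rNew <- (1 - beta) * as.numeric(P %*% r) +
      (beta + (1 - beta) * dmass) * as.numeric(v)
    if (checkConservation && abs(sum(rNew) - 1) > 1e-10)
      stop("probability mass not conserved at iteration ", it)
    res <- sum(abs(rNew - r))
    r <- rNew
    if (res <= alpha) {
      r <- r / sum(r)
      return(structure(stats::setNames(r, nodeKeys(op)),
                       iterations = it, residual = res))
    }
  }
  stop("PSEV iteration did not converge within ", maxIter,
       " iterations (last L1 residual ", signif(res, 4), ")")
}

#' Compute a PSEV matrix for a collection of restart specifications
#'
#' One converged PSEV per restart distribution; rows are independent, so the
#' result is identical regardless of execution order.
#'
#' @param op a \linkS4class{TransitionOperator}.
#' @param restarts named list of restart distributions (each over all graph
#'   nodes, summing to 1).
#' @param alpha,maxIter as in \code{\link{computePsev}}.
#' @return a \linkS4class{PsevMatrix} with \code{kind = "raw"}.
#' @export
computeAllPsevs <- function(op, restarts, alpha = 1e-6, maxIter = 1000L) {
  if (!length(restarts)) stop("at least one restart specification is required")
  if (is.null(names(restarts)))
    names(restarts) <- paste0("psev", seq_along(restarts))
  rows <- lapply(names(restarts), function(nm) {
    r <- tryCatch(computePsev(op, restarts[[nm]], alpha, maxIter),
                  error = function(e)
                    stop("PSEV row '", nm, "': ", conditionMessage(e),
                         call. = FALSE))
    r
  })
  vals <- do.call(rbind, lapply(rows, as.numeric))
  dimnames(vals) <- list(names(restarts), nodeKeys(op))
  prov <- data.frame(
    row = names(restarts),
    beta = restartBeta(op),
    alpha = alpha,
    iterations = vapply(rows, function(r) attr(r, "iterations"), numeric(1)),
    stringsAsFactors = FALSE
  )
  new("PsevMatrix", values = vals, rowKeys = names(restarts),
      colKeys = nodeKeys(op), kind = "raw", provenance = prov)
}

#' Single-SEP, network-only PSEV (restart beta = 0.33)
#'
#' Personalised PageRank with a point-mass restart on one entry-point node,
#' computed on the (benchmark) graph with the relevant edge types deleted.
#' Used to attribute the mass a target node receives to individual SEPs when
#' tracing explanations; the stronger restart (beta = 0.33) keeps the walk
#' close to the entry point.
#'
#' @param op a \linkS4class{TransitionOperator} built with beta = 0.33 (any
#'   beta is accepted; 0.33 is the tracing convention).
#' @param sep node key or integer node index of the entry point.
#' @param alpha,maxIter as in \code{\link{computePsev}}.
#' @return numeric PSEV, as \code{\link{computePsev}}.
#' @export
computePsevSpokeOnly <- function(op, sep, alpha = 1e-6, maxIter = 1000L) {
  idx <- resolveNode(op, sep)
  v <- numeric(length(nodeKeys(op)))
  v[idx] <- 1
  computePsev(op, v, alpha, maxIter)
}

#' Matrix of single-SEP network-only PSEVs
#'
#' One \code{\link{computePsevSpokeOnly}} row per SEP; the input to
#' \code{\link{sepContributions}}.
#'
#' @param op a \linkS4class{TransitionOperator} (conventionally beta = 0.33).
#' @param sepIndex integer node indices (or keys) of the SEPs.
#' @param alpha,maxIter as in \code{\link{computePsev}}.
#' @return a \linkS4class{PsevMatrix} whose rows are named by SEP node key.
#' @export
spokeOnlyMatrix <- function(op, sepIndex, alpha = 1e-6, maxIter = 1000L) {
  keys <- nodeKeys(op)
  idx <- vapply(sepIndex, function(s) resolveNode(op, s), integer(1))
  restarts <- lapply(idx, function(i) {
    v <- numeric(length(keys))
    v[i] <- 1
    v
  })
  names(restarts) <- keys[idx]
  computeAllPsevs(op, restarts, alpha, maxIter)
}

# resolveNode works for anything with a nodeKeys() method
resolveNode <- function(x, node) {
  keys <- nodeKeys(x)
  if (is.character(node)) {
    i <- match(node, keys)
    if (is.na(i)) stop("unknown node key: ", node)
    i
  } else {
    i <- as.integer(node)
    if (is.na(i) || i < 1L || i > length(keys)) stop("node index out of range")
    i
  }
}
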