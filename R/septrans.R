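#' Build the SEP transition matrix from patient co-occurrence
#'
#' For each patient, the binary vector of the SEPs in their record is divided
#' by its sum and added to the rows corresponding to the patient's SEPs. The
#' accumulated matrix is then transposed and each column divided by its sum,
#' giving a column-stochastic matrix: column j is the distribution over SEPs
#' with which a walker restarting "at" SEP j re-enters the network, weighted
#' by how often other SEPs co-occur with j across patients.
#'
#' Patients with an empty SEP set are skipped with a message.
#'
#' @param patients a \linkS4class{PatientSet}.
#' @param sepIndex optional integer node indices fixing the SEP ordering;
#'   defaults to the patient set's observed SEP universe.
#' @return a \linkS4class{SepTransitionMatrix}.
#' @export
buildSepTransition <- function(patients, sepIndex = NULL) {
  if (is.null(sepIndex)) sepIndex <- sepUniverse(patients)
  sepIndex <- as.integer(sepIndex)
  n <- length(sepIndex)
  if (n == 0L) stop("empty SEP universe")
  keys <- nodeKeys(patients)[sepIndex]
  M <- matrix(0, n, n, dimnames = list(keys, keys))
  skipped <- 0L
  for (rec in patientRecords(patients)) {
    pos <- match(rec, sepIndex)
    pos <- pos[!is.na(pos)]
    if (!length(pos)) {
      skipped <- skipped + 1L
      next
    }
    v <- numeric(n)
    v[pos] <- 1 / length(pos)
    M[pos, ] <- M[pos, , drop = FALSE] +
      matrix(v, nrow = length(pos), ncol = n, byrow = TRUE)
  }
  if (skipped) message(skipped, " patient(s) with no SEPs skipped")
  S <- t(M)
  cs <- colSums(S)
  nz <- cs > 0
  S[, nz] <- sweep(S[, nz, drop = FALSE], 2, cs[nz], "/")
  new("SepTransitionMatrix", S = S, sepKeys = keys)
}

#' Restart distribution over graph nodes
#'
#' Builds the personalised restart vector of the walk. For a single concept
#' (a SEP key or index), the restart vector is the corresponding column of
#' the SEP transition matrix scattered onto graph-node positions: on a jump
#' the walker re-enters through any SEP with the co-occurrence probabilities
#' of that column. For a cohort, the default restart is the cohort's SEP
#' weight vector normalised to sum 1 (the walker jumps to a random cohort
#' patient and traverses to one of that patient's SEPs); set
#' \code{composed = TRUE} to additionally route the cohort weights through
#' the SEP transition matrix (S times the normalised weights).
#'
#' @param S a \linkS4class{SepTransitionMatrix}.
#' @param target a SEP node key / integer node index, or a named numeric
#'   cohort weight vector over SEP keys (from \code{\link{sepWeights}}).
#' @param nodeKeys the graph's node-key ordering (defines the output length).
#' @param composed for cohort weights, return S %*% w-normalised instead of
#'   the normalised weights themselves.
#' @return numeric vector over all graph nodes, summing to 1.
#' @export
restartDistribution <- function(S, target, nodeKeys, composed = FALSE) {
  keys <- sepKeys(S)
  if (is.numeric(target) && !is.null(names(target))) {
    w <- target[match(keys, names(target))]
    w[is.na(w)] <- 0
    if (sum(w) <= 0) stop("cohort weight vector has no support on the SEPs")
    w <- w / sum(w)
    sepDist <- if (composed) drop(sepMatrix(S) %*% w) else w
  } else {
    j <- if (is.character(target)) match(target, keys)
         else match(target, match(keys, nodeKeys))
    if (is.na(j)) stop("target SEP not present in the SEP transition matrix")
    sepDist <- sepMatrix(S)[, j]
    if (sum(sepDist) <= 0) stop("target SEP column has no support")
  }
  v <- numeric(length(nodeKeys))
  pos <- match(keys, nodeKeys)
  if (anyNA(pos)) stop("SEP keys missing from the node ordering")
  v[pos] <- sepDist
  v / sum(v)
}
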