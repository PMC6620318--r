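#' Orient held-out edges as (concept, candidate) pairs
#'
#' Turns the raw gold-standard edge table returned by
#' \code{\link{deleteEdgesByType}} into (from, to) key pairs, with the "from"
#' endpoint of \code{fromType} (the concepts that have PSEV rows, e.g.
#' Disease) and the "to" endpoint of \code{toType} (the ranked candidates,
#' e.g. Gene). Edges not joining the two types are dropped.
#'
#' @param gold data.frame from \code{\link{deleteEdgesByType}}.
#' @param graph the \linkS4class{HeteroGraph}.
#' @param fromType,toType node types of the two endpoints.
#' @param edgeTypes optional filter on gold edge types (e.g. keep only the
#'   well-established association type as the scoring standard).
#' @return data.frame with columns \code{from_key}, \code{to_key},
#'   \code{type}.
#' @export
orientGold <- function(gold, graph, fromType = "Disease", toType = "Gene",
                       edgeTypes = NULL) {
  if (!is.null(edgeTypes)) gold <- gold[gold$type %in% edgeTypes, , drop = FALSE]
  nd <- nodeTable(graph)
  sty <- nd$type[gold$src]
  dty <- nd$type[gold$dst]
  fwd <- sty == fromType & dty == toType
  rev <- sty == toType & dty == fromType
  out <- data.frame(
    from_key = c(gold$src_key[fwd], gold$dst_key[rev]),
    to_key = c(gold$dst_key[fwd], gold$src_key[rev]),
    type = c(gold$type[fwd], gold$type[rev]),
    stringsAsFactors = FALSE
  )
  out[order(out$from_key, out$to_key), , drop = FALSE]
}

#' Infer a top-K network from ranked PSEVs
#'
#' For each concept (PSEV row) present in the gold standard, the top
#' K ranked candidate nodes are selected, with K equal to that concept's
#' number of held-out gold edges. The candidate universe is either every
#' node of the candidate type or only candidates appearing in the gold
#' standard.
#'
#' @param M a \linkS4class{PsevMatrix} (z-scored).
#' @param graph the \linkS4class{HeteroGraph}.
#' @param gold oriented gold standard from \code{\link{orientGold}}.
#' @param universe "all" (every node of \code{toType}) or "associated"
#'   (only gold candidates).
#' @param toType candidate node type, default "Gene".
#' @param exclude optional data.frame (\code{from_key}, \code{to_key}) of
#'   already-known pairs (e.g. edges restored to the graph) removed from the
#'   corresponding concept's candidate list before the top-K cut, the usual
#'   exclusion of training edges in link-prediction evaluation.
#' @return data.frame of inferred edges (\code{from_key}, \code{to_key}).
#' @export
inferTopkNetwork <- function(M, graph, gold,
                             universe = c("all", "associated"),
                             toType = "Gene", exclude = NULL) {
  universe <- match.arg(universe)
  cand <- if (universe == "associated") sort(unique(gold$to_key)) else NULL
  ranks <- rankByType(M, graph, toType, universe = cand)
  K <- table(gold$from_key)
  concepts <- intersect(rownames(ranks), names(K))
  skipped <- setdiff(names(K), rownames(ranks))
  if (length(skipped))
    message(length(skipped), " gold concept(s) without a PSEV row skipped")
  out <- lapply(concepts, function(d) {
    k <- as.integer(K[[d]])
    rk <- ranks[d, ]
    if (!is.null(exclude)) {
      drop <- exclude$to_key[exclude$from_key == d]
      rk <- rk[!names(rk) %in% drop]
    }
    data.frame(from_key = d,
               to_key = names(sort(rk)[seq_len(min(k, length(rk)))]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(from_key = character(), to_key = character(),
                      stringsAsFactors = FALSE)
  attr(res, "universeSize") <- ncol(ranks)
  res
}

#' Combine p-values with Fisher's method
#'
#' X = -2 sum(log p) is chi-square with 2m degrees of freedom under the
#' null of independent uniform p-values.
#'
#' @param p numeric vector of p-values (NA dropped).
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @export
fisherCombine <- function(p) {
  p <- p[!is.na(p)]
  X <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(statistic = X, df = df,
       p.value = stats::pchisq(X, df = df, lower.tail = FALSE))
}

#' Score an inferred network against the gold standard
#'
#' Per concept: the overlap between its inferred top-K edges and its gold
#' edges, with a binomial upper-tail p-value using n = K and success
#' probability p0 = K / G (G = candidate universe size), the probability
#' that a uniformly random rank list places a gold candidate in the top K;
#' this matches the permutation expectation K^2 / G. Per-concept p-values
#' are combined across concepts by Fisher's method with 2 x (number of
#' scored concepts) degrees of freedom.
#'
#' @param inferred data.frame from \code{\link{inferTopkNetwork}}.
#' @param gold oriented gold standard (same universe).
#' @param universeSize candidate universe size G; defaults to the value
#'   recorded by \code{\link{inferTopkNetwork}}.
#' @return list of class \code{psevRecovery}: \code{perConcept} (data.frame
#'   with concept, K, overlap, p), \code{totalOverlap}, \code{fisher}
#'   (statistic, df, p.value), \code{universeSize}.
#' @export
scoreOverlap <- function(inferred, gold, universeSize = NULL) {
  if (is.null(universeSize)) universeSize <- attr(inferred, "universeSize")
  if (is.null(universeSize)) stop("universeSize is required")
  concepts <- sort(unique(inferred$from_key))
  goldPairs <- paste(gold$from_key, gold$to_key)
  per <- do.call(rbind, lapply(concepts, function(d) {
    inf <- inferred$to_key[inferred$from_key == d]
    gd <- gold$to_key[gold$from_key == d]
    k <- length(intersect(inf, gd))
    K <- length(gd)
    p0 <- K / universeSize
    p <- stats::pbinom(k - 1L, size = K, prob = p0, lower.tail = FALSE)
    data.frame(concept = d, K = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(per))
    per <- data.frame(concept = character(), K = integer(),
                      overlap = integer(), p = numeric())
  structure(list(
    perConcept = per,
    totalOverlap = sum(per$overlap),
    fisher = fisherCombine(per$p),
    universeSize = universeSize
  ), class = "psevRecovery")
}

#' @rdname scoreOverlap
#' @param x a \code{psevRecovery} object.
#' @param ... ignored.
#' @method print psevRecovery
#' @export
print.psevRecovery <- function(x, ...) {
  cat("Edge recovery:", x$totalOverlap, "of", sum(x$perConcept$K),
      "held-out edges recovered over", nrow(x$perConcept),
      "concepts (G =", x$universeSize, ")\n")
  cat("Fisher's method: X =", signif(x$fisher$statistic, 5), "on",
      x$fisher$df, "df, p =", format(x$fisher$p.value, digits = 4), "\n")
  invisible(x)
}

#' Fisher-Yates permutation null for a PSEV matrix
#'
#' Each permutation independently shuffles the node axis of every PSEV row
#' (a Fisher-Yates permutation per row) and applies the full top-K /
#' overlap scoring pipeline, giving the empirical null distribution of the
#' overlap statistic.
#'
#' @param M a z-scored \linkS4class{PsevMatrix}.
#' @param graph the \linkS4class{HeteroGraph}.
#' @param gold oriented gold standard.
#' @param universe,toType as in \code{\link{inferTopkNetwork}}.
#' @param nPerm number of permutations.
#' @param seed integer seed; runs reproduce bit-identically.
#' @return list: \code{total} (numeric vector of total overlaps),
#'   \code{perConcept} (nPerm x concepts overlap matrix),
#'   \code{universeSize}.
#' @export
nullRandomPsev <- function(M, graph, gold, universe = c("all", "associated"),
                           toType = "Gene", nPerm = 1000L, seed = 1L) {
  universe <- match.arg(universe)
  X <- psevValues(M)
  concepts <- sort(intersect(M@rowKeys, unique(gold$from_key)))
  per <- matrix(0L, nrow = nPerm, ncol = length(concepts),
                dimnames = list(NULL, concepts))
  total <- numeric(nPerm)
  withSeed(seed, {
    for (b in seq_len(nPerm)) {
      Xp <- X
      for (i in seq_len(nrow(Xp))) Xp[i, ] <- Xp[i, sample.int(ncol(Xp))]
      Mp <- methods::initialize(M, values = Xp, kind = "zscore")
      inf <- suppressMessages(
        inferTopkNetwork(Mp, graph, gold, universe = universe,
                         toType = toType))
      sc <- scoreOverlap(inf, gold)
      per[b, sc$perConcept$concept] <- sc$perConcept$overlap
      total[b] <- sc$totalOverlap
    }
  })
  list(total = total, perConcept = per,
       universeSize = if (universe == "associated")
         length(unique(gold$to_key))
       else sum(nodeTable(graph)$type == toType))
}

#' End-to-end PSEV recovery pipeline for a set of cohorts
#'
#' Convenience wrapper running the full benchmark pipeline on a given graph:
#' build the transition operator, the SEP transition matrix, per-cohort
#' restart distributions and PSEVs, z-score per node, rank candidates and
#' score the overlap with the gold standard.
#'
#' @param graph the (possibly edge-deleted or shuffled)
#'   \linkS4class{HeteroGraph} to walk on.
#' @param patients a \linkS4class{PatientSet} (SEP sets drive the restart).
#' @param cohorts named list of \linkS4class{Cohort}s; names are the concept
#'   keys matching \code{gold$from_key}.
#' @param gold oriented gold standard from \code{\link{orientGold}}.
#' @param universe,toType as in \code{\link{inferTopkNetwork}}.
#' @param beta,alpha walk parameters (defaults 0.1 and 1e-6).
#' @param composed route cohort weights through the SEP transition matrix
#'   (see \code{\link{restartDistribution}}).
#' @return list: \code{score} (a \code{psevRecovery}), \code{psev} (raw
#'   \linkS4class{PsevMatrix}), \code{zscore} (z-scored matrix),
#'   \code{inferred} (edge data.frame).
#' @export
recoverHeldOutEdges <- function(graph, patients, cohorts, gold,
                                universe = c("all", "associated"),
                                toType = "Gene", beta = 0.1, alpha = 1e-6,
                                composed = FALSE, exclude = NULL) {
  universe <- match.arg(universe)
  op <- buildTransitionOperator(graph, beta = beta)
  S <- buildSepTransition(patients)
  restarts <- lapply(cohorts, function(co)
    restartDistribution(S, sepWeights(co, patients), nodeKeys(graph),
                        composed = composed))
  M <- computeAllPsevs(op, restarts, alpha = alpha)
  Z <- zscoreNormalize(M, axis = "node")
  inf <- inferTopkNetwork(Z, graph, gold, universe = universe,
                          toType = toType, exclude = exclude)
  list(score = scoreOverlap(inf, gold), psev = M, zscore = Z, inferred = inf)
}

#' Shuffled-substrate nulls (network edges or patient-SEP links)
#'
#' Recomputes the whole pipeline on a randomised substrate. In
#' \code{"spoke-edges"} mode every edge type of the full network is rewired
#' by degree-preserving swaps before PSEV creation (held-out edge types are
#' NOT deleted first, so the true edges can survive by chance, a stricter
#' null). In \code{"sep-edges"} mode the network is left untouched and the
#' patient-to-SEP incidence links are shuffled once (the SEP endpoints of
#' all patient-SEP pairs are permuted), then the pipeline is rerun.
#'
#' @param graph the full \linkS4class{HeteroGraph} (no deletions).
#' @param patients a \linkS4class{PatientSet}.
#' @param cohorts named list of \linkS4class{Cohort}s.
#' @param gold oriented gold standard.
#' @param mode "spoke-edges" or "sep-edges".
#' @param seed integer seed.
#' @param ... passed to \code{\link{recoverHeldOutEdges}}.
#' @return as \code{\link{recoverHeldOutEdges}}.
#' @export
nullShuffledGraph <- function(graph, patients, cohorts, gold,
                              mode = c("spoke-edges", "sep-edges"),
                              seed = 1L, ...) {
  mode <- match.arg(mode)
  if (mode == "spoke-edges") {
    g2 <- shuffleEdgesByType(graph, seed = seed)
    recoverHeldOutEdges(g2, patients, cohorts, gold, ...)
  } else {
    recs <- patientRecords(patients)
    pid <- rep(names(recs), lengths(recs))
    sep <- unlist(recs, use.names = FALSE)
    withSeed(seed, sep <- sep[sample.int(length(sep))])
    shuffled <- patientSet(split(sep, pid),
                           measurements = patientMeasurements(patients),
                           graph = nodeKeys(patients),
                           allIds = names(recs))
    recoverHeldOutEdges(graph, shuffled, cohorts, gold, ...)
  }
}

#' Add-back learning curves
#'
#' Gradually restores held-out knowledge: at each fraction f, f of each
#' gold stratum (edge type) is restored, PSEVs are recomputed on the
#' partially restored graph, and the inferred top-K network is scored
#' against the full deleted gold standard of each stratum (restored edges
#' are ranked from direct knowledge, still-held-out ones must be inferred
#' through redundant routes, so the curve tracks how the network learns as
#' knowledge returns). The rate is overlap / (stratum gold size); at
#' fraction 1 nothing remains held out and the curve reaches the
#' full-knowledge level.
#'
#' @param graph the full \linkS4class{HeteroGraph}.
#' @param patients a \linkS4class{PatientSet}.
#' @param cohorts named list of \linkS4class{Cohort}s.
#' @param deleteTypes edge types to hold out before PSEV creation.
#' @param strata edge types whose recovery curves are reported (subset of
#'   \code{deleteTypes} joining the from/to node types).
#' @param fractions ascending proportions, conventionally including 0.
#' @param seed integer seed for the add-back sampling.
#' @param fromType,toType endpoint node types of the scored strata.
#' @param universe,beta,alpha,composed as in
#'   \code{\link{recoverHeldOutEdges}}.
#' @return data.frame (fraction, stratum, gold, heldOut, overlap, rate).
#' @export
addbackCurve <- function(graph, patients, cohorts, deleteTypes, strata,
                         fractions = c(0, 0.25, 0.5, 0.75),
                         seed = 1L, fromType = "Disease", toType = "Gene",
                         universe = c("all", "associated"),
                         beta = 0.1, alpha = 1e-6, composed = FALSE) {
  universe <- match.arg(universe)
  del <- deleteEdgesByType(graph, deleteTypes)
  out <- list()
  for (f in fractions) {
    ab <- addbackEdges(del$graph, del$gold, f, seed = seed,
                       stratifyBy = "type")
    for (s in strata) {
      goldS <- orientGold(del$gold, graph, fromType, toType, edgeTypes = s)
      stillHeld <- sum(ab$heldOut$type == s)
      if (!nrow(goldS)) next
      res <- recoverHeldOutEdges(ab$graph, patients, cohorts, goldS,
                                 universe = universe, toType = toType,
                                 beta = beta, alpha = alpha,
                                 composed = composed)
      out[[length(out) + 1L]] <- data.frame(
        fraction = f, stratum = s, gold = nrow(goldS),
        heldOut = stillHeld, overlap = res$score$totalOverlap,
        rate = res$score$totalOverlap / nrow(goldS))
    }
  }
  do.call(rbind, out)
}

#' Permutation enrichment of a disease/gene block
#'
#' Observed statistic: the number of cluster genes associated with at least
#' t cluster diseases. Expected: the mean of the same statistic over
#' \code{nPerm} uniformly random draws of equally sized disease and gene
#' sets from the full universes. Fold change = observed / expected; an
#' expected value of 0 yields Inf with a flag.
#'
#' @param assoc data.frame with columns \code{disease}, \code{gene}; the
#'   association table over the full universes.
#' @param clusterDiseases,clusterGenes the block to test.
#' @param diseaseUniverse,geneUniverse full universes; default the distinct
#'   values in \code{assoc} unioned with the cluster members.
#' @param thresholds integer thresholds t, default 1:3.
#' @param nPerm number of permutations, default 1000.
#' @param seed integer seed.
#' @return data.frame (threshold, observed, expected, sd, fold, infinite);
#'   \code{sd} is the permutation standard deviation of the statistic, so
#'   \code{sd/sqrt(nPerm)} is the Monte-Carlo standard error of
#'   \code{expected}.
#' @export
blockEnrichment <- function(assoc, clusterDiseases, clusterGenes,
                            diseaseUniverse = NULL, geneUniverse = NULL,
                            thresholds = 1:3, nPerm = 1000L, seed = 1L) {
  if (is.null(diseaseUniverse))
    diseaseUniverse <- sort(unique(c(assoc$disease, clusterDiseases)))
  if (is.null(geneUniverse))
    geneUniverse <- sort(unique(c(assoc$gene, clusterGenes)))
  stopifnot(all(clusterDiseases %in% diseaseUniverse),
            all(clusterGenes %in% geneUniverse))
  nD <- length(diseaseUniverse)
  nG <- length(geneUniverse)
  A <- matrix(FALSE, nG, nD, dimnames = list(geneUniverse, diseaseUniverse))
  if (nrow(assoc))
    A[cbind(match(assoc$gene, geneUniverse),
            match(assoc$disease, diseaseUniverse))] <- TRUE
  md <- length(clusterDiseases)
  mg <- length(clusterGenes)
  cntObs <- rowSums(A[match(clusterGenes, geneUniverse),
                      match(clusterDiseases, diseaseUniverse),
                      drop = FALSE])
  observed <- vapply(thresholds, function(t) sum(cntObs >= t), numeric(1))
  expSum <- numeric(length(thresholds))
  expSq <- numeric(length(thresholds))
  withSeed(seed, {
    for (b in seq_len(nPerm)) {
      di <- sample.int(nD, md)
      gi <- sample.int(nG, mg)
      cnt <- rowSums(A[gi, di, drop = FALSE])
      for (j in seq_along(thresholds)) {
        s <- sum(cnt >= thresholds[j])
        expSum[j] <- expSum[j] + s
        expSq[j] <- expSq[j] + s * s
      }
    }
  })
  expected <- expSum / nPerm
  data.frame(
    threshold = thresholds, observed = observed, expected = expected,
    sd = sqrt(pmax(0, expSq / nPerm - expected^2)),
    fold = ifelse(expected == 0, Inf, observed / expected),
    infinite = expected == 0
  )
}
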