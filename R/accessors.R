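#' Accessors for the core classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of one of the package's classes.
#' @return \code{nodeTable} and \code{edgeTable} return data.frames;
#'   \code{nodeKeys} the canonical \code{"type:id"} keys; \code{numNodes} /
#'   \code{numEdges} integer counts; \code{psevValues} the numeric matrix of a
#'   \linkS4class{PsevMatrix}; \code{sepKeys} the SEP ordering of a
#'   \linkS4class{SepTransitionMatrix}; \code{patientIds} the member ids of a
#'   \linkS4class{Cohort} or the patient ids of a \linkS4class{PatientSet}.
#'
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("nodeKeys", function(x) standardGeneric("nodeKeys"))
#' @rdname accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))
#' @rdname accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))
#' @rdname accessors
#' @export
setGeneric("psevValues", function(x) standardGeneric("psevValues"))
#' @rdname accessors
#' @export
setGeneric("sepKeys", function(x) standardGeneric("sepKeys"))
#' @rdname accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname accessors
setMethod("nodeTable", "HeteroGraph", function(x) x@nodes)
#' @rdname accessors
setMethod("edgeTable", "HeteroGraph", function(x) x@edges)
#' @rdname accessors
setMethod("nodeKeys", "HeteroGraph", function(x) x@nodes$key)
#' @rdname accessors
setMethod("numNodes", "HeteroGraph", function(x) nrow(x@nodes))
#' @rdname accessors
setMethod("numEdges", "HeteroGraph", function(x) nrow(x@edges))
#' @rdname accessors
setMethod("nodeKeys", "TransitionOperator", function(x) x@nodeKeys)
#' @rdname accessors
setMethod("nodeKeys", "PatientSet", function(x) x@nodeKeys)
#' @rdname accessors
setMethod("psevValues", "PsevMatrix", function(x) x@values)
#' @rdname accessors
setMethod("sepKeys", "SepTransitionMatrix", function(x) x@sepKeys)
#' @rdname accessors
setMethod("patientIds", "Cohort", function(x) x@patientIds)
#' @rdname accessors
setMethod("patientIds", "PatientSet", function(x) names(x@records))

#' @describeIn accessors transition probability matrix of a
#'   \linkS4class{TransitionOperator}.
#' @export
transitionMatrix <- function(x) {
  stopifnot(is(x, "TransitionOperator"))
  x@P
}

#' @describeIn accessors restart probability beta of a
#'   \linkS4class{TransitionOperator}.
#' @export
restartBeta <- function(x) {
  stopifnot(is(x, "TransitionOperator"))
  x@beta
}

#' @describeIn accessors logical mask of zero-degree nodes.
#' @export
danglingMask <- function(x) {
  stopifnot(is(x, "TransitionOperator"))
  x@danglingMask
}

#' @describeIn accessors SEP co-occurrence matrix of a
#'   \linkS4class{SepTransitionMatrix}.
#' @export
sepMatrix <- function(x) {
  stopifnot(is(x, "SepTransitionMatrix"))
  x@S
}

#' @describeIn accessors SEP universe (integer node indices) of a
#'   \linkS4class{PatientSet}.
#' @export
sepUniverse <- function(x) {
  stopifnot(is(x, "PatientSet"))
  x@sepUniverse
}

#' @describeIn accessors per-patient SEP sets (named list of node indices).
#' @export
patientRecords <- function(x) {
  stopifnot(is(x, "PatientSet"))
  x@records
}

#' @describeIn accessors measurement table of a \linkS4class{PatientSet}.
#' @export
patientMeasurements <- function(x) {
  stopifnot(is(x, "PatientSet"))
  x@measurements
}

setMethod("show", "HeteroGraph", function(object) {
  cat("HeteroGraph with", nrow(object@nodes), "nodes of",
      length(unique(object@nodes$type)), "types and",
      nrow(object@edges), "edges of",
      length(unique(object@edges$type)), "types\n")
  nt <- table(object@nodes$type)
  cat("  nodes:", paste0(names(nt), "(", nt, ")", collapse = " "), "\n")
  if (nrow(object@edges)) {
    et <- table(object@edges$type)
    cat("  edges:", paste0(names(et), "(", et, ")", collapse = " "), "\n")
  }
})

setMethod("show", "TransitionOperator", function(object) {
  cat("TransitionOperator over", length(object@nodeKeys),
      "nodes; beta =", object@beta,
      "; dangling =", sum(object@danglingMask), "\n")
})

setMethod("show", "SepTransitionMatrix", function(object) {
  cat("SepTransitionMatrix over", length(object@sepKeys), "SEPs\n")
})

setMethod("show", "PsevMatrix", function(object) {
  cat("PsevMatrix [", object@kind, "]: ", length(object@rowKeys),
      " PSEVs x ", length(object@colKeys), " nodes\n", sep = "")
})

setMethod("show", "PatientSet", function(object) {
  cat("PatientSet:", length(object@records), "patients,",
      length(object@sepUniverse), "SEPs observed\n")
})

setMethod("show", "Cohort", function(object) {
  cat("Cohort of", length(object@patientIds), "patients (",
      object@definition$rule[1], ")\n")
})
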