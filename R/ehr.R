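#' Read a concept-to-node mapping table
#'
#' The map links structured EHR codes (diagnosis, medication order, lab) to
#' graph nodes. Each code must map to exactly one node; multi-mapping codes
#' are rejected, and every mapped node must exist in the graph.
#'
#' @param path TSV file with columns \code{code}, \code{node_type},
#'   \code{node_id}.
#' @param graph the \linkS4class{HeteroGraph} the map refers to.
#' @return data.frame with columns \code{code}, \code{key}, \code{node}
#'   (integer node index).
#' @export
readConceptMap <- function(path, graph) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  conceptMap(tab, graph)
}

#' @rdname readConceptMap
#' @param table in-memory data.frame with the same columns as the file form.
#' @export
conceptMap <- function(table, graph) {
  req <- c("code", "node_type", "node_id")
  if (!all(req %in% names(table)))
    stop("concept map needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(table$code))
    stop("multi-mapping concept code(s): ",
         paste(unique(table$code[duplicated(table$code)]), collapse = ", "))
  key <- paste(table$node_type, table$node_id, sep = ":")
  idx <- match(key, nodeKeys(graph))
  if (anyNA(idx))
    stop("mapped node(s) absent from graph: ",
         paste(utils::head(key[is.na(idx)], 5), collapse = ", "))
  data.frame(code = as.character(table$code), key = key, node = idx,
             stringsAsFactors = FALSE)
}

#' Load patient tables and map concepts to entry-point nodes
#'
#' Reads the diagnosis, medication-order and lab tables (TSV, columns
#' \code{patient_id}, \code{code} and optionally \code{value}), maps each code
#' through the concept map, and collapses each patient's mapped concepts to a
#' binary incidence set of entry-point (SEP) nodes. Unmapped codes are counted
#' and reported. Rows with a numeric \code{value} are additionally kept as
#' continuous measurements named by their code.
#'
#' @param diagnosisFile,medicationFile,labFile TSV paths; any may be NULL.
#' @param map concept map from \code{\link{conceptMap}}.
#' @param graph the \linkS4class{HeteroGraph}.
#' @return a \linkS4class{PatientSet}; the SEP universe is the union of
#'   mapped nodes observed in at least one patient.
#' @export
loadPatients <- function(diagnosisFile = NULL, medicationFile = NULL,
                         labFile = NULL, map, graph) {
  paths <- Filter(Negate(is.null),
                  list(diagnosisFile, medicationFile, labFile))
  if (!length(paths)) stop("at least one patient table is required")
  tabs <- lapply(paths, utils::read.delim, stringsAsFactors = FALSE,
                 colClasses = c(patient_id = "character", code = "character"))
  rows <- do.call(rbind, lapply(tabs, function(t) {
    if (!all(c("patient_id", "code") %in% names(t)))
      stop("patient tables need columns patient_id, code")
    data.frame(patient_id = t$patient_id, code = t$code,
               value = if ("value" %in% names(t))
                 suppressWarnings(as.numeric(t$value)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  meas <- rows[!is.na(rows$value), c("patient_id", "code", "value")]
  names(meas)[2] <- "name"
  rownames(meas) <- NULL
  node <- map$node[match(rows$code, map$code)]
  unmapped <- sum(is.na(node))
  if (unmapped)
    message(unmapped, " row(s) with unmapped code(s) ignored for SEP sets")
  ok <- !is.na(node)
  if (!any(ok))
    stop("no patient code maps to a graph node")
  patientSet(split(node[ok], rows$patient_id[ok]),
             measurements = meas, graph = graph,
             allIds = unique(rows$patient_id))
}

#' Build a PatientSet from in-memory records
#'
#' @param records named list of integer node-index vectors (or a list of
#'   node keys), one per patient; multiplicity is collapsed.
#' @param measurements data.frame with columns \code{patient_id},
#'   \code{name}, \code{value}.
#' @param graph the \linkS4class{HeteroGraph}, or directly its node-key
#'   character vector.
#' @param allIds optional full patient-id universe (patients with no mapped
#'   concept are kept with empty SEP sets).
#' @return a \linkS4class{PatientSet}.
#' @export
patientSet <- function(records, measurements = NULL, graph, allIds = NULL) {
  keys <- if (is.character(graph)) graph else nodeKeys(graph)
  records <- lapply(records, function(v) {
    if (is.character(v)) {
      i <- match(v, keys)
      if (anyNA(i)) stop("unknown node key(s): ",
                         paste(v[is.na(i)], collapse = ", "))
      v <- i
    }
    sort(unique(as.integer(v)))
  })
  if (!is.null(allIds)) {
    missing <- setdiff(allIds, names(records))
    if (length(missing)) {
      empty <- stats::setNames(
        rep(list(integer()), length(missing)), missing)
      records <- c(records, empty)
    }
    records <- records[order(names(records), method = "radix")]
  }
  if (is.null(measurements))
    measurements <- data.frame(patient_id = character(), name = character(),
                               value = numeric(), stringsAsFactors = FALSE)
  universe <- sort(unique(unlist(records, use.names = FALSE)))
  new("PatientSet", records = records, measurements = measurements,
      sepUniverse = as.integer(universe), nodeKeys = keys)
}

#' Select a cohort by concept code / entry-point node
#'
#' The cohort is every patient whose SEP set contains the given node, the
#' direct analogue of "all patients carrying this diagnosis / medication /
#' lab concept".
#'
#' @param patients a \linkS4class{PatientSet}.
#' @param sep node key ("Type:id") or integer node index.
#' @return a \linkS4class{Cohort}.
#' @export
selectCohortByCode <- function(patients, sep) {
  idx <- resolveNode(patients, sep)
  hit <- vapply(patientRecords(patients), function(v) idx %in% v, logical(1))
  if (!any(hit))
    stop("no patient carries SEP ", nodeKeys(patients)[idx])
  new("Cohort", patientIds = names(which(hit)),
      definition = data.frame(rule = paste0("code:", nodeKeys(patients)[idx]),
                              stringsAsFactors = FALSE))
}

#' Select a cohort by an interval on a continuous measurement
#'
#' Patients whose reduced per-patient value lies in the closed interval
#' [lo, hi] form the cohort; open bounds are expressed with -Inf / Inf.
#' Repeated measurements are reduced per patient by the median (default) or
#' the last recorded value.
#'
#' @param patients a \linkS4class{PatientSet}.
#' @param measurement measurement name (e.g. "BMI").
#' @param lo,hi closed interval bounds; use -Inf / Inf for open sides.
#' @param reduce "median" (default) or "last".
#' @return a \linkS4class{Cohort}.
#' @export
selectCohortByInterval <- function(patients, measurement, lo, hi,
                                   reduce = c("median", "last")) {
  reduce <- match.arg(reduce)
  if (lo > hi) stop("lo must not exceed hi")
  v <- patientMeasurementValues(patients, measurement, reduce)
  if (!length(v)) stop("measurement not recorded: ", measurement)
  ids <- names(v)[v >= lo & v <= hi]
  new("Cohort", patientIds = ids,
      definition = data.frame(
        rule = sprintf("interval:%s[%g,%g]", measurement, lo, hi),
        stringsAsFactors = FALSE))
}

# Per-patient reduced values of one measurement.
patientMeasurementValues <- function(patients, measurement,
                                     reduce = c("median", "last")) {
  reduce <- match.arg(reduce)
  m <- patientMeasurements(patients)
  m <- m[m$name == measurement, , drop = FALSE]
  if (!nrow(m)) return(stats::setNames(numeric(), character()))
  f <- if (reduce == "median") stats::median else function(x) x[length(x)]
  vapply(split(m$value, m$patient_id), f, numeric(1))
}

#' Standard BMI cohorts
#'
#' Splits patients into the four weight-class cohorts using the boundary
#' values <18, 18-24.5, 24.6-29.5 and >29.6 (BMI in kg m^-2 recorded to one
#' decimal), i.e. the closed intervals [-Inf, 17.9], [18, 24.5],
#' [24.6, 29.5], [29.6, Inf], which partition any one-decimal BMI column.
#'
#' @param patients a \linkS4class{PatientSet}.
#' @param measurement measurement name, default "BMI".
#' @param reduce per-patient reduction, see
#'   \code{\link{selectCohortByInterval}}.
#' @return named list of four \linkS4class{Cohort}s
#'   (underweight, normal, overweight, obese).
#' @export
bmiCohorts <- function(patients, measurement = "BMI",
                       reduce = c("median", "last")) {
  reduce <- match.arg(reduce)
  bounds <- list(
    underweight = c(-Inf, 17.9),
    normal = c(18, 24.5),
    overweight = c(24.6, 29.5),
    obese = c(29.6, Inf)
  )
  lapply(bounds, function(b)
    selectCohortByInterval(patients, measurement, b[1], b[2], reduce = reduce))
}

#' Cohort SEP weights
#'
#' weight(SEP_i) = proportion of cohort patients whose record contains SEP_i.
#' Weights lie in [0, 1] and are not required to sum to 1; normalisation
#' happens when the restart distribution is built.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param patients the \linkS4class{PatientSet} the cohort was drawn from.
#' @return named numeric vector over the SEP universe (names are node keys).
#' @export
sepWeights <- function(cohort, patients) {
  ids <- patientIds(cohort)
  recs <- patientRecords(patients)[ids]
  if (!length(ids) || any(!ids %in% patientIds(patients)))
    stop("cohort must be a nonempty subset of known patients")
  uni <- sepUniverse(patients)
  counts <- tabulate(match(unlist(recs, use.names = FALSE), uni),
                     nbins = length(uni))
  stats::setNames(counts / length(ids), nodeKeys(patients)[uni])
}
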