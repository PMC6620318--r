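#' Configuration of the synthetic knowledge graph / patient generator
#'
#' The defaults are the study conditions used throughout the package's
#' benchmark: 5 diseases, 200 genes, 60 other nodes (15 each of anatomy,
#' symptom, compound, pathway), 1000 patients and SEP co-occurrence strength
#' theta = 0.8. Each disease is planted with well-established association
#' edges (kAssoc per disease) that are strongly supported by redundant
#' indirect routes (its compounds bind and its anatomies express the
#' associated genes with probability redundancyAssoc), and with noisier
#' regulation edges (kReg per disease) whose indirect support is much weaker
#' (redundancyReg), so that held-out edges of the first stratum are easier
#' to re-infer than the second.
#'
#' @param nDiseases,nGenes,nAnatomy,nSymptoms,nCompounds,nPathways node
#'   counts per type.
#' @param kAssoc,kReg ranges (integer vectors) of planted association /
#'   regulation edges per disease.
#' @param neighborhood number of anatomy, symptom and compound nodes wired
#'   to each disease.
#' @param redundancyAssoc,redundancyReg probability that a planted edge of
#'   the stratum gains each indirect route (compound binding, anatomy
#'   expression, shared pathway).
#' @param bgExpressPerAnatomy,bgBindPerCompound,nGeneGene background edge
#'   counts (noise routes unrelated to the planted structure).
#' @param nPatients number of synthetic patients.
#' @param theta probability that a patient record slot carries the true
#'   disease-adjacent SEP rather than a random SEP; theta = 0 gives
#'   structure-free records.
#' @param noiseRate Poisson mean of extra random SEP codes per patient.
#' @param bmiMean,bmiSd,bmiShift BMI-like covariate: baseline mean/sd and
#'   the mean shift applied to carriers of the first disease; values are
#'   recorded to one decimal.
#' @param seed default generator seed.
#' @return a list of class \code{synthConfig}.
#' @export
synthConfig <- function(nDiseases = 5L, nGenes = 200L, nAnatomy = 15L,
                        nSymptoms = 15L, nCompounds = 15L, nPathways = 15L,
                        kAssoc = 4:8, kReg = 3:6, neighborhood = 3L,
                        redundancyAssoc = 0.9, redundancyReg = 0.25,
                        bgExpressPerAnatomy = 8L, bgBindPerCompound = 3L,
                        nGeneGene = 150L, nPatients = 1000L, theta = 0.8,
                        noiseRate = 1, bmiMean = 24, bmiSd = 3,
                        bmiShift = 8, seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$redundancyAssoc, cfg$redundancyReg, cfg$theta)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$nDiseases >= 1, cfg$nGenes >= 1, cfg$nPatients >= 1)
  class(cfg) <- "synthConfig"
  cfg
}

#' Generate a synthetic typed knowledge graph with planted structure
#'
#' Emulates a SPOKE-like multityped network at toy scale: diseases are wired
#' to anatomy (LOCALIZES_DlA), symptoms (PRESENTS_DpS) and treating
#' compounds (TREATS_CtD); planted disease-gene edges come in a
#' well-established stratum (ASSOCIATES_DaG) and a noisy stratum
#' (UPREGULATES_DuG); redundant indirect routes (compound-BINDS_CbG-gene,
#' anatomy-EXPRESSES_AeG-gene, shared PARTICIPATES_GpP pathways, and
#' INTERACTS_GiG gene interactions) keep deleted direct edges inferable.
#' Diseases sharing a planted gene are linked by RESEMBLES_DrD.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @param seed integer seed; defaults to \code{cfg$seed}.
#' @return list: \code{graph} (a \linkS4class{HeteroGraph}) and
#'   \code{manifest} (planted edge table with stratum labels, per-disease
#'   K, and the per-disease neighborhood nodes).
#' @export
generateGraph <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthConfig"))
  dis <- sprintf("D%02d", seq_len(cfg$nDiseases))
  gen <- sprintf("G%03d", seq_len(cfg$nGenes))
  ana <- sprintf("A%02d", seq_len(cfg$nAnatomy))
  sym <- sprintf("S%02d", seq_len(cfg$nSymptoms))
  cmp <- sprintf("C%02d", seq_len(cfg$nCompounds))
  pwy <- sprintf("P%02d", seq_len(cfg$nPathways))
  e <- function(sid, sty, ety, tid, tty)
    data.frame(source_id = sid, source_type = sty, edge_type = ety,
               target_id = tid, target_type = tty, stringsAsFactors = FALSE)
  edges <- list()
  manifest <- list()
  withSeed(seed, {
    hood <- lapply(seq_along(dis), function(i) list(
      anatomy = sample(ana, min(cfg$neighborhood, length(ana))),
      symptoms = sample(sym, min(cfg$neighborhood, length(sym))),
      compounds = sample(cmp, min(cfg$neighborhood, length(cmp)))
    ))
    names(hood) <- dis
    planted <- list()
    for (i in seq_along(dis)) {
      d <- dis[i]
      h <- hood[[d]]
      edges[[length(edges) + 1L]] <- e(d, "Disease", "LOCALIZES_DlA",
                                       h$anatomy, "Anatomy")
      edges[[length(edges) + 1L]] <- e(d, "Disease", "PRESENTS_DpS",
                                       h$symptoms, "Symptom")
      edges[[length(edges) + 1L]] <- e(h$compounds, "Compound", "TREATS_CtD",
                                       d, "Disease")
      kA <- if (length(cfg$kAssoc) > 1L) sample(cfg$kAssoc, 1L) else cfg$kAssoc
      kR <- if (length(cfg$kReg) > 1L) sample(cfg$kReg, 1L) else cfg$kReg
      gAssoc <- sample(gen, kA)
      gReg <- sample(setdiff(gen, gAssoc), kR)
      planted[[d]] <- data.frame(
        disease = d, gene = c(gAssoc, gReg),
        type = rep(c("ASSOCIATES_DaG", "UPREGULATES_DuG"), c(kA, kR)),
        stringsAsFactors = FALSE)
      edges[[length(edges) + 1L]] <- e(d, "Disease", "ASSOCIATES_DaG",
                                       gAssoc, "Gene")
      edges[[length(edges) + 1L]] <- e(d, "Disease", "UPREGULATES_DuG",
                                       gReg, "Gene")
      # redundant indirect routes, strong for the associates stratum
      for (spec in list(list(g = gAssoc, p = cfg$redundancyAssoc),
                        list(g = gReg, p = cfg$redundancyReg))) {
        for (g in spec$g) {
          if (stats::runif(1) < spec$p)
            edges[[length(edges) + 1L]] <- e(sample(h$compounds, 1L),
                                             "Compound", "BINDS_CbG",
                                             g, "Gene")
          if (stats::runif(1) < spec$p)
            edges[[length(edges) + 1L]] <- e(sample(h$anatomy, 1L),
                                             "Anatomy", "EXPRESSES_AeG",
                                             g, "Gene")
          if (stats::runif(1) < spec$p)
            edges[[length(edges) + 1L]] <- e(g, "Gene", "PARTICIPATES_GpP",
                                             pwy[(i - 1L) %% length(pwy) + 1L],
                                             "Pathway")
        }
      }
    }
    plantedAll <- do.call(rbind, planted)
    # resemblance edges between diseases sharing a planted gene
    if (length(dis) > 1L) {
      pairs <- utils::combn(dis, 2L)
      share <- apply(pairs, 2L, function(pr) {
        length(intersect(plantedAll$gene[plantedAll$disease == pr[1]],
                         plantedAll$gene[plantedAll$disease == pr[2]])) > 0
      })
      # guarantee a nonempty DrD stratum even with disjoint gene sets
      if (!any(share)) share[sample.int(ncol(pairs), 1L)] <- TRUE
      for (j in which(share))
        edges[[length(edges) + 1L]] <- e(pairs[1, j], "Disease",
                                         "RESEMBLES_DrD",
                                         pairs[2, j], "Disease")
    }
    # background noise routes
    for (a in ana)
      edges[[length(edges) + 1L]] <- e(a, "Anatomy", "EXPRESSES_AeG",
                                       sample(gen, cfg$bgExpressPerAnatomy),
                                       "Gene")
    for (cc in cmp)
      edges[[length(edges) + 1L]] <- e(cc, "Compound", "BINDS_CbG",
                                       sample(gen, cfg$bgBindPerCompound),
                                       "Gene")
    gg <- matrix(gen[sample.int(length(gen), 2L * cfg$nGeneGene,
                                replace = TRUE)], ncol = 2L)
    gg <- gg[gg[, 1] != gg[, 2], , drop = FALSE]
    edges[[length(edges) + 1L]] <- e(gg[, 1], "Gene", "INTERACTS_GiG",
                                     gg[, 2], "Gene")
    member <- stats::runif(length(gen)) < 0.3
    if (any(member))
      edges[[length(edges) + 1L]] <- e(gen[member], "Gene",
                                       "PARTICIPATES_GpP",
                                       sample(pwy, sum(member),
                                              replace = TRUE), "Pathway")
    manifest <- list(
      planted = plantedAll,
      K = vapply(dis, function(d)
        sum(plantedAll$disease == d &
              plantedAll$type == "ASSOCIATES_DaG"), integer(1)),
      neighborhoods = hood,
      diseases = dis
    )
  })
  nodes <- data.frame(
    id = c(dis, gen, ana, sym, cmp, pwy),
    type = rep(c("Disease", "Gene", "Anatomy", "Symptom", "Compound",
                 "Pathway"),
               c(length(dis), length(gen), length(ana), length(sym),
                 length(cmp), length(pwy))),
    stringsAsFactors = FALSE
  )
  g <- suppressMessages(heteroGraph(nodes = nodes,
                                    edges = do.call(rbind, edges)))
  list(graph = g, manifest = manifest)
}

#' Generate synthetic patient records for a generated graph
#'
#' Each patient is assigned one disease uniformly at random. Their record is
#' built from "slots": the diagnosis itself plus the disease's symptom and
#' compound neighborhood; each slot independently yields its true node with
#' probability theta and a uniformly random SEP-eligible node (any disease,
#' symptom or compound) otherwise, plus Poisson(noiseRate) extra random
#' codes. At theta = 1 every record is exactly the disease neighborhood; at
#' theta = 0 records carry no information about the assigned disease. A
#' BMI-like measurement (one decimal) is drawn for every patient, with its
#' mean shifted for carriers of the first disease.
#'
#' @param graph,manifest output of \code{\link{generateGraph}}.
#' @param cfg the same \code{\link{synthConfig}}.
#' @param seed integer seed; defaults to \code{cfg$seed + 1}.
#' @return list: \code{patients} (a \linkS4class{PatientSet}),
#'   \code{assignment} (data.frame patient_id, disease key) and
#'   \code{conceptMap} (data.frame code, node_type, node_id covering every
#'   SEP-eligible node).
#' @export
generatePatients <- function(graph, manifest, cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "synthConfig"))
  nd <- nodeTable(graph)
  sepEligible <- which(nd$type %in% c("Disease", "Symptom", "Compound"))
  keys <- nodeKeys(graph)
  dis <- manifest$diseases
  disIdx <- match(paste0("Disease:", dis), keys)
  ids <- sprintf("P%04d", seq_len(cfg$nPatients))
  records <- vector("list", cfg$nPatients)
  assign <- character(cfg$nPatients)
  bmi <- numeric(cfg$nPatients)
  withSeed(seed, {
    for (p in seq_len(cfg$nPatients)) {
      d <- sample.int(length(dis), 1L)
      assign[p] <- keys[disIdx[d]]
      h <- manifest$neighborhoods[[dis[d]]]
      slots <- c(disIdx[d],
                 match(paste0("Symptom:", h$symptoms), keys),
                 match(paste0("Compound:", h$compounds), keys))
      take <- stats::runif(length(slots)) < cfg$theta
      rec <- slots
      nRand <- sum(!take) + stats::rpois(1L, cfg$noiseRate)
      rec <- c(slots[take],
               sepEligible[sample.int(length(sepEligible), nRand,
                                      replace = TRUE)])
      records[[p]] <- unique(rec)
      shift <- if (d == 1L) cfg$bmiShift else 0
      bmi[p] <- round(stats::rnorm(1L, cfg$bmiMean + shift, cfg$bmiSd), 1L)
    }
  })
  names(records) <- ids
  meas <- data.frame(patient_id = ids, name = "BMI", value = bmi,
                     stringsAsFactors = FALSE)
  patients <- patientSet(records, measurements = meas, graph = graph)
  cmap <- data.frame(
    code = paste0("code_", nd$id[sepEligible]),
    node_type = nd$type[sepEligible],
    node_id = nd$id[sepEligible],
    stringsAsFactors = FALSE
  )
  list(patients = patients,
       assignment = data.frame(patient_id = ids, disease = assign,
                               stringsAsFactors = FALSE),
       conceptMap = cmap)
}

#' Cohorts from the generator's patient-disease assignment
#'
#' One cohort per planted disease, taken from the manifest assignment (exact
#' membership regardless of how noisy the records are).
#'
#' @param assignment data.frame from \code{\link{generatePatients}}.
#' @return named list of \linkS4class{Cohort}s, names = disease node keys.
#' @export
cohortsFromAssignment <- function(assignment) {
  sp <- split(assignment$patient_id, assignment$disease)
  lapply(sp, function(ids)
    new("Cohort", patientIds = ids,
        definition = data.frame(rule = "manifest-assignment",
                                stringsAsFactors = FALSE)))
}

#' Write a synthetic fixture to TSV files
#'
#' Emits the same plain-text formats the pipeline consumes: the edge list,
#' the concept map, and diagnosis / medication / lab patient tables (the lab
#' table carries the BMI measurements).
#'
#' @param graph,patients,conceptMap generator outputs.
#' @param dir output directory (created if needed).
#' @return named character vector of the written file paths.
#' @export
writeSynthFixture <- function(graph, patients, conceptMap, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(edges = file.path(dir, "edges.tsv"),
             nodes = file.path(dir, "nodes.tsv"),
             concept_map = file.path(dir, "concept_map.tsv"),
             diagnoses = file.path(dir, "diagnoses.tsv"),
             medications = file.path(dir, "medications.tsv"),
             labs = file.path(dir, "labs.tsv"))
  writeEdgeList(graph, paths[["edges"]], nodesPath = paths[["nodes"]])
  utils::write.table(conceptMap, paths[["concept_map"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nd <- nodeTable(graph)
  recs <- patientRecords(patients)
  long <- data.frame(
    patient_id = rep(names(recs), lengths(recs)),
    node = unlist(recs, use.names = FALSE), stringsAsFactors = FALSE)
  long$type <- nd$type[long$node]
  long$code <- paste0("code_", nd$id[long$node])
  wr <- function(rows, path, withValue = FALSE) {
    tab <- data.frame(patient_id = rows$patient_id, code = rows$code,
                      stringsAsFactors = FALSE)
    if (withValue) tab$value <- rows$value
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(long[long$type == "Disease", ], paths[["diagnoses"]])
  wr(long[long$type == "Compound", ], paths[["medications"]])
  labRows <- long[long$type == "Symptom", c("patient_id", "code")]
  labRows$value <- NA_real_
  m <- patientMeasurements(patients)
  if (nrow(m))
    labRows <- rbind(labRows,
                     data.frame(patient_id = m$patient_id, code = m$name,
                                value = m$value, stringsAsFactors = FALSE))
  wr(labRows, paths[["labs"]], withValue = TRUE)
  paths
}
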