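## Synthetic patient cohorts: the fixture generator emulating a transplant
## clinic's RDF database.  Each patient carries creatinine and BUN
## time-courses; a controllable fraction is generated with an increasing
## creatinine trend.  Ground truth is emitted per patient: the intended
## label (which generating slope was used) and the oracle label (the sign
## of an independent OLS fit — stats::lm, not the package's own olsFit —
## on the realized, serialized-then-parsed values).  The oracle label is
## what the engine must reproduce; defining truth on realized data keeps
## noisy borderline cases exactly checkable.

#' Cohort specification
#'
#' Defaults describe the study conditions used throughout: a small clinic
#' cohort on a mg/dL creatinine scale (baseline 1.0), weekly measurements,
#' five per analyte, 40 percent of patients trending upward at
#' +0.05 mg/dL/day against -0.02 for the rest, with 0.05 mg/dL measurement
#' noise.
#'
#' @param nPatients,fractionRejecter,nTimepoints,intervalDays,baseCreatinine
#'   see \code{\linkS4class{CohortSpec}}.
#' @param slopeRejecter,slopeNon,noiseSd,seed see
#'   \code{\linkS4class{CohortSpec}}.
#' @return a validated \code{CohortSpec}.
#' @export
cohortSpec <- function(nPatients = 10, fractionRejecter = 0.4,
                       nTimepoints = 5, intervalDays = 7,
                       baseCreatinine = 1.0, slopeRejecter = 0.05,
                       slopeNon = -0.02, noiseSd = 0.05, seed = 1) {
  new("CohortSpec", nPatients = nPatients,
      fractionRejecter = fractionRejecter, nTimepoints = nTimepoints,
      intervalDays = intervalDays, baseCreatinine = baseCreatinine,
      slopeRejecter = slopeRejecter, slopeNon = slopeNon, noiseSd = noiseSd,
      seed = seed)
}

## BUN side of the generator (not dials of the study design: BUN is payload
## for the latest-value service, uncorrelated with the creatinine trend)
.BUN_BASE <- 15
.BUN_SLOPE_SD <- 0.01
.BUN_NOISE_FACTOR <- 10

#' Closed-form triple count of a generated cohort
#'
#' Per patient: one type triple, two collection links, two collection type
#' triples, and per measurement (2 analytes x nTimepoints) a link, a type
#' and two value literals — 5 + 8 * nTimepoints.
#'
#' @param spec a \code{CohortSpec}.
#' @return integer.
#' @export
cohortTripleCount <- function(spec) {
  spec@nPatients * (5 + 8 * spec@nTimepoints)
}

#' Generate a synthetic cohort
#'
#' Deterministic under the spec's seed; each patient uses a dedicated
#' pseudo-random stream (seed + patient index), so enlarging a cohort never
#' shifts earlier patients.  Creatinine series:
#' \code{y_t = base + slope * x_t + N(0, noiseSd^2)} with the rejecter slope
#' for the first \code{round(nPatients * fractionRejecter)} patients; BUN
#' analogous around its own baseline with a small random per-patient slope.
#' The graph is typed per the demo ontology; ground truth is computed by
#' the independent OLS oracle on the values as serialized.
#'
#' @param spec a \code{CohortSpec}.
#' @return list with elements \code{graph} (\code{RDFGraph}) and
#'   \code{truth} (data.frame with columns \code{patient}, \code{intended},
#'   \code{oracle}; labels are \code{"rejecter"}/\code{"non"}).
#' @examples
#' cohort <- generateCohort(cohortSpec(nPatients = 4, noiseSd = 0))
#' graphSize(cohort$graph)
#' table(cohort$truth$intended)
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  v <- demoVocabulary()
  n <- spec@nPatients
  nRej <- round(n * spec@fractionRejecter)
  x <- (seq_len(spec@nTimepoints) - 1) * spec@intervalDays

  rows <- list()
  emit <- function(s, p, o, ot, dt = NA_character_)
    rows[[length(rows) + 1L]] <<- data.frame(s = s, p = p, o = o, ot = ot,
                                             dt = dt, stringsAsFactors = FALSE)
  truth <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("p%03d", i)
    patient <- paste0(DEMO_DATA, pid)
    intended <- if (i <= nRej) "rejecter" else "non"
    genSlope <- if (intended == "rejecter") spec@slopeRejecter else
      spec@slopeNon
    set.seed(spec@seed + i) # dedicated per-patient stream
    creatNoise <- stats::rnorm(spec@nTimepoints, 0, spec@noiseSd)
    bunSlope <- stats::rnorm(1, 0, .BUN_SLOPE_SD)
    bunNoise <- stats::rnorm(spec@nTimepoints, 0,
                             spec@noiseSd * .BUN_NOISE_FACTOR)
    creatY <- spec@baseCreatinine + genSlope * x + creatNoise
    bunY <- .BUN_BASE + bunSlope * x + bunNoise

    emit(patient, RDF_TYPE, v$Patient, "iri")
    seriesFor <- list(creatinine = creatY, bun = bunY)
    yAsStored <- list()
    for (analyte in names(seriesFor)) {
      coll <- paste0(patient, "/", analyte)
      linkProp <- if (analyte == "creatinine") v$hasCreatinineCollection else
        v$hasBUNCollection
      emit(patient, linkProp, coll, "iri")
      emit(coll, RDF_TYPE, v$BloodChemistryTimeCourse, "iri")
      lex <- decimalLexical(seriesFor[[analyte]])
      yAsStored[[analyte]] <- as.numeric(lex)
      for (t in seq_len(spec@nTimepoints)) {
        m <- sprintf("%s/m%02d", coll, t)
        emit(coll, v$hasMeasurement, m, "iri")
        emit(m, RDF_TYPE, v$Measurement, "iri")
        emit(m, v$hasXValue, decimalLexical(x[t]), "lit", XSD_DECIMAL)
        emit(m, v$hasYValue, lex[t], "lit", XSD_DECIMAL)
      }
    }
    ## independent oracle on the values exactly as stored in the graph
    fit <- stats::lm(y ~ x, data = data.frame(x = x,
                                              y = yAsStored$creatinine))
    oracleSlope <- unname(stats::coef(fit)[["x"]])
    truth[[i]] <- data.frame(
      patient = patient, intended = intended,
      oracle = if (oracleSlope > 0) "rejecter" else "non",
      oracleSlope = oracleSlope, stringsAsFactors = FALSE)
  }
  graph <- if (length(rows)) .makeGraph(do.call(rbind, rows)) else emptyGraph()
  truthDf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(patient = character(), intended = character(),
               oracle = character(), oracleSlope = numeric(),
               stringsAsFactors = FALSE)
  rownames(truthDf) <- NULL
  list(graph = graph, truth = truthDf)
}

.demoPrefixes <- function() {
  c(STANDARD_PREFIXES, pat = DEMO_PAT, pred = DEMO_PRED, data = DEMO_DATA)
}

#' Write a cohort fixture to disk
#'
#' Layout: \code{cohort.ttl} (the graph, canonical Turtle), \code{truth.csv}
#' (patient IRI, intended and oracle labels, oracle slope) and
#' \code{spec.yaml} (echo of the generating parameters).  Reloading with
#' \code{\link{readCohortFixture}} reproduces graph and truth exactly; the
#' same spec always produces byte-identical files.
#'
#' @param cohort list as returned by \code{\link{generateCohort}}.
#' @param dir output directory (created if needed).
#' @param spec optional \code{CohortSpec} to echo into \code{spec.yaml}.
#' @return invisibly, the directory path.
#' @export
writeCohortFixture <- function(cohort, dir, spec = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeTurtle(cohort$graph, file.path(dir, "cohort.ttl"),
              prefixes = .demoPrefixes())
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = TRUE)
  if (!is.null(spec)) {
    fields <- c("nPatients", "fractionRejecter", "nTimepoints",
                "intervalDays", "baseCreatinine", "slopeRejecter",
                "slopeNon", "noiseSd", "seed")
    yaml::write_yaml(setNames(lapply(fields, function(f) slot(spec, f)),
                              fields),
                     file.path(dir, "spec.yaml"))
  }
  invisible(dir)
}

#' Read a cohort fixture from disk
#'
#' @param dir fixture directory written by \code{\link{writeCohortFixture}}.
#' @return list with \code{graph}, \code{truth} and (when present)
#'   \code{spec}.
#' @export
readCohortFixture <- function(dir) {
  out <- list(
    graph = loadGraph(file.path(dir, "cohort.ttl")),
    truth = utils::read.csv(file.path(dir, "truth.csv"),
                            stringsAsFactors = FALSE))
  specPath <- file.path(dir, "spec.yaml")
  if (file.exists(specPath)) {
    fields <- yaml::read_yaml(specPath)
    out$spec <- do.call(cohortSpec, fields)
  }
  out
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d patient(s), %.0f%% rejecters, %d timepoints every %g d, noise sd %g, seed %d\n",
    object@nPatients, 100 * object@fractionRejecter, object@nTimepoints,
    object@intervalDays, object@noiseSd, object@seed))
})
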