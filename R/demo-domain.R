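## The clinical worked example: a transplant-clinic ontology (patients,
## blood-chemistry time-courses, regression models, the Likely Rejecter
## cascade) and the three demo annotation services.  The Likely Rejecter
## class is deliberately a *hypothesis* encoded as an ontology class — a
## patient whose creatinine time-course has an increasing linear-regression
## model — not a clinically validated definition.

DEMO_PAT  <- "http://sadi-share.example.org/ontologies/patients.owl#"
DEMO_PRED <- "http://sadi-share.example.org/ontologies/predicates.owl#"
DEMO_DATA <- "http://sadi-share.example.org/data/patients/"
DEMO_DOC  <- "http://sadi-share.example.org/data/patients.rdf"
DEMO_SVC  <- "http://sadi-share.example.org/services/"

#' Demo vocabulary
#'
#' Named list of every IRI of the worked example: namespaces, classes,
#' properties, services and the data-document IRI.
#'
#' @return named list of IRI strings.
#' @export
demoVocabulary <- function() {
  list(
    nsPatients = DEMO_PAT, nsPredicates = DEMO_PRED, nsData = DEMO_DATA,
    document = DEMO_DOC,
    Patient = paste0(DEMO_PAT, "Patient"),
    Measurement = paste0(DEMO_PAT, "Measurement"),
    MeasurementCollection = paste0(DEMO_PAT, "MeasurementCollection"),
    BloodChemistryTimeCourse = paste0(DEMO_PAT, "BloodChemistryTimeCourse"),
    XYCoordinateData = paste0(DEMO_PAT, "XYCoordinateData"),
    LinearRegressionModel = paste0(DEMO_PAT, "LinearRegressionModel"),
    LikelyRejecter = paste0(DEMO_PAT, "LikelyRejecter"),
    ElevatedLevels = paste0(DEMO_PAT, "ElevatedLevels"),
    IncreasingModel = paste0(DEMO_PAT, "IncreasingModel"),
    hasCreatinineCollection = paste0(DEMO_PAT, "hasCreatinineCollection"),
    hasBUNCollection = paste0(DEMO_PAT, "hasBUNCollection"),
    hasMeasurement = paste0(DEMO_PAT, "hasMeasurement"),
    hasXValue = paste0(DEMO_PAT, "hasXValue"),
    hasYValue = paste0(DEMO_PAT, "hasYValue"),
    hasRegressionModel = paste0(DEMO_PRED, "hasRegressionModel"),
    slope = paste0(DEMO_PRED, "slope"),
    intercept = paste0(DEMO_PRED, "intercept"),
    latestCreatinine = paste0(DEMO_PRED, "latestCreatinine"),
    latestBUN = paste0(DEMO_PRED, "latestBUN"),
    latestMeasurement = paste0(DEMO_PRED, "latestMeasurement"),
    RegressionAnnotatedData = paste0(DEMO_PRED, "RegressionAnnotatedData"),
    PatientWithCreatinineSeries = paste0(DEMO_PRED, "PatientWithCreatinineSeries"),
    PatientWithLatestCreatinine = paste0(DEMO_PRED, "PatientWithLatestCreatinine"),
    PatientWithBUNSeries = paste0(DEMO_PRED, "PatientWithBUNSeries"),
    PatientWithLatestBUN = paste0(DEMO_PRED, "PatientWithLatestBUN"),
    regressionService = paste0(DEMO_SVC, "linear-regression"),
    latestCreatinineService = paste0(DEMO_SVC, "latest-creatinine"),
    latestBUNService = paste0(DEMO_SVC, "latest-bun")
  )
}

#' The demo ontology
#'
#' Loads the shipped Turtle document defining the cascade
#' LikelyRejecter == Patient and (hasCreatinineCollection some
#' ElevatedLevels); ElevatedLevels == MeasurementCollection and
#' (hasRegressionModel some IncreasingModel); IncreasingModel ==
#' LinearRegressionModel and (slope some decimal > 0) — "increasing" is
#' read strictly, so a zero-slope model is NOT increasing — plus the
#' subclass axiom making a blood-chemistry time-course a specialized type
#' of X-Y coordinate data, and the service input/output classes.
#'
#' @return an \code{\linkS4class{Ontology}}.
#' @export
demoOntology <- function() {
  ontologyFromGraph(demoOntologyGraph())
}

#' @rdname demoOntology
#' @export
demoOntologyGraph <- function() {
  path <- system.file("extdata", "patients-ontology.ttl",
                      package = "sadishare", mustWork = TRUE)
  loadGraph(path, blankNodes = "skolemize")
}

## measurement series of one collection node: data.frame(x, y, m, ylex, ydt)
.collectionSeries <- function(g, coll) {
  v <- demoVocabulary()
  df <- g@triples
  ms <- df$o[df$s == coll & df$p == v$hasMeasurement & df$ot == "iri"]
  if (length(ms) == 0L)
    return(data.frame(x = numeric(), y = numeric(), m = character(),
                      ylex = character(), ydt = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(sort(ms), function(m) {
    xr <- df[df$s == m & df$p == v$hasXValue & df$ot == "lit", , drop = FALSE]
    yr <- df[df$s == m & df$p == v$hasYValue & df$ot == "lit", , drop = FALSE]
    if (nrow(xr) == 0L || nrow(yr) == 0L) return(NULL)
    data.frame(x = .literalNumeric(xr$o[1L], xr$dt[1L]),
               y = .literalNumeric(yr$o[1L], yr$dt[1L]),
               m = m, ylex = yr$o[1L], ydt = yr$dt[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) out <- data.frame(x = numeric(), y = numeric(),
                                      m = character(), ylex = character(),
                                      ydt = character(),
                                      stringsAsFactors = FALSE)
  out
}

#' The linear-regression annotation service
#'
#' Consumes X-Y coordinate data (any measurement collection; the ontology
#' makes a blood-chemistry time-course a specialized type of X-Y coordinate
#' data), fits an ordinary-least-squares line to the collection's
#' measurements, and attaches a regression-model node carrying slope and
#' intercept to the *same* collection URI.  The model node IRI is a
#' deterministic function of the collection IRI, so repeated runs mint the
#' same node.
#'
#' @return a \code{\linkS4class{ServiceDescription}}.
#' @export
regressionService <- function() {
  v <- demoVocabulary()
  impl <- function(g, subject) {
    series <- .collectionSeries(g, subject)
    model <- olsFit(series$x, series$y) # not-fittable propagates as failure
    node <- paste0(subject, "/regression-model")
    out <- emptyGraph()
    out <- addTriple(out, subject, v$hasRegressionModel, node)
    out <- addTriple(out, node, RDF_TYPE, v$LinearRegressionModel)
    out <- addTriple(out, node, v$slope, rdfLiteral(slope(model)))
    out <- addTriple(out, node, v$intercept, rdfLiteral(intercept(model)))
    out
  }
  serviceDescription(
    iri = v$regressionService, name = "linear-regression",
    inputClass = v$XYCoordinateData,
    outputClass = v$RegressionAnnotatedData,
    implementation = impl)
}

#' Latest-measurement annotation services
#'
#' Consume a patient with at least one measurement of the analyte and
#' attach the \code{latestCreatinine} / \code{latestBUN} literal: the y
#' value of the maximum-x measurement, ties broken by lexicographically
#' greatest measurement IRI (deterministic; "latest" has no other
#' operational definition in the domain).
#'
#' @param analyte \code{"creatinine"} or \code{"BUN"}.
#' @return a \code{\linkS4class{ServiceDescription}}.
#' @export
latestValueService <- function(analyte = c("creatinine", "BUN")) {
  analyte <- match.arg(analyte)
  v <- demoVocabulary()
  collProp <- if (analyte == "creatinine") v$hasCreatinineCollection else
    v$hasBUNCollection
  target <- if (analyte == "creatinine") v$latestCreatinine else v$latestBUN
  svcIri <- if (analyte == "creatinine") v$latestCreatinineService else
    v$latestBUNService
  inCls <- if (analyte == "creatinine") v$PatientWithCreatinineSeries else
    v$PatientWithBUNSeries
  outCls <- if (analyte == "creatinine") v$PatientWithLatestCreatinine else
    v$PatientWithLatestBUN
  impl <- function(g, subject) {
    df <- g@triples
    colls <- df$o[df$s == subject & df$p == collProp & df$ot == "iri"]
    series <- do.call(rbind, lapply(sort(colls), .collectionSeries, g = g))
    if (is.null(series) || nrow(series) == 0L)
      stop("patient has no measurements of ", analyte, call. = FALSE)
    ## max x; ties by lexicographically greatest measurement IRI
    best <- series[order(-series$x, series$m, method = "radix",
                         decreasing = c(FALSE, TRUE)), , drop = FALSE][1L, ]
    addTriple(emptyGraph(), subject, target,
              new("Literal", lexical = best$ylex, datatype = best$ydt))
  }
  serviceDescription(iri = svcIri, name = paste0("latest-", tolower(analyte)),
                     inputClass = inCls, outputClass = outCls,
                     implementation = impl)
}

#' A deliberately broken service (negative control)
#'
#' Mints a brand-new subject URI instead of annotating its input subject,
#' violating the same-URI contract; \code{\link{validateContract}} must
#' flag it.  Used in tests and never registered in the demo registry.
#'
#' @return a \code{\linkS4class{ServiceDescription}}.
#' @export
misbehavingDemoService <- function() {
  impl <- function(g, subject) {
    stray <- paste0(DEMO_DATA, "not-the-input-subject")
    addTriple(emptyGraph(), stray, paste0(DEMO_PRED, "bogus"),
              rdfLiteral("oops"))
  }
  serviceDescription(
    iri = paste0(DEMO_SVC, "broken-annotator"), name = "broken-annotator",
    inputClass = OWL_THING, outputClass = OWL_THING, implementation = impl)
}

#' The demo registry
#'
#' The three worked-example services (linear regression, latest creatinine,
#' latest BUN) registered against the demo ontology.
#'
#' @param ont ontology to index against (default \code{\link{demoOntology}}).
#' @return a \code{\linkS4class{ServiceRegistry}}.
#' @export
demoRegistry <- function(ont = demoOntology()) {
  r <- serviceRegistry(ont)
  r <- registerService(r, regressionService())
  r <- registerService(r, latestValueService("BUN"))
  r <- registerService(r, latestValueService("creatinine"))
  r
}

#' The worked-example query
#'
#' The clinical query driving the whole demonstration: retrieve the latest
#' blood urea nitrogen and creatinine levels of patients who are likely to
#' be rejecting their kidney transplant.  The triple patterns require the
#' patient to be a \code{LikelyRejecter} — a defined class whose definition
#' acts as an abstract workflow — and to carry the \code{latestBUN} /
#' \code{latestCreatinine} annotations that dedicated services supply.
#'
#' @param from document IRI for the FROM clause (default: the demo cohort
#'   document IRI; resolved locally, never dereferenced).
#' @return SPARQL SELECT text.
#' @export
likelyRejecterQuery <- function(from = DEMO_DOC) {
  paste0(
    "PREFIX rdf: <", RDF_NS, ">\n",
    "PREFIX patients: <", DEMO_PAT, ">\n",
    "PREFIX pred: <", DEMO_PRED, ">\n",
    "SELECT ?patient ?bun ?creat\n",
    "FROM <", from, ">\n",
    "WHERE {\n",
    "?patient rdf:type patients:LikelyRejecter.\n",
    "?patient pred:latestBUN ?bun.\n",
    "?patient pred:latestCreatinine ?creat.\n",
    "}\n")
}
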