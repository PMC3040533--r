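#' @import methods
NULL

## ---------------------------------------------------------------------------
## RDF core
## ---------------------------------------------------------------------------

#' RDFGraph: a set of RDF triples
#'
#' An \code{RDFGraph} holds a finite set of triples (subject, predicate,
#' object) with set semantics: duplicates are removed on construction and
#' merging two graphs is set union.  Subjects and predicates are absolute
#' IRIs; objects are either IRIs or typed literals.  Blank-node subjects are
#' excluded from instance data by design (the same-URI service contract is
#' unverifiable for unnamed nodes); ontology documents may be loaded with
#' blank nodes skolemized to stable \code{urn:bnode:} IRIs.
#'
#' The triple table has columns \code{s}, \code{p}, \code{o} (character),
#' \code{ot} (object type, \code{"iri"} or \code{"lit"}) and \code{dt}
#' (datatype IRI for literals, \code{NA} for IRI objects).
#'
#' @slot triples data.frame with columns \code{s,p,o,ot,dt}.
#' @aliases RDFGraph
#' @exportClass RDFGraph
setClass("RDFGraph", representation(triples = "data.frame"))

.emptyTripleDF <- function() {
  data.frame(s = character(), p = character(), o = character(),
             ot = character(), dt = character(), stringsAsFactors = FALSE)
}

.tripleKeys <- function(df) {
  paste(df$s, df$p, df$ot, df$o, ifelse(is.na(df$dt), "", df$dt), sep = "\r")
}

setValidity("RDFGraph", function(object) {
  df <- object@triples
  need <- c("s", "p", "o", "ot", "dt")
  if (!all(need %in% names(df)))
    return(sprintf("triple table must have columns %s",
                   paste(need, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (!all(isAbsoluteIri(df$s)))
    return("all subjects must be absolute IRIs")
  if (!all(isAbsoluteIri(df$p)))
    return("all predicates must be absolute IRIs")
  if (!all(df$ot %in% c("iri", "lit")))
    return("object type must be 'iri' or 'lit'")
  if (any(df$ot == "iri" & !isAbsoluteIri(df$o)))
    return("IRI objects must be absolute IRIs")
  if (any(df$ot == "lit" & is.na(df$dt)))
    return("literal objects must carry a datatype IRI")
  if (anyDuplicated(.tripleKeys(df)))
    return("duplicate triples (set semantics violated)")
  TRUE
})

#' Literal: a typed RDF literal
#'
#' @slot lexical character lexical form.
#' @slot datatype character datatype IRI (defaults to \code{xsd:string}).
#' @aliases Literal
#' @exportClass Literal
setClass("Literal", representation(lexical = "character",
                                   datatype = "character"))

setValidity("Literal", function(object) {
  if (length(object@lexical) != 1L) return("lexical form must be length 1")
  if (length(object@datatype) != 1L || !isAbsoluteIri(object@datatype))
    return("datatype must be one absolute IRI")
  if (object@datatype %in% XSD_NUMERIC_TYPES &&
      !is.finite(suppressWarnings(as.numeric(object@lexical))))
    return(sprintf("numeric literal '%s' does not parse to a finite number",
                   object@lexical))
  TRUE
})

## ---------------------------------------------------------------------------
## Class-expression algebra (supported OWL-DL fragment)
## ---------------------------------------------------------------------------

#' ClassExpression: algebraic OWL class descriptions
#'
#' The supported positive-existential fragment: named classes, intersections,
#' existential property restrictions (\code{someValuesFrom}), value
#' restrictions (\code{hasValue}) and numeric datatype ranges with XSD facets.
#' Constructs outside the fragment (universal restrictions, cardinality,
#' union, complement) are rejected at parse time, never silently dropped.
#'
#' @aliases ClassExpression
#' @exportClass ClassExpression
setClass("ClassExpression", representation("VIRTUAL"))

#' @rdname ClassExpression-constructors
#' @aliases NamedClass
#' @exportClass NamedClass
setClass("NamedClass", contains = "ClassExpression",
         representation(iri = "character"))
setValidity("NamedClass", function(object) {
  if (length(object@iri) != 1L || !isAbsoluteIri(object@iri))
    return("iri must be one absolute IRI")
  TRUE
})

#' @rdname ClassExpression-constructors
#' @aliases IntersectionOf
#' @exportClass IntersectionOf
setClass("IntersectionOf", contains = "ClassExpression",
         representation(members = "list"))
setValidity("IntersectionOf", function(object) {
  if (length(object@members) == 0L)
    return("empty intersection must be normalized to owl:Thing")
  ok <- vapply(object@members, is, logical(1), class2 = "ClassExpression")
  if (!all(ok)) return("all members must be ClassExpression objects")
  TRUE
})

#' @rdname ClassExpression-constructors
#' @aliases NumericRange
#' @exportClass NumericRange
setClass("NumericRange", representation(datatype = "character",
                                        facets = "numeric"))
setValidity("NumericRange", function(object) {
  if (length(object@datatype) != 1L || !isAbsoluteIri(object@datatype))
    return("datatype must be one absolute IRI")
  allowed <- c("minInclusive", "maxInclusive", "minExclusive", "maxExclusive")
  if (length(object@facets) && !all(names(object@facets) %in% allowed))
    return(sprintf("facet names must be among %s",
                   paste(allowed, collapse = ", ")))
  f <- object@facets
  lo <- suppressWarnings(max(c(f["minInclusive"], f["minExclusive"]), na.rm = TRUE))
  hi <- suppressWarnings(min(c(f["maxInclusive"], f["maxExclusive"]), na.rm = TRUE))
  if (is.finite(lo) && is.finite(hi) && lo > hi)
    return("inconsistent facets: lower bound exceeds upper bound")
  TRUE
})

#' @rdname ClassExpression-constructors
#' @aliases SomeValuesFrom
#' @exportClass SomeValuesFrom
setClass("SomeValuesFrom", contains = "ClassExpression",
         representation(property = "character", filler = "ANY"))
setValidity("SomeValuesFrom", function(object) {
  if (length(object@property) != 1L || !isAbsoluteIri(object@property))
    return("property must be one absolute IRI")
  if (!is(object@filler, "ClassExpression") && !is(object@filler, "NumericRange"))
    return("filler must be a ClassExpression or a NumericRange")
  TRUE
})

#' @rdname ClassExpression-constructors
#' @aliases HasValue
#' @exportClass HasValue
setClass("HasValue", contains = "ClassExpression",
         representation(property = "character", value = "ANY"))
setValidity("HasValue", function(object) {
  if (length(object@property) != 1L || !isAbsoluteIri(object@property))
    return("property must be one absolute IRI")
  v <- object@value
  if (!(is(v, "Literal") || (is.character(v) && length(v) == 1L && isAbsoluteIri(v))))
    return("value must be an IRI string or a Literal")
  TRUE
})

## ---------------------------------------------------------------------------
## Requirements (the "needs" of a class)
## ---------------------------------------------------------------------------

#' Requirement: one conjunct of a decomposed class expression
#'
#' Decomposing a class expression yields a flat list of requirements whose
#' conjunction is logically equivalent to the expression: membership in a
#' named class, or possession of a property whose value satisfies a filler.
#'
#' @aliases Requirement
#' @exportClass Requirement
setClass("Requirement", representation("VIRTUAL"))

#' @rdname Requirement
#' @aliases MembershipReq
#' @exportClass MembershipReq
setClass("MembershipReq", contains = "Requirement",
         representation(classIri = "character"))

#' @rdname Requirement
#' @aliases PropertyReq
#' @exportClass PropertyReq
setClass("PropertyReq", contains = "Requirement",
         representation(property = "character", filler = "ANY"))

## ---------------------------------------------------------------------------
## Ontology
## ---------------------------------------------------------------------------

#' Ontology: definitions plus subclass/subproperty axioms
#'
#' @slot classDefinitions named list, IRI -> \code{ClassExpression}
#'   (equivalence axioms).
#' @slot subclassAxioms data.frame with columns \code{sub}, \code{super}.
#' @slot subpropertyAxioms data.frame with columns \code{sub}, \code{super}.
#' @aliases Ontology
#' @exportClass Ontology
setClass("Ontology", representation(classDefinitions = "list",
                                    subclassAxioms = "data.frame",
                                    subpropertyAxioms = "data.frame"))

.acyclic <- function(edges) {
  ## iteratively strip edges into sinks; TRUE iff no cycle remains
  ## (reflexive self-loops are allowed and ignored)
  edges <- edges[edges$sub != edges$super, , drop = FALSE]
  repeat {
    if (nrow(edges) == 0L) return(TRUE)
    sinks <- setdiff(unique(edges$super), unique(edges$sub))
    drop <- edges$super %in% sinks
    if (!any(drop)) return(FALSE)
    edges <- edges[!drop, , drop = FALSE]
  }
}

setValidity("Ontology", function(object) {
  defs <- object@classDefinitions
  if (length(defs)) {
    if (is.null(names(defs)) || any(!nzchar(names(defs))))
      return("classDefinitions must be a named list keyed by class IRI")
    ok <- vapply(defs, is, logical(1), class2 = "ClassExpression")
    if (!all(ok)) return("all class definitions must be ClassExpression")
  }
  for (slotname in c("subclassAxioms", "subpropertyAxioms")) {
    ax <- slot(object, slotname)
    if (!all(c("sub", "super") %in% names(ax)))
      return(sprintf("%s needs columns sub, super", slotname))
    if (!.acyclic(ax))
      return(sprintf("%s must be acyclic over named terms", slotname))
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Services
## ---------------------------------------------------------------------------

#' ServiceDescription: a typed annotation service
#'
#' A service is described by two OWL classes: individuals of the input class
#' are consumed and the same-URI individuals, now described by the output
#' class, are returned.  The difference between the properties restricted in
#' the output and input classes is the service's advertised contribution
#' (its attached properties).  The implementation is an in-process callable
#' taking \code{(RDFGraph, subject IRI)} and returning the added triples
#' only; the caller merges.
#'
#' @slot iri service identity (absolute IRI).
#' @slot name short human-readable label.
#' @slot inputClass IRI of the input class (resolved against an Ontology).
#' @slot outputClass IRI of the output class.
#' @slot implementation function(graph, subject) -> RDFGraph of added triples.
#' @aliases ServiceDescription
#' @exportClass ServiceDescription
setClass("ServiceDescription",
         representation(iri = "character", name = "character",
                        inputClass = "character", outputClass = "character",
                        implementation = "function"))

setValidity("ServiceDescription", function(object) {
  for (s in c("iri", "inputClass", "outputClass")) {
    v <- slot(object, s)
    if (length(v) != 1L || !isAbsoluteIri(v))
      return(sprintf("%s must be one absolute IRI", s))
  }
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a non-empty string")
  TRUE
})

#' InvocationRecord: provenance of one service invocation
#'
#' @slot service service IRI.
#' @slot inputSubjects subjects the service was asked to annotate.
#' @slot succeeded subjects for which annotation succeeded.
#' @slot skipped subjects rejected for not satisfying the input class.
#' @slot failed named character: subject -> error message.
#' @slot added RDFGraph of added triples (caller merges).
#' @slot timestamp POSIXct invocation time.
#' @aliases InvocationRecord
#' @exportClass InvocationRecord
setClass("InvocationRecord",
         representation(service = "character", inputSubjects = "character",
                        succeeded = "character", skipped = "character",
                        failed = "character", added = "RDFGraph",
                        timestamp = "POSIXct"))

#' ValidationReport: result of checking the service contract
#'
#' @slot service service IRI.
#' @slot violations data.frame with columns \code{type}, \code{subject},
#'   \code{detail}; zero rows means the contract held.
#' @aliases ValidationReport
#' @exportClass ValidationReport
setClass("ValidationReport",
         representation(service = "character", violations = "data.frame"))

## ---------------------------------------------------------------------------
## Registry
## ---------------------------------------------------------------------------

#' ServiceRegistry: an index of service descriptions
#'
#' Services are indexed by their attached properties (and, for discovery by a
#' more general predicate, by the declared superproperties of those).  The
#' index is rebuilt on every mutation so it is always exactly consistent with
#' the registered descriptions.
#'
#' @slot services named list, service IRI -> ServiceDescription.
#' @slot ontology Ontology used for subsumption-aware matching.
#' @slot predicateIndex named list, property IRI -> character vector of
#'   service IRIs.
#' @aliases ServiceRegistry
#' @exportClass ServiceRegistry
setClass("ServiceRegistry",
         representation(services = "list", ontology = "Ontology",
                        predicateIndex = "list"))

## ---------------------------------------------------------------------------
## Planner
## ---------------------------------------------------------------------------

#' Workflow steps
#'
#' A workflow is a DAG of steps: \code{ServiceStep} invokes one registered
#' service for the subjects that still need its attached predicate;
#' \code{ReasonStep} runs the forward-chaining classifier over the whole
#' working graph.
#'
#' @slot label unique step label (used for deterministic linearization).
#' @aliases WorkflowStep
#' @exportClass WorkflowStep
setClass("WorkflowStep", representation("VIRTUAL", label = "character"))

#' @rdname WorkflowStep
#' @slot service IRI of the registered service to invoke.
#' @slot predicate the attached predicate this step supplies.
#' @slot selector ClassExpression the target subjects must satisfy (carrier
#'   classes from the decomposition context), or NULL for no constraint.
#' @slot typeConstraints class IRIs the query binds on the subject variable;
#'   candidates must be entailed members at execution time.
#' @aliases ServiceStep
#' @exportClass ServiceStep
setClass("ServiceStep", contains = "WorkflowStep",
         representation(service = "character", predicate = "character",
                        selector = "ANY", typeConstraints = "character"))

#' @rdname WorkflowStep
#' @aliases ReasonStep
#' @exportClass ReasonStep
setClass("ReasonStep", contains = "WorkflowStep")

#' Workflow: a DAG of service and reasoning steps
#'
#' @slot steps named list of WorkflowStep keyed by label.
#' @slot edges data.frame with columns \code{from}, \code{to} (step labels).
#' @slot coverage data.frame with columns \code{requirement}, \code{context},
#'   \code{resolution}, \code{provider}: how each decomposed requirement will
#'   be satisfied (\code{data}, \code{service}, \code{reasoner} or
#'   \code{UNRESOLVED}).
#' @aliases Workflow
#' @exportClass Workflow
setClass("Workflow", representation(steps = "list", edges = "data.frame",
                                    coverage = "data.frame"))

setValidity("Workflow", function(object) {
  if (length(object@steps)) {
    labs <- vapply(object@steps, function(s) s@label, character(1))
    if (!identical(unname(labs), names(object@steps)))
      return("steps must be keyed by their labels")
  }
  e <- object@edges
  if (!all(c("from", "to") %in% names(e)))
    return("edges needs columns from, to")
  if (nrow(e) && !all(c(e$from, e$to) %in% names(object@steps)))
    return("edges reference unknown step labels")
  if (nrow(e) && !.acyclic(data.frame(sub = e$from, super = e$to)))
    return("workflow edges must be acyclic")
  TRUE
})

#' QueryPlan: a resolved SPARQL query
#'
#' @slot query the SPARQL SELECT text the plan was built for.
#' @slot patterns data.frame with one row per triple pattern: \code{pattern}
#'   (rendered text), \code{resolution} (\code{in-data}, \code{service},
#'   \code{class-plan} or \code{UNRESOLVED}) and \code{provider}.
#' @slot workflow merged Workflow realizing the plan.
#' @aliases QueryPlan
#' @exportClass QueryPlan
setClass("QueryPlan", representation(query = "character",
                                     patterns = "data.frame",
                                     workflow = "Workflow"))

## ---------------------------------------------------------------------------
## Engine
## ---------------------------------------------------------------------------

#' ExecutionTrace: provenance of one plan execution
#'
#' Each round records the step that ran and the triples it added, so the
#' final graph is exactly the initial graph plus the recorded deltas and
#' every added triple is attributable to exactly one step.
#'
#' @slot rounds list of lists with elements \code{label}, \code{kind}
#'   (\code{service} or \code{reasoner}), \code{added} (RDFGraph) and
#'   \code{record} (InvocationRecord or NULL).
#' @slot initialSize triple count before execution.
#' @slot totalAdded total triples added.
#' @slot finalSize triple count after execution.
#' @slot warnings character vector of execution warnings (failed services,
#'   unresolved requirements).
#' @aliases ExecutionTrace
#' @exportClass ExecutionTrace
setClass("ExecutionTrace",
         representation(rounds = "list", initialSize = "numeric",
                        totalAdded = "numeric", finalSize = "numeric",
                        warnings = "character"))

## ---------------------------------------------------------------------------
## Demo domain & synthetic cohorts
## ---------------------------------------------------------------------------

#' LinearRegressionModel: slope and intercept of an OLS fit
#'
#' @slot slope change in analyte units per unit of x (days, in the demo).
#' @slot intercept fitted value at x = 0.
#' @aliases LinearRegressionModel
#' @exportClass LinearRegressionModel
setClass("LinearRegressionModel",
         representation(slope = "numeric", intercept = "numeric"))

setValidity("LinearRegressionModel", function(object) {
  if (!is.finite(object@slope) || !is.finite(object@intercept))
    return("slope and intercept must be finite")
  TRUE
})

#' CohortSpec: parameters of a synthetic patient cohort
#'
#' The generator emulates a transplant-clinic dataset: each patient carries
#' creatinine and BUN measurement time-courses; a controllable fraction has
#' an increasing creatinine trend (the intended rejecters).  Ground truth is
#' emitted alongside the graph.
#'
#' @slot nPatients number of patients.
#' @slot fractionRejecter proportion in [0,1] generated with the rejecter
#'   slope; the intended rejecter count is \code{round(nPatients * fraction)}.
#' @slot nTimepoints measurements per analyte (>= 2).
#' @slot intervalDays days between consecutive measurements (> 0).
#' @slot baseCreatinine baseline creatinine (mg/dL scale).
#' @slot slopeRejecter generating creatinine slope for rejecters (> 0,
#'   mg/dL per day).
#' @slot slopeNon generating slope for non-rejecters (<= 0).
#' @slot noiseSd standard deviation of Gaussian measurement noise (>= 0).
#' @slot seed integer seed; each patient draws from a dedicated stream
#'   (seed + patient index) so extending a cohort never shifts earlier
#'   patients.
#' @aliases CohortSpec
#' @exportClass CohortSpec
setClass("CohortSpec",
         representation(nPatients = "numeric", fractionRejecter = "numeric",
                        nTimepoints = "numeric", intervalDays = "numeric",
                        baseCreatinine = "numeric", slopeRejecter = "numeric",
                        slopeNon = "numeric", noiseSd = "numeric",
                        seed = "numeric"))

setValidity("CohortSpec", function(object) {
  bad <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  chk(object@nPatients >= 0 && object@nPatients == round(object@nPatients),
      "nPatients must be a non-negative integer")
  chk(object@fractionRejecter >= 0 && object@fractionRejecter <= 1,
      "fractionRejecter must be in [0, 1]")
  chk(object@nTimepoints >= 2 && object@nTimepoints == round(object@nTimepoints),
      "nTimepoints must be an integer >= 2")
  chk(object@intervalDays > 0, "intervalDays must be > 0")
  chk(is.finite(object@baseCreatinine), "baseCreatinine must be finite")
  chk(object@slopeRejecter > 0, "slopeRejecter must be > 0")
  chk(object@slopeNon <= 0, "slopeNon must be <= 0")
  chk(object@noiseSd >= 0, "noiseSd must be >= 0")
  chk(object@seed == round(object@seed), "seed must be an integer")
  if (length(bad)) paste(bad, collapse = "; ") else TRUE
})
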