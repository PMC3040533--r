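## The annotation-service contract: typed services that consume OWL
## individuals of their input class and return the same-URI individuals
## described by the output class.  Invocation returns added triples only;
## the caller merges them into the working graph.

#' Construct a service description
#'
#' @param iri service identity (absolute IRI).
#' @param name short label.
#' @param inputClass,outputClass IRIs of the input and output classes,
#'   resolved against an \code{Ontology} when used.
#' @param implementation function(graph, subject) returning an
#'   \code{RDFGraph} of added triples for that one subject.
#' @return a \code{\linkS4class{ServiceDescription}}.
#' @export
serviceDescription <- function(iri, name, inputClass, outputClass,
                               implementation) {
  new("ServiceDescription", iri = iri, name = name, inputClass = inputClass,
      outputClass = outputClass, implementation = implementation)
}

#' Accessors for service descriptions
#'
#' @param s a \code{ServiceDescription}.
#' @return character(1).
#' @export
serviceIri <- function(s) s@iri

#' @rdname serviceIri
#' @export
serviceName <- function(s) s@name

#' @rdname serviceIri
#' @export
inputClass <- function(s) s@inputClass

#' @rdname serviceIri
#' @export
outputClass <- function(s) s@outputClass

#' Attached properties of a service
#'
#' What a service does, computed by comparing its input and output classes:
#' the properties restricted in the decomposed output class but not in the
#' decomposed input class.  Deterministic (sorted).
#'
#' @param s a \code{ServiceDescription}.
#' @param ont an \code{\linkS4class{Ontology}} used to resolve the class
#'   IRIs to their definitions.
#' @return character vector of property IRIs.
#' @export
attachedProperties <- function(s, ont) {
  stopifnot(is(s, "ServiceDescription"), is(ont, "Ontology"))
  outProps <- restrictedProperties(resolveClass(ont, s@outputClass))
  inProps <- restrictedProperties(resolveClass(ont, s@inputClass))
  sort(setdiff(outProps, inProps))
}

#' Invoke a service on a set of subjects
#'
#' Subjects not entailed to satisfy the input class are skipped with one
#' collective warning (batch annotation semantics: one bad individual never
#' aborts a cohort).  Implementation failures are recorded per subject and
#' leave other subjects unaffected.  The returned record carries the added
#' triples only; merge them with \code{\link{mergeGraphs}}.
#'
#' @param s a \code{ServiceDescription}.
#' @param g the working \code{RDFGraph}.
#' @param subjects character vector of subject IRIs.
#' @param ont an \code{Ontology}.
#' @param quiet suppress the skipped-subject warning (used by the engine,
#'   which pre-filters candidates).
#' @return an \code{\linkS4class{InvocationRecord}}.
#' @export
invokeService <- function(s, g, subjects, ont, quiet = FALSE) {
  stopifnot(is(s, "ServiceDescription"), is(g, "RDFGraph"), is(ont, "Ontology"))
  subjects <- unique(subjects)
  inExpr <- resolveClass(ont, s@inputClass)
  ctx <- .reasonCtx(g, ont)
  eligible <- subjects[vapply(subjects, function(x) .entails(ctx, x, inExpr),
                              logical(1))]
  skipped <- setdiff(subjects, eligible)
  if (length(skipped) && !quiet)
    warning(sprintf(
      "service <%s>: skipping %d subject(s) not satisfying the input class: %s",
      s@iri, length(skipped), paste(skipped, collapse = ", ")),
      call. = FALSE)
  added <- emptyGraph()
  failed <- character(0)
  succeeded <- character(0)
  for (subj in eligible) {
    res <- tryCatch(s@implementation(g, subj), error = function(e) e)
    if (inherits(res, "error")) {
      failed[subj] <- conditionMessage(res)
    } else {
      stopifnot(is(res, "RDFGraph"))
      added <- mergeGraphs(added, res)
      succeeded <- c(succeeded, subj)
    }
  }
  new("InvocationRecord", service = s@iri, inputSubjects = subjects,
      succeeded = succeeded, skipped = skipped, failed = failed,
      added = added, timestamp = Sys.time())
}

## subjects a record may legitimately describe: the input subjects plus any
## node newly minted as the (transitive) object of added triples rooted at
## an input subject
.allowedSubjects <- function(record, gIn) {
  df <- record@added@triples
  known <- unique(gIn@triples$s)
  allowed <- record@inputSubjects
  repeat {
    minted <- unique(df$o[df$s %in% allowed & df$ot == "iri"])
    minted <- setdiff(minted, c(allowed, known))
    if (length(minted) == 0L) break
    allowed <- c(allowed, minted)
  }
  allowed
}

#' Validate the service contract for one invocation
#'
#' Checks the two clauses of the annotation contract: (a) every added-triple
#' subject is an input subject (or a node newly minted as the object of
#' added triples rooted at one — services may describe the model nodes they
#' mint); (b) after merging, every subject the service succeeded on is an
#' entailed member of the output class.  Validation reports violations; it
#' never throws.
#'
#' @param s the \code{ServiceDescription}.
#' @param gIn the graph the service was invoked against.
#' @param record the \code{InvocationRecord} to check.
#' @param ont an \code{Ontology}.
#' @return a \code{\linkS4class{ValidationReport}}.
#' @export
validateContract <- function(s, gIn, record, ont) {
  violations <- list()
  addViolation <- function(type, subject, detail) {
    violations[[length(violations) + 1L]] <<- data.frame(
      type = type, subject = subject, detail = detail,
      stringsAsFactors = FALSE)
  }
  allowed <- .allowedSubjects(record, gIn)
  strays <- setdiff(unique(record@added@triples$s), allowed)
  for (x in strays)
    addViolation("foreign-subject", x,
                 "added triple about a node that is neither an input subject nor minted from one")
  merged <- mergeGraphs(gIn, record@added)
  outExpr <- resolveClass(ont, s@outputClass)
  ctx <- .reasonCtx(merged, ont)
  for (subj in record@succeeded) {
    if (!.entails(ctx, subj, outExpr))
      addViolation("output-class", subj,
                   sprintf("subject does not satisfy the output class <%s> after merge",
                           s@outputClass))
  }
  v <- if (length(violations)) do.call(rbind, violations) else
    data.frame(type = character(), subject = character(),
               detail = character(), stringsAsFactors = FALSE)
  new("ValidationReport", service = s@iri, violations = v)
}

#' Did a validation pass?
#'
#' @param report a \code{ValidationReport}.
#' @return logical(1): TRUE iff no violations.
#' @export
contractHolds <- function(report) nrow(report@violations) == 0L

#' RDF rendering of a service description
#'
#' Uses the package's own small service-description vocabulary
#' (\code{http://sadi-share.example.org/vocab#}): type, label, input class,
#' output class and attached properties.  \code{\link{interpretService}}
#' round-trips it back (implementations are rebound by IRI).
#'
#' @param s a \code{ServiceDescription}.
#' @param ont an \code{Ontology}; when supplied, attached properties are
#'   included in the description.
#' @return an \code{RDFGraph}.
#' @export
describeService <- function(s, ont = NULL) {
  g <- emptyGraph()
  g <- addTriple(g, s@iri, RDF_TYPE, SSV_SERVICE)
  g <- addTriple(g, s@iri, RDFS_LABEL, rdfLiteral(s@name))
  g <- addTriple(g, s@iri, SSV_INPUT_CLASS, s@inputClass)
  g <- addTriple(g, s@iri, SSV_OUTPUT_CLASS, s@outputClass)
  if (!is.null(ont))
    for (p in attachedProperties(s, ont))
      g <- addTriple(g, s@iri, SSV_ATTACHES, p)
  g
}

#' Rebuild a service description from its RDF rendering
#'
#' @param g an \code{RDFGraph} containing a service description.
#' @param iri the service IRI to extract.
#' @param implementations named list, service IRI -> implementation
#'   function; services without an entry get a stub that errors on call.
#' @return a \code{ServiceDescription}.
#' @export
interpretService <- function(g, iri, implementations = list()) {
  df <- g@triples
  mine <- df[df$s == iri, , drop = FALSE]
  if (!any(mine$p == RDF_TYPE & mine$o == SSV_SERVICE))
    stop(sprintf("<%s> is not described as a service", iri), call. = FALSE)
  pick <- function(p) {
    v <- mine$o[mine$p == p]
    if (length(v) == 0L) stop(sprintf(
      "service description <%s> lacks <%s>", iri, p), call. = FALSE)
    v[1L]
  }
  impl <- implementations[[iri]]
  if (is.null(impl))
    impl <- function(graph, subject)
      stop(sprintf("service <%s> has no bound implementation", iri),
           call. = FALSE)
  serviceDescription(iri = iri, name = pick(RDFS_LABEL),
                     inputClass = pick(SSV_INPUT_CLASS),
                     outputClass = pick(SSV_OUTPUT_CLASS),
                     implementation = impl)
}

setMethod("show", "ServiceDescription", function(object) {
  cat(sprintf("ServiceDescription <%s>\n  name: %s\n  input:  <%s>\n  output: <%s>\n",
              object@iri, object@name, object@inputClass, object@outputClass))
})

setMethod("show", "InvocationRecord", function(object) {
  cat(sprintf(
    "InvocationRecord for <%s>: %d subject(s), %d succeeded, %d skipped, %d failed, %d triple(s) added\n",
    object@service, length(object@inputSubjects), length(object@succeeded),
    length(object@skipped), length(object@failed), graphSize(object@added)))
})

setMethod("show", "ValidationReport", function(object) {
  if (contractHolds(object)) {
    cat(sprintf("ValidationReport for <%s>: contract holds\n", object@service))
  } else {
    cat(sprintf("ValidationReport for <%s>: %d violation(s)\n",
                object@service, nrow(object@violations)))
    print(object@violations)
  }
})
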