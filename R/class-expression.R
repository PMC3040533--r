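## Constructors, normalization, decomposition and rendering for the
## supported class-expression fragment.

#' Class-expression constructors
#'
#' Build expressions in the supported OWL-DL fragment.  \code{intersectionOf}
#' normalizes: nested intersections are flattened and the empty intersection
#' collapses to \code{owl:Thing}.
#'
#' @param iri class IRI.
#' @param ... member \code{ClassExpression}s (or one list of them).
#' @param property property IRI.
#' @param filler a \code{ClassExpression} or \code{NumericRange}.
#' @param value an IRI string or \code{\linkS4class{Literal}}.
#' @param datatype datatype IRI, e.g. \code{xsd:decimal}.
#' @param minInclusive,maxInclusive,minExclusive,maxExclusive optional facet
#'   bounds.
#' @return a \code{ClassExpression} (or \code{NumericRange}).
#' @examples
#' increasing <- someValuesFrom("http://ex.org/slope",
#'                              numericRange(minExclusive = 0))
#' renderExpression(increasing)
#' @name ClassExpression-constructors
NULL

#' @rdname ClassExpression-constructors
#' @export
namedClass <- function(iri) new("NamedClass", iri = iri)

#' @rdname ClassExpression-constructors
#' @export
owlThing <- function() namedClass(OWL_THING)

#' @rdname ClassExpression-constructors
#' @export
intersectionOf <- function(...) {
  members <- list(...)
  if (length(members) == 1L && is.list(members[[1]]) &&
      !is(members[[1]], "ClassExpression"))
    members <- members[[1]]
  flat <- list()
  for (m in members) {
    if (is(m, "IntersectionOf")) flat <- c(flat, m@members)
    else flat <- c(flat, list(m))
  }
  if (length(flat) == 0L) return(owlThing())
  if (length(flat) == 1L) return(flat[[1]])
  new("IntersectionOf", members = flat)
}

#' @rdname ClassExpression-constructors
#' @export
someValuesFrom <- function(property, filler)
  new("SomeValuesFrom", property = property, filler = filler)

#' @rdname ClassExpression-constructors
#' @export
hasValue <- function(property, value)
  new("HasValue", property = property, value = value)

#' @rdname ClassExpression-constructors
#' @export
numericRange <- function(datatype = XSD_DECIMAL, minInclusive = NULL,
                         maxInclusive = NULL, minExclusive = NULL,
                         maxExclusive = NULL) {
  facets <- c(minInclusive = minInclusive, maxInclusive = maxInclusive,
              minExclusive = minExclusive, maxExclusive = maxExclusive)
  new("NumericRange", datatype = datatype,
      facets = if (is.null(facets)) setNames(numeric(0), character(0)) else facets)
}

#' Test a numeric value against range facets
#'
#' @param range a \code{NumericRange}.
#' @param x numeric vector.
#' @return logical vector.
#' @export
inNumericRange <- function(range, x) {
  stopifnot(is(range, "NumericRange"))
  f <- range@facets
  ok <- rep(TRUE, length(x))
  if ("minInclusive" %in% names(f)) ok <- ok & x >= f[["minInclusive"]]
  if ("maxInclusive" %in% names(f)) ok <- ok & x <= f[["maxInclusive"]]
  if ("minExclusive" %in% names(f)) ok <- ok & x >  f[["minExclusive"]]
  if ("maxExclusive" %in% names(f)) ok <- ok & x <  f[["maxExclusive"]]
  ok & !is.na(x)
}

## ---------------------------------------------------------------------------
## Requirements
## ---------------------------------------------------------------------------

#' @rdname Requirement
#' @param class class IRI.
#' @export
membershipReq <- function(class) new("MembershipReq", classIri = class)

#' @rdname Requirement
#' @param property property IRI.
#' @param filler \code{ClassExpression}, \code{NumericRange}, or a term value
#'   (IRI string / \code{Literal}) for value restrictions.
#' @export
propertyReq <- function(property, filler)
  new("PropertyReq", property = property, filler = filler)

#' @rdname decompose
setMethod("decompose", "NamedClass", function(expr) list(membershipReq(expr@iri)))

#' @rdname decompose
setMethod("decompose", "IntersectionOf", function(expr) {
  out <- list()
  for (m in expr@members) out <- c(out, decompose(m))
  out
})

#' @rdname decompose
setMethod("decompose", "SomeValuesFrom", function(expr)
  list(propertyReq(expr@property, expr@filler)))

#' @rdname decompose
setMethod("decompose", "HasValue", function(expr)
  list(propertyReq(expr@property, expr@value)))

#' Properties restricted by a class expression
#'
#' The set of property IRIs appearing in the (flattened) property
#' requirements of an expression; the basis of the input/output class diff
#' that states what an annotation service does.
#'
#' @param expr a \code{ClassExpression}.
#' @return character vector of property IRIs (sorted, unique).
#' @export
restrictedProperties <- function(expr) {
  reqs <- decompose(expr)
  props <- vapply(Filter(function(r) is(r, "PropertyReq"), reqs),
                  function(r) r@property, character(1))
  sort(unique(props))
}

## ---------------------------------------------------------------------------
## Rendering
## ---------------------------------------------------------------------------

#' @rdname renderExpression
setMethod("renderExpression", "NamedClass", function(x) localName(x@iri))

#' @rdname renderExpression
setMethod("renderExpression", "IntersectionOf", function(x) {
  paste0("(", paste(vapply(x@members, renderExpression, character(1)),
                    collapse = " and "), ")")
})

#' @rdname renderExpression
setMethod("renderExpression", "SomeValuesFrom", function(x) {
  paste0("(", localName(x@property), " some ", renderExpression(x@filler), ")")
})

#' @rdname renderExpression
setMethod("renderExpression", "HasValue", function(x) {
  v <- if (is(x@value, "Literal")) sprintf("\"%s\"", x@value@lexical) else
    localName(x@value)
  paste0("(", localName(x@property), " value ", v, ")")
})

#' @rdname renderExpression
setMethod("renderExpression", "NumericRange", function(x) {
  if (length(x@facets) == 0L) return(localName(x@datatype))
  sym <- c(minInclusive = ">=", maxInclusive = "<=",
           minExclusive = ">", maxExclusive = "<")
  paste0(localName(x@datatype), "[",
         paste(sprintf("%s %s", sym[names(x@facets)],
                       decimalLexical(unname(x@facets))), collapse = ", "),
         "]")
})

#' @rdname renderExpression
setMethod("renderExpression", "MembershipReq", function(x) localName(x@classIri))

#' @rdname renderExpression
setMethod("renderExpression", "PropertyReq", function(x) {
  f <- x@filler
  fr <- if (is(f, "ClassExpression") || is(f, "NumericRange"))
    renderExpression(f)
  else if (is(f, "Literal")) sprintf("\"%s\"", f@lexical)
  else localName(f)
  paste0(localName(x@property), " some ", fr)
})

setMethod("show", "NamedClass", function(object)
  cat("<NamedClass>", renderExpression(object), "\n"))
setMethod("show", "IntersectionOf", function(object)
  cat("<IntersectionOf>", renderExpression(object), "\n"))
setMethod("show", "SomeValuesFrom", function(object)
  cat("<SomeValuesFrom>", renderExpression(object), "\n"))
setMethod("show", "HasValue", function(object)
  cat("<HasValue>", renderExpression(object), "\n"))
setMethod("show", "NumericRange", function(object)
  cat("<NumericRange>", renderExpression(object), "\n"))
setMethod("show", "MembershipReq", function(object)
  cat("<MembershipReq>", renderExpression(object), "\n"))
setMethod("show", "PropertyReq", function(object)
  cat("<PropertyReq>", renderExpression(object), "\n"))

## structural equality of expressions (used for registry idempotence checks)
.exprEqual <- function(a, b) {
  if (!identical(class(a), class(b))) return(FALSE)
  if (is(a, "NamedClass")) return(a@iri == b@iri)
  if (is(a, "IntersectionOf")) {
    if (length(a@members) != length(b@members)) return(FALSE)
    return(all(mapply(.exprEqual, a@members, b@members)))
  }
  if (is(a, "SomeValuesFrom"))
    return(a@property == b@property && .exprEqual(a@filler, b@filler))
  if (is(a, "HasValue")) {
    if (a@property != b@property) return(FALSE)
    av <- a@value; bv <- b@value
    if (is(av, "Literal") && is(bv, "Literal"))
      return(av@lexical == bv@lexical && av@datatype == bv@datatype)
    return(identical(av, bv))
  }
  if (is(a, "NumericRange")) {
    return(a@datatype == b@datatype &&
           identical(sort(names(a@facets)), sort(names(b@facets))) &&
           all(a@facets[sort(names(a@facets))] ==
               b@facets[sort(names(b@facets))]))
  }
  identical(a, b)
}
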