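## Generics. Most package operations are plain functions; generics are used
## where dispatch over the S4 data model genuinely varies (rendering,
## decomposition, size).

#' Number of triples in a graph
#'
#' @param x an \code{RDFGraph}.
#' @return integer triple count.
#' @export
setGeneric("graphSize", function(x) standardGeneric("graphSize"))

#' Decompose a class expression into requirements
#'
#' Flattens nested intersections into a deterministic (document-order) list
#' of \code{\linkS4class{Requirement}} objects whose conjunction is logically
#' equivalent to the expression: one \code{MembershipReq} per named conjunct
#' and one \code{PropertyReq} per property restriction.
#'
#' @param expr a \code{ClassExpression}.
#' @return list of \code{Requirement}.
#' @examples
#' decompose(namedClass("http://example.org/C"))
#' @export
setGeneric("decompose", function(expr) standardGeneric("decompose"))

#' Render a class expression, requirement or term in Manchester-like syntax
#'
#' @param x object to render.
#' @return character(1).
#' @export
setGeneric("renderExpression", function(x) standardGeneric("renderExpression"))
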