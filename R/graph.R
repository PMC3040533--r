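## RDF graph construction, merging and accessors.

.canonicalOrder <- function(df) {
  ord <- order(df$s, df$p, df$ot, df$o, ifelse(is.na(df$dt), "", df$dt),
               method = "radix")
  df[ord, , drop = FALSE]
}

.makeGraph <- function(df) {
  df <- df[!duplicated(.tripleKeys(df)), , drop = FALSE]
  df <- .canonicalOrder(df)
  rownames(df) <- NULL
  new("RDFGraph", triples = df)
}

#' Create an RDF graph
#'
#' @param triples optional data.frame with columns \code{s}, \code{p},
#'   \code{o}, \code{ot} (\code{"iri"}/\code{"lit"}) and \code{dt} (datatype
#'   IRI, \code{NA} for IRI objects).  Duplicates are removed; triples are
#'   kept in a canonical sort order so identical sets serialize identically.
#' @return an \code{\linkS4class{RDFGraph}}.
#' @examples
#' g <- rdfGraph()
#' g <- addTriple(g, "http://ex.org/s", "http://ex.org/p", "http://ex.org/o")
#' graphSize(g)
#' @export
rdfGraph <- function(triples = NULL) {
  if (is.null(triples)) triples <- .emptyTripleDF()
  .makeGraph(triples)
}

#' @rdname rdfGraph
#' @export
emptyGraph <- function() rdfGraph()

#' Typed RDF literal
#'
#' @param lexical lexical form (coerced to character; numbers are formatted
#'   without scientific notation so they remain valid \code{xsd:decimal}
#'   lexical forms).
#' @param datatype datatype IRI; defaults to \code{xsd:string} for character
#'   input and \code{xsd:decimal} for numeric input.
#' @return a \code{\linkS4class{Literal}}.
#' @examples
#' rdfLiteral(1.9)
#' rdfLiteral("2010-12-21T00:00:00", paste0("http://www.w3.org/2001/XMLSchema#",
#'   "dateTime"))
#' @export
rdfLiteral <- function(lexical, datatype = NULL) {
  if (is.numeric(lexical)) {
    if (is.null(datatype)) datatype <- XSD_DECIMAL
    lexical <- decimalLexical(lexical)
  } else {
    lexical <- as.character(lexical)
    if (is.null(datatype)) datatype <- XSD_STRING
  }
  new("Literal", lexical = lexical, datatype = datatype)
}

#' Format a number as an xsd:decimal lexical form
#'
#' Plain (never scientific) notation, up to 15 significant digits, no
#' trailing zeros; deterministic, so equal numbers always serialize equally.
#'
#' @param x numeric vector.
#' @return character vector.
#' @export
decimalLexical <- function(x) {
  vapply(x, function(v) {
    s <- format(v, scientific = FALSE, trim = TRUE, digits = 15)
    s
  }, character(1))
}

#' Add one triple to a graph
#'
#' @param g an \code{RDFGraph}.
#' @param s,p subject and predicate IRIs.
#' @param o object: an IRI string or a \code{\linkS4class{Literal}}.
#' @return the extended \code{RDFGraph}.
#' @export
addTriple <- function(g, s, p, o) {
  stopifnot(is(g, "RDFGraph"))
  if (is(o, "Literal")) {
    row <- data.frame(s = s, p = p, o = o@lexical, ot = "lit",
                      dt = o@datatype, stringsAsFactors = FALSE)
  } else {
    row <- data.frame(s = s, p = p, o = o, ot = "iri", dt = NA_character_,
                      stringsAsFactors = FALSE)
  }
  .makeGraph(rbind(g@triples, row))
}

#' Merge graphs (set union)
#'
#' Merge is the union of the triple sets: commutative, associative,
#' idempotent, with the empty graph as identity.  This is the operation that
#' folds every annotation service's output into the transient working graph.
#'
#' @param ... \code{RDFGraph} objects.
#' @return the merged \code{RDFGraph}.
#' @examples
#' g <- addTriple(emptyGraph(), "http://ex.org/s", "http://ex.org/p",
#'                "http://ex.org/o")
#' graphSize(mergeGraphs(g, g))  # 1: idempotent
#' @export
mergeGraphs <- function(...) {
  gs <- list(...)
  stopifnot(all(vapply(gs, is, logical(1), class2 = "RDFGraph")))
  if (length(gs) == 0L) return(emptyGraph())
  .makeGraph(do.call(rbind, lapply(gs, function(g) g@triples)))
}

#' @rdname graphSize
#' @export
setMethod("graphSize", "RDFGraph", function(x) nrow(x@triples))

#' Triple table of a graph
#'
#' @param g an \code{RDFGraph}.
#' @return the underlying data.frame (copy).
#' @export
graphTriples <- function(g) {
  stopifnot(is(g, "RDFGraph"))
  g@triples
}

#' Set difference of two graphs
#'
#' @param a,b \code{RDFGraph} objects.
#' @return \code{RDFGraph} holding the triples of \code{a} not in \code{b}.
#' @export
graphDifference <- function(a, b) {
  keep <- !(.tripleKeys(a@triples) %in% .tripleKeys(b@triples))
  .makeGraph(a@triples[keep, , drop = FALSE])
}

#' Test whether two graphs hold the same triple set
#'
#' @param a,b \code{RDFGraph} objects.
#' @return logical(1).
#' @export
sameGraph <- function(a, b) {
  setequal(.tripleKeys(a@triples), .tripleKeys(b@triples))
}

#' Individuals mentioned in a graph
#'
#' All IRIs occurring as a subject or as an IRI object, excluding RDF/OWL
#' vocabulary terms and class IRIs used only as \code{rdf:type} objects'
#' vocabulary is retained (a type object is an individual candidate only for
#' punning-free data, so type objects are excluded).
#'
#' @param g an \code{RDFGraph}.
#' @return character vector of IRIs, sorted.
#' @export
graphIndividuals <- function(g) {
  df <- g@triples
  typeObjects <- df$o[df$p == RDF_TYPE & df$ot == "iri"]
  objs <- df$o[df$ot == "iri" & df$p != RDF_TYPE]
  out <- setdiff(unique(c(df$s, objs)), typeObjects)
  out <- out[!startsWith(out, RDF_NS) & !startsWith(out, RDFS_NS) &
             !startsWith(out, OWL_NS) & !startsWith(out, XSD_NS)]
  sort(out)
}

## objects (IRIs) of triples (s, p in preds, ?o)
.objectsOf <- function(df, s, preds) {
  rows <- df$s == s & df$p %in% preds
  df[rows, c("o", "ot", "dt"), drop = FALSE]
}

#' Asserted types of an individual
#'
#' @param g an \code{RDFGraph}.
#' @param ind individual IRI.
#' @return character vector of class IRIs.
#' @export
assertedTypes <- function(g, ind) {
  df <- g@triples
  unique(df$o[df$s == ind & df$p == RDF_TYPE & df$ot == "iri"])
}

setMethod("show", "RDFGraph", function(object) {
  n <- graphSize(object)
  cat(sprintf("RDFGraph with %d triple%s\n", n, if (n == 1) "" else "s"))
  if (n > 0) {
    df <- utils::head(object@triples, 6L)
    disp <- sprintf("  <%s> <%s> %s", df$s, df$p,
                    ifelse(df$ot == "iri", sprintf("<%s>", df$o),
                           sprintf("\"%s\"^^<%s>", df$o, df$dt)))
    cat(disp, sep = "\n")
    if (n > 6L) cat(sprintf("  ... and %d more\n", n - 6L))
  }
})

setMethod("show", "Literal", function(object) {
  cat(sprintf("\"%s\"^^<%s>\n", object@lexical, object@datatype))
})

## numeric value of literal rows; NA for non-numeric datatypes or bad forms
.literalNumeric <- function(o, dt) {
  out <- rep(NA_real_, length(o))
  num <- !is.na(dt) & dt %in% XSD_NUMERIC_TYPES
  out[num] <- suppressWarnings(as.numeric(o[num]))
  out
}
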