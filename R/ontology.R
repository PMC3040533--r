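## Ontology construction: parse OWL graphs (standard vocabulary:
## owl:equivalentClass, owl:intersectionOf, owl:someValuesFrom, owl:hasValue,
## owl:onProperty, owl:onDatatype/owl:withRestrictions with XSD facets,
## rdfs:subClassOf, rdfs:subPropertyOf) into the class-expression algebra
## plus subclass/subproperty axiom tables.  Constructs outside the fragment
## raise an UnsupportedFragment error naming the construct.

.unsupportedFragment <- function(construct, where) {
  stop(structure(class = c("sadishare_unsupported_fragment", "error",
                           "condition"),
                 list(message = sprintf(
                   "unsupported OWL construct %s at <%s>: outside the positive-existential fragment",
                   construct, where), call = NULL)))
}

.readRdfList <- function(df, head) {
  items <- list()
  node <- head
  seen <- character(0)
  while (!identical(node, RDF_NIL)) {
    if (node %in% seen)
      stop(sprintf("cyclic RDF list at <%s>", node), call. = FALSE)
    seen <- c(seen, node)
    first <- df[df$s == node & df$p == RDF_FIRST, , drop = FALSE]
    rest <- df[df$s == node & df$p == RDF_REST, , drop = FALSE]
    if (nrow(first) != 1L || nrow(rest) != 1L)
      stop(sprintf("malformed RDF list at <%s>", node), call. = FALSE)
    items[[length(items) + 1L]] <- first[1L, ]
    node <- rest$o[1L]
  }
  items
}

.parseExprNode <- function(df, node, visited = character(0)) {
  if (node %in% visited)
    stop(sprintf("cyclic class definition involving <%s>", node),
         call. = FALSE)
  visited <- c(visited, node)

  here <- df[df$s == node, , drop = FALSE]
  bad <- intersect(here$p, OWL_UNSUPPORTED)
  if (length(bad)) .unsupportedFragment(paste0("owl:", localName(bad[1L])), node)

  ## datatype range with facets
  if (OWL_ON_DATATYPE %in% here$p) {
    dt <- here$o[here$p == OWL_ON_DATATYPE][1L]
    facets <- numeric(0)
    wr <- here$o[here$p == OWL_WITH_RESTRICTIONS]
    if (length(wr)) {
      for (item in .readRdfList(df, wr[1L])) {
        frows <- df[df$s == item$o & df$p %in% XSD_FACETS, , drop = FALSE]
        for (k in seq_len(nrow(frows))) {
          v <- suppressWarnings(as.numeric(frows$o[k]))
          if (!is.finite(v))
            stop(sprintf("non-numeric facet value '%s' at <%s>",
                         frows$o[k], item$o), call. = FALSE)
          facets[localName(frows$p[k])] <- v
        }
      }
    }
    return(new("NumericRange", datatype = dt, facets = facets))
  }

  if (OWL_INTERSECTION_OF %in% here$p) {
    head <- here$o[here$p == OWL_INTERSECTION_OF][1L]
    members <- lapply(.readRdfList(df, head), function(item) {
      if (item$ot != "iri")
        stop(sprintf("literal in intersection list at <%s>", node),
             call. = FALSE)
      .parseExprNode(df, item$o, visited)
    })
    return(intersectionOf(members))
  }

  if (OWL_ON_PROPERTY %in% here$p) {
    prop <- here$o[here$p == OWL_ON_PROPERTY][1L]
    if (OWL_SOME_VALUES_FROM %in% here$p) {
      frow <- here[here$p == OWL_SOME_VALUES_FROM, , drop = FALSE][1L, ]
      if (frow$ot != "iri")
        stop(sprintf("someValuesFrom filler must be a class or datatype at <%s>",
                     node), call. = FALSE)
      filler <- if (startsWith(frow$o, XSD_NS))
        new("NumericRange", datatype = frow$o, facets = numeric(0))
      else .parseExprNode(df, frow$o, visited)
      return(someValuesFrom(prop, filler))
    }
    if (OWL_HAS_VALUE %in% here$p) {
      vrow <- here[here$p == OWL_HAS_VALUE, , drop = FALSE][1L, ]
      value <- if (vrow$ot == "lit")
        new("Literal", lexical = vrow$o, datatype = vrow$dt) else vrow$o
      return(hasValue(prop, value))
    }
    .unsupportedFragment("owl:Restriction without someValuesFrom/hasValue",
                         node)
  }

  ## a plain named class reference (possibly with its own definition, which
  ## is resolved lazily at reasoning time, keeping parses finite)
  if (startsWith(node, "urn:bnode:"))
    .unsupportedFragment("anonymous class with no recognized operator", node)
  namedClass(node)
}

#' Parse the class expression defining a class
#'
#' Returns the algebraic form of \code{classIri}'s equivalence definition in
#' \code{g}, or \code{NamedClass(classIri)} when the class is primitive.
#' Constructs outside the supported fragment (\code{allValuesFrom},
#' cardinality, \code{unionOf}, \code{complementOf}, ...) raise an error
#' naming the construct; they are never silently dropped.  Cyclic
#' definitions are an error.
#'
#' @param g an \code{RDFGraph} holding the ontology (load with
#'   \code{blankNodes = "skolemize"}).
#' @param classIri IRI of the class to parse.
#' @return a \code{ClassExpression}.
#' @export
parseClassExpression <- function(g, classIri) {
  stopifnot(is(g, "RDFGraph"))
  df <- g@triples
  defs <- df[df$s == classIri & df$p == OWL_EQUIVALENT_CLASS, , drop = FALSE]
  if (nrow(defs) == 0L) {
    ## also accept the symmetric orientation
    defs <- df[df$o == classIri & df$p == OWL_EQUIVALENT_CLASS &
               df$ot == "iri", , drop = FALSE]
    if (nrow(defs) == 0L) return(.parseExprNode(df, classIri))
    return(.parseExprNode(df, defs$s[1L], visited = classIri))
  }
  .parseExprNode(df, defs$o[1L], visited = classIri)
}

#' Construct an ontology
#'
#' @param classDefinitions named list, class IRI -> \code{ClassExpression}.
#' @param subclassAxioms data.frame with columns \code{sub}, \code{super}.
#' @param subpropertyAxioms data.frame with columns \code{sub}, \code{super}.
#' @return an \code{\linkS4class{Ontology}}.
#' @export
ontology <- function(classDefinitions = list(),
                     subclassAxioms = data.frame(sub = character(),
                                                 super = character()),
                     subpropertyAxioms = data.frame(sub = character(),
                                                    super = character())) {
  new("Ontology", classDefinitions = classDefinitions,
      subclassAxioms = subclassAxioms, subpropertyAxioms = subpropertyAxioms)
}

#' Build an ontology from an OWL graph
#'
#' Collects equivalence definitions (parsed into the fragment), named
#' subclass axioms and named subproperty axioms.  A \code{rdfs:subClassOf}
#' axiom whose superclass is an anonymous expression is outside the fragment
#' and raises an error.
#'
#' @param g an \code{RDFGraph} (load ontology documents with
#'   \code{blankNodes = "skolemize"}).
#' @return an \code{\linkS4class{Ontology}}.
#' @export
ontologyFromGraph <- function(g) {
  stopifnot(is(g, "RDFGraph"))
  df <- g@triples
  eq <- df[df$p == OWL_EQUIVALENT_CLASS & !startsWith(df$s, "urn:bnode:"), ,
           drop = FALSE]
  defs <- list()
  for (i in seq_len(nrow(eq))) {
    ciri <- eq$s[i]
    defs[[ciri]] <- parseClassExpression(g, ciri)
  }
  sc <- df[df$p == RDFS_SUBCLASS, , drop = FALSE]
  if (nrow(sc)) {
    anon <- startsWith(sc$o, "urn:bnode:") | startsWith(sc$s, "urn:bnode:")
    if (any(anon))
      .unsupportedFragment("rdfs:subClassOf with an anonymous class",
                           sc$s[anon][1L])
  }
  sp <- df[df$p == RDFS_SUBPROPERTY, , drop = FALSE]
  ontology(
    classDefinitions = defs,
    subclassAxioms = data.frame(sub = sc$s, super = sc$o,
                                stringsAsFactors = FALSE),
    subpropertyAxioms = data.frame(sub = sp$s, super = sp$o,
                                   stringsAsFactors = FALSE))
}

#' Load an ontology document
#'
#' @param path Turtle or RDF/XML file.
#' @param dialect optional dialect override; see \code{\link{loadGraph}}.
#' @return an \code{\linkS4class{Ontology}}.
#' @export
loadOntology <- function(path, dialect = NULL) {
  ontologyFromGraph(loadGraph(path, dialect = dialect,
                              blankNodes = "skolemize"))
}

#' Resolve a class IRI against an ontology
#'
#' @param ont an \code{Ontology}.
#' @param classIri class IRI.
#' @return the class's definition (\code{ClassExpression}), or
#'   \code{NamedClass(classIri)} for primitive classes.
#' @export
resolveClass <- function(ont, classIri) {
  def <- ont@classDefinitions[[classIri]]
  if (is.null(def)) namedClass(classIri) else def
}

#' Whether a class has an equivalence definition
#'
#' @param ont an \code{Ontology}.
#' @param classIri class IRI.
#' @return logical(1).
#' @export
isDefinedClass <- function(ont, classIri) {
  classIri %in% names(ont@classDefinitions)
}

.transitiveClosure <- function(edges, start, direction = c("up", "down")) {
  direction <- match.arg(direction)
  fromCol <- if (direction == "up") "sub" else "super"
  toCol <- if (direction == "up") "super" else "sub"
  out <- unique(start)
  frontier <- out
  while (length(frontier)) {
    nxt <- unique(edges[[toCol]][edges[[fromCol]] %in% frontier])
    frontier <- setdiff(nxt, out)
    out <- c(out, frontier)
  }
  out
}

#' Subclass / subproperty closures
#'
#' Reflexive-transitive closures over the asserted axioms.
#'
#' @param ont an \code{Ontology}.
#' @param classes,properties IRIs to close over.
#' @return character vector of IRIs (includes the input).
#' @export
superClassesOf <- function(ont, classes)
  .transitiveClosure(ont@subclassAxioms, classes, "up")

#' @rdname superClassesOf
#' @export
subClassesOf <- function(ont, classes)
  .transitiveClosure(ont@subclassAxioms, classes, "down")

#' @rdname superClassesOf
#' @export
superPropertiesOf <- function(ont, properties)
  .transitiveClosure(ont@subpropertyAxioms, properties, "up")

#' @rdname superClassesOf
#' @export
subPropertiesOf <- function(ont, properties)
  .transitiveClosure(ont@subpropertyAxioms, properties, "down")

setMethod("show", "Ontology", function(object) {
  cat(sprintf("Ontology: %d defined class%s, %d subclass axiom%s, %d subproperty axiom%s\n",
              length(object@classDefinitions),
              if (length(object@classDefinitions) == 1) "" else "es",
              nrow(object@subclassAxioms),
              if (nrow(object@subclassAxioms) == 1) "" else "s",
              nrow(object@subpropertyAxioms),
              if (nrow(object@subpropertyAxioms) == 1) "" else "s"))
  for (ciri in names(object@classDefinitions))
    cat(sprintf("  %s == %s\n", localName(ciri),
                renderExpression(object@classDefinitions[[ciri]])))
})
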