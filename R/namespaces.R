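## Well-known vocabulary IRIs used throughout the package.

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"

RDF_TYPE  <- paste0(RDF_NS, "type")
RDF_FIRST <- paste0(RDF_NS, "first")
RDF_REST  <- paste0(RDF_NS, "rest")
RDF_NIL   <- paste0(RDF_NS, "nil")

RDFS_LABEL       <- paste0(RDFS_NS, "label")
RDFS_SUBCLASS    <- paste0(RDFS_NS, "subClassOf")
RDFS_SUBPROPERTY <- paste0(RDFS_NS, "subPropertyOf")

OWL_THING            <- paste0(OWL_NS, "Thing")
OWL_CLASS            <- paste0(OWL_NS, "Class")
OWL_RESTRICTION      <- paste0(OWL_NS, "Restriction")
OWL_EQUIVALENT_CLASS <- paste0(OWL_NS, "equivalentClass")
OWL_INTERSECTION_OF  <- paste0(OWL_NS, "intersectionOf")
OWL_ON_PROPERTY      <- paste0(OWL_NS, "onProperty")
OWL_SOME_VALUES_FROM <- paste0(OWL_NS, "someValuesFrom")
OWL_HAS_VALUE        <- paste0(OWL_NS, "hasValue")
OWL_ON_DATATYPE      <- paste0(OWL_NS, "onDatatype")
OWL_WITH_RESTRICTIONS <- paste0(OWL_NS, "withRestrictions")

## constructs recognised but outside the supported fragment
OWL_UNSUPPORTED <- paste0(OWL_NS, c(
  "allValuesFrom", "unionOf", "complementOf", "oneOf",
  "cardinality", "minCardinality", "maxCardinality",
  "qualifiedCardinality", "minQualifiedCardinality", "maxQualifiedCardinality"
))

XSD_STRING   <- paste0(XSD_NS, "string")
XSD_DECIMAL  <- paste0(XSD_NS, "decimal")
XSD_INTEGER  <- paste0(XSD_NS, "integer")
XSD_DOUBLE   <- paste0(XSD_NS, "double")
XSD_FLOAT    <- paste0(XSD_NS, "float")
XSD_BOOLEAN  <- paste0(XSD_NS, "boolean")
XSD_DATETIME <- paste0(XSD_NS, "dateTime")

XSD_FACETS <- paste0(XSD_NS, c("minInclusive", "maxInclusive",
                               "minExclusive", "maxExclusive"))

XSD_NUMERIC_TYPES <- paste0(XSD_NS, c(
  "decimal", "integer", "double", "float", "long", "int", "short", "byte",
  "nonNegativeInteger", "nonPositiveInteger", "positiveInteger",
  "negativeInteger", "unsignedLong", "unsignedInt", "unsignedShort",
  "unsignedByte"
))

## service-description vocabulary (self-defined, versioned with the package)
SSV_NS <- "http://sadi-share.example.org/vocab#"
SSV_SERVICE          <- paste0(SSV_NS, "Service")
SSV_INPUT_CLASS      <- paste0(SSV_NS, "inputClass")
SSV_OUTPUT_CLASS     <- paste0(SSV_NS, "outputClass")
SSV_ATTACHES         <- paste0(SSV_NS, "attachesProperty")

STANDARD_PREFIXES <- c(
  rdf  = RDF_NS,
  rdfs = RDFS_NS,
  owl  = OWL_NS,
  xsd  = XSD_NS
)

isAbsoluteIri <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x)
}

localName <- function(iri) {
  sub(".*[#/]", "", iri)
}
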