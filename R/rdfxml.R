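## RDF/XML reader/writer (xml2-based).  Accepted on input for fidelity to
## the era's deployed services; Turtle is the primary on-disk dialect.
##
## Supported constructs: rdf:RDF root, rdf:Description and typed node
## elements, rdf:about, nested node elements, property elements with
## rdf:resource / rdf:datatype / text content, and literal property
## attributes.  rdf:nodeID and rdf:parseType follow the blank-node policy.

RDFXML_ABOUT    <- paste0(RDF_NS, "about")
RDFXML_RESOURCE <- paste0(RDF_NS, "resource")
RDFXML_DATATYPE <- paste0(RDF_NS, "datatype")
RDFXML_NODEID   <- paste0(RDF_NS, "nodeID")

.rxState <- function(blankNodes) {
  e <- new.env(parent = emptyenv())
  e$rows <- list(); e$bnodeN <- 0L; e$blankNodes <- blankNodes
  e
}

.rxBlank <- function(st, label = NULL) {
  if (identical(st$blankNodes, "reject"))
    stop(paste("RDF/XML parse failure: blank node encountered; instance data",
               "must use named subjects (load ontology documents with",
               "blankNodes = \"skolemize\")"), call. = FALSE)
  if (is.null(label)) {
    st$bnodeN <- st$bnodeN + 1L
    paste0("urn:bnode:xgen", st$bnodeN)
  } else paste0("urn:bnode:", label)
}

.rxEmit <- function(st, s, p, o, ot, dt) {
  st$rows[[length(st$rows) + 1L]] <- list(s = s, p = p, o = o, ot = ot, dt = dt)
}

.rxExpandedName <- function(node) {
  ## namespace URI + local name of an element
  full <- xml2::xml_name(node, ns = character()) # local name only
  nsmap <- xml2::xml_ns(node)
  ## xml2 gives the node's qualified name through xml_name with ns map
  qn <- xml2::xml_name(node, nsmap)
  if (grepl(":", qn, fixed = TRUE)) {
    pfx <- sub(":.*", "", qn)
    paste0(nsmap[[pfx]], sub(".*:", "", qn))
  } else {
    ## default namespace
    d <- tryCatch(nsmap[["d1"]], error = function(e) NULL)
    if (!is.null(d)) paste0(d, qn) else qn
  }
}

.rxAllAttrsExpanded <- function(node) {
  nsmap <- xml2::xml_ns(xml2::xml_root(node))
  at <- xml2::xml_attrs(node, ns = nsmap)
  if (length(at) == 0L) return(character(0))
  exp <- vapply(names(at), function(n) {
    if (grepl(":", n, fixed = TRUE)) {
      pfx <- sub(":.*", "", n)
      uri <- tryCatch(nsmap[[pfx]], error = function(e) NA_character_)
      if (is.na(uri)) n else paste0(uri, sub(".*:", "", n))
    } else n
  }, character(1))
  names(at) <- exp
  at
}

.rxNodeElement <- function(st, node) {
  attrs <- .rxAllAttrsExpanded(node)
  about <- attrs[RDFXML_ABOUT]
  nodeId <- attrs[RDFXML_NODEID]
  subject <- if (!is.na(about)) {
    if (!isAbsoluteIri(about))
      stop(sprintf("RDF/XML parse failure: rdf:about '%s' is not absolute",
                   about), call. = FALSE)
    unname(about)
  } else if (!is.na(nodeId)) .rxBlank(st, unname(nodeId)) else .rxBlank(st)

  en <- .rxExpandedName(node)
  if (en != paste0(RDF_NS, "Description"))
    .rxEmit(st, subject, RDF_TYPE, en, "iri", NA_character_)

  ## literal property attributes (abbreviated syntax)
  skip <- c(RDFXML_ABOUT, RDFXML_NODEID)
  for (i in seq_along(attrs)) {
    an <- names(attrs)[i]
    if (an %in% skip || startsWith(an, "xmlns") || !isAbsoluteIri(an)) next
    .rxEmit(st, subject, an, unname(attrs[i]), "lit", XSD_STRING)
  }

  for (prop in xml2::xml_children(node)) {
    p <- .rxExpandedName(prop)
    pAttrs <- .rxAllAttrsExpanded(prop)
    res <- pAttrs[RDFXML_RESOURCE]
    dtt <- pAttrs[RDFXML_DATATYPE]
    nid <- pAttrs[RDFXML_NODEID]
    pt  <- pAttrs[paste0(RDF_NS, "parseType")]
    kids <- xml2::xml_children(prop)
    if (!is.na(pt))
      stop(sprintf("RDF/XML parse failure: rdf:parseType='%s' not supported",
                   unname(pt)), call. = FALSE)
    if (!is.na(res)) {
      .rxEmit(st, subject, p, unname(res), "iri", NA_character_)
    } else if (!is.na(nid)) {
      .rxEmit(st, subject, p, .rxBlank(st, unname(nid)), "iri", NA_character_)
    } else if (length(kids)) {
      obj <- .rxNodeElement(st, kids[[1]])
      .rxEmit(st, subject, p, obj, "iri", NA_character_)
    } else {
      lex <- xml2::xml_text(prop)
      dt <- if (!is.na(dtt)) unname(dtt) else XSD_STRING
      .rxEmit(st, subject, p, lex, "lit", dt)
    }
  }
  subject
}

#' Parse an RDF/XML document
#'
#' @param text RDF/XML source (character) or an \code{xml2} document.
#' @param blankNodes blank-node policy, as in \code{\link{parseTurtle}}.
#' @return an \code{RDFGraph}.
#' @export
parseRdfXml <- function(text, blankNodes = c("reject", "skolemize")) {
  blankNodes <- match.arg(blankNodes)
  doc <- if (inherits(text, "xml_document")) text else
    tryCatch(xml2::read_xml(paste(text, collapse = "\n")),
             error = function(e) stop(sprintf(
               "RDF/XML parse failure: %s", conditionMessage(e)), call. = FALSE))
  st <- .rxState(blankNodes)
  for (child in xml2::xml_children(doc)) .rxNodeElement(st, child)
  rows <- st$rows
  if (length(rows) == 0L) return(emptyGraph())
  df <- data.frame(
    s  = vapply(rows, `[[`, character(1), "s"),
    p  = vapply(rows, `[[`, character(1), "p"),
    o  = vapply(rows, `[[`, character(1), "o"),
    ot = vapply(rows, `[[`, character(1), "ot"),
    dt = vapply(rows, function(r) if (is.null(r$dt) || is.na(r$dt))
      NA_character_ else r$dt, character(1)),
    stringsAsFactors = FALSE)
  .makeGraph(df)
}

.xmlEscape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub("\"", "&quot;", s, fixed = TRUE)
}

.splitIri <- function(iri) {
  ## namespace/local split at the last '#' or '/'; local must be an XML name
  m <- regexpr("[#/][A-Za-z_][A-Za-z0-9_.-]*$", iri)
  if (m == -1L) stop(sprintf(
    "cannot serialize predicate <%s> to RDF/XML: no namespace/local split",
    iri), call. = FALSE)
  c(ns = substr(iri, 1L, m), local = substr(iri, m + 1L, nchar(iri)))
}

#' Serialize a graph to RDF/XML
#'
#' One \code{rdf:Description} element per subject, deterministic order.
#'
#' @param g an \code{RDFGraph}.
#' @param path optional output file path.
#' @return the XML text, invisibly when written to a file.
#' @export
writeRdfXml <- function(g, path = NULL) {
  stopifnot(is(g, "RDFGraph"))
  df <- g@triples
  preds <- unique(df$p)
  splits <- lapply(preds, .splitIri)
  nss <- unique(c(RDF_NS, vapply(splits, `[`, character(1), "ns")))
  pfx <- setNames(paste0("ns", seq_along(nss)), nss)
  pfx[RDF_NS] <- "rdf"
  qname <- function(p) {
    sp <- .splitIri(p)
    paste0(pfx[[sp[["ns"]]]], ":", sp[["local"]])
  }
  header <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
              paste0("<rdf:RDF",
                     paste(sprintf(" xmlns:%s=\"%s\"", pfx, names(pfx)),
                           collapse = ""),
                     ">"))
  body <- character(0)
  for (s in unique(df$s)) {
    rows <- df[df$s == s, , drop = FALSE]
    body <- c(body, sprintf("  <rdf:Description rdf:about=\"%s\">",
                            .xmlEscape(s)))
    for (i in seq_len(nrow(rows))) {
      q <- qname(rows$p[i])
      if (rows$ot[i] == "iri") {
        body <- c(body, sprintf("    <%s rdf:resource=\"%s\"/>",
                                q, .xmlEscape(rows$o[i])))
      } else if (rows$dt[i] == XSD_STRING) {
        body <- c(body, sprintf("    <%s>%s</%s>",
                                q, .xmlEscape(rows$o[i]), q))
      } else {
        body <- c(body, sprintf("    <%s rdf:datatype=\"%s\">%s</%s>",
                                q, .xmlEscape(rows$dt[i]),
                                .xmlEscape(rows$o[i]), q))
      }
    }
    body <- c(body, "  </rdf:Description>")
  }
  text <- paste0(paste(c(header, body, "</rdf:RDF>"), collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(text), con)
    return(invisible(text))
  }
  text
}
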