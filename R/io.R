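## Graph load/save dispatch over the two supported dialects.

#' Load an RDF graph from a file or string
#'
#' @param source a file path, or RDF text when \code{text = TRUE}.
#' @param dialect \code{"turtle"} or \code{"rdfxml"}; when missing it is
#'   inferred from the file extension (\code{.ttl}/\code{.n3} vs
#'   \code{.rdf}/\code{.owl}/\code{.xml}), defaulting to Turtle.
#' @param blankNodes blank-node policy; see \code{\link{parseTurtle}}.
#' @param text logical: treat \code{source} as document text rather than a
#'   path.
#' @return an \code{RDFGraph}.
#' @examples
#' g <- loadGraph("@prefix ex: <http://ex.org/> . ex:s ex:p ex:o .",
#'                text = TRUE)
#' graphSize(g)
#' @export
loadGraph <- function(source, dialect = NULL,
                      blankNodes = c("reject", "skolemize"), text = FALSE) {
  blankNodes <- match.arg(blankNodes)
  if (is.null(dialect)) {
    dialect <- if (!text && grepl("\\.(rdf|owl|xml)$", source, ignore.case = TRUE))
      "rdfxml" else "turtle"
  }
  dialect <- match.arg(dialect, c("turtle", "rdfxml"))
  if (!text) {
    if (!file.exists(source))
      stop(sprintf("no such file: %s", source), call. = FALSE)
    source <- readChar(source, file.size(source), useBytes = TRUE)
    Encoding(source) <- "UTF-8"
  }
  switch(dialect,
         turtle = parseTurtle(source, blankNodes = blankNodes),
         rdfxml = parseRdfXml(source, blankNodes = blankNodes))
}

#' Save an RDF graph
#'
#' @param g an \code{RDFGraph}.
#' @param path output file path.
#' @param dialect \code{"turtle"} (default) or \code{"rdfxml"}; inferred from
#'   the extension when missing.
#' @param prefixes prefix map for Turtle output.
#' @return invisibly, the serialized text.
#' @export
saveGraph <- function(g, path, dialect = NULL, prefixes = STANDARD_PREFIXES) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.(rdf|owl|xml)$", path, ignore.case = TRUE))
      "rdfxml" else "turtle"
  }
  dialect <- match.arg(dialect, c("turtle", "rdfxml"))
  switch(dialect,
         turtle = writeTurtle(g, path, prefixes = prefixes),
         rdfxml = writeRdfXml(g, path))
}
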