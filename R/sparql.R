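## SPARQL 1.1 SELECT subset: PREFIX declarations, SELECT [DISTINCT]
## (vars | *), a single optional FROM, and a WHERE block of basic graph
## patterns plus FILTER expressions (comparisons, arithmetic-free, with
## && || ! and parentheses).  Unsupported query forms (OPTIONAL, UNION,
## GRAPH, subqueries, ...) raise an error naming the feature.  Evaluation is
## plain pattern matching over one graph: no services, no inference.

.SPARQL_TOKEN_RE <- paste0(
  "(?:",
  "<[^<>\"{}|^`\\\\\\x00-\\x20]*>",          # IRIREF
  "|\"(?:[^\"\\\\\\n]|\\\\.)*\"",            # string
  "|#[^\\n]*",                               # comment
  "|\\?[A-Za-z_][A-Za-z0-9_]*",              # variable
  "|\\^\\^",                                 # datatype marker
  "|(?:[A-Za-z_][A-Za-z0-9_.-]*)?:(?:[A-Za-z0-9_%](?:[A-Za-z0-9_.%-]*",
  "[A-Za-z0-9_%-])?)?",                      # prefixed name
  "|[+-]?(?:\\d+\\.\\d+|\\.\\d+|\\d+)(?:[eE][+-]?\\d+)?",  # number
  "|[A-Za-z][A-Za-z0-9_]*",                  # keyword / bare word
  "|&&|\\|\\||!=|<=|>=|[=<>!*]",             # operators
  "|[{}().;,]",                              # punctuation
  ")")

.sparqlTokenize <- function(text) {
  m <- gregexpr(.SPARQL_TOKEN_RE, text, perl = TRUE)[[1]]
  if (m[1] == -1L) stop("malformed SPARQL query: no tokens", call. = FALSE)
  starts <- as.integer(m); lens <- attr(m, "match.length")
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(starts)) covered[starts[i] + seq_len(lens[i]) - 1L] <- TRUE
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  stray <- which(!covered & !(chars %in% c(" ", "\t", "\r", "\n")))
  if (length(stray)) {
    line <- sum(chars[seq_len(stray[1])] == "\n") + 1L
    stop(sprintf("malformed SPARQL query at line %d: unexpected character '%s'",
                 line, chars[stray[1]]), call. = FALSE)
  }
  toks <- substring(text, starts, starts + lens - 1L)
  keep <- !startsWith(toks, "#")
  lines <- findInterval(starts, c(0L, which(chars == "\n")))
  list(tok = toks[keep], line = lines[keep])
}

.spState <- function(tokens) {
  e <- new.env(parent = emptyenv())
  e$tok <- tokens$tok; e$line <- tokens$line; e$i <- 1L
  e$prefixes <- list()
  e
}
.spPeek <- function(st, ahead = 0L) {
  j <- st$i + ahead
  if (j <= length(st$tok)) st$tok[j] else NA_character_
}
.spNext <- function(st) {
  t <- .spPeek(st)
  if (is.na(t)) stop("malformed SPARQL query: unexpected end of input",
                     call. = FALSE)
  st$i <- st$i + 1L
  t
}
.spErr <- function(st, msg) {
  ln <- if (st$i <= length(st$line)) st$line[st$i] else
    st$line[length(st$line)]
  stop(sprintf("malformed SPARQL query at line %d: %s", ln, msg),
       call. = FALSE)
}
.spKw <- function(t, kw) !is.na(t) && toupper(t) == kw

.spResolvePName <- function(st, tok) {
  colon <- regexpr(":", tok, fixed = TRUE)
  pfx <- substr(tok, 1L, colon - 1L)
  ns <- st$prefixes[[pfx]]
  if (is.null(ns)) .spErr(st, sprintf("undeclared prefix '%s:'", pfx))
  paste0(ns, substr(tok, colon + 1L, nchar(tok)))
}

## a term: list(kind = "var"/"iri"/"lit", value, dt)
.spTerm <- function(st, position) {
  t <- .spNext(st)
  if (startsWith(t, "?"))
    return(list(kind = "var", value = substr(t, 2L, nchar(t))))
  if (startsWith(t, "<"))
    return(list(kind = "iri", value = substr(t, 2L, nchar(t) - 1L)))
  if (identical(t, "a") && position == "p")
    return(list(kind = "iri", value = RDF_TYPE))
  if (startsWith(t, "\"")) {
    lex <- .ttlUnescape(substr(t, 2L, nchar(t) - 1L))
    if (identical(.spPeek(st), "^^")) {
      .spNext(st)
      dtok <- .spNext(st)
      dt <- if (startsWith(dtok, "<")) substr(dtok, 2L, nchar(dtok) - 1L) else
        .spResolvePName(st, dtok)
      return(list(kind = "lit", value = lex, dt = dt))
    }
    return(list(kind = "lit", value = lex, dt = XSD_STRING))
  }
  if (grepl("^[+-]?(\\d+\\.\\d+|\\.\\d+|\\d+)([eE][+-]?\\d+)?$", t)) {
    dt <- if (grepl("[eE]", t)) XSD_DOUBLE else
      if (grepl("\\.", t)) XSD_DECIMAL else XSD_INTEGER
    return(list(kind = "lit", value = t, dt = dt))
  }
  if (t %in% c("true", "false"))
    return(list(kind = "lit", value = t, dt = XSD_BOOLEAN))
  if (grepl("^(?:[A-Za-z_][A-Za-z0-9_.-]*)?:", t))
    return(list(kind = "iri", value = .spResolvePName(st, t)))
  .spErr(st, sprintf("unexpected token '%s' in %s position", t, position))
}

## FILTER expression grammar: or <- and ('||' and)* ; and <- not ('&&' not)*;
## not <- '!' not | rel ; rel <- prim (cmp prim)? ; prim <- '(' or ')' | term
.spFilterExpr <- function(st) {
  parseOr <- function() {
    l <- parseAnd()
    while (identical(.spPeek(st), "||")) { .spNext(st); l <- list(op = "||", l = l, r = parseAnd()) }
    l
  }
  parseAnd <- function() {
    l <- parseNot()
    while (identical(.spPeek(st), "&&")) { .spNext(st); l <- list(op = "&&", l = l, r = parseNot()) }
    l
  }
  parseNot <- function() {
    if (identical(.spPeek(st), "!")) { .spNext(st); return(list(op = "!", l = parseNot())) }
    parseRel()
  }
  parseRel <- function() {
    l <- parsePrim()
    nxt <- .spPeek(st)
    if (!is.na(nxt) && nxt %in% c("=", "!=", "<", ">", "<=", ">=")) {
      .spNext(st)
      return(list(op = nxt, l = l, r = parsePrim()))
    }
    l
  }
  parsePrim <- function() {
    if (identical(.spPeek(st), "(")) {
      .spNext(st)
      e <- parseOr()
      if (!identical(.spNext(st), ")")) .spErr(st, "expected ')' in FILTER")
      return(e)
    }
    nxt <- .spPeek(st)
    if (!is.na(nxt) && grepl("^[A-Za-z]", nxt) && identical(.spPeek(st, 1L), "("))
      .spErr(st, sprintf("FILTER function '%s' is not supported", nxt))
    list(op = "term", term = .spTerm(st, "filter"))
  }
  parseOr()
}

.UNSUPPORTED_KEYWORDS <- c("OPTIONAL", "UNION", "GRAPH", "MINUS", "BIND",
                           "VALUES", "SERVICE", "EXISTS")

#' Parse a SPARQL SELECT query
#'
#' @param query SPARQL SELECT text.
#' @return a parsed query object (list with elements \code{vars},
#'   \code{distinct}, \code{from}, \code{patterns}, \code{filters},
#'   \code{prefixes}, \code{text}), class \code{"sparqlQuery"}.
#' @export
parseSparql <- function(query) {
  st <- .spState(.sparqlTokenize(query))
  while (.spKw(.spPeek(st), "PREFIX")) {
    .spNext(st)
    pn <- .spNext(st)
    if (!endsWith(pn, ":")) .spErr(st, "expected 'prefix:' after PREFIX")
    iriTok <- .spNext(st)
    if (!startsWith(iriTok, "<")) .spErr(st, "expected IRI in PREFIX")
    st$prefixes[[substr(pn, 1L, nchar(pn) - 1L)]] <-
      substr(iriTok, 2L, nchar(iriTok) - 1L)
  }
  if (!.spKw(.spNext(st), "SELECT")) .spErr(st, "only SELECT queries are supported")
  distinct <- FALSE
  if (.spKw(.spPeek(st), "DISTINCT")) { .spNext(st); distinct <- TRUE }
  vars <- character(0)
  star <- FALSE
  repeat {
    t <- .spPeek(st)
    if (identical(t, "*")) { .spNext(st); star <- TRUE; next }
    if (!is.na(t) && startsWith(t, "?")) {
      vars <- c(vars, substr(.spNext(st), 2L, nchar(t)))
      next
    }
    break
  }
  if (!star && length(vars) == 0L) .spErr(st, "SELECT needs variables or *")
  from <- NA_character_
  if (.spKw(.spPeek(st), "FROM")) {
    .spNext(st)
    iriTok <- .spNext(st)
    if (!startsWith(iriTok, "<")) .spErr(st, "expected IRI after FROM")
    from <- substr(iriTok, 2L, nchar(iriTok) - 1L)
    if (.spKw(.spPeek(st), "FROM"))
      .spErr(st, "multiple FROM clauses are not supported")
  }
  if (.spKw(.spPeek(st), "WHERE")) .spNext(st)
  if (!identical(.spNext(st), "{")) .spErr(st, "expected '{' to open WHERE")
  patterns <- list()
  filters <- list()
  repeat {
    t <- .spPeek(st)
    if (is.na(t)) .spErr(st, "unterminated WHERE block")
    if (identical(t, "}")) { .spNext(st); break }
    if (toupper(t) %in% .UNSUPPORTED_KEYWORDS)
      .spErr(st, sprintf("%s is not supported", toupper(t)))
    if (.spKw(t, "FILTER")) {
      .spNext(st)
      if (!identical(.spNext(st), "(")) .spErr(st, "expected '(' after FILTER")
      filters[[length(filters) + 1L]] <- .spFilterExpr(st)
      if (!identical(.spNext(st), ")")) .spErr(st, "expected ')' after FILTER")
      if (identical(.spPeek(st), ".")) .spNext(st)
      next
    }
    s <- .spTerm(st, "s")
    p <- .spTerm(st, "p")
    o <- .spTerm(st, "o")
    patterns[[length(patterns) + 1L]] <- list(s = s, p = p, o = o)
    if (identical(.spPeek(st), ".")) .spNext(st)
  }
  patVars <- unique(unlist(lapply(patterns, function(pt)
    vapply(Filter(function(tm) tm$kind == "var", pt), `[[`, character(1),
           "value"))))
  if (star) vars <- patVars
  structure(list(vars = vars, distinct = distinct, from = from,
                 patterns = patterns, filters = filters,
                 prefixes = st$prefixes, text = query),
            class = "sparqlQuery")
}

## encoded binding values: IRIs verbatim; literals \x01 dt \x01 lexical
.encodeLit <- function(lex, dt) paste0("\x01", dt, "\x01", lex)
.isEncodedLit <- function(x) startsWith(x, "\x01")
.decodeLexical <- function(x) sub("^\x01[^\x01]*\x01", "", x)
.decodeDatatype <- function(x) {
  ifelse(.isEncodedLit(x), sub("^\x01([^\x01]*)\x01.*$", "\\1", x),
         NA_character_)
}

## rows of g matching one pattern -> data.frame of encoded var bindings
.matchPattern <- function(df, pat) {
  keep <- rep(TRUE, nrow(df))
  for (pos in c("s", "p", "o")) {
    tm <- pat[[pos]]
    if (tm$kind == "var") next
    col <- df[[pos]]
    if (pos %in% c("s", "p")) {
      if (tm$kind != "iri") return(NULL)
      keep <- keep & col == tm$value
    } else if (tm$kind == "iri") {
      keep <- keep & df$ot == "iri" & col == tm$value
    } else { # literal object term
      if (tm$dt %in% XSD_NUMERIC_TYPES) {
        v <- as.numeric(tm$value)
        keep <- keep & df$ot == "lit" &
          !is.na(.literalNumeric(df$o, df$dt)) &
          .literalNumeric(df$o, df$dt) == v
      } else {
        keep <- keep & df$ot == "lit" & col == tm$value & df$dt == tm$dt
      }
    }
  }
  sub <- df[keep, , drop = FALSE]
  posValue <- function(pos) {
    if (pos == "o") ifelse(sub$ot == "lit", .encodeLit(sub$o, sub$dt), sub$o)
    else sub[[pos]]
  }
  varPos <- list()
  for (pos in c("s", "p", "o")) {
    tm <- pat[[pos]]
    if (tm$kind == "var") varPos[[tm$value]] <- c(varPos[[tm$value]], pos)
  }
  ## repeated variable within one pattern: enforce equality across positions
  for (v in names(varPos)) {
    ps <- varPos[[v]]
    if (length(ps) > 1L) {
      eq <- rep(TRUE, nrow(sub))
      for (k in seq_along(ps)[-1L]) eq <- eq & posValue(ps[1L]) == posValue(ps[k])
      sub <- sub[eq, , drop = FALSE]
    }
  }
  if (length(varPos) == 0L) {
    ## fully concrete pattern: matched (one empty mapping) or not (none)
    return(data.frame(row.names = seq_len(as.integer(nrow(sub) > 0L))))
  }
  cols <- lapply(varPos, function(ps) posValue(ps[1L]))
  as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
}

.filterValue <- function(term, bindings) {
  n <- nrow(bindings)
  if (term$kind == "var") {
    if (!term$value %in% names(bindings))
      return(rep(NA_character_, n))
    return(bindings[[term$value]])
  }
  if (term$kind == "iri") return(rep(term$value, n))
  rep(.encodeLit(term$value, term$dt), n)
}

.evalFilter <- function(expr, bindings) {
  n <- nrow(bindings)
  if (identical(expr$op, "term")) {
    v <- .filterValue(expr$term, bindings)
    lex <- .decodeLexical(v)
    return(tolower(lex) == "true")
  }
  if (expr$op == "!") return(!.evalFilter(expr$l, bindings))
  if (expr$op %in% c("&&", "||")) {
    l <- .evalFilter(expr$l, bindings)
    r <- .evalFilter(expr$r, bindings)
    return(if (expr$op == "&&") l & r else l | r)
  }
  ## comparison: numeric when both sides are numeric literals, else string
  operand <- function(node) {
    if (identical(node$op, "term")) return(.filterValue(node$term, bindings))
    stop("malformed SPARQL query: boolean operand in comparison",
         call. = FALSE)
  }
  lv <- operand(expr$l)
  rv <- operand(expr$r)
  ldt <- .decodeDatatype(lv); rdt <- .decodeDatatype(rv)
  lnum <- !is.na(ldt) & ldt %in% XSD_NUMERIC_TYPES
  rnum <- !is.na(rdt) & rdt %in% XSD_NUMERIC_TYPES
  num <- lnum & rnum
  ln <- suppressWarnings(as.numeric(.decodeLexical(lv)))
  rn <- suppressWarnings(as.numeric(.decodeLexical(rv)))
  ls <- .decodeLexical(lv); rs <- .decodeLexical(rv)
  op <- switch(expr$op, "=" = `==`, "!=" = `!=`, "<" = `<`, ">" = `>`,
               "<=" = `<=`, ">=" = `>=`)
  out <- ifelse(num, op(ln, rn), op(ls, rs))
  out & !is.na(out)
}

#' Evaluate a SPARQL SELECT query over one graph
#'
#' Standard basic-graph-pattern evaluation over the given graph only: no
#' service invocation, no reasoning.  Row order is unspecified; compare
#' results as multisets.  A \code{FROM} clause is resolved against the
#' \code{from} argument (a named list of graphs keyed by document IRI) when
#' an entry exists, otherwise the passed graph is used as the named dataset
#' (documents are never dereferenced remotely).
#'
#' @param g an \code{RDFGraph}.
#' @param query SPARQL SELECT text or a parsed query from
#'   \code{\link{parseSparql}}.
#' @param from named list of \code{RDFGraph}, document IRI -> graph.
#' @return data.frame with one column per selected variable; IRI bindings
#'   are IRI strings, literal bindings their lexical forms.
#' @examples
#' g <- addTriple(emptyGraph(), "http://ex.org/s",
#'                paste0("http://www.w3.org/1999/02/22-rdf-syntax-ns#type"),
#'                "http://ex.org/C")
#' evaluateSparql(g, "SELECT ?s WHERE { ?s a <http://ex.org/C> }")
#' @export
evaluateSparql <- function(g, query, from = list()) {
  stopifnot(is(g, "RDFGraph"))
  q <- if (inherits(query, "sparqlQuery")) query else parseSparql(query)
  if (!is.na(q$from) && q$from %in% names(from)) g <- from[[q$from]]
  df <- g@triples
  bindings <- NULL
  for (pat in q$patterns) {
    b <- .matchPattern(df, pat)
    if (is.null(b)) { bindings <- data.frame(); break }
    bindings <- if (is.null(bindings)) b else {
      shared <- intersect(names(bindings), names(b))
      merge(bindings, b, by = shared)
    }
    if (nrow(bindings) == 0L) break
  }
  if (is.null(bindings))
    bindings <- data.frame(row.names = 1L) # zero patterns: one empty row
  for (f in q$filters) {
    if (nrow(bindings) == 0L) break
    bindings <- bindings[.evalFilter(f, bindings), , drop = FALSE]
  }
  out <- data.frame(row.names = seq_len(nrow(bindings)))
  for (v in q$vars) {
    col <- if (v %in% names(bindings)) bindings[[v]] else
      rep(NA_character_, nrow(bindings))
    out[[v]] <- .decodeLexical(col)
  }
  if (q$distinct) out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Write a bindings table as SPARQL-results CSV
#'
#' @param bindings data.frame as returned by \code{\link{evaluateSparql}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeBindingsCsv <- function(bindings, path) {
  utils::write.csv(bindings, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
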