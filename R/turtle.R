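## Turtle reader/writer.
##
## Supported grammar: @prefix/PREFIX and @base/BASE directives, IRIREFs,
## prefixed names, 'a', typed/plain/language-tagged string literals, numeric
## and boolean shorthand, predicate-object lists (';', ','), blank nodes
## ('_:label', '[ ... ]') and collections ('( ... )').  Blank nodes are
## rejected by default (instance data must name its subjects so the same-URI
## service contract is checkable) or skolemized to stable urn:bnode: IRIs for
## ontology documents.  Language tags are accepted and stored as xsd:string.

.TTL_TOKEN_RE <- paste0(
  "(?:",
  "<[^<>\"{}|^`\\\\\\x00-\\x20]*>",          # IRIREF
  "|\"\"\"(?s:.*?)\"\"\"",                   # long string
  "|\"(?:[^\"\\\\\\n]|\\\\.)*\"",            # string
  "|#[^\\n]*",                               # comment
  "|@prefix|@base",                          # directives
  "|@[A-Za-z]+(?:-[A-Za-z0-9]+)*",           # language tag
  "|\\^\\^",                                 # datatype marker
  "|_:[A-Za-z0-9_]+",                        # labelled blank node
  "|(?:[A-Za-z_][A-Za-z0-9_.-]*)?:(?:[A-Za-z0-9_%](?:[A-Za-z0-9_.%-]*",
  "[A-Za-z0-9_%-])?)?",                      # prefixed name
  "|[+-]?(?:\\d+\\.\\d+|\\.\\d+|\\d+)(?:[eE][+-]?\\d+)?",  # number
  "|[A-Za-z][A-Za-z0-9]*",                   # bare word (a, true, PREFIX...)
  "|[][().;,]",                              # punctuation
  ")")

.ttlTokenize <- function(text) {
  if (!nzchar(text)) return(list(tok = character(0), line = integer(0)))
  m <- gregexpr(.TTL_TOKEN_RE, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    starts <- integer(0); lens <- integer(0)
  } else {
    starts <- as.integer(m); lens <- attr(m, "match.length")
  }
  ## everything between tokens must be whitespace
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(starts)) covered[starts[i] + seq_len(lens[i]) - 1L] <- TRUE
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  stray <- which(!covered & !(chars %in% c(" ", "\t", "\r", "\n")))
  if (length(stray)) {
    line <- sum(chars[seq_len(stray[1])] == "\n") + 1L
    stop(sprintf("Turtle parse failure at line %d: unexpected character '%s'",
                 line, chars[stray[1]]), call. = FALSE)
  }
  toks <- substring(text, starts, starts + lens - 1L)
  keep <- !startsWith(toks, "#")
  lines <- findInterval(starts, c(0L, which(chars == "\n"))) # 1-based line no.
  list(tok = toks[keep], line = lines[keep])
}

.ttlUnescape <- function(s) {
  if (!grepl("\\", s, fixed = TRUE)) return(s)
  out <- character(0)
  i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "\\" && i < n) {
      nx <- substr(s, i + 1L, i + 1L)
      rep <- switch(nx, n = "\n", t = "\t", r = "\r", b = "\b", f = "\f",
                    `"` = "\"", `'` = "'", `\\` = "\\", u = NA, U = NA, nx)
      if (is.na(rep)) {
        width <- if (nx == "u") 4L else 8L
        hex <- substr(s, i + 2L, i + 1L + width)
        rep <- intToUtf8(strtoi(hex, 16L))
        i <- i + 2L + width
      } else i <- i + 2L
      out <- c(out, rep)
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  paste0(out, collapse = "")
}

.ttlEscape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  gsub("\t", "\\t", s, fixed = TRUE)
}

## parser state: mutable environment
.ttlState <- function(tokens, blankNodes) {
  e <- new.env(parent = emptyenv())
  e$tok <- tokens$tok; e$line <- tokens$line; e$i <- 1L
  e$prefixes <- list(); e$base <- NULL
  e$bnodeN <- 0L; e$blankNodes <- blankNodes
  e$rows <- vector("list", 0L)
  e
}

.ttlPeek <- function(st) if (st$i <= length(st$tok)) st$tok[st$i] else NA_character_
.ttlNext <- function(st) {
  t <- .ttlPeek(st)
  if (is.na(t)) stop("Turtle parse failure: unexpected end of document",
                     call. = FALSE)
  st$i <- st$i + 1L
  t
}
.ttlErr <- function(st, msg) {
  ln <- if (st$i <= length(st$line)) st$line[st$i] else
    st$line[length(st$line)]
  stop(sprintf("Turtle parse failure at line %d: %s", ln, msg), call. = FALSE)
}
.ttlExpect <- function(st, what) {
  t <- .ttlNext(st)
  if (!identical(t, what)) .ttlErr(st, sprintf("expected '%s', got '%s'", what, t))
  t
}

.ttlResolveIri <- function(st, tok) {
  iri <- substr(tok, 2L, nchar(tok) - 1L)
  iri <- .ttlUnescape(iri)
  if (!isAbsoluteIri(iri)) {
    if (is.null(st$base))
      .ttlErr(st, sprintf("relative IRI <%s> with no @base", iri))
    iri <- paste0(st$base, iri)
  }
  iri
}

.ttlResolvePName <- function(st, tok) {
  colon <- regexpr(":", tok, fixed = TRUE)
  pfx <- substr(tok, 1L, colon - 1L)
  loc <- substr(tok, colon + 1L, nchar(tok))
  ns <- st$prefixes[[pfx]]
  if (is.null(ns)) .ttlErr(st, sprintf("undeclared prefix '%s:'", pfx))
  paste0(ns, gsub("%([0-9A-Fa-f]{2})", "\\1", loc)) # %-escapes kept literal
}

.ttlBlank <- function(st, label = NULL) {
  if (identical(st$blankNodes, "reject"))
    .ttlErr(st, paste("blank node encountered; instance data must use named",
                      "subjects (load ontology documents with",
                      "blankNodes = \"skolemize\")"))
  if (is.null(label)) {
    st$bnodeN <- st$bnodeN + 1L
    paste0("urn:bnode:gen", st$bnodeN)
  } else paste0("urn:bnode:", label)
}

.ttlEmit <- function(st, s, p, o, ot, dt) {
  st$rows[[length(st$rows) + 1L]] <- list(s = s, p = p, o = o, ot = ot, dt = dt)
}

.isIriRef  <- function(t) !is.na(t) && startsWith(t, "<")
.isPName   <- function(t) !is.na(t) && grepl("^(?:[A-Za-z_][A-Za-z0-9_.-]*)?:", t)
.isString  <- function(t) !is.na(t) && startsWith(t, "\"")
.isBlankL  <- function(t) !is.na(t) && startsWith(t, "_:")
.isNumber  <- function(t) !is.na(t) &&
  grepl("^[+-]?(\\d+\\.\\d+|\\.\\d+|\\d+)([eE][+-]?\\d+)?$", t)

## returns list(kind = "iri"/"lit", value, dt)
.ttlObject <- function(st) {
  t <- .ttlNext(st)
  if (.isIriRef(t)) return(list(kind = "iri", value = .ttlResolveIri(st, t)))
  if (identical(t, "a")) .ttlErr(st, "'a' is only valid in predicate position")
  if (identical(t, "true") || identical(t, "false"))
    return(list(kind = "lit", value = t, dt = XSD_BOOLEAN))
  if (.isBlankL(t)) return(list(kind = "iri", value = .ttlBlank(st, substr(t, 3L, nchar(t)))))
  if (identical(t, "[")) {
    node <- .ttlBlank(st)
    if (!identical(.ttlPeek(st), "]")) .ttlPredicateObjectList(st, node)
    .ttlExpect(st, "]")
    return(list(kind = "iri", value = node))
  }
  if (identical(t, "(")) {
    items <- list()
    while (!identical(.ttlPeek(st), ")")) items[[length(items) + 1L]] <- .ttlObject(st)
    .ttlExpect(st, ")")
    if (length(items) == 0L) return(list(kind = "iri", value = RDF_NIL))
    nodes <- vapply(seq_along(items), function(i) .ttlBlank(st), character(1))
    for (i in seq_along(items)) {
      it <- items[[i]]
      .ttlEmit(st, nodes[i], RDF_FIRST, it$value, it$kind,
               if (it$kind == "lit") it$dt else NA_character_)
      .ttlEmit(st, nodes[i], RDF_REST,
               if (i < length(items)) nodes[i + 1L] else RDF_NIL,
               "iri", NA_character_)
    }
    return(list(kind = "iri", value = nodes[1L]))
  }
  if (.isString(t)) {
    body <- if (startsWith(t, "\"\"\"")) substr(t, 4L, nchar(t) - 3L) else
      substr(t, 2L, nchar(t) - 1L)
    lex <- .ttlUnescape(body)
    nxt <- .ttlPeek(st)
    if (identical(nxt, "^^")) {
      .ttlNext(st)
      dtok <- .ttlNext(st)
      dt <- if (.isIriRef(dtok)) .ttlResolveIri(st, dtok) else
        if (.isPName(dtok)) .ttlResolvePName(st, dtok) else
          .ttlErr(st, "expected datatype IRI after '^^'")
      return(list(kind = "lit", value = lex, dt = dt))
    }
    if (!is.na(nxt) && grepl("^@[A-Za-z]", nxt) &&
        !nxt %in% c("@prefix", "@base")) {
      .ttlNext(st) # language tag accepted, stored as xsd:string
      return(list(kind = "lit", value = lex, dt = XSD_STRING))
    }
    return(list(kind = "lit", value = lex, dt = XSD_STRING))
  }
  if (.isNumber(t)) {
    dt <- if (grepl("[eE]", t)) XSD_DOUBLE else
      if (grepl("\\.", t)) XSD_DECIMAL else XSD_INTEGER
    return(list(kind = "lit", value = t, dt = dt))
  }
  if (.isPName(t)) return(list(kind = "iri", value = .ttlResolvePName(st, t)))
  .ttlErr(st, sprintf("unexpected token '%s' in object position", t))
}

.ttlVerb <- function(st) {
  t <- .ttlNext(st)
  if (identical(t, "a")) return(RDF_TYPE)
  if (.isIriRef(t)) return(.ttlResolveIri(st, t))
  if (.isPName(t)) return(.ttlResolvePName(st, t))
  .ttlErr(st, sprintf("unexpected token '%s' in predicate position", t))
}

.ttlPredicateObjectList <- function(st, subject) {
  repeat {
    p <- .ttlVerb(st)
    repeat {
      o <- .ttlObject(st)
      .ttlEmit(st, subject, p, o$value, o$kind,
               if (o$kind == "lit") o$dt else NA_character_)
      if (identical(.ttlPeek(st), ",")) .ttlNext(st) else break
    }
    if (identical(.ttlPeek(st), ";")) {
      .ttlNext(st)
      ## allow trailing ';' before '.' or ']'
      if (.ttlPeek(st) %in% c(".", "]")) break
    } else break
  }
}

.ttlSubject <- function(st) {
  t <- .ttlNext(st)
  if (.isIriRef(t)) return(.ttlResolveIri(st, t))
  if (.isBlankL(t)) return(.ttlBlank(st, substr(t, 3L, nchar(t))))
  if (identical(t, "[")) {
    node <- .ttlBlank(st)
    if (!identical(.ttlPeek(st), "]")) .ttlPredicateObjectList(st, node)
    .ttlExpect(st, "]")
    return(node)
  }
  if (.isPName(t)) return(.ttlResolvePName(st, t))
  .ttlErr(st, sprintf("unexpected token '%s' in subject position", t))
}

#' Parse a Turtle document
#'
#' @param text Turtle source as a single character string.
#' @param blankNodes \code{"reject"} (default: any blank node is an error,
#'   since unnamed subjects break the same-URI annotation contract) or
#'   \code{"skolemize"} (blank nodes become deterministic
#'   \code{urn:bnode:} IRIs; use for ontology documents).
#' @return an \code{RDFGraph}.
#' @export
parseTurtle <- function(text, blankNodes = c("reject", "skolemize")) {
  blankNodes <- match.arg(blankNodes)
  st <- .ttlState(.ttlTokenize(paste(text, collapse = "\n")), blankNodes)
  repeat {
    t <- .ttlPeek(st)
    if (is.na(t)) break
    if (identical(t, "@prefix") || identical(toupper(t), "PREFIX")) {
      .ttlNext(st)
      pn <- .ttlNext(st)
      if (!.isPName(pn) || !endsWith(pn, ":"))
        .ttlErr(st, "expected 'prefix:' in @prefix directive")
      iriTok <- .ttlNext(st)
      if (!.isIriRef(iriTok)) .ttlErr(st, "expected IRI in @prefix directive")
      st$prefixes[[substr(pn, 1L, nchar(pn) - 1L)]] <- .ttlResolveIri(st, iriTok)
      if (identical(.ttlPeek(st), ".")) .ttlNext(st)
      next
    }
    if (identical(t, "@base") || identical(toupper(t), "BASE")) {
      .ttlNext(st)
      iriTok <- .ttlNext(st)
      if (!.isIriRef(iriTok)) .ttlErr(st, "expected IRI in @base directive")
      st$base <- substr(iriTok, 2L, nchar(iriTok) - 1L)
      if (identical(.ttlPeek(st), ".")) .ttlNext(st)
      next
    }
    s <- .ttlSubject(st)
    .ttlPredicateObjectList(st, s)
    .ttlExpect(st, ".")
  }
  rows <- st$rows
  if (length(rows) == 0L) return(emptyGraph())
  df <- data.frame(
    s  = vapply(rows, `[[`, character(1), "s"),
    p  = vapply(rows, `[[`, character(1), "p"),
    o  = vapply(rows, `[[`, character(1), "o"),
    ot = vapply(rows, `[[`, character(1), "ot"),
    dt = vapply(rows, function(r) if (is.null(r$dt)) NA_character_ else r$dt,
                character(1)),
    stringsAsFactors = FALSE)
  .makeGraph(df)
}

#' Serialize a graph to Turtle
#'
#' Triples are written one per line in canonical sort order so equal graphs
#' always produce byte-identical documents.  IRIs are abbreviated with the
#' supplied prefixes where the local name is simple.
#'
#' @param g an \code{RDFGraph}.
#' @param path optional file path; when NULL the document is returned as a
#'   character string.
#' @param prefixes named character vector, prefix -> namespace IRI.
#' @return the Turtle text, invisibly when written to a file.
#' @export
writeTurtle <- function(g, path = NULL, prefixes = STANDARD_PREFIXES) {
  stopifnot(is(g, "RDFGraph"))
  prefixes <- prefixes[!duplicated(names(prefixes))]
  ## longest namespace first so the most specific prefix wins
  prefixes <- prefixes[order(nchar(prefixes), decreasing = TRUE)]
  abbrev <- function(iri) {
    for (i in seq_along(prefixes)) {
      ns <- prefixes[[i]]
      if (startsWith(iri, ns)) {
        loc <- substr(iri, nchar(ns) + 1L, nchar(iri))
        if (grepl("^[A-Za-z_][A-Za-z0-9_-]*$", loc))
          return(paste0(names(prefixes)[i], ":", loc))
      }
    }
    paste0("<", iri, ">")
  }
  df <- g@triples
  lines <- c(
    sprintf("@prefix %s: <%s> .", names(prefixes), unname(prefixes)),
    ""
  )
  if (nrow(df)) {
    ss <- vapply(df$s, abbrev, character(1), USE.NAMES = FALSE)
    ps <- vapply(df$p, abbrev, character(1), USE.NAMES = FALSE)
    ps[df$p == RDF_TYPE] <- "a"
    os <- character(nrow(df))
    isIriO <- df$ot == "iri"
    os[isIriO] <- vapply(df$o[isIriO], abbrev, character(1), USE.NAMES = FALSE)
    lit <- which(!isIriO)
    if (length(lit)) {
      dtTok <- vapply(df$dt[lit], abbrev, character(1), USE.NAMES = FALSE)
      lex <- vapply(df$o[lit], .ttlEscape, character(1), USE.NAMES = FALSE)
      os[lit] <- ifelse(df$dt[lit] == XSD_STRING,
                        sprintf("\"%s\"", lex),
                        sprintf("\"%s\"^^%s", lex, dtTok))
    }
    lines <- c(lines, sprintf("%s %s %s .", ss, ps, os))
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(text), con)
    return(invisible(text))
  }
  text
}
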