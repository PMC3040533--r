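# Independent oracles the implementation is checked against.
#
# - bruteJoin(): nested-loop SPARQL BGP join over all triple assignments.
# - oracleMemberships(): set-based (denotational) model checker computing
#   class extensions bottom-up by Kleene iteration — a different algorithm
#   from the package's top-down entailment.
# - bruteMaterialize(): invoke every registered service on every eligible
#   subject to fixpoint, then classify; the fully materialized graph.
# - oracleOlsSlope(): stats::lm, independent of olsFit.

XSD <- "http://www.w3.org/2001/XMLSchema#"
RDFNS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
rdfType <- paste0(RDFNS, "type")

# ---- brute-force SPARQL join ------------------------------------------------

# patterns: list of list(s, p, o) terms as parseSparql produces.
# Returns a data.frame of variable bindings (term strings: IRIs verbatim,
# literal lexical forms), one row per solution, duplicates preserved.
bruteJoin <- function(g, patterns) {
  df <- graphTriples(g)
  n <- nrow(df)
  termMatches <- function(tm, pos, row) {
    if (tm$kind == "var") return(TRUE)
    if (pos != "o") return(tm$kind == "iri" && df[[pos]][row] == tm$value)
    if (tm$kind == "iri") return(df$ot[row] == "iri" && df$o[row] == tm$value)
    if (df$ot[row] != "lit") return(FALSE)
    numeric <- tm$dt %in% paste0(XSD, c("decimal", "integer", "double")) &&
      df$dt[row] %in% paste0(XSD, c("decimal", "integer", "double"))
    if (numeric) return(as.numeric(df$o[row]) == as.numeric(tm$value))
    df$o[row] == tm$value && df$dt[row] == tm$dt
  }
  termValue <- function(pos, row) {
    if (pos == "o" && df$ot[row] == "lit")
      paste0("LIT|", df$dt[row], "|", df$o[row])
    else df[[pos]][row]
  }
  solutions <- list()
  assign1 <- function(k, binding) {
    if (k > length(patterns)) {
      solutions[[length(solutions) + 1L]] <<- binding
      return(invisible())
    }
    pat <- patterns[[k]]
    for (row in seq_len(n)) {
      ok <- TRUE
      b <- binding
      for (pos in c("s", "p", "o")) {
        tm <- pat[[pos]]
        if (tm$kind == "var") {
          v <- termValue(pos, row)
          if (!is.null(b[[tm$value]])) {
            if (b[[tm$value]] != v) { ok <- FALSE; break }
          } else b[[tm$value]] <- v
        } else if (!termMatches(tm, pos, row)) { ok <- FALSE; break }
      }
      if (ok) assign1(k + 1L, b)
    }
  }
  assign1(1L, list())
  vars <- unique(unlist(lapply(patterns, function(p)
    unlist(lapply(p, function(tm) if (tm$kind == "var") tm$value)))))
  out <- as.data.frame(
    setNames(lapply(vars, function(v) vapply(solutions, function(b)
      if (is.null(b[[v]])) NA_character_ else b[[v]], character(1))), vars),
    stringsAsFactors = FALSE, optional = TRUE)
  # strip literal tagging down to lexical forms, like evaluateSparql output
  for (v in names(out)) out[[v]] <- sub("^LIT\\|[^|]*\\|", "", out[[v]])
  out
}

# multiset equality of two bindings tables over the same columns
sameBindings <- function(a, b) {
  if (nrow(a) != nrow(b)) return(FALSE)
  cols <- sort(names(a))
  if (!identical(cols, sort(names(b)))) return(FALSE)
  keyOf <- function(d) sort(do.call(paste, c(d[cols], sep = "\r")))
  identical(keyOf(a), keyOf(b))
}

# ---- set-based model checker ------------------------------------------------

oracleIndividuals <- function(g) {
  df <- graphTriples(g)
  unique(c(df$s, df$o[df$ot == "iri" & df$p != rdfType]))
}

# extension of an expression given current defined-class extensions
oracleExtension <- function(expr, g, ont, defExt) {
  df <- graphTriples(g)
  inds <- oracleIndividuals(g)
  numericTypes <- paste0(XSD, c("decimal", "integer", "double", "float"))
  if (is(expr, "NamedClass")) {
    ciri <- expr@iri
    if (ciri == paste0("http://www.w3.org/2002/07/owl#", "Thing"))
      return(inds)
    withAsserted <- unique(df$s[df$p == rdfType & df$ot == "iri" &
                                  df$o %in% subClassesOf(ont, ciri)])
    unique(c(withAsserted, defExt[[ciri]]))
  } else if (is(expr, "IntersectionOf")) {
    out <- inds
    for (m in expr@members)
      out <- intersect(out, oracleExtension(m, g, ont, defExt))
    out
  } else if (is(expr, "SomeValuesFrom")) {
    preds <- subPropertiesOf(ont, expr@property)
    rows <- df[df$p %in% preds, , drop = FALSE]
    if (is(expr@filler, "NumericRange")) {
      num <- rows$ot == "lit" & rows$dt %in% numericTypes
      vals <- suppressWarnings(as.numeric(rows$o))
      hit <- num & !is.na(vals) & inNumericRange(expr@filler, vals)
      unique(rows$s[hit])
    } else {
      fext <- oracleExtension(expr@filler, g, ont, defExt)
      unique(rows$s[rows$ot == "iri" & rows$o %in% fext])
    }
  } else if (is(expr, "HasValue")) {
    preds <- subPropertiesOf(ont, expr@property)
    rows <- df[df$p %in% preds, , drop = FALSE]
    v <- expr@value
    if (is(v, "Literal")) {
      if (v@datatype %in% numericTypes) {
        num <- rows$ot == "lit" & rows$dt %in% numericTypes
        vals <- suppressWarnings(as.numeric(rows$o))
        hit <- num & !is.na(vals) & vals == as.numeric(v@lexical)
      } else {
        hit <- rows$ot == "lit" & rows$o == v@lexical & rows$dt == v@datatype
      }
      unique(rows$s[hit])
    } else unique(rows$s[rows$ot == "iri" & rows$o == v])
  } else stop("unexpected expression type in oracle")
}

# Kleene fixpoint over defined-class extensions; returns named list,
# class IRI -> individuals (includes asserted members via NamedClass eval).
oracleDefinedExtensions <- function(g, ont) {
  defs <- ont@classDefinitions
  defExt <- setNames(vector("list", length(defs)), names(defs))
  repeat {
    nxt <- defExt
    for (ciri in names(defs)) {
      ext <- oracleExtension(defs[[ciri]], g, ont, defExt)
      asserted <- oracleExtension(namedClass(ciri), g, ont, defExt)
      nxt[[ciri]] <- unique(c(ext, asserted))
    }
    if (identical(lapply(nxt, sort), lapply(defExt, sort))) break
    defExt <- nxt
  }
  defExt
}

# all (individual, class) memberships after classification, per the oracle:
# asserted types closed under subclass axioms, plus defined-class
# extensions, themselves closed under subclass axioms, to fixpoint
oracleMemberships <- function(g, ont) {
  pairs <- function(ext) {
    do.call(rbind, c(list(data.frame(ind = character(), cls = character(),
                                     stringsAsFactors = FALSE)),
                     lapply(names(ext), function(ciri)
                       if (length(ext[[ciri]]))
                         data.frame(ind = ext[[ciri]], cls = ciri,
                                    stringsAsFactors = FALSE))))
  }
  current <- g
  repeat {
    df <- graphTriples(current)
    tdf <- df[df$p == rdfType & df$ot == "iri", , drop = FALSE]
    up <- do.call(rbind, c(
      list(data.frame(ind = character(), cls = character(),
                      stringsAsFactors = FALSE)),
      lapply(seq_len(nrow(tdf)), function(i)
        data.frame(ind = tdf$s[i], cls = superClassesOf(ont, tdf$o[i]),
                   stringsAsFactors = FALSE))))
    defExt <- oracleDefinedExtensions(current, ont)
    all <- unique(rbind(up, pairs(defExt)))
    ## re-assert and iterate: defined memberships can feed subclass closure
    g2 <- current
    tdfKeys <- paste(tdf$s, tdf$o)
    newPairs <- all[!(paste(all$ind, all$cls) %in% tdfKeys), , drop = FALSE]
    if (nrow(newPairs) == 0L) return(unique(all))
    add <- data.frame(s = newPairs$ind, p = rdfType, o = newPairs$cls,
                      ot = "iri", dt = NA_character_, stringsAsFactors = FALSE)
    current <- mergeGraphs(current, rdfGraph(add))
  }
}

oracleEntails <- function(g, ind, expr, ont) {
  defExt <- oracleDefinedExtensions(g, ont)
  ind %in% oracleExtension(expr, g, ont, defExt)
}

# ---- brute-force full materialization --------------------------------------

bruteMaterialize <- function(g, r, ont, maxRounds = 5L) {
  for (round in seq_len(maxRounds)) {
    before <- graphSize(g)
    for (iri in sort(names(r@services))) {
      s <- getService(r, iri)
      subjects <- unique(graphTriples(g)$s)
      rec <- suppressWarnings(invokeService(s, g, subjects, ont, quiet = TRUE))
      g <- mergeGraphs(g, rec@added)
    }
    g <- suppressWarnings(classifyAll(g, ont))
    if (graphSize(g) == before) break
  }
  g
}

# ---- independent OLS --------------------------------------------------------

oracleOlsFit <- function(x, y) {
  co <- stats::coef(stats::lm(y ~ x))
  list(intercept = unname(co[1]), slope = unname(co[2]))
}
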