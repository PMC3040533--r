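## Built-in instance reasoner for the positive-existential fragment:
## membership entailment for one individual, and forward-chaining
## classification of a whole graph to fixpoint.  The fragment is monotone,
## so classification only ever adds rdf:type triples.
##
## This is the package's built-in classifier; executePlan() accepts any
## drop-in replacement with the same classifyAll contract through its
## `reasoner` argument (the reasoner-adapter seam).

.reasonCtx <- function(g, ont) {
  e <- new.env(parent = emptyenv())
  e$df <- g@triples
  ## plain column vectors: the hot path avoids data.frame row subsetting
  e$S <- e$df$s; e$P <- e$df$p; e$O <- e$df$o
  e$OT <- e$df$ot; e$DT <- e$df$dt
  e$bySubj <- split(seq_along(e$S), e$S) # subject index
  e$ont <- ont
  e$warnings <- character(0)
  e$memo <- new.env(parent = emptyenv())     # (ind, class, visited) results
  e$subProps <- new.env(parent = emptyenv()) # property closure cache
  ## upward-closed asserted types per individual
  tsel <- e$P == RDF_TYPE & e$OT == "iri"
  typeSupers <- lapply(
    setNames(nm = unique(e$O[tsel])),
    function(cls) superClassesOf(ont, cls))
  e$typesUp <- lapply(split(e$O[tsel], e$S[tsel]), function(types)
    unique(unlist(typeSupers[types], use.names = FALSE)))
  e
}

.ctxSubProps <- function(ctx, p) {
  got <- ctx$subProps[[p]]
  if (is.null(got)) {
    got <- subPropertiesOf(ctx$ont, p)
    ctx$subProps[[p]] <- got
  }
  got
}

.ctxTypes <- function(ctx, ind) {
  t <- ctx$typesUp[[ind]]
  if (is.null(t)) character(0) else t
}

.entails <- function(ctx, ind, expr, visited = character(0)) {
  switch(class(expr)[1L],
  NamedClass = {
    ciri <- expr@iri
    if (ciri == OWL_THING) return(TRUE)
    if (ciri %in% .ctxTypes(ctx, ind)) return(TRUE)
    if (isDefinedClass(ctx$ont, ciri) && !(ciri %in% visited)) {
      ## memo key includes the cycle-guard context, so cached results are
      ## exact even for recursive definitions
      key <- paste(ind, ciri, paste(visited, collapse = ","), sep = "\r")
      got <- ctx$memo[[key]]
      if (!is.null(got)) return(got)
      out <- .entails(ctx, ind, ctx$ont@classDefinitions[[ciri]],
                      c(visited, ciri))
      ctx$memo[[key]] <- out
      return(out)
    }
    FALSE
  },
  IntersectionOf = {
    for (m in expr@members)
      if (!.entails(ctx, ind, m, visited)) return(FALSE)
    TRUE
  },
  SomeValuesFrom = {
    preds <- .ctxSubProps(ctx, expr@property)
    mine <- ctx$bySubj[[ind]]
    sel <- mine[ctx$P[mine] %in% preds]
    if (length(sel) == 0L) return(FALSE)
    filler <- expr@filler
    if (is(filler, "NumericRange")) {
      lit <- ctx$OT[sel] == "lit"
      numeric <- lit & ctx$DT[sel] %in% XSD_NUMERIC_TYPES
      if (any(lit & !numeric)) {
        ctx$warnings <- unique(c(ctx$warnings, sprintf(
          "non-numeric literal tested against a numeric range on <%s> (property <%s>); treated as not satisfying",
          ind, expr@property)))
      }
      vals <- suppressWarnings(as.numeric(ctx$O[sel][numeric]))
      return(any(inNumericRange(filler, vals)))
    }
    for (o in ctx$O[sel][ctx$OT[sel] == "iri"])
      if (.entails(ctx, o, filler, visited)) return(TRUE)
    FALSE
  },
  HasValue = {
    preds <- .ctxSubProps(ctx, expr@property)
    mine <- ctx$bySubj[[ind]]
    sel <- mine[ctx$P[mine] %in% preds]
    if (length(sel) == 0L) return(FALSE)
    v <- expr@value
    if (is(v, "Literal")) {
      lit <- sel[ctx$OT[sel] == "lit"]
      if (v@datatype %in% XSD_NUMERIC_TYPES) {
        num <- lit[ctx$DT[lit] %in% XSD_NUMERIC_TYPES]
        vals <- suppressWarnings(as.numeric(ctx$O[num]))
        return(any(is.finite(vals) & vals == as.numeric(v@lexical)))
      }
      return(any(ctx$O[lit] == v@lexical & ctx$DT[lit] == v@datatype))
    }
    any(ctx$OT[sel] == "iri" & ctx$O[sel] == v)
  },
  stop(sprintf("cannot test membership in a %s", class(expr)),
       call. = FALSE))
}

.flushReasonerWarnings <- function(ctx) {
  for (w in ctx$warnings) warning(w, call. = FALSE)
}

#' Does a graph entail that an individual belongs to a class expression?
#'
#' A pure function over the graph: membership requirements are checked
#' against asserted \code{rdf:type} triples closed under the subclass
#' axioms and, for defined classes, against their definitions (recursively);
#' property requirements against existing triples whose predicate is the
#' restricted property or a declared subproperty, with the filler checked
#' recursively (facet test for numeric ranges).  No service calls are made.
#' A literal of the wrong datatype tested against a numeric range counts as
#' not satisfying, with a warning.
#'
#' @param g an \code{RDFGraph} of instance data.
#' @param ind individual IRI.
#' @param expr a \code{ClassExpression} (or class IRI, resolved against
#'   \code{ont}).
#' @param ont an \code{\linkS4class{Ontology}}.
#' @return logical(1).
#' @examples
#' ex <- "http://ex.org/"
#' g <- addTriple(emptyGraph(), paste0(ex, "m"), paste0(ex, "slope"),
#'                rdfLiteral(0.5))
#' entailsMembership(g, paste0(ex, "m"),
#'                   someValuesFrom(paste0(ex, "slope"),
#'                                  numericRange(minExclusive = 0)),
#'                   ontology())
#' @export
entailsMembership <- function(g, ind, expr, ont) {
  stopifnot(is(g, "RDFGraph"), is(ont, "Ontology"))
  if (is.character(expr)) expr <- resolveClass(ont, expr)
  ctx <- .reasonCtx(g, ont)
  out <- .entails(ctx, ind, expr)
  .flushReasonerWarnings(ctx)
  out
}

#' Satisfaction of one decomposed requirement
#'
#' @param g an \code{RDFGraph}.
#' @param ind individual IRI.
#' @param req a \code{\linkS4class{Requirement}}.
#' @param ont an \code{Ontology}.
#' @return logical(1).
#' @export
satisfiesRequirement <- function(g, ind, req, ont) {
  expr <- if (is(req, "MembershipReq")) namedClass(req@classIri)
  else if (is(req, "PropertyReq")) {
    f <- req@filler
    if (is(f, "ClassExpression") || is(f, "NumericRange"))
      someValuesFrom(req@property, f)
    else hasValue(req@property, f)
  } else stop("req must be a Requirement")
  entailsMembership(g, ind, expr, ont)
}

#' Forward-chaining classification of all individuals
#'
#' Materializes entailed \code{rdf:type} triples: the subclass closure of
#' every asserted type, plus membership in every defined class where
#' \code{\link{entailsMembership}} holds, iterated to fixpoint (definitions
#' may cascade: a regression model classified as increasing makes its
#' collection elevated, which makes its patient a likely rejecter).  The
#' result always contains the input graph (monotone) and re-running on the
#' result adds nothing (idempotent).
#'
#' @param g an \code{RDFGraph} of instance data.
#' @param ont an \code{\linkS4class{Ontology}}.
#' @param maxIterations fixpoint iteration cap; exceeding it is an error
#'   (it indicates a definition cycle, which ontology validity normally
#'   rejects).
#' @return the classified \code{RDFGraph}.
#' @export
classifyAll <- function(g, ont, maxIterations = 10L) {
  stopifnot(is(g, "RDFGraph"), is(ont, "Ontology"))
  defined <- names(ont@classDefinitions)
  ## candidate narrowing: for each defined class, a primitive named conjunct
  ## (if any) restricts which individuals can possibly qualify
  carrier <- lapply(setNames(nm = defined), function(ciri) {
    reqs <- decompose(ont@classDefinitions[[ciri]])
    prim <- vapply(reqs, function(r)
      is(r, "MembershipReq") && !isDefinedClass(ont, r@classIri) &&
        r@classIri != OWL_THING, logical(1))
    if (any(prim)) vapply(reqs[prim], function(r) r@classIri, character(1))[1L]
    else NA_character_
  })
  allWarnings <- character(0)
  for (iter in seq_len(maxIterations + 1L)) {
    ctx <- .reasonCtx(g, ont)
    df <- ctx$df
    inds <- unique(df$s)
    newRows <- list()
    addType <- function(ind, cls) {
      newRows[[length(newRows) + 1L]] <<- data.frame(
        s = ind, p = RDF_TYPE, o = cls, ot = "iri", dt = NA_character_,
        stringsAsFactors = FALSE)
    }
    ## subclass closure of asserted types
    tdf <- df[df$p == RDF_TYPE & df$ot == "iri", , drop = FALSE]
    for (ind in unique(tdf$s)) {
      have <- tdf$o[tdf$s == ind]
      for (cls in setdiff(.ctxTypes(ctx, ind), have)) addType(ind, cls)
    }
    ## defined-class membership
    for (ciri in defined) {
      cands <- if (is.na(carrier[[ciri]])) unique(c(inds, graphIndividuals(g)))
      else names(ctx$typesUp)[vapply(ctx$typesUp, function(t)
        carrier[[ciri]] %in% t, logical(1))]
      expr <- ont@classDefinitions[[ciri]]
      for (ind in cands) {
        if (ciri %in% .ctxTypes(ctx, ind)) next
        if (.entails(ctx, ind, expr, visited = ciri)) addType(ind, ciri)
      }
    }
    allWarnings <- unique(c(allWarnings, ctx$warnings))
    if (length(newRows) == 0L) {
      for (w in allWarnings) warning(w, call. = FALSE)
      return(g)
    }
    if (iter > maxIterations)
      stop(sprintf(
        "classification did not reach a fixpoint within %d iterations (definition cycle?)",
        maxIterations), call. = FALSE)
    g <- .makeGraph(rbind(g@triples, do.call(rbind, newRows)))
  }
  g
}
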