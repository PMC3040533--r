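## Workflow planning: turn a class definition or a SPARQL query plus
## ontology into a concrete DAG of service invocations and reasoning steps
## — the concretization of the class-as-abstract-workflow idea.  Planning
## examines the "needs" (decomposed requirements) of each class: a need
## already present in the data resolves to `data`, a need some registered
## service can attach resolves to `service`, purely logical needs (facet
## and value checks, defined-class membership) resolve to `reasoner`, and
## anything else is surfaced as UNRESOLVED rather than silently dropped.

reasonStepLabel <- "reason"

#' Workflow step constructors
#'
#' @param service service IRI.
#' @param predicate the attached predicate the step supplies.
#' @param selector \code{ClassExpression} the target subjects must satisfy,
#'   or NULL.
#' @param typeConstraints class IRIs the query binds on the subject variable.
#' @param label step label.
#' @return a \code{WorkflowStep}.
#' @export
serviceStep <- function(service, predicate, selector = NULL,
                        typeConstraints = character(0), label = NULL) {
  if (is.null(label))
    label <- sprintf("service:%s:%s", localName(predicate), localName(service))
  new("ServiceStep", label = label, service = service, predicate = predicate,
      selector = selector, typeConstraints = typeConstraints)
}

#' @rdname serviceStep
#' @export
reasonStep <- function(label = reasonStepLabel) new("ReasonStep", label = label)

.emptyCoverage <- function() {
  data.frame(requirement = character(), context = character(),
             resolution = character(), provider = character(),
             stringsAsFactors = FALSE)
}

.newWorkflowBuilder <- function() {
  e <- new.env(parent = emptyenv())
  e$steps <- list(); e$edges <- list(); e$coverage <- list()
  e$visited <- character(0)
  e
}

.wbAddStep <- function(wb, step) {
  if (is.null(wb$steps[[step@label]])) wb$steps[[step@label]] <- step
  step@label
}

.wbAddEdge <- function(wb, from, to) {
  wb$edges[[length(wb$edges) + 1L]] <- c(from = from, to = to)
}

.wbAddCoverage <- function(wb, requirement, context, resolution, provider) {
  wb$coverage[[length(wb$coverage) + 1L]] <- data.frame(
    requirement = requirement, context = context, resolution = resolution,
    provider = provider, stringsAsFactors = FALSE)
}

.wbBuild <- function(wb) {
  edges <- if (length(wb$edges))
    unique(do.call(rbind, lapply(wb$edges, function(e)
      data.frame(from = e[["from"]], to = e[["to"]],
                 stringsAsFactors = FALSE))))
  else data.frame(from = character(), to = character(),
                  stringsAsFactors = FALSE)
  coverage <- if (length(wb$coverage)) do.call(rbind, wb$coverage) else
    .emptyCoverage()
  rownames(coverage) <- NULL
  new("Workflow", steps = wb$steps, edges = edges, coverage = coverage)
}

## --------------------------------------------------------------------------
## class planning
## --------------------------------------------------------------------------

## walk the requirements of a class definition, filling the builder.
## guarantee: classes a producing service promises for minted fillers,
## with the providing service IRIs.
.planWalkReqs <- function(wb, reqs, contextLabel, r, ont, ctx, guarantee) {
  carrierClasses <- unlist(lapply(reqs, function(q)
    if (is(q, "MembershipReq") && !isDefinedClass(ont, q@classIri) &&
        q@classIri != OWL_THING) q@classIri else character(0)))
  indsWith <- function(cls) {
    names(ctx$typesUp)[vapply(ctx$typesUp, function(t) cls %in% t, logical(1))]
  }
  candidates <- if (length(carrierClasses))
    unique(unlist(lapply(carrierClasses, indsWith)))
  else unique(ctx$df$s)

  for (q in reqs) {
    reqLabel <- renderExpression(q)
    if (is(q, "MembershipReq")) {
      C <- q@classIri
      if (C == OWL_THING) next
      if (isDefinedClass(ont, C)) {
        .wbAddCoverage(wb, reqLabel, contextLabel, "reasoner", localName(C))
        .planWalkClass(wb, C, r, ont, ctx, guarantee)
      } else if (length(indsWith(C))) {
        .wbAddCoverage(wb, reqLabel, contextLabel, "data", "")
      } else if (!is.null(guarantee) &&
                 any(C %in% superClassesOf(ont, guarantee$classes))) {
        .wbAddCoverage(wb, reqLabel, contextLabel, "service",
                       paste(guarantee$providers, collapse = " "))
      } else {
        .wbAddCoverage(wb, reqLabel, contextLabel, "UNRESOLVED", C)
      }
    } else if (is(q, "PropertyReq")) {
      f <- q@filler
      logicalFiller <- is(f, "NumericRange") || is(f, "Literal") ||
        (is.character(f) && !is(f, "ClassExpression"))
      if (logicalFiller) {
        ## facet / value restriction: a pure check for the reasoner
        .wbAddCoverage(wb, reqLabel, contextLabel, "reasoner", "")
        next
      }
      preds <- subPropertiesOf(ont, q@property)
      hasP <- unique(ctx$df$s[ctx$df$p %in% preds])
      lacking <- setdiff(candidates, hasP)
      if (length(candidates) && length(lacking) == 0L) {
        .wbAddCoverage(wb, reqLabel, contextLabel, "data", "")
        .planRecurseFiller(wb, f, contextLabel, r, ont, ctx, guarantee = NULL)
      } else {
        svcs <- findByPredicate(r, q@property)
        if (length(svcs)) {
          iris <- vapply(svcs, serviceIri, character(1))
          .wbAddCoverage(wb, reqLabel, contextLabel, "service",
                         paste(iris, collapse = " "))
          selector <- if (length(carrierClasses))
            intersectionOf(lapply(carrierClasses, namedClass)) else NULL
          for (s in svcs) {
            lab <- .wbAddStep(wb, serviceStep(s@iri, q@property, selector))
            .wbAddEdge(wb, lab, reasonStepLabel)
          }
          ## what the services promise about the minted filler values
          promised <- character(0)
          for (s in svcs) {
            outReqs <- decompose(resolveClass(ont, s@outputClass))
            for (oq in outReqs) {
              if (is(oq, "PropertyReq") &&
                  oq@property %in% subPropertiesOf(ont, q@property) &&
                  is(oq@filler, "NamedClass"))
                promised <- c(promised, oq@filler@iri)
            }
          }
          g2 <- list(classes = unique(promised), providers = iris)
          .planRecurseFiller(wb, f, contextLabel, r, ont, ctx, g2)
        } else if (length(hasP)) {
          ## partially materialized and no service: what exists is usable
          .wbAddCoverage(wb, reqLabel, contextLabel, "data", "")
          .planRecurseFiller(wb, f, contextLabel, r, ont, ctx, guarantee = NULL)
        } else {
          .wbAddCoverage(wb, reqLabel, contextLabel, "UNRESOLVED", q@property)
          ## the filler's needs are moot until the property is suppliable
        }
      }
    }
  }
}

.planRecurseFiller <- function(wb, filler, contextLabel, r, ont, ctx,
                               guarantee) {
  if (is(filler, "NamedClass")) {
    if (isDefinedClass(ont, filler@iri)) {
      .planWalkClass(wb, filler@iri, r, ont, ctx, guarantee)
    }
    ## primitive named filler membership is covered by the producing
    ## service's output guarantee (already reflected in coverage when the
    ## enclosing property resolved to a service) or by asserted types
  } else {
    .planWalkReqs(wb, decompose(filler), contextLabel, r, ont, ctx, guarantee)
  }
}

.planWalkClass <- function(wb, classIri, r, ont, ctx, guarantee = NULL) {
  if (classIri %in% wb$visited) return(invisible())
  wb$visited <- c(wb$visited, classIri)
  expr <- resolveClass(ont, classIri)
  .planWalkReqs(wb, decompose(expr), localName(classIri), r, ont, ctx,
                guarantee)
}

#' Plan the workflow concretizing a class definition
#'
#' Recursively walks the decomposed requirements of \code{classIri} and all
#' defined classes it references.  Each property requirement resolves to
#' \code{data} when instances already carry the property, otherwise to a
#' \code{ServiceStep} per discovered service (all matching services are
#' invoked; RDF merge is monotone, so union preserves completeness), and
#' otherwise surfaces as UNRESOLVED in the coverage table.  Facet and value
#' checks, and membership in defined classes, are the reasoner's job.  A
#' final \code{ReasonStep} follows every service step.
#'
#' @param classIri IRI of the (defined) class to concretize.
#' @param r a \code{ServiceRegistry}.
#' @param ont an \code{Ontology}.
#' @param g the current instance \code{RDFGraph}.
#' @return a \code{\linkS4class{Workflow}}.
#' @export
planForClass <- function(classIri, r, ont, g) {
  stopifnot(is(r, "ServiceRegistry"), is(ont, "Ontology"), is(g, "RDFGraph"))
  wb <- .newWorkflowBuilder()
  .wbAddStep(wb, reasonStep())
  ctx <- .reasonCtx(g, ont)
  .planWalkClass(wb, classIri, r, ont, ctx)
  .wbBuild(wb)
}

## --------------------------------------------------------------------------
## query planning
## --------------------------------------------------------------------------

.renderTerm <- function(tm) {
  switch(tm$kind,
         var = paste0("?", tm$value),
         iri = if (tm$value == RDF_TYPE) "rdf:type" else
           sprintf("<%s>", tm$value),
         lit = sprintf("\"%s\"", tm$value))
}

.renderPattern <- function(pat) {
  sprintf("%s %s %s .", .renderTerm(pat$s), .renderTerm(pat$p),
          .renderTerm(pat$o))
}

#' Plan the resolution of a SPARQL query
#'
#' The query is deconstructed into its triple patterns; only the basic graph
#' pattern drives planning (FILTERs are applied during final evaluation).
#' Each pattern is resolved: \code{rdf:type} patterns whose object is a
#' defined class get a class plan (the class definition acts as an abstract
#' workflow); bound-predicate patterns resolve to \code{service} when a
#' registered service attaches the predicate and instances lack it, to
#' \code{in-data} when the data already carries it, and to UNRESOLVED
#' otherwise.  In the merged workflow all class-plan service steps precede
#' the reasoning step, and predicate services run after reasoning so that
#' classification has narrowed their subjects (they are invoked only for
#' subjects bound to the pattern's variable, i.e. members of the classes the
#' query requires of it).
#'
#' @param query SPARQL SELECT text or parsed query.
#' @param r a \code{ServiceRegistry}.
#' @param ont an \code{Ontology}.
#' @param g the current instance \code{RDFGraph}.
#' @return a \code{\linkS4class{QueryPlan}}.
#' @export
planForQuery <- function(query, r, ont, g) {
  q <- if (inherits(query, "sparqlQuery")) query else parseSparql(query)
  wb <- .newWorkflowBuilder()
  .wbAddStep(wb, reasonStep())
  ctx <- .reasonCtx(g, ont)

  ## classes the query requires of each subject variable
  varTypes <- list()
  for (pat in q$patterns) {
    if (pat$s$kind == "var" && pat$p$kind == "iri" && pat$p$value == RDF_TYPE &&
        pat$o$kind == "iri")
      varTypes[[pat$s$value]] <- unique(c(varTypes[[pat$s$value]],
                                          pat$o$value))
  }

  patRows <- list()
  addPat <- function(pat, resolution, provider) {
    patRows[[length(patRows) + 1L]] <<- data.frame(
      pattern = .renderPattern(pat), resolution = resolution,
      provider = provider, stringsAsFactors = FALSE)
  }

  for (pat in q$patterns) {
    if (pat$p$kind != "iri") { addPat(pat, "in-data", ""); next }
    p <- pat$p$value
    if (p == RDF_TYPE) {
      if (pat$o$kind == "iri" && isDefinedClass(ont, pat$o$value)) {
        addPat(pat, "class-plan", pat$o$value)
        .planWalkClass(wb, pat$o$value, r, ont, ctx)
      } else {
        addPat(pat, "in-data", "")
      }
      next
    }
    preds <- subPropertiesOf(ont, p)
    hasP <- unique(ctx$df$s[ctx$df$p %in% preds])
    lackers <- setdiff(unique(ctx$df$s), hasP)
    svcs <- findByPredicate(r, p)
    if (length(svcs) && length(lackers)) {
      iris <- vapply(svcs, serviceIri, character(1))
      addPat(pat, "service", paste(iris, collapse = " "))
      tc <- if (pat$s$kind == "var") varTypes[[pat$s$value]] else NULL
      if (is.null(tc)) tc <- character(0)
      for (s in svcs) {
        lab <- .wbAddStep(wb, serviceStep(s@iri, p, selector = NULL,
                                          typeConstraints = tc))
        ## predicate services run on classification-narrowed subjects
        .wbAddEdge(wb, reasonStepLabel, lab)
      }
    } else if (length(hasP)) {
      addPat(pat, "in-data", "")
    } else if (length(svcs)) {
      addPat(pat, "service",
             paste(vapply(svcs, serviceIri, character(1)), collapse = " "))
    } else {
      addPat(pat, "UNRESOLVED", p)
      .wbAddCoverage(wb, .renderPattern(pat), "query", "UNRESOLVED", p)
    }
  }

  wf <- .wbBuild(wb)
  patterns <- if (length(patRows)) do.call(rbind, patRows) else
    data.frame(pattern = character(), resolution = character(),
               provider = character(), stringsAsFactors = FALSE)
  new("QueryPlan", query = q$text, patterns = patterns, workflow = wf)
}

#' Deterministic linearization of a workflow
#'
#' Topological order over the precedence edges, ties broken by step label,
#' so identical inputs always yield identical step sequences.
#'
#' @param wf a \code{Workflow}.
#' @return character vector of step labels.
#' @export
linearizeWorkflow <- function(wf) {
  stopifnot(is(wf, "Workflow"))
  labels <- sort(names(wf@steps))
  edges <- wf@edges
  out <- character(0)
  placed <- character(0)
  while (length(placed) < length(labels)) {
    ready <- sort(setdiff(
      labels[vapply(labels, function(l)
        all(edges$from[edges$to == l] %in% placed), logical(1))],
      placed))
    if (length(ready) == 0L)
      stop("workflow has a precedence cycle", call. = FALSE)
    nxt <- ready[1L]
    out <- c(out, nxt)
    placed <- c(placed, nxt)
  }
  out
}

#' Coverage report of a plan
#'
#' Lists every decomposed requirement and query pattern with its resolution;
#' UNRESOLVED entries carry the predicate or class that no data or service
#' supplies, so gaps are visible instead of producing silently empty
#' answers.
#'
#' @param p a \code{QueryPlan} or \code{Workflow}.
#' @return data.frame with columns \code{requirement}, \code{context},
#'   \code{resolution}, \code{provider}.
#' @export
coverageReport <- function(p) {
  if (is(p, "QueryPlan")) {
    patCov <- data.frame(requirement = p@patterns$pattern,
                         context = "query",
                         resolution = p@patterns$resolution,
                         provider = p@patterns$provider,
                         stringsAsFactors = FALSE)
    cov <- p@workflow@coverage
    ## pattern-level UNRESOLVED rows are already in the workflow coverage
    cov <- rbind(patCov[patCov$resolution != "UNRESOLVED", , drop = FALSE],
                 cov)
    rownames(cov) <- NULL
    return(cov)
  }
  if (is(p, "Workflow")) return(p@coverage)
  stop("p must be a QueryPlan or Workflow", call. = FALSE)
}

setMethod("show", "Workflow", function(object) {
  cat(sprintf("Workflow with %d step(s)\n", length(object@steps)))
  for (lab in linearizeWorkflow(object)) {
    st <- object@steps[[lab]]
    if (is(st, "ServiceStep"))
      cat(sprintf("  %s  [invoke <%s> for %s]\n", lab, st@service,
                  localName(st@predicate)))
    else cat(sprintf("  %s  [classify]\n", lab))
  }
  if (nrow(object@coverage)) {
    cat("coverage:\n")
    for (i in seq_len(nrow(object@coverage)))
      cat(sprintf("  %-55s -> %s %s\n", object@coverage$requirement[i],
                  object@coverage$resolution[i], object@coverage$provider[i]))
  }
})

setMethod("show", "QueryPlan", function(object) {
  cat("QueryPlan\n patterns:\n")
  for (i in seq_len(nrow(object@patterns)))
    cat(sprintf("  %-55s -> %s %s\n", object@patterns$pattern[i],
                object@patterns$resolution[i], object@patterns$provider[i]))
  cat(" workflow: ")
  show(object@workflow)
})
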