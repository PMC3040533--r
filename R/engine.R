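## Plan execution over the transient graph: invoke services, merge their
## annotations immediately, classify, re-plan when a service's output may
## have enabled another's input, and finally evaluate the original query
## over the materialized graph.  Every added triple is recorded in a trace,
## so the final graph is exactly the initial graph plus the recorded deltas.

.execServiceStep <- function(step, g, r, ont) {
  s <- getService(r, step@service)
  if (is.null(s))
    return(list(added = emptyGraph(), record = NULL,
                warning = sprintf("step %s: service <%s> is not registered",
                                  step@label, step@service)))
  preds <- subPropertiesOf(ont, step@predicate)
  df <- g@triples
  hasP <- unique(df$s[df$p %in% preds])
  cands <- setdiff(unique(df$s), hasP) # only subjects still lacking it
  ctx <- .reasonCtx(g, ont)
  if (length(step@typeConstraints)) {
    for (cls in step@typeConstraints) {
      expr <- namedClass(cls)
      cands <- cands[vapply(cands, function(x) .entails(ctx, x, expr),
                            logical(1))]
    }
  }
  if (!is.null(step@selector)) {
    cands <- cands[vapply(cands, function(x)
      .entails(ctx, x, step@selector), logical(1))]
  }
  ## quiet input-class pre-filter: the service itself re-checks, but the
  ## engine narrows first so batch invocation does not warn about subjects
  ## that were never intended targets
  inExpr <- resolveClass(ont, s@inputClass)
  cands <- cands[vapply(cands, function(x) .entails(ctx, x, inExpr),
                        logical(1))]
  if (length(cands) == 0L)
    return(list(added = emptyGraph(), record = NULL, warning = NULL))
  rec <- invokeService(s, g, sort(cands), ont, quiet = TRUE)
  w <- if (length(rec@failed))
    sprintf("step %s: %d subject(s) failed: %s", step@label,
            length(rec@failed),
            paste(sprintf("<%s>: %s", names(rec@failed), rec@failed),
                  collapse = "; "))
  else NULL
  list(added = graphDifference(rec@added, g), record = rec, warning = w)
}

.execWorkflowOnce <- function(wf, g, r, ont, reasoner, rounds, warnings) {
  for (lab in linearizeWorkflow(wf)) {
    step <- wf@steps[[lab]]
    if (is(step, "ServiceStep")) {
      res <- .execServiceStep(step, g, r, ont)
      if (!is.null(res$warning)) warnings <- c(warnings, res$warning)
      rounds[[length(rounds) + 1L]] <- list(
        label = lab, kind = "service", added = res$added, record = res$record)
      g <- mergeGraphs(g, res$added)
    } else {
      g2 <- suppressWarnings(reasoner(g, ont))
      delta <- graphDifference(g2, g)
      rounds[[length(rounds) + 1L]] <- list(
        label = lab, kind = "reasoner", added = delta, record = NULL)
      g <- g2
    }
  }
  list(g = g, rounds = rounds, warnings = warnings)
}

#' Execute a query plan
#'
#' Steps run in linearized order; each service step's added triples are
#' merged immediately and each reasoning step runs the classifier over the
#' whole graph.  After a pass, the query is re-planned against the enlarged
#' graph and executed again if the new pass still adds triples (a service's
#' output may have enabled another service's input), up to \code{maxRounds}
#' passes — bounded iteration approximates the fixpoint without risking
#' non-termination; the worked example needs one pass.  Per-step service
#' failures are recorded in the trace and execution continues.
#'
#' @param plan a \code{\linkS4class{QueryPlan}} (or bare \code{Workflow},
#'   executed in a single pass).
#' @param g the initial instance \code{RDFGraph}.
#' @param r a \code{ServiceRegistry}.
#' @param ont an \code{Ontology}.
#' @param maxRounds maximum design-then-execute passes (default 3).
#' @param reasoner classifier to use for \code{ReasonStep}s; any function
#'   with the \code{\link{classifyAll}} contract (the reasoner-adapter
#'   seam).
#' @return list with elements \code{graph} (the final transient graph) and
#'   \code{trace} (an \code{\linkS4class{ExecutionTrace}}).
#' @export
executePlan <- function(plan, g, r, ont, maxRounds = 3L,
                        reasoner = classifyAll) {
  stopifnot(is(g, "RDFGraph"), is(r, "ServiceRegistry"), is(ont, "Ontology"))
  initialSize <- graphSize(g)
  rounds <- list()
  warnings <- character(0)

  if (is(plan, "Workflow")) {
    res <- .execWorkflowOnce(plan, g, r, ont, reasoner, rounds, warnings)
    g <- res$g; rounds <- res$rounds; warnings <- res$warnings
  } else if (is(plan, "QueryPlan")) {
    current <- plan
    for (pass in seq_len(maxRounds)) {
      nBefore <- length(rounds)
      res <- .execWorkflowOnce(current@workflow, g, r, ont, reasoner,
                               rounds, warnings)
      g <- res$g; rounds <- res$rounds; warnings <- res$warnings
      ## a further pass can only matter if some service produced triples
      ## this pass (only service output can enable another service's input;
      ## each pass already ends with everything classified)
      svcAdded <- sum(vapply(rounds[seq(nBefore + 1L, length(rounds))],
                             function(rd) if (rd$kind == "service")
                               graphSize(rd$added) else 0L, numeric(1)))
      if (svcAdded == 0) break
      if (pass == maxRounds) {
        warnings <- c(warnings, sprintf(
          "still adding triples after %d passes; stopping (bounded re-planning)",
          maxRounds))
        break
      }
      current <- planForQuery(current@query, r, ont, g)
    }
  } else stop("plan must be a QueryPlan or Workflow", call. = FALSE)

  unresolved <- coverageReport(plan)
  unresolved <- unresolved[unresolved$resolution == "UNRESOLVED", ,
                           drop = FALSE]
  if (nrow(unresolved))
    warnings <- c(warnings, sprintf(
      "unresolved requirement: %s (no data or service supplies <%s>)",
      unresolved$requirement, unresolved$provider))

  trace <- new("ExecutionTrace", rounds = rounds, initialSize = initialSize,
               totalAdded = graphSize(g) - initialSize,
               finalSize = graphSize(g), warnings = warnings)
  for (w in warnings) warning(w, call. = FALSE)
  list(graph = g, trace = trace)
}

#' Answer a SPARQL query through service discovery and reasoning
#'
#' The full pipeline: plan the query, execute the workflow (service
#' invocations plus classification over the transient graph), then evaluate
#' the original query over the final materialized graph.  Equivalent to
#' \code{evaluateSparql(executePlan(planForQuery(q, ...), ...)$graph, q)}.
#'
#' @param query SPARQL SELECT text.
#' @param g instance \code{RDFGraph}.
#' @param r a \code{ServiceRegistry}.
#' @param ont an \code{Ontology}.
#' @param maxRounds see \code{\link{executePlan}}.
#' @param reasoner see \code{\link{executePlan}}.
#' @param from named list of graphs for FROM resolution; see
#'   \code{\link{evaluateSparql}}.
#' @return list with elements \code{bindings} (data.frame), \code{trace}
#'   (\code{ExecutionTrace}), \code{graph} (final transient graph) and
#'   \code{plan} (\code{QueryPlan}).
#' @export
answerQuery <- function(query, g, r, ont, maxRounds = 3L,
                        reasoner = classifyAll, from = list()) {
  q <- parseSparql(if (inherits(query, "sparqlQuery")) query$text else query)
  if (!is.na(q$from) && q$from %in% names(from)) g <- from[[q$from]]
  plan <- planForQuery(q, r, ont, g)
  res <- executePlan(plan, g, r, ont, maxRounds = maxRounds,
                     reasoner = reasoner)
  bindings <- evaluateSparql(res$graph, q)
  list(bindings = bindings, trace = res$trace, graph = res$graph, plan = plan)
}

#' Per-triple provenance of an execution
#'
#' Attributes every added triple to the step (service invocation or
#' reasoning round) that added it; because each round records only its
#' delta, the attribution is a partition: every added triple is attributed
#' exactly once.
#'
#' @param trace an \code{\linkS4class{ExecutionTrace}}.
#' @return data.frame with columns \code{round}, \code{step}, \code{kind},
#'   \code{s}, \code{p}, \code{o}, \code{ot}, \code{dt}.
#' @export
explainTrace <- function(trace) {
  stopifnot(is(trace, "ExecutionTrace"))
  rows <- list()
  for (i in seq_along(trace@rounds)) {
    rd <- trace@rounds[[i]]
    df <- rd$added@triples
    if (nrow(df) == 0L) next
    df$round <- i
    df$step <- rd$label
    df$kind <- rd$kind
    rows[[length(rows) + 1L]] <- df[, c("round", "step", "kind",
                                        "s", "p", "o", "ot", "dt")]
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(round = integer(), step = character(), kind = character(),
               s = character(), p = character(), o = character(),
               ot = character(), dt = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Replay a trace onto its initial graph
#'
#' Conservation check helper: merging all recorded deltas into the graph the
#' execution started from must reproduce the final graph exactly.
#'
#' @param trace an \code{ExecutionTrace}.
#' @param g the initial graph the plan was executed against.
#' @return the replayed \code{RDFGraph}.
#' @export
replayTrace <- function(trace, g) {
  for (rd in trace@rounds) g <- mergeGraphs(g, rd$added)
  g
}

setMethod("show", "ExecutionTrace", function(object) {
  cat(sprintf(
    "ExecutionTrace: %d round(s), %d -> %d triples (+%d)\n",
    length(object@rounds), object@initialSize, object@finalSize,
    object@totalAdded))
  for (i in seq_along(object@rounds)) {
    rd <- object@rounds[[i]]
    cat(sprintf("  %2d. %-40s +%d\n", i, rd$label, graphSize(rd$added)))
  }
  if (length(object@warnings))
    cat("warnings:\n", paste0("  ", object@warnings, "\n"), sep = "")
})
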