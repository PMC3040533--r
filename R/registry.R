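## Service registry: indexes descriptions by attached predicate (and by the
## declared superproperties of those, so discovery by a more general
## predicate succeeds) and answers class-compatibility discovery queries.

#' Create a service registry
#'
#' @param ont the \code{\linkS4class{Ontology}} used for subsumption-aware
#'   matching.
#' @return an empty \code{\linkS4class{ServiceRegistry}}.
#' @export
serviceRegistry <- function(ont = ontology()) {
  new("ServiceRegistry", services = list(), ontology = ont,
      predicateIndex = list())
}

.rebuildIndex <- function(r) {
  idx <- list()
  for (s in r@services) {
    for (p in attachedProperties(s, r@ontology)) {
      ## index the property and its declared superproperties
      for (q in superPropertiesOf(r@ontology, p))
        idx[[q]] <- sort(unique(c(idx[[q]], s@iri)))
    }
  }
  r@predicateIndex <- idx
  r
}

#' Register a service
#'
#' Registration is idempotent by IRI: re-registering identical content is a
#' no-op; a duplicate IRI with different content is an error.  The predicate
#' index is rebuilt on every mutation, so it is always exactly consistent
#' with the attached properties of the registered services.
#'
#' @param r a \code{ServiceRegistry}.
#' @param s a \code{ServiceDescription}.
#' @return the updated registry.
#' @export
registerService <- function(r, s) {
  stopifnot(is(r, "ServiceRegistry"), is(s, "ServiceDescription"))
  old <- r@services[[s@iri]]
  if (!is.null(old)) {
    ## content = the published description; implementations are rebound
    ## callables and not part of identity
    same <- old@name == s@name && old@inputClass == s@inputClass &&
      old@outputClass == s@outputClass
    if (same) return(r)
    stop(sprintf("service <%s> already registered with different content",
                 s@iri), call. = FALSE)
  }
  r@services[[s@iri]] <- s
  .rebuildIndex(r)
}

#' Remove a service from the registry
#'
#' @param r a \code{ServiceRegistry}.
#' @param iri service IRI.
#' @return the updated registry.
#' @export
deregisterService <- function(r, iri) {
  r@services[[iri]] <- NULL
  .rebuildIndex(r)
}

#' Look up a registered service by IRI
#'
#' @param r a \code{ServiceRegistry}.
#' @param iri service IRI.
#' @return the \code{ServiceDescription} or NULL.
#' @export
getService <- function(r, iri) r@services[[iri]]

#' Discover services by attached predicate
#'
#' All services whose attached properties include \code{p} or a declared
#' subproperty of \code{p}, in deterministic order (by service IRI).
#'
#' @param r a \code{ServiceRegistry}.
#' @param p property IRI.
#' @return list of \code{ServiceDescription} (possibly empty).
#' @export
findByPredicate <- function(r, p) {
  iris <- r@predicateIndex[[p]]
  if (is.null(iris)) return(list())
  unname(r@services[sort(iris)])
}

## is requirement `req` syntactically covered by the requirements of the
## available class, under subclass/subproperty closure? (sound, cheap
## approximation of subsumption; full TBox reasoning is out of fragment)
.fillerCovers <- function(have, need, ont, depth = 0L) {
  if (depth > 10L) return(FALSE)
  if (is(need, "NumericRange")) {
    if (!is(have, "NumericRange")) return(FALSE)
    if (have@datatype != need@datatype) return(FALSE)
    ## every value admitted by `have` must be admitted by `need`
    lo <- function(f) {
      v <- c(f["minInclusive"], f["minExclusive"] )
      suppressWarnings(max(v, na.rm = TRUE))
    }
    hi <- function(f) {
      v <- c(f["maxInclusive"], f["maxExclusive"])
      suppressWarnings(min(v, na.rm = TRUE))
    }
    needsLo <- any(c("minInclusive", "minExclusive") %in% names(need@facets))
    needsHi <- any(c("maxInclusive", "maxExclusive") %in% names(need@facets))
    okLo <- !needsLo || (lo(have@facets) >= lo(need@facets) &&
                           is.finite(lo(have@facets)))
    okHi <- !needsHi || (hi(have@facets) <= hi(need@facets) &&
                           is.finite(hi(have@facets)))
    return(okLo && okHi)
  }
  if (!is(have, "ClassExpression") || !is(need, "ClassExpression"))
    return(FALSE)
  .requirementsCovered(decompose(have), decompose(need), ont, depth + 1L)
}

.requirementsCovered <- function(haveReqs, needReqs, ont, depth = 0L) {
  if (depth > 10L) return(FALSE)
  haveClasses <- unlist(lapply(haveReqs, function(r)
    if (is(r, "MembershipReq")) r@classIri else character(0)))
  haveClassesUp <- superClassesOf(ont, haveClasses)
  for (need in needReqs) {
    ok <- FALSE
    if (is(need, "MembershipReq")) {
      if (need@classIri == OWL_THING || need@classIri %in% haveClassesUp) {
        ok <- TRUE
      } else if (isDefinedClass(ont, need@classIri)) {
        ok <- .requirementsCovered(
          haveReqs, decompose(ont@classDefinitions[[need@classIri]]), ont,
          depth + 1L)
      }
    } else if (is(need, "PropertyReq")) {
      needPreds <- subPropertiesOf(ont, need@property)
      for (have in haveReqs) {
        if (!is(have, "PropertyReq")) next
        if (!(have@property %in% needPreds)) next
        nf <- need@filler
        hf <- have@filler
        coveredFiller <-
          if (is(nf, "ClassExpression") || is(nf, "NumericRange"))
            .fillerCovers(hf, nf, ont, depth + 1L)
          else identical(hf, nf) # value restriction: exact value needed
        if (coveredFiller) { ok <- TRUE; break }
      }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Discover services that can consume a class of data
#'
#' Services whose input class would be satisfied by an individual of the
#' \code{available} class: every requirement of the input class is
#' syntactically covered by the available class's requirements under the
#' subclass/subproperty closures.  This is a sound approximation of
#' subsumption (requirement coverage), deliberately cheaper than full TBox
#' reasoning.
#'
#' @param r a \code{ServiceRegistry}.
#' @param available a \code{ClassExpression} or class IRI describing the
#'   data at hand.
#' @return list of \code{ServiceDescription}, ordered by service IRI.
#' @export
findConsuming <- function(r, available) {
  ont <- r@ontology
  if (is.character(available)) available <- resolveClass(ont, available)
  ## a named available class contributes both its own membership and (if
  ## defined) its definition's requirements
  haveReqs <- decompose(available)
  extra <- list()
  for (req in haveReqs) {
    if (is(req, "MembershipReq") && isDefinedClass(ont, req@classIri))
      extra <- c(extra, decompose(ont@classDefinitions[[req@classIri]]))
  }
  haveReqs <- c(haveReqs, extra)
  hits <- Filter(function(s) {
    needReqs <- decompose(resolveClass(ont, s@inputClass))
    .requirementsCovered(haveReqs, needReqs, ont)
  }, r@services)
  unname(hits[order(vapply(hits, serviceIri, character(1)))])
}

#' Export the registry as an RDF graph
#'
#' The union of \code{\link{describeService}} for every registered service;
#' SPARQL over this graph reproduces predicate discovery.
#'
#' @param r a \code{ServiceRegistry}.
#' @return an \code{RDFGraph}.
#' @export
exportRegistryGraph <- function(r) {
  gs <- lapply(r@services, describeService, ont = r@ontology)
  do.call(mergeGraphs, unname(gs))
}

#' Rebuild a registry from its exported graph
#'
#' Implementation callables are rebound by service IRI from
#' \code{implementations}.
#'
#' @param g the exported \code{RDFGraph}.
#' @param ont an \code{Ontology}.
#' @param implementations named list, service IRI -> function.
#' @return a \code{ServiceRegistry}.
#' @export
importRegistryGraph <- function(g, ont, implementations = list()) {
  df <- g@triples
  iris <- sort(unique(df$s[df$p == RDF_TYPE & df$o == SSV_SERVICE]))
  r <- serviceRegistry(ont)
  for (iri in iris)
    r <- registerService(r, interpretService(g, iri, implementations))
  r
}

#' Registered services, as a data.frame index
#'
#' @param r a \code{ServiceRegistry}.
#' @return data.frame with columns \code{iri}, \code{name}, \code{input},
#'   \code{output}, \code{attaches}.
#' @export
listServices <- function(r) {
  rows <- lapply(unname(r@services), function(s) data.frame(
    iri = s@iri, name = s@name, input = s@inputClass, output = s@outputClass,
    attaches = paste(attachedProperties(s, r@ontology), collapse = " "),
    stringsAsFactors = FALSE))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(iri = character(), name = character(), input = character(),
               output = character(), attaches = character(),
               stringsAsFactors = FALSE)
  out[order(out$iri), , drop = FALSE]
}

setMethod("show", "ServiceRegistry", function(object) {
  cat(sprintf("ServiceRegistry with %d service(s)\n", length(object@services)))
  df <- listServices(object)
  for (i in seq_len(nrow(df)))
    cat(sprintf("  <%s> (%s) attaches: %s\n", df$iri[i], df$name[i],
                df$attaches[i]))
})
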