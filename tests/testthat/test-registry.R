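test_that("registration is idempotent by IRI and rejects conflicting content", {
  r <- demoRegistry()
  svc <- regressionService()
  expect_identical(getService(r, serviceIri(svc))@name, serviceName(svc))
  # identical re-registration is a no-op
  r2 <- registerService(r, svc)
  expect_equal(sort(names(r2@services)), sort(names(r@services)))
  # same IRI, different content
  clash <- serviceDescription(serviceIri(svc), "other name",
                              inputClass(svc), outputClass(svc),
                              svc@implementation)
  expect_error(registerService(r, clash), "different content")
})

test_that("predicate discovery covers exactly the attached properties", {
  v <- demoVocabulary()
  r <- demoRegistry()
  # brute-force union of attached properties over the three demo services
  expected <- sort(unique(unlist(lapply(r@services, attachedProperties,
                                        ont = r@ontology))))
  expect_setequal(expected,
                  c(v$hasRegressionModel, v$latestBUN, v$latestCreatinine))
  indexed <- sort(names(r@predicateIndex))
  expect_setequal(indexed, sort(c(expected, v$latestMeasurement)))

  hits <- findByPredicate(r, v$latestBUN)
  expect_length(hits, 1)
  expect_equal(serviceIri(hits[[1]]), v$latestBUNService)
  expect_length(findByPredicate(r, exIri("nosuch")), 0)

  # every registered service is discoverable by each attached property
  for (s in r@services)
    for (p in attachedProperties(s, r@ontology))
      expect_true(serviceIri(s) %in%
                    vapply(findByPredicate(r, p), serviceIri, character(1)))
})

test_that("discovery by a declared superproperty subsumes the subproperty", {
  v <- demoVocabulary()
  r <- demoRegistry()
  general <- vapply(findByPredicate(r, v$latestMeasurement), serviceIri,
                    character(1))
  forCreat <- vapply(findByPredicate(r, v$latestCreatinine), serviceIri,
                     character(1))
  forBun <- vapply(findByPredicate(r, v$latestBUN), serviceIri, character(1))
  expect_true(all(forCreat %in% general))
  expect_true(all(forBun %in% general))
  expect_setequal(general, c(v$latestBUNService, v$latestCreatinineService))
})

test_that("consumption discovery respects the subclass closure", {
  v <- demoVocabulary()
  r <- demoRegistry()
  # a blood-chemistry time-course is a specialized type of X-Y coordinate
  # data, so the regression service (input XYCoordinateData) can consume it
  hits <- vapply(findConsuming(r, v$BloodChemistryTimeCourse), serviceIri,
                 character(1))
  expect_true(v$regressionService %in% hits)
  # the top class satisfies no restricted input
  expect_length(findConsuming(r, owlThing()), 0)
})

test_that("consumption discovery matches the canonical-individual oracle", {
  # materialize a canonical individual of the available expression and test
  # actual input-class membership
  canonicalIndividual <- function(expr, ont) {
    node <- exIri("canonical")
    rows <- list()
    build <- function(subj, e) {
      if (is(e, "NamedClass")) {
        rows[[length(rows) + 1L]] <<- list(subj, rdfType, e@iri)
        if (isDefinedClass(ont, e@iri)) build(subj, resolveClass(ont, e@iri))
      } else if (is(e, "IntersectionOf")) {
        for (m in e@members) build(subj, m)
      } else if (is(e, "SomeValuesFrom")) {
        if (is(e@filler, "NumericRange")) {
          f <- e@filler@facets
          val <- if ("minExclusive" %in% names(f)) f[["minExclusive"]] + 1
          else if ("minInclusive" %in% names(f)) f[["minInclusive"]]
          else if ("maxInclusive" %in% names(f)) f[["maxInclusive"]]
          else if ("maxExclusive" %in% names(f)) f[["maxExclusive"]] - 1
          else 0
          rows[[length(rows) + 1L]] <<- list(subj, e@property, rdfLiteral(val))
        } else {
          child <- paste0(subj, "-x")
          rows[[length(rows) + 1L]] <<- list(subj, e@property, child)
          build(child, e@filler)
        }
      } else if (is(e, "HasValue")) {
        rows[[length(rows) + 1L]] <<- list(subj, e@property, e@value)
      }
    }
    build(node, expr)
    list(graph = buildGraph(rows), ind = node)
  }

  set.seed(303)
  for (k in 1:15) {
    ont <- randomTestOntology(depth = 2)
    r <- serviceRegistry(ont)
    svcs <- lapply(1:4, function(i)
      serviceDescription(exIri("svc/", i), paste0("s", i),
                         inputClass = sample(c(exIri("C", 1:4),
                                               exIri("D1")), 1),
                         outputClass = exIri("D2"),
                         function(g, s) emptyGraph()))
    for (s in svcs) r <- tryCatch(registerService(r, s), error = function(e) r)
    avail <- randomExpression(2, definedOk = exIri("D1"))
    got <- vapply(findConsuming(r, avail), serviceIri, character(1))
    can <- canonicalIndividual(avail, ont)
    want <- vapply(Filter(function(s) suppressWarnings(entailsMembership(
      can$graph, can$ind, resolveClass(ont, inputClass(s)), ont)),
      r@services), serviceIri, character(1))
    # requirement coverage is a sound approximation: no false positives
    expect_true(all(got %in% want),
                label = sprintf("soundness, case %d", k))
  }
})

test_that("the exported registry graph is query-equivalent to the index", {
  v <- demoVocabulary()
  r <- demoRegistry()
  expect_equal(graphSize(exportRegistryGraph(serviceRegistry())), 0)

  g <- exportRegistryGraph(r)
  ssv <- "http://sadi-share.example.org/vocab#"
  q <- paste0("SELECT ?svc WHERE { ?svc <", ssv, "attachesProperty> <",
              v$latestCreatinine, "> }")
  out <- evaluateSparql(g, q)
  expect_equal(out$svc, v$latestCreatinineService)

  # SPARQL over the export reproduces findByPredicate for every indexed
  # attached property
  for (p in c(v$hasRegressionModel, v$latestBUN, v$latestCreatinine)) {
    viaSparql <- sort(evaluateSparql(g, paste0(
      "SELECT ?svc WHERE { ?svc <", ssv, "attachesProperty> <", p, "> }"))$svc)
    viaIndex <- sort(vapply(findByPredicate(r, p), serviceIri, character(1)))
    expect_equal(viaSparql, viaIndex)
  }
})

test_that("export then reimport yields an equivalent registry", {
  r <- demoRegistry()
  impls <- lapply(r@services, function(s) s@implementation)
  back <- importRegistryGraph(exportRegistryGraph(r), r@ontology, impls)
  expect_setequal(names(back@services), names(r@services))
  for (iri in names(r@services)) {
    expect_equal(inputClass(back@services[[iri]]),
                 inputClass(r@services[[iri]]))
    expect_equal(outputClass(back@services[[iri]]),
                 outputClass(r@services[[iri]]))
  }
  expect_equal(sort(names(back@predicateIndex)), sort(names(r@predicateIndex)))
})
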