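test_that("the class plan for the clinical cascade discovers the regression service", {
  v <- demoVocabulary()
  ont <- demoOntology()
  r <- demoRegistry(ont)
  cohort <- generateCohort(cohortSpec(nPatients = 3, noiseSd = 0, seed = 2))
  wf <- planForClass(v$LikelyRejecter, r, ont, cohort$graph)

  labs <- linearizeWorkflow(wf)
  svcSteps <- Filter(function(l) is(wf@steps[[l]], "ServiceStep"), labs)
  expect_length(svcSteps, 1)
  expect_equal(wf@steps[[svcSteps]]@service, v$regressionService)
  expect_lt(match(svcSteps, labs), match("reason", labs))

  cov <- coverageReport(wf)
  regRow <- cov[grepl("hasRegressionModel", cov$requirement), ]
  expect_equal(regRow$resolution, "service")
  expect_match(regRow$provider, "linear-regression")
  slopeRow <- cov[grepl("slope", cov$requirement), ]
  expect_equal(slopeRow$resolution, "reasoner")
  expect_false(any(cov$resolution == "UNRESOLVED"))
})

test_that("a primitive class with data present plans to a lone reasoning step", {
  v <- demoVocabulary()
  ont <- demoOntology()
  r <- demoRegistry(ont)
  g <- buildGraph(list(list(exIri("x"), rdfType, v$Patient)))
  wf <- planForClass(v$Patient, r, ont, g)
  expect_equal(linearizeWorkflow(wf), "reason")
})

test_that("requirements already materialized in the data plan to `data`", {
  v <- demoVocabulary()
  ont <- demoOntology()
  r <- demoRegistry(ont)
  cohort <- generateCohort(cohortSpec(nPatients = 3, noiseSd = 0, seed = 2))
  ## materialize regression models by hand, then re-plan
  rec <- invokeService(regressionService(), cohort$graph,
                       unique(graphTriples(cohort$graph)$s), ont,
                       quiet = TRUE)
  g2 <- mergeGraphs(cohort$graph, rec@added)
  wf <- planForClass(v$LikelyRejecter, r, ont, g2)
  expect_equal(linearizeWorkflow(wf), "reason")
  cov <- coverageReport(wf)
  regRow <- cov[grepl("hasRegressionModel", cov$requirement), ]
  expect_equal(regRow$resolution, "data")
})

test_that("the worked-example query plans regression -> reasoning -> latest values", {
  v <- demoVocabulary()
  ont <- demoOntology()
  r <- demoRegistry(ont)
  cohort <- generateCohort(cohortSpec(nPatients = 5, noiseSd = 0, seed = 4))
  plan <- planForQuery(likelyRejecterQuery(), r, ont, cohort$graph)

  expect_equal(plan@patterns$resolution, c("class-plan", "service", "service"))
  expect_equal(plan@patterns$provider[1], v$LikelyRejecter)

  labs <- linearizeWorkflow(plan@workflow)
  reg <- grep("linear-regression", labs)
  rsn <- match("reason", labs)
  latest <- grep("latest", labs)
  expect_length(reg, 1)
  expect_length(latest, 2)
  expect_true(reg < rsn)
  expect_true(all(rsn < latest))
})

test_that("a query whose patterns all match existing data plans to a single reasoning step", {
  v <- demoVocabulary()
  ont <- demoOntology()
  r <- demoRegistry(ont)
  g <- buildGraph(list(
    list(exIri("p"), rdfType, v$Patient),
    list(exIri("p"), v$latestBUN, rdfLiteral(14))))
  q <- paste0("SELECT ?p ?b WHERE { ?p <", RDFNS, "type> <", v$Patient,
              "> . ?p <", v$latestBUN, "> ?b }")
  plan <- planForQuery(q, r, ont, g)
  expect_true(all(plan@patterns$resolution == "in-data"))
  expect_equal(linearizeWorkflow(plan@workflow), "reason")
})

test_that("deregistering the regression service leaves exactly one unresolved need", {
  v <- demoVocabulary()
  ont <- demoOntology()
  r <- deregisterService(demoRegistry(ont), v$regressionService)
  cohort <- generateCohort(cohortSpec(nPatients = 3, noiseSd = 0, seed = 2))
  plan <- planForQuery(likelyRejecterQuery(), r, ont, cohort$graph)
  cov <- coverageReport(plan)
  unres <- cov[cov$resolution == "UNRESOLVED", ]
  expect_equal(nrow(unres), 1)
  expect_match(unres$requirement, "hasRegressionModel")
  expect_equal(unres$provider, v$hasRegressionModel)
})

test_that("unsatisfiable predicates are surfaced, not silently dropped", {
  v <- demoVocabulary()
  ont <- demoOntology()
  r <- demoRegistry(ont)
  g <- buildGraph(list(list(exIri("p"), rdfType, v$Patient)))
  q <- paste0("SELECT ?p ?z WHERE { ?p <", exIri("unknownPredicate"),
              "> ?z }")
  plan <- planForQuery(q, r, ont, g)
  cov <- coverageReport(plan)
  expect_equal(sum(cov$resolution == "UNRESOLVED"), 1)
  expect_equal(cov$provider[cov$resolution == "UNRESOLVED"],
               exIri("unknownPredicate"))
})

test_that("planning is deterministic", {
  ont <- demoOntology()
  r <- demoRegistry(ont)
  cohort <- generateCohort(cohortSpec(nPatients = 4, noiseSd = 0.05,
                                      seed = 10))
  p1 <- planForQuery(likelyRejecterQuery(), r, ont, cohort$graph)
  p2 <- planForQuery(likelyRejecterQuery(), r, ont, cohort$graph)
  expect_identical(linearizeWorkflow(p1@workflow),
                   linearizeWorkflow(p2@workflow))
  expect_identical(coverageReport(p1), coverageReport(p2))
  expect_identical(p1@patterns, p2@patterns)
})

test_that("pattern resolution agrees with a rule-by-rule brute-force resolver", {
  v <- demoVocabulary()
  ont <- demoOntology()
  set.seed(77)
  for (k in 1:10) {
    ## random registry subset; random data with/without materialized preds
    full <- demoRegistry(ont)
    keep <- sample(names(full@services), sample(0:3, 1))
    r <- serviceRegistry(ont)
    for (iri in keep) r <- registerService(r, getService(full, iri))
    cohort <- generateCohort(cohortSpec(nPatients = 2, noiseSd = 0,
                                        seed = 50 + k))
    g <- cohort$graph
    if (stats::runif(1) < 0.5) {
      rec <- invokeService(latestValueService("BUN"), g,
                           unique(graphTriples(g)$s), ont, quiet = TRUE)
      g <- mergeGraphs(g, rec@added)
    }
    plan <- planForQuery(likelyRejecterQuery(), r, ont, g)
    df <- graphTriples(g)
    for (i in seq_len(nrow(plan@patterns))) {
      pat <- plan@patterns[i, ]
      want <- if (grepl("rdf:type", pat$pattern)) "class-plan" else {
        p <- sub("^.* <([^>]*)> \\?.*$", "\\1", pat$pattern)
        hasData <- any(df$p %in% subPropertiesOf(ont, p))
        svcs <- findByPredicate(r, p)
        lacking <- length(setdiff(unique(df$s),
                                  df$s[df$p %in% subPropertiesOf(ont, p)]))
        if (length(svcs) && lacking > 0) "service"
        else if (hasData) "in-data"
        else if (length(svcs)) "service"
        else "UNRESOLVED"
      }
      expect_equal(pat$resolution, want,
                   label = sprintf("case %d pattern %d", k, i))
    }
  }
})
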