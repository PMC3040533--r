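test_that("the three-patient fixture yields exactly one likely rejecter", {
  v <- demoVocabulary()
  ont <- demoOntology()
  r <- demoRegistry(ont)
  g <- threePatientFixture()
  res <- answerQuery(likelyRejecterQuery(), g, r, ont)

  rising <- paste0(v$nsData, "rising")
  expect_equal(res$bindings$patient, rising)
  # hand-computed: latest creatinine 1.9 at x=14; latest BUN 15
  expect_equal(as.numeric(res$bindings$creat), 1.9)
  expect_equal(as.numeric(res$bindings$bun), 15)

  final <- res$graph
  # regression models were attached to all three creatinine collections
  df <- graphTriples(final)
  collsWithModel <- df$s[df$p == v$hasRegressionModel]
  for (pid in c("rising", "flat", "falling"))
    expect_true(paste0(v$nsData, pid, "/creatinine") %in% collsWithModel)
  # the flat (slope 0) and falling patients are NOT classified
  expect_false(v$LikelyRejecter %in%
                 assertedTypes(final, paste0(v$nsData, "flat")))
  expect_false(v$LikelyRejecter %in%
                 assertedTypes(final, paste0(v$nsData, "falling")))
  # latest values were added only for the rejecter
  expect_equal(df$s[df$p == v$latestCreatinine], rising)
  expect_equal(df$s[df$p == v$latestBUN], rising)
})

test_that("execution is idempotent on the final graph", {
  ont <- demoOntology()
  r <- demoRegistry(ont)
  g <- threePatientFixture()
  res1 <- answerQuery(likelyRejecterQuery(), g, r, ont)
  res2 <- answerQuery(likelyRejecterQuery(), res1$graph, r, ont)
  expect_equal(res2$trace@totalAdded, 0)
  expect_true(sameGraph(res1$graph, res2$graph))
  expect_true(sameBindings(res1$bindings, res2$bindings))
})

test_that("a plan with only a reasoning step leaves classified data unchanged", {
  v <- demoVocabulary()
  ont <- demoOntology()
  r <- demoRegistry(ont)
  g <- classifyAll(buildGraph(list(list(exIri("p"), rdfType, v$Patient))), ont)
  wf <- planForClass(v$Patient, r, ont, g)
  res <- executePlan(wf, g, r, ont)
  expect_true(sameGraph(res$graph, g))
  expect_length(res$trace@rounds, 1)
})

test_that("answering over an empty graph returns no rows", {
  ont <- demoOntology()
  r <- demoRegistry(ont)
  ## the unresolved-requirement warnings for the empty data are expected
  res <- suppressWarnings(answerQuery(likelyRejecterQuery(), emptyGraph(),
                                      r, ont))
  expect_equal(nrow(res$bindings), 0)
})

test_that("the trace conserves triples and attributes each exactly once", {
  ont <- demoOntology()
  r <- demoRegistry(ont)
  g <- threePatientFixture()
  res <- answerQuery(likelyRejecterQuery(), g, r, ont)
  tr <- res$trace

  # conservation: initial graph + all deltas == final graph
  expect_true(sameGraph(replayTrace(tr, g), res$graph))
  expect_equal(tr@initialSize + tr@totalAdded, tr@finalSize)

  # attribution partition: union of attributed triples == total added,
  # pairwise disjoint across rounds
  ex <- explainTrace(tr)
  expect_equal(nrow(ex), tr@totalAdded)
  keys <- paste(ex$s, ex$p, ex$ot, ex$o, ex$dt)
  expect_false(anyDuplicated(keys) > 0)

  v <- demoVocabulary()
  regRows <- ex[ex$p == v$hasRegressionModel, ]
  expect_true(all(grepl("linear-regression", regRows$step)))
  lrRows <- ex[ex$p == rdfType & ex$o == v$LikelyRejecter, ]
  expect_equal(unique(lrRows$kind), "reasoner")

  # empty trace renders an empty report
  empty <- new("ExecutionTrace", rounds = list(), initialSize = 0,
               totalAdded = 0, finalSize = 0, warnings = character(0))
  expect_equal(nrow(explainTrace(empty)), 0)
})

test_that("service failures degrade gracefully and are visible in the trace", {
  v <- demoVocabulary()
  ont <- demoOntology()
  r <- demoRegistry(ont)
  g <- threePatientFixture()
  # a collection with a single timepoint: regression not fittable there
  g <- addTriple(g, exIri("lone"), rdfType, v$BloodChemistryTimeCourse)
  g <- addTriple(g, exIri("lone"), v$hasMeasurement, exIri("lone/m1"))
  g <- addTriple(g, exIri("lone/m1"), rdfType, v$Measurement)
  g <- addTriple(g, exIri("lone/m1"), v$hasXValue, rdfLiteral(0))
  g <- addTriple(g, exIri("lone/m1"), v$hasYValue, rdfLiteral(1))
  w <- capture_warnings(res <- answerQuery(likelyRejecterQuery(), g, r, ont))
  expect_true(any(grepl("failed", w)))
  # the query still resolves for the healthy patients
  expect_equal(res$bindings$patient, paste0(v$nsData, "rising"))
})

test_that("unresolved requirements warn rather than failing silently", {
  v <- demoVocabulary()
  ont <- demoOntology()
  r <- deregisterService(demoRegistry(ont), v$regressionService)
  g <- threePatientFixture()
  expect_warning(res <- answerQuery(likelyRejecterQuery(), g, r, ont),
                 "unresolved requirement")
  expect_equal(nrow(res$bindings), 0)
})

test_that("engine answers equal evaluation over the brute-force materialized graph", {
  ont <- demoOntology()
  r <- demoRegistry(ont)
  q <- likelyRejecterQuery()
  set.seed(404)
  for (k in 1:5) {
    cohort <- generateCohort(cohortSpec(
      nPatients = 4, fractionRejecter = stats::runif(1, 0.2, 0.8),
      noiseSd = stats::runif(1, 0, 0.15), seed = 700 + k))
    res <- suppressWarnings(answerQuery(q, cohort$graph, r, ont))
    gstar <- bruteMaterialize(cohort$graph, r, ont)
    want <- evaluateSparql(gstar, q)
    expect_true(sameBindings(res$bindings, want),
                label = sprintf("cohort %d", k))
  }
})

test_that("a custom reasoner can be plugged in through the adapter seam", {
  v <- demoVocabulary()
  ont <- demoOntology()
  r <- demoRegistry(ont)
  calls <- 0
  counting <- function(g, ont, ...) { calls <<- calls + 1; classifyAll(g, ont) }
  res <- answerQuery(likelyRejecterQuery(), threePatientFixture(), r, ont,
                     reasoner = counting)
  expect_gt(calls, 0)
  expect_equal(res$bindings$patient, paste0(v$nsData, "rising"))
})
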