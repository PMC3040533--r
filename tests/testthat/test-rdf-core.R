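test_that("Turtle parsing handles empty documents, datatypes and round-trips", {
  expect_equal(graphSize(parseTurtle("")), 0)
  expect_equal(graphSize(parseTurtle("# just a comment\n")), 0)

  ttl <- paste0(
    "@prefix ex: <", EX, "> .\n",
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .\n",
    "ex:a ex:p ex:b ; ex:q \"hi\" , \"1.5\"^^xsd:decimal .\n")
  g <- parseTurtle(ttl)
  expect_equal(graphSize(g), 3)
  expect_true(sameGraph(g, parseTurtle(writeTurtle(g))))

  # numeric shorthand and booleans
  g2 <- parseTurtle(paste0("@prefix ex: <", EX, "> .\n",
                           "ex:a ex:n 3 ; ex:m 2.5 ; ex:b true ."))
  df <- graphTriples(g2)
  expect_setequal(df$dt, paste0(XSD, c("integer", "decimal", "boolean")))
})

test_that("parse failures report a line and blank-node subjects are rejected", {
  expect_error(parseTurtle("ex:a ex:b ex:c ."), "undeclared prefix")
  expect_error(parseTurtle("<http://a> <http://b>\n<http://c> ;;"), "line 2")
  bn <- paste0("@prefix ex: <", EX, "> .\n_:x ex:p ex:a .")
  expect_error(parseTurtle(bn), "blank node")
  expect_silent(parseTurtle(bn, blankNodes = "skolemize"))
})

test_that("load/save round-trips random small graphs in both dialects", {
  set.seed(42)
  for (k in 1:8) {
    g <- randomGraph(nInd = 6, nTriples = 15)
    expect_true(sameGraph(g, parseTurtle(writeTurtle(g))), label =
      sprintf("turtle round-trip, case %d", k))
    expect_true(sameGraph(g, parseRdfXml(writeRdfXml(g))), label =
      sprintf("rdfxml round-trip, case %d", k))
  }
  # via files, both directions of dialect inference
  g <- randomGraph(nInd = 5, nTriples = 12)
  ttl <- tempfile(fileext = ".ttl"); rdf <- tempfile(fileext = ".rdf")
  saveGraph(g, ttl); saveGraph(g, rdf)
  expect_true(sameGraph(g, loadGraph(ttl)))
  expect_true(sameGraph(g, loadGraph(rdf)))
  unlink(c(ttl, rdf))
})

test_that("merge is an idempotent commutative monoid with empty identity", {
  set.seed(7)
  for (k in 1:6) {
    a <- randomGraph(8, 14); b <- randomGraph(8, 14); c <- randomGraph(8, 14)
    expect_true(sameGraph(mergeGraphs(a, emptyGraph()), a))
    expect_true(sameGraph(mergeGraphs(a, a), a))
    expect_true(sameGraph(mergeGraphs(a, b), mergeGraphs(b, a)))
    expect_true(sameGraph(mergeGraphs(mergeGraphs(a, b), c),
                          mergeGraphs(a, mergeGraphs(b, c))))
    expect_lte(graphSize(mergeGraphs(a, b)), graphSize(a) + graphSize(b))
  }
  # inclusion-exclusion on a constructed overlap
  mk <- function(idx) buildGraph(lapply(idx, function(i)
    list(exIri("s", i), exIri("p"), exIri("o", i))))
  expect_equal(graphSize(mergeGraphs(mk(1:5), mk(4:8))), 8)
})

test_that("generated cohort file triple count matches the closed form", {
  spec <- cohortSpec(nPatients = 10, nTimepoints = 5, noiseSd = 0, seed = 3)
  cohort <- generateCohort(spec)
  dir <- tempfile(); writeCohortFixture(cohort, dir, spec)
  reloaded <- readCohortFixture(dir)
  expect_equal(graphSize(reloaded$graph), cohortTripleCount(spec))
  # cross-check by brute-force enumeration of the reloaded triples
  expect_equal(nrow(graphTriples(reloaded$graph)), 10 * (5 + 8 * 5))
  expect_true(sameGraph(reloaded$graph, cohort$graph))
  unlink(dir, recursive = TRUE)
})

test_that("SPARQL SELECT evaluation matches basic expectations", {
  g0 <- emptyGraph()
  expect_equal(nrow(evaluateSparql(
    g0, paste0("SELECT ?s WHERE { ?s a <", exIri("C1"), "> }"))), 0)

  g <- buildGraph(list(
    list(exIri("a"), rdfType, exIri("C1")),
    list(exIri("b"), rdfType, exIri("C1")),
    list(exIri("a"), exIri("p1"), rdfLiteral(2.0))))
  out <- evaluateSparql(g, paste0(
    "SELECT ?s ?v WHERE { ?s a <", exIri("C1"), "> . ?s <", exIri("p1"),
    "> ?v }"))
  expect_equal(nrow(out), 1)
  expect_equal(out$s, exIri("a"))
  expect_equal(out$v, "2")

  # FILTER support
  out2 <- evaluateSparql(g, paste0(
    "SELECT ?s WHERE { ?s <", exIri("p1"), "> ?v . FILTER(?v > 1) }"))
  expect_equal(out2$s, exIri("a"))
  out3 <- evaluateSparql(g, paste0(
    "SELECT ?s WHERE { ?s <", exIri("p1"), "> ?v . FILTER(?v > 3) }"))
  expect_equal(nrow(out3), 0)

  expect_error(evaluateSparql(g, "SELECT ?s WHERE { ?s ?p }"), "malformed")
  expect_error(evaluateSparql(g, "SELECT ?s WHERE { OPTIONAL { ?s ?p ?o } }"),
               "OPTIONAL")
})

test_that("a pre-materialized worked-example graph answers the clinical query", {
  v <- demoVocabulary()
  g <- buildGraph(list(
    list(paste0(v$nsData, "p1"), rdfType, v$LikelyRejecter),
    list(paste0(v$nsData, "p1"), v$latestBUN, rdfLiteral(14.2)),
    list(paste0(v$nsData, "p1"), v$latestCreatinine, rdfLiteral(1.9)),
    list(paste0(v$nsData, "p2"), rdfType, v$Patient),
    list(paste0(v$nsData, "p2"), v$latestBUN, rdfLiteral(12.0))))
  out <- evaluateSparql(g, likelyRejecterQuery())
  expect_equal(nrow(out), 1)
  expect_equal(out$patient, paste0(v$nsData, "p1"))
  expect_equal(out$bun, "14.2")
  expect_equal(out$creat, "1.9")
})

test_that("FROM resolves against the supplied local graph set only", {
  v <- demoVocabulary()
  inFrom <- buildGraph(list(list(exIri("a"), rdfType, exIri("C1"))))
  other <- buildGraph(list(list(exIri("b"), rdfType, exIri("C1"))))
  q <- paste0("SELECT ?s FROM <", v$document, "> WHERE { ?s a <",
              exIri("C1"), "> }")
  got <- evaluateSparql(other, q, from = setNames(list(inFrom), v$document))
  expect_equal(got$s, exIri("a"))
  # without a resolver entry the passed graph stands in for the document
  expect_equal(evaluateSparql(other, q)$s, exIri("b"))
})

test_that("SPARQL evaluation equals the brute-force nested-loop join", {
  set.seed(11)
  tried <- 0
  while (tried < 12) {
    g <- randomGraph(nInd = 8, nTriples = 25)
    patterns <- randomBgp(nPat = sample(2:3, 1))
    nvars <- length(unique(unlist(lapply(patterns, function(p)
      unlist(lapply(p, function(tm) if (tm$kind == "var") tm$value))))))
    if (nvars == 0) next
    tried <- tried + 1
    mine <- evaluateSparql(g, bgpToQuery(patterns))
    oracle <- bruteJoin(g, patterns)
    expect_true(sameBindings(mine, oracle),
                label = sprintf("join oracle, case %d", tried))
  }
})

test_that("bindings export as SPARQL-results CSV", {
  g <- buildGraph(list(list(exIri("a"), exIri("p1"), rdfLiteral(1.5))))
  b <- evaluateSparql(g, paste0("SELECT ?s ?v WHERE { ?s <", exIri("p1"),
                                "> ?v }"))
  f <- tempfile(fileext = ".csv")
  writeBindingsCsv(b, f)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$s, exIri("a"))
  expect_equal(back$v, 1.5)
  unlink(f)
})
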