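test_that("attached properties are the output/input restriction difference", {
  v <- demoVocabulary()
  ont <- demoOntology()
  expect_equal(attachedProperties(regressionService(), ont),
               v$hasRegressionModel)
  expect_equal(attachedProperties(latestValueService("creatinine"), ont),
               v$latestCreatinine)
  expect_equal(attachedProperties(latestValueService("BUN"), ont),
               v$latestBUN)

  # identical input and output classes attach nothing
  idsvc <- serviceDescription(exIri("svc/id"), "identity",
                              v$XYCoordinateData, v$XYCoordinateData,
                              function(g, s) emptyGraph())
  expect_length(attachedProperties(idsvc, ont), 0)

  # two added restrictions -> both properties, per the set-difference oracle
  twoOut <- exIri("TwoOut")
  ont2 <- ontology(
    classDefinitions = setNames(list(intersectionOf(
      namedClass(exIri("C1")),
      someValuesFrom(exIri("pA"), namedClass(exIri("C2"))),
      someValuesFrom(exIri("pB"), numericRange()))), twoOut))
  svc2 <- serviceDescription(exIri("svc/two"), "two", exIri("C1"), twoOut,
                             function(g, s) emptyGraph())
  inProps <- restrictedProperties(resolveClass(ont2, exIri("C1")))
  outProps <- restrictedProperties(resolveClass(ont2, twoOut))
  expect_equal(attachedProperties(svc2, ont2),
               sort(setdiff(outProps, inProps)))
  expect_setequal(attachedProperties(svc2, ont2), exIri(c("pA", "pB")))
})

test_that("invocation annotates the same-URI subject and honors the input class", {
  v <- demoVocabulary()
  ont <- demoOntology()
  g <- threePatientFixture()
  svc <- regressionService()

  # empty subject set adds nothing
  rec0 <- invokeService(svc, g, character(0), ont)
  expect_equal(graphSize(rec0@added), 0)

  coll <- paste0(v$nsData, "rising/creatinine")
  rec <- invokeService(svc, g, coll, ont)
  expect_equal(rec@succeeded, coll)
  df <- graphTriples(rec@added)
  expect_true(all(df$s %in% c(coll, paste0(coll, "/regression-model"))))
  model <- df$o[df$s == coll & df$p == v$hasRegressionModel]
  expect_equal(model, paste0(coll, "/regression-model"))
  got <- df[df$s == model & df$p == v$slope, ]
  # (0,1.0) (7,1.4) (14,1.9): the independent oracle gives the slope
  o <- oracleOlsFit(c(0, 7, 14), c(1.0, 1.4, 1.9))
  expect_equal(as.numeric(got$o), o$slope, tolerance = 1e-12)

  # a subject that is not X-Y coordinate data is skipped with a warning
  patient <- paste0(v$nsData, "rising")
  expect_warning(rec2 <- invokeService(svc, g, patient, ont), "skipping")
  expect_equal(rec2@skipped, patient)
  expect_equal(graphSize(rec2@added), 0)
})

test_that("an exact-line collection yields slope 1 and intercept 1", {
  v <- demoVocabulary()
  ont <- demoOntology()
  coll <- exIri("coll")
  triples <- list(list(coll, rdfType, v$BloodChemistryTimeCourse))
  pts <- list(c(0, 1), c(1, 2), c(2, 3))
  for (i in seq_along(pts)) {
    m <- sprintf("%s/m%d", coll, i)
    triples <- c(triples, list(
      list(coll, v$hasMeasurement, m),
      list(m, rdfType, v$Measurement),
      list(m, v$hasXValue, rdfLiteral(pts[[i]][1])),
      list(m, v$hasYValue, rdfLiteral(pts[[i]][2]))))
  }
  g <- buildGraph(triples)
  rec <- invokeService(regressionService(), g, coll, ont)
  df <- graphTriples(rec@added)
  model <- paste0(coll, "/regression-model")
  expect_equal(as.numeric(df$o[df$s == model & df$p == v$slope]), 1)
  expect_equal(as.numeric(df$o[df$s == model & df$p == v$intercept]), 1)
})

test_that("latest-value services pick the maximum-x measurement with IRI tie-break", {
  v <- demoVocabulary()
  ont <- demoOntology()
  g <- threePatientFixture()
  p <- paste0(v$nsData, "rising")
  rec <- invokeService(latestValueService("creatinine"), g, p, ont)
  df <- graphTriples(rec@added)
  expect_equal(df$s, p)
  expect_equal(df$p, v$latestCreatinine)
  expect_equal(as.numeric(df$o), 1.9)   # value at x = 14, the max

  # single measurement: that value
  single <- buildGraph(list(
    list(exIri("q"), rdfType, v$Patient),
    list(exIri("q"), v$hasCreatinineCollection, exIri("q/c")),
    list(exIri("q/c"), rdfType, v$BloodChemistryTimeCourse),
    list(exIri("q/c"), v$hasMeasurement, exIri("q/c/m1")),
    list(exIri("q/c/m1"), rdfType, v$Measurement),
    list(exIri("q/c/m1"), v$hasXValue, rdfLiteral(0)),
    list(exIri("q/c/m1"), v$hasYValue, rdfLiteral(1.3))))
  rec1 <- invokeService(latestValueService("creatinine"), single,
                        exIri("q"), ont)
  expect_equal(as.numeric(graphTriples(rec1@added)$o), 1.3)

  # tie on x: lexicographically greatest measurement IRI wins
  tie <- buildGraph(list(
    list(exIri("t"), rdfType, v$Patient),
    list(exIri("t"), v$hasCreatinineCollection, exIri("t/c")),
    list(exIri("t/c"), rdfType, v$BloodChemistryTimeCourse),
    list(exIri("t/c"), v$hasMeasurement, exIri("t/c/mA")),
    list(exIri("t/c/mA"), rdfType, v$Measurement),
    list(exIri("t/c/mA"), v$hasXValue, rdfLiteral(7)),
    list(exIri("t/c/mA"), v$hasYValue, rdfLiteral(2.2)),
    list(exIri("t/c"), v$hasMeasurement, exIri("t/c/mB")),
    list(exIri("t/c/mB"), rdfType, v$Measurement),
    list(exIri("t/c/mB"), v$hasXValue, rdfLiteral(7)),
    list(exIri("t/c/mB"), v$hasYValue, rdfLiteral(2.8))))
  recT <- invokeService(latestValueService("creatinine"), tie, exIri("t"), ont)
  expect_equal(as.numeric(graphTriples(recT@added)$o), 2.8) # from t/c/mB
})

test_that("implementation failures are per-subject and leave others unaffected", {
  v <- demoVocabulary()
  ont <- demoOntology()
  # one collection with a single timepoint (not fittable), one healthy
  g <- threePatientFixture()
  broken <- exIri("lone")
  g <- addTriple(g, broken, rdfType, v$BloodChemistryTimeCourse)
  g <- addTriple(g, broken, v$hasMeasurement, exIri("lone/m1"))
  g <- addTriple(g, exIri("lone/m1"), v$hasXValue, rdfLiteral(0))
  g <- addTriple(g, exIri("lone/m1"), v$hasYValue, rdfLiteral(1))
  healthy <- paste0(v$nsData, "flat/creatinine")
  rec <- invokeService(regressionService(), g, c(broken, healthy), ont)
  expect_equal(names(rec@failed), broken)
  expect_match(unname(rec@failed), "distinct x")
  expect_equal(rec@succeeded, healthy)
  expect_gt(graphSize(rec@added), 0)
})

test_that("contract validation passes well-behaved services and catches the broken one", {
  v <- demoVocabulary()
  ont <- demoOntology()
  g <- threePatientFixture()
  coll <- paste0(v$nsData, "rising/creatinine")
  rec <- invokeService(regressionService(), g, coll, ont)
  expect_true(contractHolds(validateContract(regressionService(), g, rec, ont)))

  bad <- misbehavingDemoService()
  recB <- invokeService(bad, g, coll, ont)
  repB <- validateContract(bad, g, recB, ont)
  expect_false(contractHolds(repB))
  expect_true("foreign-subject" %in% repB@violations$type)

  # an output-class violation: claims success but adds nothing
  liar <- serviceDescription(exIri("svc/liar"), "liar",
                             v$XYCoordinateData, v$RegressionAnnotatedData,
                             function(g, s) emptyGraph())
  recL <- invokeService(liar, g, coll, ont)
  repL <- validateContract(liar, g, recL, ont)
  expect_true("output-class" %in% repL@violations$type)
})

test_that("contract fuzzing over all demo services finds no violations", {
  v <- demoVocabulary()
  ont <- demoOntology()
  services <- list(regressionService(), latestValueService("creatinine"),
                   latestValueService("BUN"))
  set.seed(61)
  invocations <- 0
  for (k in 1:6) {
    cohort <- generateCohort(cohortSpec(nPatients = 3, noiseSd = 0.1,
                                        seed = 100 + k))
    g <- cohort$graph
    # regression first so latest-value inputs stay realistic on merge
    for (svc in services) {
      subjects <- unique(graphTriples(g)$s)
      rec <- invokeService(svc, g, sample(subjects, min(8, length(subjects))),
                           ont, quiet = TRUE)
      invocations <- invocations + 1
      rep <- validateContract(svc, g, rec, ont)
      expect_true(contractHolds(rep),
                  label = sprintf("fuzz case %d, %s", k, serviceName(svc)))
      # attached properties appear among the added predicates
      df <- graphTriples(rec@added)
      if (nrow(df))
        expect_true(all(attachedProperties(svc, ont) %in%
                          superPropertiesOf(ont, unique(df$p))))
      g <- mergeGraphs(g, rec@added)
    }
  }
  expect_gte(invocations, 18)
})

test_that("service descriptions round-trip through their RDF rendering", {
  ont <- demoOntology()
  for (svc in list(regressionService(), latestValueService("creatinine"),
                   latestValueService("BUN"))) {
    d <- describeService(svc, ont)
    expect_gte(graphSize(d), 4)
    df <- graphTriples(d)
    expect_true(any(df$s == serviceIri(svc) & df$o == inputClass(svc)))
    back <- interpretService(d, serviceIri(svc),
                             setNames(list(svc@implementation),
                                      serviceIri(svc)))
    expect_equal(serviceName(back), serviceName(svc))
    expect_equal(inputClass(back), inputClass(svc))
    expect_equal(outputClass(back), outputClass(svc))
  }
})
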