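test_that("class-expression parsing recovers the clinical cascade", {
  v <- demoVocabulary()
  g <- demoOntologyGraph()

  lr <- parseClassExpression(g, v$LikelyRejecter)
  expect_s4_class(lr, "IntersectionOf")
  expect_equal(lr@members[[1]]@iri, v$Patient)
  expect_s4_class(lr@members[[2]], "SomeValuesFrom")
  expect_equal(lr@members[[2]]@property, v$hasCreatinineCollection)
  expect_equal(lr@members[[2]]@filler@iri, v$ElevatedLevels)

  inc <- parseClassExpression(g, v$IncreasingModel)
  expect_equal(inc@members[[1]]@iri, v$LinearRegressionModel)
  rng <- inc@members[[2]]@filler
  expect_s4_class(rng, "NumericRange")
  expect_equal(rng@datatype, paste0(XSD, "decimal"))
  expect_equal(rng@facets, c(minExclusive = 0))

  # a primitive class parses to itself
  expect_equal(parseClassExpression(g, v$Patient)@iri, v$Patient)
})

test_that("constructs outside the fragment raise naming errors", {
  base <- paste0(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .\n",
    "@prefix ex: <", EX, "> .\n")
  forAll <- paste0(base,
    "ex:Bad owl:equivalentClass [ a owl:Restriction ;",
    " owl:onProperty ex:p1 ; owl:allValuesFrom ex:C1 ] .\n")
  g <- parseTurtle(forAll, blankNodes = "skolemize")
  expect_error(parseClassExpression(g, exIri("Bad")), "allValuesFrom")

  unionOf <- paste0(base,
    "ex:Bad owl:equivalentClass [ a owl:Class ;",
    " owl:unionOf ( ex:C1 ex:C2 ) ] .\n")
  g2 <- parseTurtle(unionOf, blankNodes = "skolemize")
  expect_error(parseClassExpression(g2, exIri("Bad")), "unionOf")

  card <- paste0(base,
    "ex:Bad owl:equivalentClass [ a owl:Restriction ;",
    " owl:onProperty ex:p1 ; owl:minCardinality 2 ] .\n")
  g3 <- parseTurtle(card, blankNodes = "skolemize")
  expect_error(parseClassExpression(g3, exIri("Bad")), "minCardinality")
})

test_that("cyclic definitions and cyclic axiom sets are rejected", {
  base <- paste0(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .\n",
    "@prefix ex: <", EX, "> .\n")
  ## a structural cycle (an expression node reachable from itself) is a
  ## parse error
  cyc <- paste0(base,
    "ex:Bad owl:equivalentClass ex:R .\n",
    "ex:R owl:onProperty ex:p ; owl:someValuesFrom ex:R .\n")
  g <- parseTurtle(cyc, blankNodes = "skolemize")
  expect_error(parseClassExpression(g, exIri("Bad")), "cyclic")

  ## mutual equivalence of named classes is tolerated: named references
  ## parse lazily and the reasoning-time guard keeps entailment finite
  eqc <- paste0(base, "ex:A owl:equivalentClass ex:B .\n",
                "ex:B owl:equivalentClass ex:A .\n")
  g2 <- parseTurtle(eqc, blankNodes = "skolemize")
  ont <- ontologyFromGraph(g2)
  inst <- buildGraph(list(list(exIri("x"), rdfType, exIri("A"))))
  out <- classifyAll(inst, ont)   # converges; membership propagates
  expect_true(exIri("B") %in% assertedTypes(out, exIri("x")))

  expect_error(ontology(subclassAxioms = data.frame(
    sub = c(exIri("A"), exIri("B")), super = c(exIri("B"), exIri("A")))),
    "acyclic")
})

test_that("decompose flattens intersections in document order", {
  A <- namedClass(exIri("A")); B <- namedClass(exIri("B"))
  C <- namedClass(exIri("C"))
  expect_length(decompose(A), 1)
  expect_s4_class(decompose(A)[[1]], "MembershipReq")

  nested <- intersectionOf(intersectionOf(A, B), C)
  reqs <- decompose(nested)
  expect_length(reqs, 3)
  expect_equal(vapply(reqs, function(r) r@classIri, character(1)),
               exIri(c("A", "B", "C")))

  lr <- resolveClass(demoOntology(), demoVocabulary()$LikelyRejecter)
  reqs2 <- decompose(lr)
  expect_s4_class(reqs2[[1]], "MembershipReq")
  expect_equal(reqs2[[1]]@classIri, demoVocabulary()$Patient)
  expect_s4_class(reqs2[[2]], "PropertyReq")
  expect_equal(reqs2[[2]]@property, demoVocabulary()$hasCreatinineCollection)
})

test_that("the conjunction of decomposed requirements is equivalent to the expression", {
  # on random instance data: entailment of the whole expression agrees with
  # the conjunction of per-requirement satisfaction (and with the
  # truth-table over its atoms, which the set-based oracle realizes)
  set.seed(23)
  for (k in 1:25) {
    g <- randomGraph(nInd = 8, nTriples = 25)
    ont <- randomTestOntology(depth = 2)
    expr <- randomExpression(2)
    reqs <- decompose(expr)
    for (ind in exIri("i", 1:8)) {
      whole <- suppressWarnings(entailsMembership(g, ind, expr, ont))
      parts <- all(vapply(reqs, function(q)
        suppressWarnings(satisfiesRequirement(g, ind, q, ont)), logical(1)))
      expect_identical(whole, parts,
                       label = sprintf("case %d, %s", k, ind))
    }
  }
})

test_that("intersection normalization and facet validity hold", {
  expect_equal(intersectionOf()@iri, paste0("http://www.w3.org/2002/07/owl#",
                                            "Thing"))
  A <- namedClass(exIri("A"))
  expect_identical(intersectionOf(A), A)
  expect_error(numericRange(minInclusive = 3, maxInclusive = 1),
               "inconsistent")
})

test_that("closures follow subclass and subproperty axioms reflexively", {
  ont <- ontology(
    subclassAxioms = data.frame(sub = exIri(c("A", "B")),
                                super = exIri(c("B", "C"))),
    subpropertyAxioms = data.frame(sub = exIri("p"), super = exIri("q")))
  expect_setequal(superClassesOf(ont, exIri("A")), exIri(c("A", "B", "C")))
  expect_setequal(subClassesOf(ont, exIri("C")), exIri(c("A", "B", "C")))
  expect_setequal(superPropertiesOf(ont, exIri("p")), exIri(c("p", "q")))
  expect_setequal(subPropertiesOf(ont, exIri("q")), exIri(c("p", "q")))
})
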