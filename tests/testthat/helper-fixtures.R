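# Programmatic fixtures: small hand-built graphs, random graphs, random
# fragment expressions and random ontologies used by the property tests.

EX <- "http://test.example.org/"
exIri <- function(...) paste0(EX, ...)

# quick graph builder: triples given as list(s, p, o) with o either an IRI
# string or a Literal
buildGraph <- function(triples) {
  g <- emptyGraph()
  for (t in triples) g <- addTriple(g, t[[1]], t[[2]], t[[3]])
  g
}

# three-patient clinic fixture with creatinine slopes +, 0, - (and a flat
# BUN series for each), built on the demo vocabulary
threePatientFixture <- function() {
  v <- demoVocabulary()
  triples <- list()
  addP <- function(pid, creatY, bunY, x = c(0, 7, 14)) {
    p <- paste0(v$nsData, pid)
    triples[[length(triples) + 1L]] <<- list(p, rdfType, v$Patient)
    for (analyte in c("creatinine", "bun")) {
      coll <- paste0(p, "/", analyte)
      link <- if (analyte == "creatinine") v$hasCreatinineCollection else
        v$hasBUNCollection
      ys <- if (analyte == "creatinine") creatY else bunY
      triples[[length(triples) + 1L]] <<- list(p, link, coll)
      triples[[length(triples) + 1L]] <<-
        list(coll, rdfType, v$BloodChemistryTimeCourse)
      for (i in seq_along(x)) {
        m <- sprintf("%s/m%02d", coll, i)
        triples[[length(triples) + 1L]] <<- list(coll, v$hasMeasurement, m)
        triples[[length(triples) + 1L]] <<- list(m, rdfType, v$Measurement)
        triples[[length(triples) + 1L]] <<- list(m, v$hasXValue, rdfLiteral(x[i]))
        triples[[length(triples) + 1L]] <<- list(m, v$hasYValue, rdfLiteral(ys[i]))
      }
    }
  }
  addP("rising",  c(1.0, 1.4, 1.9), c(15, 14, 15))
  addP("flat",    c(1.2, 1.2, 1.2), c(12, 12, 12))
  addP("falling", c(1.5, 1.2, 1.0), c(18, 17, 16))
  buildGraph(triples)
}

# ---- random structures ------------------------------------------------------

# random instance graph over nInd individuals, 4 primitive classes C1..C4,
# 3 object properties p1..p3 (p1 subPropertyOf p2 in randomTestOntology),
# and a numeric property q1
randomGraph <- function(nInd = 10, nTriples = 30) {
  inds <- exIri("i", seq_len(nInd))
  classes <- exIri("C", 1:4)
  oprops <- exIri("p", 1:3)
  rows <- lapply(seq_len(nTriples), function(k) {
    kind <- sample(c("type", "link", "num"), 1,
                   prob = c(0.35, 0.45, 0.2))
    if (kind == "type") {
      data.frame(s = sample(inds, 1), p = rdfType, o = sample(classes, 1),
                 ot = "iri", dt = NA_character_, stringsAsFactors = FALSE)
    } else if (kind == "link") {
      data.frame(s = sample(inds, 1), p = sample(oprops, 1),
                 o = sample(inds, 1), ot = "iri", dt = NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(s = sample(inds, 1), p = exIri("q1"),
                 o = as.character(sample(-5:5, 1)), ot = "lit",
                 dt = paste0(XSD, "decimal"), stringsAsFactors = FALSE)
    }
  })
  rdfGraph(do.call(rbind, rows))
}

# random fragment expression of depth <= d over the same vocabulary;
# definedOk: IRIs of defined classes that may be referenced
randomExpression <- function(d = 3, definedOk = character(0)) {
  choices <- c("named", "some", "hasvalue")
  if (d > 1) choices <- c(choices, "and", "some")
  kind <- sample(choices, 1)
  if (kind == "named") {
    pool <- c(exIri("C", 1:4), definedOk)
    namedClass(sample(pool, 1))
  } else if (kind == "and") {
    intersectionOf(randomExpression(d - 1, definedOk),
                   randomExpression(d - 1, definedOk))
  } else if (kind == "some") {
    if (stats::runif(1) < 0.3) {
      lo <- sample(-3:3, 1)
      someValuesFrom(exIri("q1"),
                     numericRange(minExclusive = lo, maxInclusive = lo + 4))
    } else {
      someValuesFrom(sample(exIri("p", 1:3), 1),
                     if (d > 1) randomExpression(d - 1, definedOk) else
                       namedClass(sample(exIri("C", 1:4), 1)))
    }
  } else {
    if (stats::runif(1) < 0.5)
      hasValue(sample(exIri("p", 1:3), 1), exIri("i", sample(1:10, 1)))
    else hasValue(exIri("q1"), rdfLiteral(sample(-5:5, 1)))
  }
}

# ontology with subclass chain C1 <= C2, C3 <= C4, subproperty p1 <= p2,
# and two defined classes D1 (no defined refs) and D2 (may reference D1)
randomTestOntology <- function(depth = 3) {
  d1 <- exIri("D1"); d2 <- exIri("D2")
  ontology(
    classDefinitions = setNames(
      list(randomExpression(depth),
           randomExpression(depth, definedOk = d1)),
      c(d1, d2)),
    subclassAxioms = data.frame(
      sub = c(exIri("C1"), exIri("C3")),
      super = c(exIri("C2"), exIri("C4")), stringsAsFactors = FALSE),
    subpropertyAxioms = data.frame(
      sub = exIri("p1"), super = exIri("p2"), stringsAsFactors = FALSE))
}

# random SPARQL basic graph pattern (as parsed-term lists) with nPat
# patterns over the randomGraph vocabulary
randomBgp <- function(nPat = 2) {
  vars <- c("x", "y", "z")
  term <- function(pos) {
    r <- stats::runif(1)
    if (r < 0.5) list(kind = "var", value = sample(vars, 1))
    else if (pos == "p") list(kind = "iri",
                              value = sample(c(exIri("p", 1:3), rdfType), 1))
    else if (r < 0.85) list(kind = "iri",
                            value = sample(c(exIri("i", 1:10),
                                             exIri("C", 1:4)), 1))
    else list(kind = "lit", value = as.character(sample(-5:5, 1)),
              dt = paste0(XSD, "decimal"))
  }
  lapply(seq_len(nPat), function(k)
    list(s = term("s"), p = term("p"), o = term("o")))
}

# render parsed-term patterns back to SPARQL text
bgpToQuery <- function(patterns, vars = NULL) {
  rt <- function(tm) switch(tm$kind,
    var = paste0("?", tm$value),
    iri = paste0("<", tm$value, ">"),
    lit = sprintf("\"%s\"^^<%s>", tm$value, tm$dt))
  body <- vapply(patterns, function(p)
    paste(rt(p$s), rt(p$p), rt(p$o), "."), character(1))
  allVars <- unique(unlist(lapply(patterns, function(p)
    unlist(lapply(p, function(tm) if (tm$kind == "var") tm$value)))))
  if (is.null(vars)) vars <- allVars
  sel <- if (length(vars)) paste0("?", vars, collapse = " ") else "*"
  paste0("SELECT ", sel, " WHERE {\n", paste(body, collapse = "\n"), "\n}")
}
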