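---
title: "Semantic annotation services, workflow planning and query resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic annotation services, workflow planning and query resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sadishare)
```

## The model

This package implements, end to end, the contract of SADI-style semantic
annotation services and a SHARE-style query engine over them.

An **annotation service** is described by two OWL classes. It consumes
individuals of its *input class* and returns the *same-URI* individuals,
now described by the *output class*. Because input and output individuals
share their URI, every service output is a set of new RDF statements about
things the caller already knows, and the difference between the properties
restricted in the output class and those restricted in the input class is a
machine-readable statement of *what the service does* — its **attached
properties** (`attachedProperties()`).

The **query engine** treats a SPARQL SELECT query as a specification rather
than a lookup: it deconstructs the basic graph pattern into triple
patterns, maps each pattern either to data already present, to a registered
service that can attach the missing predicate, or to the reasoner
(`planForQuery()`); executes the resulting workflow against a transient
working graph, merging each service's annotations as they arrive and
classifying with a forward-chaining reasoner (`executePlan()`); and finally
evaluates the original query over the materialized graph
(`answerQuery()`). An OWL class definition mentioned in an `rdf:type`
pattern acts as an *abstract workflow*: its decomposed requirements — the
"needs" of the class — are concretized at run time into data lookups,
service invocations and reasoning steps (`planForClass()`).

## The supported OWL fragment

Class expressions are restricted to a positive-existential fragment: named
classes, intersections, existential restrictions (`someValuesFrom`), value
restrictions (`hasValue`) and numeric datatype ranges with XSD facets,
plus asserted `rdfs:subClassOf` / `rdfs:subPropertyOf` axioms.  Universal
restrictions and cardinalities are deliberately excluded: positive
membership entailment for them requires closed-world assumptions that a
graph which grows by service invocation cannot honestly make.  Everything
in the fragment is monotone, which is what makes the execution model sound:
merging more service output can never retract an earlier classification.
Constructs outside the fragment raise an error naming the construct —
nothing is silently dropped.

The built-in classifier (`classifyAll()`) materializes entailed `rdf:type`
triples to a fixpoint and is idempotent; any external classifier with the
same contract can be plugged into the engine through the `reasoner`
argument of `executePlan()`/`answerQuery()`.

## The worked clinical example

The demonstration domain is a transplant clinic. The shipped ontology
defines the cascade

* `LikelyRejecter == Patient and (hasCreatinineCollection some ElevatedLevels)`
* `ElevatedLevels == MeasurementCollection and (hasRegressionModel some IncreasingModel)`
* `IncreasingModel == LinearRegressionModel and (slope some decimal[> 0])`

together with the subclass axiom that a blood-chemistry time-course is a
specialized type of X-Y coordinate data — the link that lets a *generic*
regression service consume *clinical* collections.  Three services are
registered: an ordinary-least-squares regression annotator and two
latest-value annotators (`latestCreatinine`, `latestBUN`).

`LikelyRejecter` is deliberately a *hypothesis encoded as a class*, not a
validated clinical definition: creatinine can be dangerously elevated
without rising.  The package takes no position on its clinical merit; a
threshold-based notion of "elevated" is a natural extension point that is
not implemented.

```{r demo}
cohort <- generateCohort(cohortSpec(nPatients = 10, noiseSd = 0, seed = 1))
ont <- demoOntology()
reg <- demoRegistry(ont)
res <- answerQuery(likelyRejecterQuery(), cohort$graph, reg, ont)
res$bindings
```

## Design choices

Several points were genuinely open and were decided once, as follows.

**"Increasing" is strict.** The increasing-model class uses a
`minExclusive 0` facet on the slope: a perfectly flat series is *not*
increasing.  Strict inequality is the natural reading and makes the
zero-slope boundary exactly testable.

**"Latest" is the maximum-x measurement**, ties broken by
lexicographically greatest measurement IRI.  No operational definition
exists in the domain vocabulary, so the package fixes a deterministic one.

**Blank-node subjects are rejected in instance data.** The same-URI
service contract is unverifiable for unnamed nodes.  Ontology documents,
which need anonymous restriction nodes, are loaded with blank nodes
skolemized to stable `urn:bnode:` IRIs.

**Services may describe the nodes they mint.** The regression service
attaches a model node and states its slope; the contract validator
(`validateContract()`) therefore accepts added triples whose subject is
reachable from an input subject through the added triples themselves, and
flags everything else as a foreign-subject violation.

**All matching services are invoked** when several attach the same
predicate: RDF merge is monotone, so union preserves completeness without
inventing a ranking the service descriptions do not carry.  A service is
invoked only for subjects that still lack the predicate — an optimization,
not a correctness choice, under merge semantics.

**Planning inspects only the basic graph pattern**; `FILTER` is applied at
final evaluation.  Predicate services run after classification so their
subject sets are narrowed to the individuals the query can still bind
(in the worked example, latest values are fetched only for classified
likely rejecters).

**Bounded re-planning.** After a pass, the query is re-planned and
re-executed only while some service is still producing triples (service
output is the only thing that can enable another service's input; each
pass already ends with classification), up to 3 passes.  The worked
example settles in one pass plus a confirming classification.

**Minted node IRIs are deterministic** functions of their source IRI
(a fixed suffix), so repeated runs produce identical graphs and traces.

**Numeric literal comparison** promotes all XSD numeric types to R
doubles.  Fixture values carry at most 15 significant digits, for which
double comparison is exact in every test the package performs; serialized
decimals always use plain (never scientific) notation.

## The synthetic cohort generator

`generateCohort()` emulates a clinical RDF database: `nPatients` patients,
each with creatinine and BUN time-courses of `nTimepoints` measurements
every `intervalDays` days.  Creatinine follows
`y = base + slope * x + N(0, noiseSd^2)` with `slopeRejecter`
(+0.05 mg/dL/day by default) for the first `round(nPatients *
fractionRejecter)` patients and `slopeNon` (-0.02) for the rest; baseline
1.0 mg/dL and 0.05 mg/dL noise are plausible clinical magnitudes.  BUN is
generated around a 15 mg/dL baseline with a small random per-patient slope,
uncorrelated with the creatinine trend — it exists as payload for the
latest-value service.  Each patient draws from a dedicated random stream
(`seed + patient index`), so enlarging a cohort never changes earlier
patients' measurements.

Ground truth is emitted per patient: the *intended* label (which
generating slope was used) and the *oracle* label — the sign of an
independent OLS fit (`stats::lm`) on the values exactly as serialized into
the graph.  The oracle label, not the generating parameter, is what the
engine must reproduce: this keeps noisy borderline patients exactly
checkable instead of stochastically flaky.  With zero noise the two labels
coincide; they may legitimately differ when the generating slope is small
relative to the noise-induced slope standard error.

What the generator does **not** emulate: pharmacokinetic creatinine
dynamics, missing measurements, or correlation between analytes.  Passing
tests therefore demonstrate the correctness of the discovery, planning,
annotation and classification machinery on data of realistic shape — not
clinical validity on real patients.

## Numerical and degenerate-input behavior

`olsFit()` uses the closed form (centered cross-products) and is exact for
collinear input; it refuses series with fewer than two distinct x values
with a typed `sadishare_not_fittable` condition, which services translate
into a per-subject failure that never aborts the rest of a batch.  A
literal of the wrong datatype tested against a numeric facet counts as
not satisfying, with a warning — open-world data is messy and
classification should not abort on one bad literal.  Unresolvable query
requirements are surfaced in the coverage table and as warnings, never as
silently empty answers.

## Problem sizes

The shipped test-suite exercises: round-trips and merge algebra on random
graphs; classifier-versus-model-checker agreement on 100 random graphs of
up to 20 individuals with random expressions of depth up to 3; end-to-end
engine-versus-full-materialization agreement on 20 noisy 50-patient
cohorts; contract fuzzing across more than 50 invocations; and 1000 random
regression fits against `stats::lm` at 1e-9 relative tolerance.  These
sizes were chosen so the whole suite completes in a few minutes on one
core while still covering every cascade depth the demo ontology can
produce.

## Known limitations

* The ontology reader handles the OWL vocabulary the fragment needs, not
  arbitrary OWL 2 documents; the SPARQL engine covers SELECT with basic
  graph patterns, FILTER, DISTINCT and a single FROM (resolved against
  local graphs only, never dereferenced).
* Consumption-based discovery (`findConsuming()`) uses syntactic
  requirement coverage under the subclass/subproperty closures — a sound,
  cheap approximation of subsumption, not full TBox reasoning.
* Services are in-process callables behind the invocation contract; no
  HTTP transport, authentication or asynchronous polling is provided.
* One shared predicate namespace per deployment is assumed; predicate
  polysemy across providers is out of scope.
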