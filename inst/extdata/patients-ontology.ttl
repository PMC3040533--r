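# Transplant-clinic demo ontology: the Likely Rejecter cascade.
#
# A Likely Rejecter is a patient whose creatinine collection is "elevated";
# elevated levels are a measurement collection with an "increasing" linear
# regression model; an increasing model is one with strictly positive slope.
# A blood-chemistry time-course is a specialized type of X-Y coordinate
# data, which is what lets a generic regression service consume it.

@prefix owl:  <http://www.w3.org/2002/07/owl#> .
@prefix rdf:  <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix xsd:  <http://www.w3.org/2001/XMLSchema#> .
@prefix pat:  <http://sadi-share.example.org/ontologies/patients.owl#> .
@prefix pred: <http://sadi-share.example.org/ontologies/predicates.owl#> .

# --- primitive classes ------------------------------------------------------

pat:Patient               a owl:Class .
pat:Measurement           a owl:Class .
pat:MeasurementCollection a owl:Class .
pat:XYCoordinateData      a owl:Class .
pat:LinearRegressionModel a owl:Class .

pat:BloodChemistryTimeCourse a owl:Class ;
    rdfs:subClassOf pat:MeasurementCollection ;
    rdfs:subClassOf pat:XYCoordinateData .

# --- properties -------------------------------------------------------------

pat:hasCreatinineCollection a owl:ObjectProperty .
pat:hasBUNCollection        a owl:ObjectProperty .
pat:hasMeasurement          a owl:ObjectProperty .
pat:hasXValue               a owl:DatatypeProperty .
pat:hasYValue               a owl:DatatypeProperty .
pred:hasRegressionModel     a owl:ObjectProperty .
pred:slope                  a owl:DatatypeProperty .
pred:intercept              a owl:DatatypeProperty .
pred:latestMeasurement      a owl:DatatypeProperty .

pred:latestCreatinine a owl:DatatypeProperty ;
    rdfs:subPropertyOf pred:latestMeasurement .
pred:latestBUN a owl:DatatypeProperty ;
    rdfs:subPropertyOf pred:latestMeasurement .

# --- the Likely Rejecter cascade --------------------------------------------

pat:IncreasingModel a owl:Class ;
    owl:equivalentClass [ a owl:Class ;
        owl:intersectionOf ( pat:LinearRegressionModel
            [ a owl:Restriction ;
              owl:onProperty pred:slope ;
              owl:someValuesFrom [ a rdfs:Datatype ;
                  owl:onDatatype xsd:decimal ;
                  owl:withRestrictions ( [ xsd:minExclusive 0.0 ] ) ] ] ) ] .

pat:ElevatedLevels a owl:Class ;
    owl:equivalentClass [ a owl:Class ;
        owl:intersectionOf ( pat:MeasurementCollection
            [ a owl:Restriction ;
              owl:onProperty pred:hasRegressionModel ;
              owl:someValuesFrom pat:IncreasingModel ] ) ] .

pat:LikelyRejecter a owl:Class ;
    owl:equivalentClass [ a owl:Class ;
        owl:intersectionOf ( pat:Patient
            [ a owl:Restriction ;
              owl:onProperty pat:hasCreatinineCollection ;
              owl:someValuesFrom pat:ElevatedLevels ] ) ] .

# --- service input/output classes -------------------------------------------

pred:RegressionAnnotatedData a owl:Class ;
    owl:equivalentClass [ a owl:Class ;
        owl:intersectionOf ( pat:XYCoordinateData
            [ a owl:Restriction ;
              owl:onProperty pred:hasRegressionModel ;
              owl:someValuesFrom pat:LinearRegressionModel ] ) ] .

pred:PatientWithCreatinineSeries a owl:Class ;
    owl:equivalentClass [ a owl:Class ;
        owl:intersectionOf ( pat:Patient
            [ a owl:Restriction ;
              owl:onProperty pat:hasCreatinineCollection ;
              owl:someValuesFrom [ a owl:Restriction ;
                  owl:onProperty pat:hasMeasurement ;
                  owl:someValuesFrom pat:Measurement ] ] ) ] .

pred:PatientWithLatestCreatinine a owl:Class ;
    owl:equivalentClass [ a owl:Class ;
        owl:intersectionOf ( pat:Patient
            [ a owl:Restriction ;
              owl:onProperty pred:latestCreatinine ;
              owl:someValuesFrom xsd:decimal ] ) ] .

pred:PatientWithBUNSeries a owl:Class ;
    owl:equivalentClass [ a owl:Class ;
        owl:intersectionOf ( pat:Patient
            [ a owl:Restriction ;
              owl:onProperty pat:hasBUNCollection ;
              owl:someValuesFrom [ a owl:Restriction ;
                  owl:onProperty pat:hasMeasurement ;
                  owl:someValuesFrom pat:Measurement ] ] ) ] .

pred:PatientWithLatestBUN a owl:Class ;
    owl:equivalentClass [ a owl:Class ;
        owl:intersectionOf ( pat:Patient
            [ a owl:Restriction ;
              owl:onProperty pred:latestBUN ;
              owl:someValuesFrom xsd:decimal ] ) ] .
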