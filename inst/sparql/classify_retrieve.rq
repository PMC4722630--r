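# Retrieve, for one finding, all normal-size specifications applicable to
# its entity and measured quality via the subclass hierarchies.
# (Reference query; the package executes the equivalent triple patterns
# with its built-in matcher.)
PREFIX rs:   <http://example.org/radsize#>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>

SELECT ?finding ?spec ?rangeLow ?rangeHigh WHERE {
  ?finding  a rs:ClinicalFinding ;
            rs:describes ?q .
  ?q        rs:inheresIn ?e ;
            a ?qualityClass ;
            rs:hasMeasurement ?m .
  ?e        a ?entityClass .
  ?spec     a rs:NormalSizeSpecification ;
            rs:isAbout ?specEntity ;
            rs:hasQualityType ?specQuality .
  ?entityClass  rdfs:subClassOf* ?specEntity .
  ?qualityClass rdfs:subClassOf* ?specQuality .
  OPTIONAL { ?spec rs:low ?rangeLow }
  OPTIONAL { ?spec rs:high ?rangeHigh }
}
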