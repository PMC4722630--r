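# Boolean verification of a target-lesion selection: true iff the limits
# are violated (at most five target lesions, at most two per organ).
PREFIX rs: <http://example.org/radsize#>

ASK {
  {
    SELECT (COUNT(?l) AS ?n) WHERE { ?l a rs:TargetLesion }
    HAVING (?n > 5)
  }
  UNION
  {
    SELECT ?organ (COUNT(?l) AS ?k) WHERE {
      ?l a rs:TargetLesion ; rs:locatedIn ?organ .
    }
    GROUP BY ?organ
    HAVING (?k > 2)
  }
}
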