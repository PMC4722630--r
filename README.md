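# radsize

Ontology-based classification of radiology size measurements and RECIST
response evaluation.

Radiology reports state sizes without interpretation — "spleen
14.8 × 8.5 cm", "lymph nodes up to 1.6 × 1.2 cm" — and whether such a value
is normal depends on *which* anatomical entity was measured, in *which*
direction, and on reference knowledge scattered across the literature.
radsize is for clinical-informatics developers and researchers who need
that interpretation step as code: it encodes normal-size knowledge over an
anatomical concept hierarchy, classifies measurement findings as
normal / abnormal / unclassified, applies the RECIST 1.1 rules to target
lesions over time, exports everything as an RDF knowledge graph with an
equivalent query-based execution path, and renders longitudinal red/green
views of a patient's findings.

## The core method

A *normal size specification* states that quality Q′ of entity E′ is normal
within a range: an upper bound (lymph node, short axis, ≤ 10 mm), a lower
bound (ascending aorta at the root, diameter, ≥ 40 mm) or an interval
(gallbladder wall, thickness, 1–3 mm). A finding measures quality Q of
entity E. A specification applies when E ⊑ E′ in the subclass hierarchy and
Q ⊑ Q′ in the quality hierarchy, and the *most specific* applicable pair
(E′, Q′) is retrieved: no other specification (E″, Q″) may sit with E″
strictly on the subclass path between E and E′ and Q″ on the path between Q
and Q′; remaining candidates are ranked by subclass path length (entity,
then quality), and a full tie is reported as an ambiguous knowledge base.
The retrieved range is then compared with the measured value (inclusive
bounds, everything in mm) and the finding labelled; findings whose entity
has no applicable specification stay *unclassified*.

On top of this sit the RECIST 1.1 computations: target-lesion candidacy
(short axis ≥ 15 mm for nodes, longest diameter ≥ 10 mm otherwise),
selection verification (≤ 5 lesions, ≤ 2 per organ), per-exam diameter sums,
and response labels — CR iff all targets disappeared and every pathological
node is < 10 mm; PD iff new lesions, or current ≥ 1.2 × nadir with an
absolute increase ≥ 5 mm; PR iff current ≤ 0.7 × baseline; SD otherwise,
with precedence CR > PD > PR > SD.

## Worked example

```r
library(radsize)
kb <- packaged_kb()   # ~36-concept hierarchy + published size specifications

f <- new_finding("P1", "E1", "2024-01-15", "RID86",
                 data.frame(value = c(14.8, 8.5), unit = "cm"),
                 entity_kind = "anatomical_structure", entity_label = "spleen",
                 sentence = "Milz 14,8 x 8,5 cm.")
classify_finding(f, kb)
#> <rad_classification> P1:E1:RID86: normal (eq_match)
#>   value unit value_mm quality       spec_id  label
#> 1  14.8   cm      148  height spleen_height normal
#> 2   8.5   cm       85  length spleen_length normal
```

The two unlabeled values are assigned positionally (largest value to the
spec with the largest bound): 14.8 cm is read as the height (normal range
11–15 cm) and 8.5 cm as the length (7–10 cm), so the finding is overall
normal — the known failure mode of purely size-based classification when
the measurement was actually taken in the axial plane.

```r
classify_response(c(100, 50, 61))
#> <rad_response> exam NA: PD (baseline 100 mm, nadir 50 mm, current 61 mm)
```

61 mm is 22 % and 11 mm above the 50 mm nadir, so both progression
conditions are met: Progressive Disease.

A command-line front end (`inst/cli/radsize.R`) wraps the same functions:

```sh
Rscript inst/cli/radsize.R simulate --scenario PR --seed 7 --out cohort/
Rscript inst/cli/radsize.R classify --findings cohort/findings.jsonl --rdf graph.ttl
Rscript inst/cli/radsize.R recist --findings cohort/findings.jsonl \
        --selection cohort/selection.json --flags cohort/new_lesions.csv
Rscript inst/cli/radsize.R view --findings cohort/findings.jsonl \
        --patient P001 --by-region thorax --format html --out view.html
```

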