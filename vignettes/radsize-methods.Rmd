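---
title: "Normal-size classification and RECIST evaluation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normal-size classification and RECIST evaluation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsize)
```

## The problem

Radiology reports state sizes without interpretation: "spleen 14.8 × 8.5 cm"
or "lymph nodes up to 1.6 × 1.2 cm" leave it to the reader to decide whether
these values are normal. For laboratory values this normal/low/high
classification is routine; for imaging measurements it is not, because the
reference knowledge is scattered (which entity, which direction of
measurement, which bound) and because the measured entity may be described
at any level of an anatomical hierarchy. radsize encodes that reference
knowledge as a small knowledge base of *normal size specifications* over a
concept hierarchy, classifies measurement findings against it, and layers
the RECIST 1.1 response rules and a longitudinal viewer on top.

## Normal-size specifications

A specification states that a quality $Q'$ of an anatomical entity $E'$ is
normal within a range. Three range types cover the forms found in the
literature:

* **upper bound** — normal iff $v \le h$ (lymph node, short axis, 10 mm);
* **lower bound** — normal iff $v \ge l$ (ascending aorta at the root,
  diameter, 40 mm);
* **interval** — normal iff $l \le v \le h$ (gallbladder wall, thickness,
  1–3 mm).

All bounds are inclusive at both ends: "up to 1 cm is normal" means a
10 mm node is normal, and a 40 mm aortic root sits exactly on its lower
bound and is normal. Bounds are converted to millimetres at load time
(1 cm = 10 mm) and every comparison happens in mm; mixing centimetre and
millimetre statements is a real source of error in this material, and a
single canonical unit removes it. Boundary comparisons carry a $10^{-9}$ mm
guard so that unit conversion can never flip a value that sits exactly on a
bound.

The packaged knowledge base holds the lymph-node bounds (generic 10 mm,
submental 15 mm), the spleen triple (height 11–15 cm, length 7–10 cm, width
4–6 cm), the ascending-aorta root lower bound (4 cm), and the kidney,
gallbladder-wall and ureter intervals. Two statements about spleen length
circulate — an interval of 7–10 cm and a single 15 cm upper bound — and they
cannot coexist for one entity/quality pair; the interval form is enabled
because the package's worked spleen examples depend on the three-range
triple, and the upper-bound form ships as a disabled alternative entry that
users may switch on instead. The aortic-root *lower* bound is kept exactly
as published even though an ectatic 4 cm ascending aorta is thereby called
normal; this reproduces the documented behavior of the approach, whose fix
(more granular specifications) is a knowledge-base extension, not a code
change.

## Entity–Quality retrieval

A finding carries an entity $E$ (e.g. *submental lymph node*) and a measured
quality $Q$ (e.g. *short axis*). A specification $(E', Q')$ *applies* when
$E \sqsubseteq E'$ in the anatomical subclass hierarchy and
$Q \sqsubseteq Q'$ in the quality hierarchy — this is what lets roughly one
statement about "lymph node" cover every nodal station. Among applicable
specifications, the *most specific* is retrieved: $(E', Q')$ is discarded if
another specification $(E'', Q'')$ has $E''$ strictly between $E$ and $E'$
on the subclass path with $Q''$ between $Q$ and $Q'$; remaining candidates
are ranked by subclass path length from $E$ to $E'$. The hierarchy is a DAG
(concepts may have several parents), so "path length" means the shortest
directed path.

Two design points go beyond that rule, which alone does not always produce
a unique answer:

* equal entity path lengths are broken by the *quality* path length,
  mirroring the entity rule on the quality side (a specification on *short
  axis* beats one on *1-D extent* at the same entity);
* if candidates still tie on both lengths, retrieval fails with an
  "ambiguous knowledge base" diagnostic instead of picking one arbitrarily.
  An ambiguous KB is a curation error and should be surfaced, not papered
  over.

The quality hierarchy is fixed: `size` → `1-D extent` → {`length`, `width`,
`height`, `thickness`, `diameter` → {`craniocaudal diameter`, `left-right
diameter`}, `longest axis`, `short axis`}. The last four are the
radiology-specific refinements: the longest axis is the longest straight
line within an object, the short axis the longest extent orthogonal to it —
the pair used to size tumors and nodes — and the two directed diameters tie
measurements to body axes (the craniocaudal axis is orthogonal to the axial
plane, so craniocaudal diameters come from coronal or sagittal images; the
packaged plane/axis model records these symmetric parallel/orthogonal
relations).

## Assigning unlabeled dimensions

Reports often give "14.8 × 8.5 cm, spleen" without saying which number is
which quality. No published rule covers this, so the package fixes one:
measurements sorted by descending value are paired positionally with the
applicable specifications sorted by descending bound (upper bound, or lower
bound when no upper exists); surplus measurements pair with nothing;
explicitly labeled measurements bypass the sort and consume the
specification of their quality first. This rule was chosen because it
reproduces both canonical spleen outcomes — 14.8 × 8.5 cm maps to height
(11–15) and length (7–10) and is overall normal, 9 × 3.5 × 6.5 cm maps to
height/length/width and is overall abnormal — while being a pure,
permutation-stable function of the measurement multiset. Note that for the
second spleen the per-dimension story differs from a radiologist's reading:
the positional rule flags 9 cm < 11 cm (height) and 6.5 cm < 7 cm (length)
in addition to the narrow width; the overall label is unaffected.

A finding is **unclassified** when no dimension finds a specification (rib,
"portion of soft tissue"), **abnormal** when at least one dimension falls
outside its range, otherwise **normal**. Unclassified is a first-class
outcome, and in evaluation it always counts as incorrect.

Findings about lesions, cysts and masses get a dedicated rule: normal-size
specifications describe anatomy, and no size makes a lesion normal, so
lesion-kind findings are labelled abnormal with provenance `lesion_rule`.
That reading is a documented assumption — nothing in the source material
states how lesions were scored — and `lesion_rule = "unclassified"` switches
it off.

## RECIST rules

Four computations, exactly as printed in the guideline summary:

1. **Candidacy**: at baseline, lymph nodes with short axis ≥ 15 mm and
   other lesions with longest diameter ≥ 10 mm are *potential* targets.
   Selection among them is the radiologist's decision and is always an
   input.
2. **Selection verification**: at most five target lesions, at most two per
   organ (organ resolved through the part-of closure); a boolean check.
3. **Diameter sum**: short axis for nodes, longest axis for other lesions,
   summed per exam; an absent lesion contributes 0 mm.
4. **Response**: with $b$ the baseline sum, $n$ the nadir (smallest sum
   strictly before the current exam, baseline included) and $c$ the current
   sum —
   CR iff $c = 0$ and every pathological node's short axis is `< 10` mm
   (strict); PD iff new lesions appeared or ($c \ge 1.2\,n$ and
   $c - n \ge 5$ mm); PR iff $c \le 0.7\,b$; SD otherwise.
   Percent thresholds are inclusive ("at least a 30 % decrease" includes
   exactly 30 %); the CR node threshold is strict ("< 10 mm").

The criteria are published without an explicit ordering beyond "if not
otherwise classified, stable disease"; the package applies CR > PD > PR >
SD, following the convention that progression dominates response when both
conditions are met. The PR reference is always the baseline sum, the PD
reference always the nadir. The 5 mm absolute-increase condition
deliberately breaks scale invariance of the percent rules: shrinking a
timeline by a factor small enough pushes a 20 % increase under 5 mm and the
label reverts to SD, and the test suite asserts the invariance both ways.

## Knowledge-graph export and the query path

`export_graph()` serializes findings (finding node → quality instances →
measurement data with value and unit, inhering in one material-entity node),
specifications, the two concept hierarchies, the plane/axis model, RECIST
sums and target-lesion selections as RDF triples, written as Turtle. IRIs
are minted in a project namespace; external vocabulary identifiers survive
as concept-IRI local parts and labels rather than importing the source
ontologies, which keeps the graph desk-scale and self-contained. The writer
emits one triple per line — a deliberately flat Turtle profile that the
bundled parser reads back losslessly (round-trip identity is tested).

`query_classify()` re-runs the classification purely as triple-pattern
queries over that graph: subclass closure, most-specific filtering,
positional assignment and value comparison are all recomputed against the
triple table, sharing no code with the in-memory classifier. Classification
is value comparison, not description-logic reasoning, so a pattern-matching
engine is the right substrate; the equivalent SPARQL texts ship under
`inst/sparql/` for reference. The two paths agreeing on every fixture
finding is the package's strongest internal oracle. `verify_selection` has
the same dual form as a boolean graph query.

## The longitudinal viewer

`select_findings()` filters by entity (subclass subtree) or by body region
(upward part-of/subclass closure — an axillary node is part of the axilla,
which is part of the thorax). `build_tracks()` orders findings by exam
date; entities that occur exactly once in the body (a configurable
whitelist shipping with spleen, liver, kidney, gallbladder wall, ureter,
aorta segments, trachea) form one *linked* track, while lymph nodes and
lesions stay unlinked and are only grouped for display — two mediastinal-node
findings from consecutive exams need not describe the same node, and the
package never pretends otherwise. `render_tracks()` emits deterministic
text or static HTML, one column per exam, values next to the verbatim
report sentence, red for abnormal, green for normal, grey for unclassified.

## The synthetic cohort generator

Real report corpora cannot ship with a package, so every component is
exercised on generated cohorts. A scenario fixes a response course (CR, PR,
PD, SD, or mixed), cohort size, per-exam scale factors and a noise level;
per patient the generator emits a three-dimensional spleen finding, labeled
kidney / gallbladder-wall / ureter measurements, a non-target lymph node, an
occasional KB-uncovered entity (rib), and 2–4 target lesions in distinct
organs whose baseline sizes respect the candidacy thresholds. Default
courses end at 0 × (CR, with a sub-10 mm residual node), 0.65 × (PR),
1.45 × (PD, a quarter of PD patients additionally flagged with new
lesions), 1.04 × (SD) of baseline. Noise is multiplicative uniform in
$[1-\varepsilon, 1+\varepsilon]$ — sizes are positive and ratio-scaled —
with default $\varepsilon = 0.02$, a realistic repeat-measurement
variability that leaves all course labels intact. Gold normality labels are
decided by which band a value is drawn from (bands keep a ≥ 5 % margin from
every specification bound, wider than the reporting quantization), never by
running the classifier; at zero noise the classifier must recover them
exactly, and with noise any disagreement must lie within the noise band of
a bound — both are tested. German sentence templates are carried verbatim
into the stream so non-ASCII handling is exercised end to end.

What the generator does *not* emulate: free-text extraction (sentences are
display payload, never parsed), inter-reader variability, realistic
prevalence of entities, and lesion-identity noise across exams. Passing
tests therefore validate the algorithms and their contracts, not
information-extraction quality on real German reports; the published
dataset-scale accuracies are represented in this package only by their
confusion-table arithmetic.

## Numerical choices and problem sizes

* Canonical unit mm; conversions snap to a 10⁻⁹ grid so cm → mm → cm is
  exact for reported precisions.
* All threshold comparisons carry a 10⁻⁹ mm guard; thresholds themselves
  are never tolerated away (a 14.9 mm node is not a target).
* Deterministic tie-breaks everywhere: specifications sort by id on equal
  bounds, exams by date then id; rendering injects no timestamps.
* Test problem sizes: the full fixture KB (36 concepts × 11 qualities)
  against a brute-force retrieval oracle; ≥ 50-finding cohorts for the
  dual-path equivalence; 1000 random timelines against a transcription of
  the response criteria; cohorts of 8–15 patients elsewhere. These sizes
  exercise every rule branch while keeping the default suite around a
  minute.

## Limitations

* The knowledge base is fixture-scale; coverage of real reports requires
  loading a fuller hierarchy and specification set (both readers accept
  user files).
* No patient context: bounds do not condition on age, sex or body size.
* The lesion-abnormality rule and the positional dimension-assignment rule
  are explicit package choices where the source material is silent; both
  are documented above and the former is switchable.
* Lesion identity across exams is an input (`lesion_id`), never inferred.
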