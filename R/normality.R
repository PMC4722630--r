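#' Compare a measured value to a normal-size specification
#'
#' Bounds are inclusive at both ends: a value equal to an upper bound is
#' normal ("normal lymph nodes are up to 1 cm in the short axis"), and a
#' value equal to a lower bound is normal. Comparisons use a 1e-9 mm
#' tolerance so unit conversion cannot flip boundary cases.
#'
#' @param value_mm Measured value in mm (positive).
#' @param spec One-row `rad_specs` data.frame.
#' @return `"normal"`, `"abnormal_high"`, or `"abnormal_low"`.
#' @export
classify_value <- function(value_mm, spec) {
  stopifnot(is.numeric(value_mm), length(value_mm) == 1, value_mm > 0)
  lo <- spec$low_mm[1]; hi <- spec$high_mm[1]
  switch(spec$range_type[1],
    upper_bound = if (value_mm <= hi + MM_TOL) "normal" else "abnormal_high",
    lower_bound = if (value_mm >= lo - MM_TOL) "normal" else "abnormal_low",
    interval = if (value_mm > hi + MM_TOL) "abnormal_high"
               else if (value_mm < lo - MM_TOL) "abnormal_low"
               else "normal",
    stop("unknown range_type: ", spec$range_type[1])
  )
}

#' Classify a measurement finding as normal / abnormal / unclassified
#'
#' The central algorithm: for each measured dimension the most specific
#' applicable normal-size specification is retrieved by Entity-Quality
#' matching ([most_specific_spec()]); unlabeled dimensions are routed
#' through [assign_dimensions()]; each matched value is compared to its
#' specification and the overall label aggregated. A finding is
#' `unclassified` when no dimension finds a specification, `abnormal` when
#' at least one dimension falls outside its normal range, otherwise
#' `normal`. The resulting type is written back onto the finding.
#'
#' Findings about lesions, cysts and masses describe inherently
#' pathological structures that no normal-size specification covers; by
#' default they are labelled abnormal with provenance `"lesion_rule"`
#' (switch with `lesion_rule = "unclassified"`).
#'
#' @param finding A `rad_finding`.
#' @param kb A knowledge base list with elements `graph` (`rad_anatomy`)
#'   and `specs` (`rad_specs`), e.g. from [packaged_kb()].
#' @param lesion_rule `"abnormal"` (default) or `"unclassified"`.
#' @return An object of class `rad_classification`: list with
#'   `finding_id`, `outcomes` (data.frame: `value`, `unit`, `value_mm`,
#'   `quality`, `spec_id`, `label`), `overall`, `provenance`, and the
#'   updated `finding`.
#' @export
classify_finding <- function(finding, kb, lesion_rule = c("abnormal", "unclassified")) {
  lesion_rule <- match.arg(lesion_rule)
  graph <- kb$graph; specs <- kb$specs
  kind <- entity_kind_of(finding, graph)

  known <- finding$entity_id %in% graph$nodes$id
  ap <- if (known) applicable_specs(graph, specs, finding$entity_id) else specs[0, ]
  pairing <- assign_dimensions(finding, ap)
  pairing$label <- vapply(seq_len(nrow(pairing)), function(i) {
    if (is.na(pairing$spec_id[i])) return("no_spec")
    classify_value(pairing$value_mm[i],
                   specs[specs$spec_id == pairing$spec_id[i], , drop = FALSE])
  }, character(1))

  provenance <- "eq_match"
  if (kind == "lesion" && lesion_rule == "abnormal") {
    overall <- "abnormal"
    provenance <- "lesion_rule"
    pairing$label <- "no_spec"
    pairing$spec_id <- NA_character_
  } else if (all(pairing$label == "no_spec")) {
    overall <- "unclassified"
  } else if (any(pairing$label %in% c("abnormal_high", "abnormal_low"))) {
    overall <- "abnormal"
  } else {
    overall <- "normal"
  }

  finding$finding_type <- overall
  structure(
    list(finding_id = finding$finding_id, outcomes = pairing,
         overall = overall, provenance = provenance, finding = finding),
    class = "rad_classification"
  )
}

#' @export
print.rad_classification <- function(x, ...) {
  cat("<rad_classification> ", x$finding_id, ": ", x$overall,
      " (", x$provenance, ")\n", sep = "")
  print.data.frame(x$outcomes, ...)
  invisible(x)
}

#' Classify a list of findings
#'
#' @param findings List of `rad_finding` objects.
#' @inheritParams classify_finding
#' @return A list of `rad_classification` results with attribute
#'   `"findings"`, the input findings with `finding_type` written back.
#' @seealso [classification_table()] for a flat per-finding summary.
#' @export
classify_findings <- function(findings, kb, lesion_rule = c("abnormal", "unclassified")) {
  lesion_rule <- match.arg(lesion_rule)
  results <- lapply(findings, classify_finding, kb = kb, lesion_rule = lesion_rule)
  attr(results, "findings") <- lapply(results, `[[`, "finding")
  results
}

#' Flatten classification results to a data.frame
#'
#' @param results List of `rad_classification` objects.
#' @return data.frame with columns `finding_id`, `overall`, `provenance`,
#'   `n_dimensions`, `matched_specs`.
#' @export
classification_table <- function(results) {
  data.frame(
    finding_id = vapply(results, `[[`, character(1), "finding_id"),
    overall = vapply(results, `[[`, character(1), "overall"),
    provenance = vapply(results, `[[`, character(1), "provenance"),
    n_dimensions = vapply(results, function(r) nrow(r$outcomes), integer(1)),
    matched_specs = vapply(results, function(r) {
      paste(stats::na.omit(r$outcomes$spec_id), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Score classifications against radiologist gold labels
#'
#' Builds the confusion table used for evaluation: `true_normal` /
#' `true_abnormal` count agreements, `false_normal` is a finding the
#' classifier called normal but the radiologist called abnormal (and vice
#' versa for `false_abnormal`). Unclassified findings are always counted as
#' incorrect: they enter the denominator but never the numerator.
#'
#' @param predicted Character vector of classifier labels (`normal`,
#'   `abnormal`, `unclassified`), named by finding id, or a list of
#'   `rad_classification` results.
#' @param gold Character vector of radiologist labels (`normal` /
#'   `abnormal`) named by finding id.
#' @return List with `counts` (named integer vector: `true_normal`,
#'   `true_abnormal`, `false_normal`, `false_abnormal`, `unclassified`),
#'   `n`, and `accuracy_pct` = 100 * (true_normal + true_abnormal) / n.
#' @export
evaluate_against_gold <- function(predicted, gold) {
  if (is.list(predicted) && !is.null(predicted[[1]]$overall)) {
    nm <- vapply(predicted, `[[`, character(1), "finding_id")
    predicted <- stats::setNames(vapply(predicted, `[[`, character(1), "overall"), nm)
  }
  if (is.null(names(predicted)) || is.null(names(gold))) {
    stop("predicted and gold must be named by finding id")
  }
  missing_pred <- setdiff(names(gold), names(predicted))
  missing_gold <- setdiff(names(predicted), names(gold))
  if (length(missing_pred) || length(missing_gold)) {
    stop("finding id sets differ; missing predictions: ",
         paste(missing_pred, collapse = ", "),
         "; missing gold labels: ", paste(missing_gold, collapse = ", "))
  }
  stopifnot(all(gold %in% c("normal", "abnormal")))
  predicted <- predicted[names(gold)]
  counts <- c(
    true_normal = sum(predicted == "normal" & gold == "normal"),
    true_abnormal = sum(predicted == "abnormal" & gold == "abnormal"),
    false_normal = sum(predicted == "normal" & gold == "abnormal"),
    false_abnormal = sum(predicted == "abnormal" & gold == "normal"),
    unclassified = sum(predicted == "unclassified")
  )
  n <- length(gold)
  list(counts = counts, n = n,
       accuracy_pct = 100 * (counts[["true_normal"]] + counts[["true_abnormal"]]) / n)
}
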