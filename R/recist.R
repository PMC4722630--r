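#' RECIST-relevant diameter of a finding
#'
#' Lymph nodes are sized by their short axis, all other lesions by their
#' longest axis. A labeled measurement of that quality wins; otherwise the
#' value is inferred from an unlabeled multi-dimensional measurement (the
#' largest value for lesions; the second-largest of at least two values for
#' lymph nodes, since nodes are reported as longest axis x short axis). A
#' lymph node with a single unlabeled value has no identifiable short axis
#' and yields `NA`.
#'
#' @param finding A `rad_finding`.
#' @param kind `"lymph_node"` or `"lesion"`.
#' @return Diameter in mm, or `NA_real_` when not identifiable.
#' @export
relevant_diameter <- function(finding, kind = c("lesion", "lymph_node")) {
  kind <- match.arg(kind)
  m <- finding$measurements
  want <- if (kind == "lymph_node") "short axis" else "longest axis"
  lab <- which(!is.na(m$quality) & m$quality == want)
  if (length(lab)) return(m$value_mm[lab[1]])
  unl <- m$value_mm[is.na(m$quality)]
  if (kind == "lesion") {
    if (length(unl)) return(max(unl))
    return(max(m$value_mm))   # fall back to the largest labeled extent
  }
  if (length(unl) >= 2) return(sort(unl, decreasing = TRUE)[2])
  NA_real_
}

#' Flag potential target lesions at baseline
#'
#' At baseline, lesions with a longest diameter of at least 10 mm and lymph
#' nodes with a short axis of at least 15 mm qualify as potential target
#' lesions. The actual selection among potential targets is made by the
#' radiologist and is an input elsewhere; this operation only computes
#' candidacy. Findings whose relevant diameter cannot be identified are
#' excluded and reported with a diagnostic.
#'
#' @param findings List of `rad_finding` objects from the baseline exam
#'   (lymph nodes and lesions; anatomical-structure findings are ignored).
#' @param graph Optional `rad_anatomy` graph for entity-kind inference.
#' @return data.frame with columns `finding_id`, `lesion_id`, `entity_id`,
#'   `kind`, `diameter_mm`, `potential`; attribute `"excluded"` is a
#'   data.frame of findings lacking the relevant diameter.
#' @export
candidate_targets <- function(findings, graph = NULL) {
  rows <- list(); excl <- list()
  for (f in findings) {
    kind <- if (!is.null(graph)) entity_kind_of(f, graph) else f$entity_kind
    if (is.na(kind) || kind == "anatomical_structure") next
    d <- relevant_diameter(f, kind)
    if (is.na(d)) {
      excl[[length(excl) + 1L]] <- data.frame(
        finding_id = f$finding_id, kind = kind,
        reason = "relevant diameter not identifiable", stringsAsFactors = FALSE)
      next
    }
    thr <- if (kind == "lymph_node") 15 else 10
    rows[[length(rows) + 1L]] <- data.frame(
      finding_id = f$finding_id, lesion_id = f$lesion_id,
      entity_id = f$entity_id, kind = kind, diameter_mm = d,
      potential = d >= thr - MM_TOL, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(finding_id = character(), lesion_id = character(),
               entity_id = character(), kind = character(),
               diameter_mm = numeric(), potential = logical(),
               stringsAsFactors = FALSE)
  attr(out, "excluded") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(finding_id = character(), kind = character(),
               reason = character(), stringsAsFactors = FALSE)
  out
}

#' Resolve the organ hosting a lesion
#'
#' Walks the upward closure (part-of and subclass edges) from the lesion's
#' entity and returns the nearest concept in the organ set.
#'
#' @param graph A `rad_anatomy` graph.
#' @param entity Concept id of the lesion or lymph node.
#' @param organs Character vector of organ/region concept ids.
#' @return An organ id, or `NA_character_` when none is reachable.
#' @export
resolve_organ <- function(graph, entity, organs = packaged_organs()) {
  assert_concept(graph, entity)
  d <- suppressWarnings(igraph::distances(graph$g_up, v = entity,
                                          to = intersect(organs, graph$nodes$id),
                                          mode = "out"))
  if (!length(d) || !any(is.finite(d))) return(NA_character_)
  colnames(d)[which.min(d)]
}

#' Organ and region concepts used for target-lesion location
#' @return Character vector of concept ids in the packaged hierarchy.
#' @export
packaged_organs <- function() {
  c("liver", "lung", "RID205", "RID86", "gallbladder",
    "mediastinum", "axilla", "neck", "thorax", "abdomen")
}

#' Verify a target-lesion selection
#'
#' RECIST allows at most five target lesions overall and at most two per
#' organ. Mirrors the boolean verification query of the prototype: a
#' selection either passes or fails, with the violated constraints listed.
#'
#' @param selection data.frame with one row per selected lesion, columns
#'   `lesion_id` and `organ_id`.
#' @return List with `pass` (logical) and `violations` (character vector).
#' @export
verify_selection <- function(selection) {
  stopifnot(is.data.frame(selection), all(c("lesion_id", "organ_id") %in% names(selection)))
  violations <- character()
  if (nrow(selection) > 5) {
    violations <- c(violations,
                    sprintf("%d target lesions selected; at most 5 allowed", nrow(selection)))
  }
  tab <- table(selection$organ_id)
  over <- tab[tab > 2]
  if (length(over)) {
    violations <- c(violations,
                    sprintf("organ %s appears %d times; at most 2 allowed",
                            names(over), as.integer(over)))
  }
  list(pass = length(violations) == 0L, violations = violations)
}

#' Sum of target-lesion diameters at one exam
#'
#' Short axis for lymph nodes, longest axis for other lesions, summed over
#' the selected target lesions. A lesion absent at the exam contributes
#' 0 mm; a selected lesion with no measurement record at all is an error.
#'
#' @param diameters data.frame with columns `lesion_id`, `diameter_mm`,
#'   `present` (logical) for the exam; one row per selected lesion.
#' @param exam_id Exam identifier carried into the result.
#' @return An object of class `rad_recist_sum`: list with `exam_id`,
#'   `value_mm`, `contributions` (named numeric vector).
#' @export
recist_sum <- function(diameters, exam_id = NA_character_) {
  stopifnot(is.data.frame(diameters),
            all(c("lesion_id", "diameter_mm") %in% names(diameters)))
  if (is.null(diameters$present)) diameters$present <- diameters$diameter_mm > 0
  if (any(is.na(diameters$diameter_mm))) {
    stop("missing measurement for selected lesion(s): ",
         paste(diameters$lesion_id[is.na(diameters$diameter_mm)], collapse = ", "))
  }
  if (any(diameters$diameter_mm < 0)) stop("negative diameter")
  if (any(!diameters$present & diameters$diameter_mm > 0)) {
    stop("absent lesion with non-zero diameter: ",
         paste(diameters$lesion_id[!diameters$present & diameters$diameter_mm > 0],
               collapse = ", "))
  }
  contributions <- stats::setNames(diameters$diameter_mm, diameters$lesion_id)
  structure(list(exam_id = exam_id, value_mm = sum(contributions),
                 contributions = contributions),
            class = "rad_recist_sum")
}

#' @export
print.rad_recist_sum <- function(x, ...) {
  cat("<rad_recist_sum> exam ", x$exam_id, ": ", x$value_mm, " mm (",
      length(x$contributions), " lesions)\n", sep = "")
  invisible(x)
}

#' Classify tumor response at the current exam
#'
#' Applies the RECIST response rules to an ordered timeline of diameter
#' sums (baseline first, current exam last):
#' * Complete Response (CR): all target lesions have disappeared (current
#'   sum 0) and every pathological lymph node, target or not, has a short
#'   axis below 10 mm (strict).
#' * Progressive Disease (PD): new lesions appeared, or the current sum is
#'   at least 20 % above the nadir (the smallest sum before the current
#'   exam, baseline included) with an absolute increase of at least 5 mm.
#' * Partial Response (PR): the current sum is at least 30 % below the
#'   baseline sum.
#' * Stable Disease (SD): none of the above.
#' Precedence is CR > PD > PR > SD; percent thresholds are inclusive.
#'
#' @param sums Numeric vector of diameter sums in mm, ordered by exam date
#'   (baseline first); length >= 2. May also be a list of
#'   `rad_recist_sum` objects.
#' @param lymph_node_short_axes_mm Short axes (mm) of pathological lymph
#'   nodes still present at the current exam; only consulted for CR.
#' @param new_lesions `TRUE` when new lesions appeared at the current exam.
#' @param exam_id Exam identifier carried into the result.
#' @return An object of class `rad_response`: list with `exam_id`, `label`
#'   (`CR`/`PR`/`PD`/`SD`), `baseline_sum`, `nadir_sum`, `current_sum`,
#'   `new_lesions`.
#' @export
classify_response <- function(sums, lymph_node_short_axes_mm = numeric(0),
                              new_lesions = FALSE, exam_id = NA_character_) {
  if (is.list(sums)) sums <- vapply(sums, `[[`, numeric(1), "value_mm")
  if (!length(sums)) stop("empty timeline")
  if (length(sums) < 2) stop("response classification needs baseline plus one follow-up")
  stopifnot(all(is.finite(sums)), all(sums >= 0))

  baseline <- sums[1]
  current <- sums[length(sums)]
  nadir <- min(sums[-length(sums)])

  cr <- current <= MM_TOL &&
    (!length(lymph_node_short_axes_mm) || all(lymph_node_short_axes_mm < 10 - MM_TOL))
  pd <- isTRUE(new_lesions) ||
    (current >= 1.2 * nadir - MM_TOL && current - nadir >= 5 - MM_TOL)
  pr <- current <= 0.7 * baseline + MM_TOL

  label <- if (cr) "CR" else if (pd) "PD" else if (pr) "PR" else "SD"
  structure(list(exam_id = exam_id, label = label, baseline_sum = baseline,
                 nadir_sum = nadir, current_sum = current,
                 new_lesions = isTRUE(new_lesions)),
            class = "rad_response")
}

#' @export
print.rad_response <- function(x, ...) {
  cat("<rad_response> exam ", x$exam_id, ": ", x$label,
      " (baseline ", x$baseline_sum, " mm, nadir ", x$nadir_sum,
      " mm, current ", x$current_sum, " mm",
      if (x$new_lesions) ", new lesions" else "", ")\n", sep = "")
  invisible(x)
}

#' RECIST assessment over a patient timeline
#'
#' Builds per-exam diameter sums for a selected set of target lesions from
#' classified findings and labels every follow-up exam. Exams are ordered
#' by date, then exam id; the first exam is the baseline.
#'
#' @param findings List of `rad_finding` objects for one patient (lesions
#'   and lymph nodes carry `lesion_id`).
#' @param selection Character vector of selected target `lesion_id`s.
#' @param new_lesion_flags Named logical vector (by exam id); missing exams
#'   default to `FALSE`.
#' @param graph Optional `rad_anatomy` for entity-kind inference.
#' @return data.frame with one row per exam: `exam_id`, `exam_date`,
#'   `sum_mm`, `label` (`NA` for the baseline row), `new_lesions`.
#' @export
assess_timeline <- function(findings, selection, new_lesion_flags = logical(0),
                            graph = NULL) {
  info <- data.frame(
    exam_id = vapply(findings, `[[`, character(1), "exam_id"),
    exam_date = as.Date(vapply(findings, function(f) format(f$exam_date), character(1))),
    lesion_id = vapply(findings, `[[`, character(1), "lesion_id"),
    stringsAsFactors = FALSE
  )
  exams <- unique(info[, c("exam_id", "exam_date")])
  exams <- exams[order(exams$exam_date, exams$exam_id), , drop = FALSE]
  if (!nrow(exams)) stop("empty timeline")

  sums <- numeric(nrow(exams))
  ln_axes <- vector("list", nrow(exams))
  for (k in seq_len(nrow(exams))) {
    ex <- exams$exam_id[k]
    diam <- lapply(selection, function(lid) {
      fs <- findings[which(!is.na(info$lesion_id) & info$lesion_id == lid &
                             info$exam_id == ex)]
      if (!length(fs)) return(data.frame(lesion_id = lid, diameter_mm = 0,
                                         present = FALSE, stringsAsFactors = FALSE))
      f <- fs[[1]]
      kind <- if (!is.null(graph)) entity_kind_of(f, graph) else f$entity_kind
      data.frame(lesion_id = lid,
                 diameter_mm = relevant_diameter(f, kind),
                 present = TRUE, stringsAsFactors = FALSE)
    })
    rs <- recist_sum(do.call(rbind, diam), exam_id = ex)
    sums[k] <- rs$value_mm
    # pathological lymph nodes present at this exam (target or not)
    ln <- vapply(findings[info$exam_id == ex], function(f) {
      kind <- if (!is.null(graph)) entity_kind_of(f, graph) else f$entity_kind
      if (identical(kind, "lymph_node")) relevant_diameter(f, "lymph_node") else NA_real_
    }, numeric(1))
    ln_axes[[k]] <- ln[!is.na(ln) & ln >= 10 - MM_TOL]
  }

  flags <- stats::setNames(rep(FALSE, nrow(exams)), exams$exam_id)
  flags[names(new_lesion_flags)[names(new_lesion_flags) %in% exams$exam_id]] <-
    unname(new_lesion_flags[names(new_lesion_flags) %in% exams$exam_id])

  label <- rep(NA_character_, nrow(exams))
  for (k in seq_len(nrow(exams))[-1]) {
    label[k] <- classify_response(sums[seq_len(k)],
                                  lymph_node_short_axes_mm = ln_axes[[k]],
                                  new_lesions = flags[[k]],
                                  exam_id = exams$exam_id[k])$label
  }
  data.frame(exam_id = exams$exam_id, exam_date = exams$exam_date,
             sum_mm = sums, label = label, new_lesions = unname(flags),
             stringsAsFactors = FALSE)
}
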