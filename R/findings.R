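#' Construct a measurement finding
#'
#' One reported measurement set about one anatomical entity at one exam.
#' Measurements may carry an explicit size quality (e.g. `"short axis"`)
#' and an acquisition plane; unlabeled dimensions are assigned to qualities
#' during classification (see [assign_dimensions()]).
#'
#' @param patient_id,exam_id,entity_id Identifier strings.
#' @param exam_date Exam date (`Date` or `"YYYY-MM-DD"`).
#' @param measurements data.frame with columns `value`, `unit` and optional
#'   `quality`, `plane`; at least one row.
#' @param entity_kind `"anatomical_structure"`, `"lymph_node"`, `"lesion"`,
#'   or `NA` to infer from the hierarchy at classification time.
#' @param entity_label,sentence Display strings (the source sentence is
#'   carried verbatim, never parsed).
#' @param finding_id,lesion_id Optional identifiers; `lesion_id` links the
#'   same physical lesion across exams for RECIST timelines.
#' @return An object of class `rad_finding`.
#' @export
new_finding <- function(patient_id, exam_id, exam_date, entity_id, measurements,
                        entity_kind = NA_character_, entity_label = entity_id,
                        sentence = "", finding_id = NULL, lesion_id = NA_character_) {
  stopifnot(is.data.frame(measurements), nrow(measurements) >= 1)
  if (is.null(measurements$quality)) measurements$quality <- NA_character_
  if (is.null(measurements$plane)) measurements$plane <- NA_character_
  measurements <- measurements[, c("value", "unit", "quality", "plane")]
  measurements$value <- as.numeric(measurements$value)
  if (any(!is.finite(measurements$value)) || any(measurements$value <= 0)) {
    stop("measurement values must be positive")
  }
  if (!all(measurements$unit %in% c("cm", "mm"))) {
    stop("unknown unit: ", paste(setdiff(measurements$unit, c("cm", "mm")), collapse = ", "))
  }
  q <- measurements$quality
  if (any(!is.na(q) & !q %in% quality_names())) {
    stop("unknown quality: ", paste(setdiff(q[!is.na(q)], quality_names()), collapse = ", "))
  }
  p <- measurements$plane
  if (any(!is.na(p) & !p %in% c("axial", "coronal", "sagittal"))) {
    stop("unknown plane: ", paste(setdiff(p[!is.na(p)], c("axial", "coronal", "sagittal")), collapse = ", "))
  }
  if (!is.na(entity_kind) &&
      !entity_kind %in% c("anatomical_structure", "lymph_node", "lesion")) {
    stop("unknown entity_kind: ", entity_kind)
  }
  measurements$value_mm <- to_mm(measurements$value, measurements$unit)
  structure(
    list(
      finding_id = finding_id %||%
        paste(patient_id, exam_id, entity_id, sep = ":"),
      patient_id = patient_id, exam_id = exam_id,
      exam_date = as.Date(exam_date),
      entity_id = entity_id, entity_label = entity_label,
      entity_kind = entity_kind, lesion_id = lesion_id,
      measurements = measurements, sentence = sentence,
      finding_type = "unset"
    ),
    class = "rad_finding"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rad_finding <- function(x, ...) {
  dims <- paste(x$measurements$value, collapse = " x ")
  cat("<rad_finding> ", x$finding_id, ": ", dims, " ",
      x$measurements$unit[1], ", ", x$entity_label,
      " [", x$finding_type, "]\n", sep = "")
  invisible(x)
}

#' Read findings from a JSON-Lines stream
#'
#' One finding per line with keys `patient_id`, `exam_id`, `exam_date`,
#' `entity_id`, `entity_label`, `entity_kind`, `measurements` (list of
#' `{value, unit, quality?, plane?}`), `sentence`, and optional
#' `finding_id` / `lesion_id`. Malformed lines are not fatal: they are
#' collected on a reject channel with their line number and reason.
#'
#' @param path Path to a JSON-Lines file (UTF-8).
#' @return A list of `rad_finding` objects with attribute `"rejects"`, a
#'   data.frame with columns `line` and `reason`.
#' @export
read_findings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  findings <- list()
  rejects <- data.frame(line = integer(), reason = character(), stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    f <- tryCatch({
      rec <- jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE)
      if (is.null(rec$entity_id) || !nzchar(rec$entity_id)) stop("missing entity")
      if (is.null(rec$measurements) || !length(rec$measurements)) {
        stop("no parsable measurement")
      }
      meas <- do.call(rbind, lapply(rec$measurements, function(m) {
        data.frame(value = as.numeric(m$value), unit = as.character(m$unit),
                   quality = if (is.null(m$quality)) NA_character_ else m$quality,
                   plane = if (is.null(m$plane)) NA_character_ else m$plane,
                   stringsAsFactors = FALSE)
      }))
      new_finding(
        patient_id = rec$patient_id, exam_id = rec$exam_id,
        exam_date = rec$exam_date, entity_id = rec$entity_id,
        measurements = meas,
        entity_kind = rec$entity_kind %||% NA_character_,
        entity_label = rec$entity_label %||% rec$entity_id,
        sentence = rec$sentence %||% "",
        finding_id = rec$finding_id,
        lesion_id = rec$lesion_id %||% NA_character_
      )
    }, error = function(e) e)
    if (inherits(f, "error")) {
      rejects <- rbind(rejects,
                       data.frame(line = i, reason = conditionMessage(f),
                                  stringsAsFactors = FALSE))
    } else {
      findings[[length(findings) + 1L]] <- f
    }
  }
  attr(findings, "rejects") <- rejects
  findings
}

#' Write findings to a JSON-Lines file
#'
#' Inverse of [read_findings()]; classified findings keep their
#' `finding_type` so the output can serve as the enriched result stream.
#'
#' @param findings List of `rad_finding` objects.
#' @param path Output path.
#' @export
write_findings <- function(findings, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (f in findings) {
    meas <- lapply(seq_len(nrow(f$measurements)), function(i) {
      m <- f$measurements[i, ]
      out <- list(value = m$value, unit = m$unit)
      if (!is.na(m$quality)) out$quality <- m$quality
      if (!is.na(m$plane)) out$plane <- m$plane
      out
    })
    rec <- list(
      finding_id = f$finding_id, patient_id = f$patient_id,
      exam_id = f$exam_id, exam_date = format(f$exam_date),
      entity_id = f$entity_id, entity_label = f$entity_label,
      entity_kind = f$entity_kind, measurements = meas,
      sentence = f$sentence
    )
    if (!is.na(f$lesion_id)) rec$lesion_id <- f$lesion_id
    if (!identical(f$finding_type, "unset")) rec$finding_type <- f$finding_type
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null"), con,
               useBytes = FALSE)
  }
  invisible(path)
}

#' Resolve the entity kind of a finding
#'
#' Explicit `entity_kind` wins; otherwise subclass descendants of the lymph
#' node concept are `lymph_node`, descendants of the lesion branch are
#' `lesion`, and everything else is `anatomical_structure`.
#'
#' @param finding A `rad_finding`.
#' @param graph A `rad_anatomy` graph.
#' @param lymph_node_root,lesion_root Concept ids of the two branch roots.
#' @return One of `"anatomical_structure"`, `"lymph_node"`, `"lesion"`.
#' @export
entity_kind_of <- function(finding, graph,
                           lymph_node_root = "RID13296", lesion_root = "lesion") {
  if (!is.na(finding$entity_kind)) return(finding$entity_kind)
  anc <- tryCatch(subclass_ancestors(graph, finding$entity_id),
                  error = function(e) character())
  if (lymph_node_root %in% anc) return("lymph_node")
  if (lesion_root %in% anc) return("lesion")
  "anatomical_structure"
}

#' Assign unlabeled measurement dimensions to size qualities
#'
#' Measurements that carry an explicit quality label pair directly with the
#' applicable specification of that quality. Unlabeled measurements are
#' sorted by descending value and paired positionally with the remaining
#' specifications sorted by descending bound (the upper bound, or the lower
#' bound when no upper bound exists); surplus measurements pair with no
#' specification. The pairing is a pure function of the measurement
#' multiset: input order never changes the result.
#'
#' @param finding A `rad_finding`.
#' @param specs A `rad_specs` data.frame of specifications applicable to
#'   the finding's entity (see [applicable_specs()]).
#' @return data.frame with one row per measurement: `value`, `unit`,
#'   `value_mm`, `quality` (the label or the assigned specification's
#'   quality), `spec_id` (`NA` when unmatched).
#' @export
assign_dimensions <- function(finding, specs) {
  m <- finding$measurements
  n <- nrow(m)
  spec_id <- rep(NA_character_, n)
  quality <- m$quality

  avail <- specs
  labeled <- which(!is.na(m$quality))
  for (i in labeled) {
    if (!nrow(avail)) break
    dq <- vapply(avail$quality, function(q) quality_path_length(m$quality[i], q), numeric(1))
    if (any(is.finite(dq))) {
      j <- which.min(dq)
      spec_id[i] <- avail$spec_id[j]
      avail <- avail[-j, , drop = FALSE]
    }
  }

  unlabeled <- setdiff(seq_len(n), labeled)
  if (length(unlabeled) && nrow(avail)) {
    bound <- ifelse(is.na(avail$high_mm), avail$low_mm, avail$high_mm)
    s_ord <- order(-bound, avail$spec_id)             # deterministic tie-break
    m_ord <- unlabeled[order(-m$value_mm[unlabeled])] # stable sort
    k <- min(length(m_ord), length(s_ord))
    if (k > 0) {
      spec_id[m_ord[seq_len(k)]] <- avail$spec_id[s_ord[seq_len(k)]]
      quality[m_ord[seq_len(k)]] <- avail$quality[s_ord[seq_len(k)]]
    }
  }

  data.frame(value = m$value, unit = m$unit, value_mm = m$value_mm,
             quality = quality, spec_id = spec_id, stringsAsFactors = FALSE)
}

#' Plane/axis orientation model
#'
#' The three imaging planes, the three body axes, and the symmetric
#' `parallel_to` / `orthogonal_to` relations between them: the craniocaudal
#' axis is orthogonal to the axial plane and parallel to the coronal and
#' sagittal planes, etc. Craniocaudal diameters are therefore measured in
#' the coronal or sagittal plane, never the axial one.
#'
#' @return A list with `planes`, `axes`, and data.frames `parallel_to`,
#'   `orthogonal_to` (columns `a`, `b`; both relations are symmetric).
#' @export
plane_axis_model <- function() {
  sym <- function(a, b) data.frame(a = c(a, b), b = c(b, a), stringsAsFactors = FALSE)
  list(
    planes = c("axial", "coronal", "sagittal"),
    axes = c("craniocaudal", "left-right", "anterior-posterior"),
    parallel_to = rbind(
      sym("craniocaudal", "coronal"), sym("craniocaudal", "sagittal"),
      sym("left-right", "axial"), sym("left-right", "coronal"),
      sym("anterior-posterior", "axial"), sym("anterior-posterior", "sagittal")
    ),
    orthogonal_to = rbind(
      sym("craniocaudal", "axial"),
      sym("left-right", "sagittal"),
      sym("anterior-posterior", "coronal")
    )
  )
}
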