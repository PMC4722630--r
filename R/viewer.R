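#' Select findings by anatomical entity or body region
#'
#' Entity selection matches the entity itself or any subclass of it;
#' region selection matches every finding whose entity reaches the region
#' through the upward part-of/subclass closure (e.g. an axillary lymph
#' node is part of the axilla, which is part of the thorax).
#'
#' @param findings List of `rad_finding` objects.
#' @param graph A `rad_anatomy` graph.
#' @param by_entity,by_region Concept id (give exactly one).
#' @return Filtered list of findings.
#' @export
select_findings <- function(findings, graph, by_entity = NULL, by_region = NULL) {
  if (is.null(by_entity) == is.null(by_region)) {
    stop("give exactly one of by_entity or by_region")
  }
  target <- by_entity %||% by_region
  assert_concept(graph, target)
  keep <- vapply(findings, function(f) {
    if (!f$entity_id %in% graph$nodes$id) return(FALSE)
    if (!is.null(by_entity)) {
      target %in% subclass_ancestors(graph, f$entity_id)
    } else {
      target %in% upward_closure(graph, f$entity_id)
    }
  }, logical(1))
  findings[keep]
}

#' Singleton anatomical entities whose findings can be linked across exams
#'
#' Concepts that occur once in the human body, so consecutive findings
#' about them describe the same physical entity. Lymph nodes and lesions
#' are never linkable: two reports about a mediastinal lymph node need not
#' describe the same node.
#'
#' @return Character vector of concept ids (packaged default; pass your
#'   own to [build_tracks()]).
#' @export
singleton_entities <- function() {
  c("RID86", "liver", "RID205", "gallbladder", "RID33779", "RID229",
    "aorta", "RID580", "descending_aorta", "trachea")
}

#' Build longitudinal finding tracks for one patient
#'
#' Findings about singleton entities form one linked track ordered by exam
#' date; lymph-node and lesion findings are grouped by entity for display
#' but remain unlinked (`linked = FALSE`), since their identity across
#' exams cannot be established without explicit lesion marking.
#'
#' @param findings List of classified `rad_finding` objects (one patient).
#' @param graph A `rad_anatomy` graph.
#' @param singletons Concept ids treated as singleton entities.
#' @return List of `rad_track` objects: `patient_id`, `entity_id`,
#'   `entity_label`, `linked`, `entries` (data.frame ordered by exam date:
#'   `exam_id`, `exam_date`, `values`, `unit`, `overall`, `sentence`).
#' @export
build_tracks <- function(findings, graph, singletons = singleton_entities()) {
  if (!length(findings)) return(list())
  pid <- unique(vapply(findings, `[[`, character(1), "patient_id"))
  if (length(pid) != 1) stop("build_tracks expects findings of a single patient")
  if (any(vapply(findings, function(f) identical(f$finding_type, "unset"), logical(1)))) {
    stop("findings must be classified before building tracks")
  }
  ent <- vapply(findings, `[[`, character(1), "entity_id")
  tracks <- lapply(unique(ent), function(e) {
    fs <- findings[ent == e]
    kind <- entity_kind_of(fs[[1]], graph)
    linked <- e %in% singletons && kind == "anatomical_structure"
    entries <- do.call(rbind, lapply(fs, function(f) {
      data.frame(exam_id = f$exam_id, exam_date = f$exam_date,
                 values = paste(f$measurements$value, collapse = " × "),
                 unit = f$measurements$unit[1],
                 overall = f$finding_type, sentence = f$sentence,
                 stringsAsFactors = FALSE)
    }))
    entries <- entries[order(entries$exam_date, entries$exam_id), , drop = FALSE]
    rownames(entries) <- NULL
    structure(list(patient_id = pid, entity_id = e,
                   entity_label = fs[[1]]$entity_label,
                   linked = linked, entries = entries),
              class = "rad_track")
  })
  tracks
}

#' @export
print.rad_track <- function(x, ...) {
  cat("<rad_track> ", x$patient_id, " / ", x$entity_label,
      if (x$linked) " (linked)" else " (unlinked)", ": ",
      nrow(x$entries), " entries\n", sep = "")
  invisible(x)
}

track_color <- function(overall) {
  switch(overall, abnormal = "red", normal = "green", "neutral")
}

#' Render longitudinal tracks as text or HTML
#'
#' Columns are exams in chronological order; each cell shows the
#' measurement values next to the verbatim report sentence, colored red
#' for abnormal, green for normal and neutral for unclassified findings.
#' Rendering is pure: the same tracks always produce the same document.
#'
#' @param tracks List of `rad_track` objects (see [build_tracks()]).
#' @param format `"text"` or `"html"`.
#' @param file Optional output path.
#' @return The document as a character vector of lines (invisibly written
#'   to `file` when given).
#' @export
render_tracks <- function(tracks, format = c("text", "html"), file = NULL) {
  format <- match.arg(format)
  exams <- unique(do.call(rbind, lapply(tracks, function(t)
    t$entries[, c("exam_id", "exam_date")])))
  if (!is.null(exams)) exams <- exams[order(exams$exam_date, exams$exam_id), , drop = FALSE]

  cell <- function(t, ex) {
    e <- t$entries[t$entries$exam_id == ex, , drop = FALSE]
    if (!nrow(e)) return(NULL)
    list(text = paste0(e$values[1], " ", e$unit[1]),
         sentence = e$sentence[1], color = track_color(e$overall[1]))
  }

  if (format == "text") {
    lines <- character()
    for (t in tracks) {
      lines <- c(lines, sprintf("%s [%s]%s", t$entity_label, t$entity_id,
                                if (t$linked) " (linked)" else ""))
      for (k in seq_len(nrow(exams %||% data.frame()))) {
        c1 <- cell(t, exams$exam_id[k])
        if (is.null(c1)) next
        lines <- c(lines, sprintf("  %s  %-14s %-10s | %s",
                                  format(exams$exam_date[k]), c1$text,
                                  paste0("[", c1$color, "]"), c1$sentence))
      }
    }
    doc <- lines
  } else {
    esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", x))
    head_cells <- if (is.null(exams)) "" else
      paste0("<th>", format(exams$exam_date), "</th>", collapse = "")
    rows <- vapply(tracks, function(t) {
      cells <- if (is.null(exams)) "" else
        paste0(vapply(seq_len(nrow(exams)), function(k) {
          c1 <- cell(t, exams$exam_id[k])
          if (is.null(c1)) return("<td></td>")
          sprintf('<td class="%s">%s<br/><span class="sentence">%s</span></td>',
                  c1$color, esc(c1$text), esc(c1$sentence))
        }, character(1)), collapse = "")
      sprintf("<tr><th>%s%s</th>%s</tr>", esc(t$entity_label),
              if (t$linked) " (linked)" else "", cells)
    }, character(1))
    doc <- c(
      "<!DOCTYPE html>",
      "<html><head><meta charset=\"utf-8\"/><style>",
      "table { border-collapse: collapse; } td, th { border: 1px solid #999; padding: 4px; }",
      "td.red { background: #f8d0d0; } td.green { background: #d0f0d0; }",
      "td.neutral { background: #eeeeee; } .sentence { font-size: smaller; color: #444; }",
      "</style></head><body>",
      "<table>",
      sprintf("<tr><th>entity</th>%s</tr>", head_cells),
      rows,
      "</table></body></html>"
    )
  }
  if (!is.null(file)) {
    writeLines(doc, file, useBytes = FALSE)
    return(invisible(doc))
  }
  doc
}
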