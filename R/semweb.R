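# Knowledge-graph export and query-based classification.
#
# Triples are held as a data.frame (s, p, o, o_kind) with o_kind one of
# "iri", "string", "decimal". IRIs are prefixed names in the project
# namespace `rs:`; external vocabulary ids (RadLex-style RIDs) survive as
# the local part of concept IRIs and as rdfs:label literals.

RDF_PREFIXES <- c(
  rs = "http://example.org/radsize#",
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  xsd = "http://www.w3.org/2001/XMLSchema#"
)

iri_safe <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)
concept_iri <- function(id) paste0("rs:C_", iri_safe(id))
quality_iri <- function(q) paste0("rs:Q_", iri_safe(gsub("[ -]", "_", q)))

quality_iri_table <- function() {
  qh <- quality_hierarchy()
  data.frame(quality = qh$quality, iri = quality_iri(qh$quality),
             stringsAsFactors = FALSE)
}

triple <- function(s, p, o, o_kind = "iri") {
  data.frame(s = s, p = p, o = o, o_kind = o_kind, stringsAsFactors = FALSE)
}

new_triples <- function(...) {
  out <- rbind(...)
  if (is.null(out)) {
    out <- data.frame(s = character(), p = character(), o = character(),
                      o_kind = character(), stringsAsFactors = FALSE)
  }
  out <- unique(out)
  rownames(out) <- NULL
  class(out) <- c("rad_triples", "data.frame")
  out
}

#' @export
print.rad_triples <- function(x, ...) {
  cat("<rad_triples> ", nrow(x), " triples\n", sep = "")
  invisible(x)
}

# triple-pattern match; NA = wildcard
tp <- function(tr, s = NA, p = NA, o = NA) {
  keep <- rep(TRUE, nrow(tr))
  if (!is.na(s)) keep <- keep & tr$s == s
  if (!is.na(p)) keep <- keep & tr$p == p
  if (!is.na(o)) keep <- keep & tr$o == o
  tr[keep, , drop = FALSE]
}

#' Export findings, specifications and RECIST results as a knowledge graph
#'
#' Instantiates one connected subgraph per finding (finding node,
#' material-entity node, one quality node per measurement, measurement
#' datum with value and unit), asserts the classified type (normal /
#' abnormal finding) on each, serializes the normal-size specifications
#' and the concept hierarchies (subclass-of, part-of), the plane/axis
#' orientation model, and optionally RECIST sums and a target-lesion
#' selection.
#'
#' @param kb Knowledge base list (`graph`, `specs`).
#' @param findings List of `rad_finding` objects. Findings must be
#'   classified (`finding_type` set) unless `allow_unclassified = TRUE`,
#'   which is how the query-based classification path obtains its input
#'   graph.
#' @param sums Optional list of `rad_recist_sum` objects.
#' @param selection Optional data.frame (`lesion_id`, `organ_id`) of
#'   selected target lesions, for the boolean verification query.
#' @param file Optional path; when given the graph is also written as
#'   Turtle.
#' @param allow_unclassified Permit findings with `finding_type = "unset"`.
#' @return A `rad_triples` data.frame.
#' @export
export_graph <- function(kb, findings = list(), sums = NULL, selection = NULL,
                         file = NULL, allow_unclassified = FALSE) {
  graph <- kb$graph; specs <- kb$specs
  out <- list()
  add <- function(...) out[[length(out) + 1L]] <<- triple(...)

  # concept hierarchy
  for (i in seq_len(nrow(graph$nodes))) {
    add(concept_iri(graph$nodes$id[i]), "rdfs:label", graph$nodes$label[i], "string")
  }
  for (i in seq_len(nrow(graph$edges))) {
    p <- if (graph$edges$relation[i] == "subclass_of") "rdfs:subClassOf" else "rs:partOf"
    add(concept_iri(graph$edges$child[i]), p, concept_iri(graph$edges$parent[i]))
  }
  qh <- quality_hierarchy()
  for (i in seq_len(nrow(qh))) {
    add(quality_iri(qh$quality[i]), "rdfs:label", qh$quality[i], "string")
    if (!is.na(qh$parent[i])) {
      add(quality_iri(qh$quality[i]), "rdfs:subClassOf", quality_iri(qh$parent[i]))
    }
  }

  # plane/axis orientation model
  pam <- plane_axis_model()
  for (i in seq_len(nrow(pam$parallel_to))) {
    add(paste0("rs:", iri_safe(pam$parallel_to$a[i])), "rs:parallelTo",
        paste0("rs:", iri_safe(pam$parallel_to$b[i])))
  }
  for (i in seq_len(nrow(pam$orthogonal_to))) {
    add(paste0("rs:", iri_safe(pam$orthogonal_to$a[i])), "rs:orthogonalTo",
        paste0("rs:", iri_safe(pam$orthogonal_to$b[i])))
  }

  # normal-size specifications (bounds in mm)
  for (i in seq_len(nrow(specs))) {
    sn <- paste0("rs:spec_", iri_safe(specs$spec_id[i]))
    add(sn, "rdf:type", "rs:NormalSizeSpecification")
    add(sn, "rdf:type", c(upper_bound = "rs:UpperBoundSpecification",
                          lower_bound = "rs:LowerBoundSpecification",
                          interval = "rs:IntervalSpecification")[[specs$range_type[i]]])
    add(sn, "rs:isAbout", concept_iri(specs$entity_id[i]))
    add(sn, "rs:hasQualityType", quality_iri(specs$quality[i]))
    if (!is.na(specs$low_mm[i])) add(sn, "rs:low", format(specs$low_mm[i]), "decimal")
    if (!is.na(specs$high_mm[i])) add(sn, "rs:high", format(specs$high_mm[i]), "decimal")
    add(sn, "rs:hasUnit", "rs:mm")
  }

  # finding subgraphs
  for (f in findings) {
    if (identical(f$finding_type, "unset") && !allow_unclassified) {
      stop("finding ", f$finding_id, " has no finding_type; classify first ",
           "or set allow_unclassified = TRUE")
    }
    fn <- paste0("rs:f_", iri_safe(f$finding_id))
    add(fn, "rdf:type", "rs:ClinicalFinding")
    if (f$finding_type == "normal") add(fn, "rdf:type", "rs:NormalFinding")
    if (f$finding_type == "abnormal") add(fn, "rdf:type", "rs:AbnormalFinding")
    if (f$finding_type == "unclassified") add(fn, "rdf:type", "rs:UnclassifiedFinding")
    add(fn, "rs:findingId", f$finding_id, "string")
    add(fn, "rs:patientId", f$patient_id, "string")
    add(fn, "rs:examId", f$exam_id, "string")
    add(fn, "rs:examDate", format(f$exam_date), "string")
    add(fn, "rs:sentence", f$sentence, "string")
    if (!is.na(f$entity_kind)) add(fn, "rs:entityKind", f$entity_kind, "string")

    en <- paste0(fn, "_e")
    add(en, "rdf:type", concept_iri(f$entity_id))
    add(en, "rdfs:label", f$entity_label, "string")
    organ <- tryCatch(resolve_organ(graph, f$entity_id), error = function(e) NA)
    if (!is.na(organ)) add(en, "rs:locatedIn", concept_iri(organ))

    for (i in seq_len(nrow(f$measurements))) {
      m <- f$measurements[i, ]
      qn <- paste0(fn, "_q", i)
      mn <- paste0(fn, "_m", i)
      add(fn, "rs:describes", qn)
      add(qn, "rdf:type",
          if (is.na(m$quality)) quality_iri("1-D extent") else quality_iri(m$quality))
      if (!is.na(m$quality)) add(qn, "rs:qualityLabel", m$quality, "string")
      if (!is.na(m$plane)) add(qn, "rs:inPlane", paste0("rs:", m$plane))
      add(qn, "rs:inheresIn", en)
      add(qn, "rs:hasMeasurement", mn)
      add(mn, "rdf:type", "rs:MeasurementDatum")
      add(mn, "rs:hasValue", format(m$value), "decimal")
      add(mn, "rs:hasUnit", paste0("rs:", m$unit))
    }
  }

  # RECIST sums
  for (s in sums %||% list()) {
    sn <- paste0("rs:sum_", iri_safe(s$exam_id))
    cn <- paste0("rs:sumcalc_", iri_safe(s$exam_id))
    add(sn, "rdf:type", "rs:RECISTSum")
    add(sn, "rs:hasValue", format(s$value_mm), "decimal")
    add(sn, "rs:hasUnit", "rs:mm")
    add(sn, "rs:outputOf", cn)
    add(cn, "rdf:type", "rs:RECISTSumCalculation")
    add(cn, "rs:examId", s$exam_id, "string")
    for (lid in names(s$contributions)) {
      ln <- paste0("rs:tl_", iri_safe(lid))
      add(cn, "rs:isAbout", ln)
      add(ln, "rs:contributes", format(s$contributions[[lid]]), "decimal")
    }
  }

  # target-lesion selection
  if (!is.null(selection)) {
    for (i in seq_len(nrow(selection))) {
      ln <- paste0("rs:tl_", iri_safe(selection$lesion_id[i]))
      add(ln, "rdf:type", "rs:TargetLesion")
      add(ln, "rs:lesionId", selection$lesion_id[i], "string")
      if (!is.na(selection$organ_id[i])) {
        add(ln, "rs:locatedIn", concept_iri(selection$organ_id[i]))
      }
    }
  }

  tr <- new_triples(do.call(rbind, out))
  if (!is.null(file)) write_turtle(tr, file)
  tr
}

escape_ttl <- function(x) gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x))
unescape_ttl <- function(x) gsub("\\\\(.)", "\\1", x)

#' Write triples as Turtle
#'
#' One triple per statement line (a deliberately flat profile of Turtle
#' that [parse_turtle()] reads back losslessly).
#'
#' @param triples A `rad_triples` data.frame.
#' @param file Output path.
#' @export
write_turtle <- function(triples, file) {
  con <- file(file, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("@prefix %s: <%s> .", names(RDF_PREFIXES), RDF_PREFIXES), con)
  writeLines("", con)
  obj <- ifelse(triples$o_kind == "iri", triples$o,
         ifelse(triples$o_kind == "decimal",
                sprintf('"%s"^^xsd:decimal', triples$o),
                sprintf('"%s"', escape_ttl(triples$o))))
  p <- ifelse(triples$p == "rdf:type", "a", triples$p)
  writeLines(sprintf("%s %s %s .", triples$s, p, obj), con)
  invisible(file)
}

#' Parse a Turtle file written by [write_turtle()]
#'
#' @param file Path to a Turtle file in the package's flat profile.
#' @return A `rad_triples` data.frame.
#' @export
parse_turtle <- function(file) {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^@prefix", lines) & !grepl("^#", lines)]
  m <- regmatches(lines, regexec("^(\\S+)\\s+(\\S+)\\s+(.+?)\\s*\\.$", lines))
  bad <- which(vapply(m, length, integer(1)) != 4)
  if (length(bad)) stop("malformed Turtle statement at line(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  rows <- lapply(m, function(g) {
    s <- g[2]; p <- if (g[3] == "a") "rdf:type" else g[3]; o <- g[4]
    if (startsWith(o, '"')) {
      lit <- regmatches(o, regexec('^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^(\\S+))?$', o))[[1]]
      if (!length(lit)) stop("malformed literal: ", o)
      kind <- if (!is.na(lit[3]) && nzchar(lit[3])) "decimal" else "string"
      triple(s, p, unescape_ttl(lit[2]), kind)
    } else triple(s, p, o)
  })
  new_triples(do.call(rbind, rows))
}

# ---- query-based execution path --------------------------------------

# BFS shortest path length over one predicate's edge set
tr_path_length <- function(edges, from, to) {
  if (from == to) return(0)
  frontier <- from; seen <- from; d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(edges$o[edges$s %in% frontier])
    nxt <- setdiff(nxt, seen)
    if (to %in% nxt) return(d)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  Inf
}

tr_closure <- function(edges, from) {
  seen <- from; frontier <- from
  while (length(frontier)) {
    nxt <- setdiff(unique(edges$o[edges$s %in% frontier]), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Classify findings by queries over the exported knowledge graph
#'
#' The alternative execution path of the classifier: specification
#' retrieval and value comparison are performed purely by triple-pattern
#' queries over the serialized graph (subclass closure, most-specific
#' filtering, positional dimension assignment, inclusive bound
#' comparison), mirroring a SPARQL-on-triple-store prototype. Results
#' agree with [classify_finding()] on every finding; the in-memory and
#' query-based paths validate each other.
#'
#' @param triples A `rad_triples` graph containing specification subgraphs
#'   and finding subgraphs (see [export_graph()]).
#' @param lesion_rule `"abnormal"` (default) or `"unclassified"`, as in
#'   [classify_finding()].
#' @param lesion_root Concept id of the lesion branch root.
#' @return data.frame with columns `finding_id` and `overall`.
#' @export
query_classify <- function(triples, lesion_rule = c("abnormal", "unclassified"),
                           lesion_root = "lesion") {
  lesion_rule <- match.arg(lesion_rule)
  sub_edges <- tp(triples, p = "rdfs:subClassOf")[, c("s", "o")]
  qmap <- quality_iri_table()

  spec_nodes <- tp(triples, p = "rdf:type", o = "rs:NormalSizeSpecification")$s
  spec_tab <- do.call(rbind, lapply(spec_nodes, function(sn) {
    types <- tp(triples, s = sn, p = "rdf:type")$o
    lo <- tp(triples, s = sn, p = "rs:low")$o
    hi <- tp(triples, s = sn, p = "rs:high")$o
    data.frame(
      node = sn,
      entity = tp(triples, s = sn, p = "rs:isAbout")$o[1],
      quality = tp(triples, s = sn, p = "rs:hasQualityType")$o[1],
      range_type = if ("rs:IntervalSpecification" %in% types) "interval"
                   else if ("rs:LowerBoundSpecification" %in% types) "lower_bound"
                   else "upper_bound",
      low = if (length(lo)) as.numeric(lo[1]) else NA_real_,
      high = if (length(hi)) as.numeric(hi[1]) else NA_real_,
      stringsAsFactors = FALSE)
  }))

  lesion_cls <- concept_iri(lesion_root)
  finding_nodes <- tp(triples, p = "rdf:type", o = "rs:ClinicalFinding")$s
  rows <- lapply(finding_nodes, function(fn) {
    fid <- tp(triples, s = fn, p = "rs:findingId")$o[1]
    ekind <- tp(triples, s = fn, p = "rs:entityKind")$o
    qnodes <- tp(triples, s = fn, p = "rs:describes")$o
    en <- unique(unlist(lapply(qnodes, function(q) tp(triples, s = q, p = "rs:inheresIn")$o)))[1]
    ecls <- setdiff(tp(triples, s = en, p = "rdf:type")$o, character(0))[1]

    is_lesion <- (length(ekind) && ekind[1] == "lesion") ||
      (!length(ekind) && lesion_cls %in% tr_closure(sub_edges, ecls))
    if (is_lesion && lesion_rule == "abnormal") {
      return(data.frame(finding_id = fid, overall = "abnormal", stringsAsFactors = FALSE))
    }

    # measurements: value in mm, labeled quality IRI or NA
    meas <- do.call(rbind, lapply(qnodes, function(q) {
      mn <- tp(triples, s = q, p = "rs:hasMeasurement")$o[1]
      val <- as.numeric(tp(triples, s = mn, p = "rs:hasValue")$o[1])
      unit <- tp(triples, s = mn, p = "rs:hasUnit")$o[1]
      lab <- tp(triples, s = q, p = "rs:qualityLabel")$o
      data.frame(value_mm = if (unit == "rs:cm") val * 10 else val,
                 quality = if (length(lab)) qmap$iri[match(lab[1], qmap$quality)]
                           else NA_character_,
                 stringsAsFactors = FALSE)
    }))

    # applicable specs: entity and quality subsumption via subclass closure
    e_anc <- tr_closure(sub_edges, ecls)
    cand <- spec_tab[spec_tab$entity %in% e_anc, , drop = FALSE]

    pick_for_quality <- function(qiri) {
      ok <- cand[vapply(cand$quality, function(qc)
        qc %in% tr_closure(sub_edges, qiri), logical(1)), , drop = FALSE]
      if (!nrow(ok)) return(NULL)
      keep <- vapply(seq_len(nrow(ok)), function(i) {
        !any(vapply(seq_len(nrow(ok)), function(j) {
          j != i && ok$entity[j] != ok$entity[i] &&
            is.finite(tr_path_length(sub_edges, ok$entity[j], ok$entity[i])) &&
            is.finite(tr_path_length(sub_edges, ok$quality[j], ok$quality[i]))
        }, logical(1)))
      }, logical(1))
      ok <- ok[keep, , drop = FALSE]
      de <- vapply(ok$entity, function(e) tr_path_length(sub_edges, ecls, e), numeric(1))
      ok <- ok[de == min(de), , drop = FALSE]
      if (nrow(ok) > 1) {
        dq <- vapply(ok$quality, function(q) tr_path_length(sub_edges, qiri, q), numeric(1))
        ok <- ok[dq == min(dq), , drop = FALSE]
      }
      if (nrow(ok) > 1) stop("ambiguous knowledge graph for ", fid)
      ok
    }

    # one resolved spec per quality mentioned by an applicable spec
    resolved <- list()
    for (qc in unique(cand$quality)) {
      subq <- qmap$iri[vapply(qmap$iri, function(qi)
        qc %in% tr_closure(sub_edges, qi), logical(1))]
      for (qi in subq) {
        r <- pick_for_quality(qi)
        if (!is.null(r)) resolved[[paste(qi, r$node)]] <- r
      }
    }
    avail <- unique(do.call(rbind, resolved))

    spec_for <- rep(NA_integer_, nrow(meas))
    used <- integer()
    labeled <- which(!is.na(meas$quality))
    for (i in labeled) {
      free <- setdiff(seq_len(nrow(avail) %||% 0), used)
      if (!length(free)) break
      r <- tryCatch(pick_for_quality(meas$quality[i]), error = function(e) NULL)
      if (!is.null(r)) {
        hit <- free[avail$node[free] == r$node]
        if (length(hit)) { spec_for[i] <- hit[1]; used <- c(used, hit[1]) }
      }
    }
    unl <- setdiff(seq_len(nrow(meas)), labeled)
    free <- setdiff(seq_len(if (is.null(avail)) 0 else nrow(avail)), used)
    if (length(unl) && length(free)) {
      bound <- ifelse(is.na(avail$high[free]), avail$low[free], avail$high[free])
      s_ord <- free[order(-bound, avail$node[free])]
      m_ord <- unl[order(-meas$value_mm[unl])]
      k <- min(length(m_ord), length(s_ord))
      spec_for[m_ord[seq_len(k)]] <- s_ord[seq_len(k)]
    }

    labels <- vapply(seq_len(nrow(meas)), function(i) {
      if (is.na(spec_for[i])) return("no_spec")
      sp <- avail[spec_for[i], ]
      v <- meas$value_mm[i]
      switch(sp$range_type,
        upper_bound = if (v <= sp$high + MM_TOL) "normal" else "abnormal",
        lower_bound = if (v >= sp$low - MM_TOL) "normal" else "abnormal",
        interval = if (v >= sp$low - MM_TOL && v <= sp$high + MM_TOL) "normal"
                   else "abnormal")
    }, character(1))

    overall <- if (all(labels == "no_spec")) "unclassified"
               else if (any(labels == "abnormal")) "abnormal" else "normal"
    data.frame(finding_id = fid, overall = overall, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(finding_id = character(),
                                      overall = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Boolean verification of a target-lesion selection over the graph
#'
#' The graph analogue of [verify_selection()]: counts `rs:TargetLesion`
#' nodes and their `rs:locatedIn` organs; `TRUE` iff at most five lesions
#' are selected and no organ hosts more than two.
#'
#' @param triples A `rad_triples` graph containing a selection.
#' @return Logical scalar.
#' @export
query_verify_selection <- function(triples) {
  lesions <- tp(triples, p = "rdf:type", o = "rs:TargetLesion")$s
  if (length(lesions) > 5) return(FALSE)
  organs <- unlist(lapply(lesions, function(l) tp(triples, s = l, p = "rs:locatedIn")$o))
  !length(organs) || all(table(organs) <= 2)
}
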