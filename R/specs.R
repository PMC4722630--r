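#' Load normal-size specifications
#'
#' Validates a set of normal-size statements against the anatomy graph and
#' the quality hierarchy and normalizes all bounds to millimetres. Each
#' record states that a quality (e.g. short axis) of an anatomical entity
#' (e.g. lymph node) is normal up to an upper bound, down to a lower bound,
#' or within an interval.
#'
#' @param records A data.frame (or list of lists) with fields `entity_id`,
#'   `quality`, `range_type` (`upper_bound`, `lower_bound`, `interval`),
#'   `low`, `high`, `unit` (`cm` or `mm`); optional `enabled` (default
#'   `TRUE`) and `spec_id`.
#' @param graph A `rad_anatomy` graph used to resolve entities.
#' @return An object of class `rad_specs`: a data.frame with one row per
#'   enabled specification, bounds in mm (`low_mm`, `high_mm`).
#' @examples
#' g <- load_anatomy(data.frame(child = "RID13296", parent = "anatomical_structure",
#'                              relation = "subclass_of"))
#' load_specs(data.frame(entity_id = "RID13296", quality = "short axis",
#'                       range_type = "upper_bound", low = NA, high = 1,
#'                       unit = "cm"), g)
#' @export
load_specs <- function(records, graph) {
  if (!is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, function(r) {
      data.frame(
        entity_id = r$entity_id, quality = r$quality, range_type = r$range_type,
        low = if (is.null(r$low)) NA_real_ else as.numeric(r$low),
        high = if (is.null(r$high)) NA_real_ else as.numeric(r$high),
        unit = r$unit,
        enabled = if (is.null(r$enabled)) TRUE else isTRUE(r$enabled),
        spec_id = if (is.null(r$spec_id)) NA_character_ else r$spec_id,
        stringsAsFactors = FALSE
      )
    }))
  }
  if (is.null(records$enabled)) records$enabled <- TRUE
  if (is.null(records$spec_id)) records$spec_id <- NA_character_
  records$low <- suppressWarnings(as.numeric(records$low))
  records$high <- suppressWarnings(as.numeric(records$high))

  reject <- function(i, why) {
    stop("specification record rejected (", why, "): entity_id=",
         records$entity_id[i], ", quality=", records$quality[i],
         ", range_type=", records$range_type[i])
  }
  for (i in seq_len(nrow(records))) {
    if (!records$entity_id[i] %in% graph$nodes$id) reject(i, "unresolvable entity")
    if (!is_quality(records$quality[i])) reject(i, "unresolvable quality")
    if (!records$unit[i] %in% c("cm", "mm")) reject(i, "unknown unit")
    rt <- records$range_type[i]
    lo <- records$low[i]; hi <- records$high[i]
    if (rt == "upper_bound") {
      if (!is.na(lo)) reject(i, "upper_bound must not carry a low bound")
      if (is.na(hi) || hi <= 0) reject(i, "malformed bounds")
    } else if (rt == "lower_bound") {
      if (!is.na(hi)) reject(i, "lower_bound must not carry a high bound")
      if (is.na(lo) || lo <= 0) reject(i, "malformed bounds")
    } else if (rt == "interval") {
      if (is.na(lo) || is.na(hi) || lo <= 0 || hi <= 0) reject(i, "malformed bounds")
      if (lo >= hi) reject(i, "interval requires low < high")
    } else reject(i, "unknown range_type")
  }

  out <- data.frame(
    spec_id = ifelse(is.na(records$spec_id),
                     paste0(records$entity_id, "|", records$quality),
                     records$spec_id),
    entity_id = records$entity_id,
    quality = records$quality,
    range_type = records$range_type,
    low_mm = to_mm(records$low, records$unit),
    high_mm = to_mm(records$high, records$unit),
    enabled = records$enabled,
    stringsAsFactors = FALSE
  )
  out <- out[out$enabled, , drop = FALSE]
  # order-independent canonical form
  out <- out[order(out$spec_id), , drop = FALSE]
  if (anyDuplicated(out$spec_id)) {
    stop("duplicate specification id(s): ",
         paste(unique(out$spec_id[duplicated(out$spec_id)]), collapse = ", "))
  }
  rownames(out) <- NULL
  class(out) <- c("rad_specs", "data.frame")
  out
}

#' @export
print.rad_specs <- function(x, ...) {
  cat("<rad_specs> ", nrow(x), " normal-size specifications\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Most specific applicable specification for an (entity, quality) pair
#'
#' Entity-Quality retrieval: a specification (E', Q') applies to a query
#' (E, Q) when E is E' or one of its subclasses and Q is Q' or one of its
#' subclasses. Among applicable specifications, one is discarded when
#' another sits strictly closer on the entity subclass path (with its
#' quality on the quality path); remaining candidates are ranked by entity
#' path length, then quality path length. A tie on both lengths is an
#' ambiguous knowledge base and raises an error.
#'
#' @param graph A `rad_anatomy` graph.
#' @param specs A `rad_specs` set.
#' @param entity Concept identifier E.
#' @param quality Quality name Q.
#' @return A one-row `rad_specs` data.frame, or `NULL` when no
#'   specification applies.
#' @export
most_specific_spec <- function(graph, specs, entity, quality) {
  assert_concept(graph, entity)
  if (!is_quality(quality)) stop("unknown quality: ", quality)

  de <- vapply(specs$entity_id, function(e) subclass_path_length(graph, entity, e), numeric(1))
  dq <- vapply(specs$quality, function(q) quality_path_length(quality, q), numeric(1))
  ok <- is.finite(de) & is.finite(dq)
  if (!any(ok)) return(NULL)
  cand <- which(ok)

  # j dominates i: E_j strictly between E and E_i on the subclass path,
  # Q_j on the path between Q and Q_i
  dominated <- vapply(cand, function(i) {
    any(vapply(cand, function(j) {
      if (j == i) return(FALSE)
      specs$entity_id[j] != specs$entity_id[i] &&
        is.finite(subclass_path_length(graph, specs$entity_id[j], specs$entity_id[i])) &&
        is.finite(quality_path_length(specs$quality[j], specs$quality[i]))
    }, logical(1)))
  }, logical(1))
  cand <- cand[!dominated]

  cand <- cand[de[cand] == min(de[cand])]
  if (length(cand) > 1) cand <- cand[dq[cand] == min(dq[cand])]
  if (length(cand) > 1) {
    stop("ambiguous knowledge base: specifications {",
         paste(specs$spec_id[cand], collapse = ", "),
         "} are equally specific for (", entity, ", ", quality, ")")
  }
  specs[cand, , drop = FALSE]
}

#' All specifications applicable to an entity
#'
#' For each quality mentioned by a specification whose entity subsumes
#' `entity`, resolves the most specific specification; the distinct result
#' set is what unlabeled measurement dimensions are matched against.
#'
#' @inheritParams most_specific_spec
#' @return A `rad_specs` data.frame (possibly empty).
#' @export
applicable_specs <- function(graph, specs, entity) {
  de <- vapply(specs$entity_id, function(e) subclass_path_length(graph, entity, e), numeric(1))
  qs <- unique(specs$quality[is.finite(de)])
  picked <- lapply(qs, function(q) most_specific_spec(graph, specs, entity, q))
  picked <- picked[!vapply(picked, is.null, logical(1))]
  if (!length(picked)) {
    out <- specs[0, , drop = FALSE]
  } else {
    out <- do.call(rbind, picked)
    out <- out[!duplicated(out$spec_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read specifications from a YAML or JSON file
#'
#' The file holds a list of objects with keys `entity_id`, `quality`,
#' `range_type`, `low`, `high`, `unit` (optional `enabled`, `spec_id`).
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param graph A `rad_anatomy` graph.
#' @return A `rad_specs` set.
#' @export
read_specs <- function(path, graph) {
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  load_specs(recs, graph)
}
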