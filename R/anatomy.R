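#' Load an anatomical concept graph
#'
#' Builds the two-layer concept hierarchy (subclass-of and part-of) used for
#' specification inheritance and body-region retrieval. Both relation layers
#' must be acyclic; contradictory duplicate edges are deduplicated with a
#' warning.
#'
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (`"subclass_of"` or `"part_of"`), one row per directed edge
#'   child -> parent.
#' @param labels Optional data.frame with columns `id`, `label`; concepts
#'   without a label fall back to their identifier.
#' @return An object of class `rad_anatomy` with the node table, the edge
#'   table, and the underlying directed graphs.
#' @examples
#' g <- load_anatomy(data.frame(
#'   child = "mediastinal_lymph_node", parent = "RID13296",
#'   relation = "subclass_of"))
#' subclass_path_length(g, "mediastinal_lymph_node", "RID13296")
#' @export
load_anatomy <- function(edges, labels = NULL) {
  stopifnot(is.data.frame(edges), all(c("child", "parent", "relation") %in% names(edges)))
  edges <- edges[, c("child", "parent", "relation")]
  edges[] <- lapply(edges, as.character)
  bad <- setdiff(unique(edges$relation), c("subclass_of", "part_of"))
  if (length(bad)) stop("unknown relation(s): ", paste(bad, collapse = ", "))
  if (any(!nzchar(edges$child)) || any(!nzchar(edges$parent))) {
    stop("empty concept identifier in edge list")
  }
  dup <- duplicated(edges)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) removed")
    edges <- edges[!dup, , drop = FALSE]
  }

  ids <- sort(unique(c(edges$child, edges$parent)))
  lab <- ids
  if (!is.null(labels)) {
    stopifnot(all(c("id", "label") %in% names(labels)))
    m <- match(ids, labels$id)
    lab <- ifelse(is.na(m), ids, as.character(labels$label)[m])
    extra <- setdiff(labels$id, ids)
    if (length(extra)) {           # labelled isolated concepts are allowed
      ids <- c(ids, extra)
      lab <- c(lab, as.character(labels$label)[match(extra, labels$id)])
    }
  }
  nodes <- data.frame(id = ids, label = lab, stringsAsFactors = FALSE)

  mk <- function(rel) {
    e <- edges[edges$relation %in% rel, c("child", "parent"), drop = FALSE]
    igraph::graph_from_data_frame(e, directed = TRUE, vertices = nodes)
  }
  g_sub <- mk("subclass_of")
  g_part <- mk("part_of")
  check_acyclic(g_sub, "subclass_of")
  check_acyclic(g_part, "part_of")

  structure(
    list(
      nodes = nodes, edges = edges,
      g_sub = g_sub,
      g_up = mk(c("subclass_of", "part_of"))   # combined upward closure
    ),
    class = "rad_anatomy"
  )
}

check_acyclic <- function(g, what) {
  if (igraph::is_dag(g)) return(invisible(TRUE))
  # name one offending cycle: nodes reachable from one of their successors
  nm <- igraph::V(g)$name
  d <- igraph::distances(g, mode = "out")
  in_cycle <- nm[vapply(seq_along(nm), function(i) {
    succ <- names(igraph::neighbors(g, nm[i], mode = "out"))
    any(is.finite(d[succ, nm[i]]))
  }, logical(1))]
  stop("cycle in ", what, " relation involving: ", paste(in_cycle, collapse = ", "))
}

#' @export
print.rad_anatomy <- function(x, ...) {
  cat("<rad_anatomy> ", nrow(x$nodes), " concepts, ",
      sum(x$edges$relation == "subclass_of"), " subclass_of / ",
      sum(x$edges$relation == "part_of"), " part_of edges\n", sep = "")
  invisible(x)
}

assert_concept <- function(graph, id) {
  missing <- setdiff(id, graph$nodes$id)
  if (length(missing)) stop("unknown concept(s): ", paste(missing, collapse = ", "))
  invisible(id)
}

#' Concept label lookup
#' @param graph A `rad_anatomy` graph.
#' @param id Concept identifier(s).
#' @return Character vector of labels.
#' @export
concept_label <- function(graph, id) {
  assert_concept(graph, id)
  graph$nodes$label[match(id, graph$nodes$id)]
}

#' Shortest subclass path length between two concepts
#'
#' Length of the shortest directed chain of subclass edges from `a` up to
#' `b`; 0 iff `a == b`, `Inf` when `b` is not a subclass ancestor of `a`.
#' The subclass layer is a DAG (concepts may have several parents), so
#' "path length" means the shortest directed path.
#'
#' @param graph A `rad_anatomy` graph.
#' @param a,b Concept identifiers.
#' @return Non-negative number, or `Inf` if unreachable.
#' @export
subclass_path_length <- function(graph, a, b) {
  assert_concept(graph, c(a, b))
  suppressWarnings(as.numeric(igraph::distances(graph$g_sub, v = a, to = b, mode = "out")))
}

#' Subclass ancestors (inclusive) of a concept
#' @inheritParams subclass_path_length
#' @param id Concept identifier.
#' @return Character vector of concept ids reachable via subclass edges,
#'   including `id` itself.
#' @export
subclass_ancestors <- function(graph, id) {
  assert_concept(graph, id)
  names(igraph::subcomponent(graph$g_sub, id, mode = "out"))
}

#' Upward closure over subclass and part-of edges (inclusive)
#' @inheritParams subclass_ancestors
#' @return Character vector of concept ids.
#' @export
upward_closure <- function(graph, id) {
  assert_concept(graph, id)
  names(igraph::subcomponent(graph$g_up, id, mode = "out"))
}

#' Subclass descendants (inclusive) of a concept
#' @inheritParams subclass_ancestors
#' @export
subclass_descendants <- function(graph, id) {
  assert_concept(graph, id)
  names(igraph::subcomponent(graph$g_sub, id, mode = "in"))
}

#' Read a concept hierarchy from tab-separated files
#'
#' @param edge_file Path to a TSV with columns child, parent, relation
#'   (no header), relation one of `subclass_of` / `part_of`.
#' @param label_file Optional TSV `id<TAB>label` (no header).
#' @return A `rad_anatomy` graph.
#' @export
read_anatomy <- function(edge_file, label_file = NULL) {
  edges <- utils::read.delim(edge_file, header = FALSE,
                             col.names = c("child", "parent", "relation"),
                             stringsAsFactors = FALSE)
  labels <- NULL
  if (!is.null(label_file)) {
    labels <- utils::read.delim(label_file, header = FALSE,
                                col.names = c("id", "label"),
                                stringsAsFactors = FALSE, quote = "",
                                fileEncoding = "UTF-8")
  }
  load_anatomy(edges, labels)
}
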