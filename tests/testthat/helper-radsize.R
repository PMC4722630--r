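# Shared fixtures. The packaged KB is loaded once per test run.
test_kb <- local({
  kb <- NULL
  function() {
    if (is.null(kb)) kb <<- packaged_kb()
    kb
  }
})

mk_finding <- function(entity_id, values, quality = NA, unit = "cm",
                       kind = "anatomical_structure", plane = NA, ...) {
  new_finding("P1", "E1", "2024-01-01", entity_id,
              data.frame(value = values, unit = unit, quality = quality,
                         plane = plane),
              entity_kind = kind, ...)
}

# Brute-force Entity-Quality retrieval oracle, built directly from the
# packaged plain-text files (no rad_anatomy / rad_specs machinery).
eq_oracle <- local({
  env <- NULL
  function() {
    if (!is.null(env)) return(env)
    edges <- utils::read.delim(
      system.file("extdata", "anatomy_edges.tsv", package = "radsize"),
      header = FALSE, col.names = c("child", "parent", "relation"),
      stringsAsFactors = FALSE)
    sub <- edges[edges$relation == "subclass_of", ]
    parents <- split(sub$parent, sub$child)
    bfs <- function(a, b) {
      if (a == b) return(0)
      frontier <- a; seen <- a; d <- 0
      while (length(frontier)) {
        d <- d + 1
        nxt <- setdiff(unique(unlist(parents[frontier])), seen)
        if (b %in% nxt) return(d)
        if (!length(nxt)) return(Inf)
        seen <- c(seen, nxt); frontier <- nxt
      }
      Inf
    }
    qh <- quality_hierarchy()
    qdist <- function(a, b) {
      d <- 0; cur <- a
      repeat {
        if (identical(cur, b)) return(d)
        cur <- qh$parent[match(cur, qh$quality)]
        if (is.na(cur)) return(Inf)
        d <- d + 1
      }
    }
    raw <- yaml::read_yaml(system.file("extdata", "size_specs.yaml", package = "radsize"))
    raw <- Filter(function(r) is.null(r$enabled) || isTRUE(r$enabled), raw)
    specs <- data.frame(
      spec_id = vapply(raw, `[[`, character(1), "spec_id"),
      entity = vapply(raw, `[[`, character(1), "entity_id"),
      quality = vapply(raw, `[[`, character(1), "quality"),
      stringsAsFactors = FALSE)
    resolve <- function(E, Q) {
      de <- vapply(specs$entity, function(e) bfs(E, e), numeric(1))
      dq <- vapply(specs$quality, function(q) qdist(Q, q), numeric(1))
      cand <- which(is.finite(de) & is.finite(dq))
      if (!length(cand)) return(NULL)
      dominated <- vapply(cand, function(i) {
        any(vapply(cand, function(j) {
          j != i && specs$entity[j] != specs$entity[i] &&
            is.finite(bfs(specs$entity[j], specs$entity[i])) &&
            is.finite(qdist(specs$quality[j], specs$quality[i]))
        }, logical(1)))
      }, logical(1))
      cand <- cand[!dominated]
      cand <- cand[de[cand] == min(de[cand])]
      if (length(cand) > 1) cand <- cand[dq[cand] == min(dq[cand])]
      if (length(cand) > 1) return("ambiguous")
      specs$spec_id[cand]
    }
    env <<- list(concepts = sort(unique(c(edges$child, edges$parent))),
                 resolve = resolve)
    env
  }
})

# Direct transcription of the four response criteria (fp guard on the
# inclusive thresholds only).
response_oracle <- function(sums, ln = numeric(0), new_lesions = FALSE) {
  eps <- 1e-9
  baseline <- sums[1]
  current <- sums[length(sums)]
  nadir <- min(sums[-length(sums)])
  if (current <= eps && (!length(ln) || all(ln < 10 - eps))) return("CR")
  if (new_lesions) return("PD")
  if (current >= 1.2 * nadir - eps && current - nadir >= 5 - eps) return("PD")
  if (current <= 0.7 * baseline + eps) return("PR")
  "SD"
}
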