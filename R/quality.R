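#' Size-quality hierarchy
#'
#' The fixed hierarchy of size qualities used throughout the package. The
#' root is `size`, whose only child here is `1-D extent`; below it sit the
#' familiar one-dimensional qualities (`length`, `width`, `height`,
#' `thickness`, `diameter`) together with four radiology-specific
#' refinements: `craniocaudal diameter` and `left-right diameter` (children
#' of `diameter`, oriented along body axes) and `longest axis` / `short
#' axis` (the in-plane pair used to size tumors and lymph nodes; the short
#' axis is the longest extent orthogonal to the longest axis).
#'
#' @return A data.frame with columns `quality` and `parent` (`NA` for the
#'   root).
#' @examples
#' quality_hierarchy()
#' @export
quality_hierarchy <- function() {
  data.frame(
    quality = c(
      "size", "1-D extent",
      "length", "width", "height", "thickness", "diameter",
      "craniocaudal diameter", "left-right diameter",
      "longest axis", "short axis"
    ),
    parent = c(
      NA, "size",
      "1-D extent", "1-D extent", "1-D extent", "1-D extent", "1-D extent",
      "diameter", "diameter",
      "1-D extent", "1-D extent"
    ),
    stringsAsFactors = FALSE
  )
}

quality_names <- function() quality_hierarchy()$quality

is_quality <- function(q) q %in% quality_names()

#' Path length between two qualities
#'
#' Number of parent steps from `from` up to `to` in the quality hierarchy
#' (a tree, so the path is unique). Zero iff `from == to`; `Inf` when `to`
#' is not an ancestor of `from`.
#'
#' @param from,to Quality names (see [quality_hierarchy()]).
#' @return Non-negative number, or `Inf` if unreachable.
#' @examples
#' quality_path_length("craniocaudal diameter", "1-D extent")  # 2
#' @export
quality_path_length <- function(from, to) {
  qh <- quality_hierarchy()
  if (!is_quality(from) || !is_quality(to)) {
    stop("unknown quality: ", paste(setdiff(c(from, to), qh$quality), collapse = ", "))
  }
  steps <- 0
  cur <- from
  repeat {
    if (identical(cur, to)) return(steps)
    cur <- qh$parent[match(cur, qh$quality)]
    if (is.na(cur)) return(Inf)
    steps <- steps + 1
  }
}

# ---- units ------------------------------------------------------------

#' Convert a length to millimetres
#'
#' Internal canonical unit is mm; 1 cm = 10 mm. Comparisons against
#' normal-size specifications are always performed in mm.
#'
#' @param value Numeric vector of lengths.
#' @param unit Character vector, `"cm"` or `"mm"` (recycled).
#' @return Numeric vector in mm.
#' @examples
#' to_mm(c(1.6, 12), c("cm", "mm"))
#' @export
to_mm <- function(value, unit) {
  if (!all(unit %in% c("cm", "mm"))) {
    stop("unknown unit: ", paste(unique(setdiff(unit, c("cm", "mm"))), collapse = ", "))
  }
  unit <- rep_len(unit, length(value))
  out <- value
  out[unit == "cm"] <- value[unit == "cm"] * 10
  # snap to a fine decimal grid so cm -> mm -> cm round-trips exactly
  round(out, 9)
}

#' @rdname to_mm
#' @export
mm_to_cm <- function(value) round(value / 10, 10)

# tolerance for boundary comparisons after unit conversion (mm)
MM_TOL <- 1e-9
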