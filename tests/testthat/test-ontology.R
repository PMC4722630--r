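test_that("anatomy loading builds both relation layers and rejects cycles", {
  g <- load_anatomy(data.frame(child = "mediastinal_lymph_node",
                               parent = "RID13296", relation = "subclass_of"))
  expect_equal(subclass_path_length(g, "mediastinal_lymph_node", "RID13296"), 1)

  expect_error(
    load_anatomy(data.frame(child = c("RID7710", "RID13296"),
                            parent = c("RID13296", "RID13296"),
                            relation = "subclass_of")),
    "cycle.*RID13296")
  expect_error(
    load_anatomy(data.frame(child = c("a", "b"), parent = c("b", "a"),
                            relation = "part_of")),
    "cycle in part_of")

  expect_warning(
    g2 <- load_anatomy(data.frame(child = c("a", "a"), parent = c("b", "b"),
                                  relation = "subclass_of")),
    "duplicate")
  expect_equal(nrow(g2$edges), 1)

  expect_error(load_anatomy(data.frame(child = "a", parent = "b",
                                       relation = "sibling_of")),
               "unknown relation")
})

test_that("subclass path length is 0 on identity, Inf across branches", {
  g <- test_kb()$graph
  expect_equal(subclass_path_length(g, "RID86", "RID86"), 0)
  expect_equal(subclass_path_length(g, "mediastinal_lymph_node", "RID13296"), 1)
  expect_true(is.infinite(subclass_path_length(g, "RID86", "RID13296")))
  expect_error(subclass_path_length(g, "nonexistent", "RID86"), "unknown concept")
})

test_that("packaged hierarchy has the documented shape", {
  g <- test_kb()$graph
  expect_gte(nrow(g$nodes), 30)
  # lymph-node subtree with at least 5 proper subclasses
  expect_gte(length(subclass_descendants(g, "RID13296")) - 1, 5)
  expect_equal(concept_label(g, "RID86"), "spleen")
})

test_that("specification loading normalizes units to mm and validates bounds", {
  g <- test_kb()$graph
  s <- load_specs(data.frame(entity_id = "RID13296", quality = "short axis",
                             range_type = "upper_bound", low = NA, high = 1,
                             unit = "cm"), g)
  expect_equal(s$high_mm, 10)
  expect_true(is.na(s$low_mm))

  s2 <- load_specs(data.frame(entity_id = "RID33779", quality = "thickness",
                              range_type = "interval", low = 0.1, high = 0.3,
                              unit = "cm"), g)
  expect_equal(c(s2$low_mm, s2$high_mm), c(1, 3))

  expect_error(
    load_specs(data.frame(entity_id = "RID205", quality = "craniocaudal diameter",
                          range_type = "interval", low = 13, high = 8,
                          unit = "cm"), g),
    "low < high")
  expect_error(
    load_specs(data.frame(entity_id = "not_a_concept", quality = "length",
                          range_type = "upper_bound", low = NA, high = 1,
                          unit = "cm"), g),
    "unresolvable entity")
  expect_error(
    load_specs(data.frame(entity_id = "RID86", quality = "girth",
                          range_type = "upper_bound", low = NA, high = 1,
                          unit = "cm"), g),
    "unresolvable quality")
})

test_that("specification loading is order-independent", {
  g <- test_kb()$graph
  recs <- data.frame(
    entity_id = c("RID13296", "RID7710", "RID86"),
    quality = c("short axis", "short axis", "length"),
    range_type = c("upper_bound", "upper_bound", "interval"),
    low = c(NA, NA, 7), high = c(1, 1.5, 10), unit = "cm",
    stringsAsFactors = FALSE)
  a <- load_specs(recs, g)
  b <- load_specs(recs[c(3, 1, 2), ], g)
  expect_identical(a, b)
})

test_that("most specific specification follows the subclass hierarchy", {
  kb <- test_kb()
  sub <- most_specific_spec(kb$graph, kb$specs, "RID7710", "short axis")
  expect_equal(sub$high_mm, 15)

  med <- most_specific_spec(kb$graph, kb$specs, "mediastinal_lymph_node", "short axis")
  expect_equal(med$spec_id, "ln_short_axis")
  expect_equal(med$high_mm, 10)

  expect_null(most_specific_spec(kb$graph, kb$specs, "rib", "1-D extent"))
})

test_that("a specification on a broader quality applies to its subclasses", {
  kb <- test_kb()
  # kidney spec is on craniocaudal diameter; a plain diameter query must not
  # match it (wrong direction), but the aorta diameter spec covers the
  # craniocaudal special case
  expect_null(most_specific_spec(kb$graph, kb$specs, "RID205", "diameter"))
  cc <- most_specific_spec(kb$graph, kb$specs, "RID580", "craniocaudal diameter")
  expect_equal(cc$spec_id, "aorta_root_diameter")
})

test_that("retrieval equals the brute-force oracle on every (E, Q) pair", {
  kb <- test_kb()
  orc <- eq_oracle()
  for (E in orc$concepts) {
    for (Q in quality_hierarchy()$quality) {
      expected <- orc$resolve(E, Q)
      got <- most_specific_spec(kb$graph, kb$specs, E, Q)
      if (is.null(expected)) {
        expect_null(got, label = paste(E, Q))
      } else if (identical(expected, "ambiguous")) {
        expect_error(most_specific_spec(kb$graph, kb$specs, E, Q), "ambiguous")
      } else {
        expect_equal(got$spec_id, expected, label = paste(E, Q))
      }
    }
  }
})

test_that("adding a specification never removes coverage", {
  kb <- test_kb()
  qs <- quality_hierarchy()$quality
  covered <- function(specs) {
    outer(kb$graph$nodes$id, qs, Vectorize(function(E, Q) {
      !is.null(most_specific_spec(kb$graph, specs, E, Q))
    }))
  }
  before <- covered(kb$specs)
  extra <- load_specs(data.frame(entity_id = "liver", quality = "length",
                                 range_type = "upper_bound", low = NA,
                                 high = 16, unit = "cm",
                                 spec_id = "liver_length"), kb$graph)
  after <- covered(rbind(kb$specs, extra))
  expect_true(all(after[before]))
})
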