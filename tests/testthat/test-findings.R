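test_that("JSON-Lines findings are parsed and validated", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  lines <- c(
    paste0('{"patient_id":"P1","exam_id":"E1","exam_date":"2024-01-01",',
           '"entity_id":"aortopulmonary_lymph_node",',
           '"entity_label":"aortopulmonary lymph node",',
           '"entity_kind":"lymph_node",',
           '"measurements":[{"value":1.6,"unit":"cm"},{"value":1.2,"unit":"cm"}],',
           '"sentence":"Die LK im aortopulmonalen Fenster und prätracheal ',
           'größenunverändert mit einer Größe von bis zu 1,6 × 1,2 cm."}'),
    '{"patient_id":"P1","exam_id":"E1","exam_date":"2024-01-01","entity_id":"RID86","measurements":[]}',
    '{"patient_id":"P1","exam_id":"E1","exam_date":"2024-01-01","entity_id":"RID86","measurements":[{"value":3,"unit":"inch"}]}',
    'this is not JSON'
  )
  writeLines(lines, path, useBytes = FALSE)
  f <- read_findings(path)
  expect_length(f, 1)
  expect_equal(f[[1]]$measurements$value_mm, c(16, 12))
  expect_true(all(is.na(f[[1]]$measurements$quality)))
  expect_equal(f[[1]]$finding_type, "unset")

  rej <- attr(f, "rejects")
  expect_equal(rej$line, c(2, 3, 4))
  expect_match(rej$reason[1], "measurement")
  expect_match(rej$reason[2], "unit")
})

test_that("findings survive a write/read round trip", {
  f <- mk_finding("RID86", c(14.8, 8.5), sentence = "Milz 14,8 × 8,5 cm.")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_findings(list(f), path)
  g <- read_findings(path)[[1]]
  expect_equal(g$measurements$value, f$measurements$value)
  expect_equal(g$sentence, f$sentence)
  expect_equal(g$entity_id, f$entity_id)
})

test_that("cm to mm conversion round-trips exactly for 2-decimal inputs", {
  v <- round(stats::runif(200, 0.01, 50), 2)
  expect_identical(mm_to_cm(to_mm(v, "cm")), v)
})

test_that("unlabeled dimensions pair positionally by descending size", {
  kb <- test_kb()
  specs <- applicable_specs(kb$graph, kb$specs, "RID86")

  f2 <- mk_finding("RID86", c(14.8, 8.5))
  p2 <- assign_dimensions(f2, specs)
  expect_equal(p2$quality, c("height", "length"))
  expect_equal(p2$spec_id, c("spleen_height", "spleen_length"))

  f3 <- mk_finding("RID86", c(9, 3.5, 6.5))
  p3 <- assign_dimensions(f3, specs)
  expect_equal(p3$quality, c("height", "width", "length"))

  # explicit quality labels bypass sorting
  ln <- mk_finding("RID13296", 0.7, quality = "short axis", kind = "lymph_node")
  pl <- assign_dimensions(ln, applicable_specs(kb$graph, kb$specs, "RID13296"))
  expect_equal(pl$spec_id, "ln_short_axis")
})

test_that("dimension assignment is permutation-stable and total", {
  kb <- test_kb()
  specs <- applicable_specs(kb$graph, kb$specs, "RID86")
  set.seed(42)
  vals <- c(13.1, 9.2, 4.4)
  ref <- assign_dimensions(mk_finding("RID86", vals), specs)
  ref_map <- ref[order(ref$value), c("value", "quality", "spec_id")]
  for (i in 1:10) {
    perm <- sample(vals)
    p <- assign_dimensions(mk_finding("RID86", perm), specs)
    expect_equal(nrow(p), length(vals))          # every measurement paired once
    expect_equal(p[order(p$value), c("value", "quality", "spec_id")],
                 ref_map, ignore_attr = TRUE)
  }
  # surplus measurements pair with no specification
  p4 <- assign_dimensions(mk_finding("RID86", c(14, 9, 5, 2)), specs)
  expect_equal(sum(is.na(p4$spec_id)), 1)
  expect_true(is.na(p4$spec_id[p4$value == 2]))
})

test_that("entity kind is inferred from the hierarchy when unset", {
  g <- test_kb()$graph
  f <- mk_finding("mediastinal_lymph_node", 1.2, kind = NA)
  expect_equal(entity_kind_of(f, g), "lymph_node")
  expect_equal(entity_kind_of(mk_finding("liver_lesion", 2, kind = NA), g), "lesion")
  expect_equal(entity_kind_of(mk_finding("RID86", 10, kind = NA), g),
               "anatomical_structure")
  expect_equal(entity_kind_of(mk_finding("RID86", 10, kind = "lesion"), g), "lesion")
})

test_that("plane/axis relations are symmetric and orient the craniocaudal axis", {
  pam <- plane_axis_model()
  for (rel in list(pam$parallel_to, pam$orthogonal_to)) {
    swapped <- data.frame(a = rel$b, b = rel$a, stringsAsFactors = FALSE)
    expect_true(all(do.call(paste, swapped) %in% do.call(paste, rel)))
  }
  expect_true(any(pam$orthogonal_to$a == "craniocaudal" &
                    pam$orthogonal_to$b == "axial"))
  expect_false(any(pam$parallel_to$a == "craniocaudal" &
                     pam$parallel_to$b == "axial"))
})
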