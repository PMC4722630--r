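test_that("value comparison uses inclusive bounds", {
  kb <- test_kb()
  ln <- kb$specs[kb$specs$spec_id == "ln_short_axis", ]
  expect_equal(classify_value(7, ln), "normal")
  expect_equal(classify_value(10, ln), "normal")        # boundary inclusive
  expect_equal(classify_value(26.5, ln), "abnormal_high")

  spl <- kb$specs[kb$specs$spec_id == "spleen_length", ]
  expect_equal(classify_value(96, spl), "normal")
  expect_equal(classify_value(70, spl), "normal")
  expect_equal(classify_value(69.9, spl), "abnormal_low")
  expect_equal(classify_value(100.1, spl), "abnormal_high")

  ao <- kb$specs[kb$specs$spec_id == "aorta_root_diameter", ]
  expect_equal(classify_value(40, ao), "normal")        # lower bound inclusive
  expect_equal(classify_value(39.9, ao), "abnormal_low")
})

test_that("findings classify as in the documented worked examples", {
  kb <- test_kb()
  overall <- function(f) classify_finding(f, kb)$overall
  expect_equal(overall(mk_finding("RID13296", 0.7, "short axis", kind = "lymph_node")), "normal")
  expect_equal(overall(mk_finding("RID13296", 2.65, "short axis", kind = "lymph_node")), "abnormal")
  expect_equal(overall(mk_finding("RID86", 9.6, "length")), "normal")
  expect_equal(overall(mk_finding("RID86", c(14.8, 8.5))), "normal")
  expect_equal(overall(mk_finding("RID86", c(9, 3.5, 6.5))), "abnormal")
  expect_equal(overall(mk_finding("RID580", 4)), "normal")
  expect_equal(overall(mk_finding("rib", c(2.8, 0.7))), "unclassified")
  expect_equal(overall(mk_finding("portion_of_soft_tissue", 5.2)), "unclassified")
})

test_that("classification writes the finding type back onto the finding", {
  kb <- test_kb()
  r <- classify_finding(mk_finding("RID86", 9.6, "length"), kb)
  expect_equal(r$finding$finding_type, "normal")
  res <- classify_findings(list(mk_finding("RID86", 9.6, "length"),
                                mk_finding("rib", 2)), kb)
  types <- vapply(attr(res, "findings"), `[[`, character(1), "finding_type")
  expect_equal(types, c("normal", "unclassified"))
})

test_that("lesions are abnormal by definition under the default rule", {
  kb <- test_kb()
  r <- classify_finding(mk_finding("liver_lesion", 0.4, kind = "lesion"), kb)
  expect_equal(r$overall, "abnormal")
  expect_equal(r$provenance, "lesion_rule")
  expect_true(all(r$outcomes$label == "no_spec"))

  r2 <- classify_finding(mk_finding("liver_lesion", 0.4, kind = "lesion"), kb,
                         lesion_rule = "unclassified")
  expect_equal(r2$overall, "unclassified")
})

test_that("gold-standard scoring reproduces the confusion arithmetic", {
  mklabels <- function(counts) {
    ids <- paste0("f", seq_len(sum(counts)))
    pred <- rep(c("normal", "abnormal", "normal", "abnormal", "unclassified"), counts)
    gold <- rep(c("normal", "abnormal", "abnormal", "normal", "normal"), counts)
    list(pred = stats::setNames(pred, ids), gold = stats::setNames(gold, ids))
  }
  onc <- mklabels(c(115, 290, 2, 2, 11))
  e1 <- evaluate_against_gold(onc$pred, onc$gold)
  expect_equal(e1$n, 420)
  expect_equal(unname(e1$counts), c(115, 290, 2, 2, 11))
  expect_equal(round(e1$accuracy_pct, 1), 96.4)

  mix <- mklabels(c(86, 279, 2, 1, 25))
  e2 <- evaluate_against_gold(mix$pred, mix$gold)
  expect_equal(e2$n, 393)
  expect_equal(round(e2$accuracy_pct, 1), 92.9)

  allu <- mklabels(c(0, 0, 0, 0, 10))
  expect_equal(evaluate_against_gold(allu$pred, allu$gold)$accuracy_pct, 0)

  expect_error(
    evaluate_against_gold(c(f1 = "normal"), c(f2 = "normal")),
    "id sets differ")
})

test_that("classification is deterministic and total", {
  kb <- test_kb()
  co <- generate_cohort(scenario("mixed", n_patients = 3, seed = 5))
  r1 <- classification_table(classify_findings(co$findings, kb))
  r2 <- classification_table(classify_findings(co$findings, kb))
  expect_identical(r1, r2)
  expect_true(all(r1$overall %in% c("normal", "abnormal", "unclassified")))
})

test_that("growing a value never flips abnormal_high back to normal", {
  kb <- test_kb()
  ln <- kb$specs[kb$specs$spec_id == "ln_short_axis", ]
  vals <- sort(stats::runif(100, 0.1, 60))
  labs <- vapply(vals, classify_value, character(1), spec = ln)
  first_abn <- match("abnormal_high", labs)
  if (!is.na(first_abn)) {
    expect_true(all(labs[first_abn:length(labs)] == "abnormal_high"))
  }
})
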