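test_that("target candidacy applies the 15 mm / 10 mm thresholds inclusively", {
  mk <- function(entity, vals, q, kind, id) {
    new_finding("P1", "E1", "2024-01-01", entity,
                data.frame(value = vals, unit = "mm", quality = q),
                entity_kind = kind, finding_id = id, lesion_id = id)
  }
  findings <- list(
    mk("mediastinal_lymph_node", 16, "short axis", "lymph_node", "ln16"),
    mk("mediastinal_lymph_node", 14.9, "short axis", "lymph_node", "ln149"),
    mk("mediastinal_lymph_node", 15, "short axis", "lymph_node", "ln15"),
    mk("liver_lesion", 10, "longest axis", "lesion", "le10"),
    mk("liver_lesion", 9.9, "longest axis", "lesion", "le99"),
    mk("RID86", 120, "height", "anatomical_structure", "spl")  # ignored
  )
  ct <- candidate_targets(findings)
  expect_equal(stats::setNames(ct$potential, ct$finding_id),
               c(ln16 = TRUE, ln149 = FALSE, ln15 = TRUE, le10 = TRUE, le99 = FALSE))

  # a lymph node with one unlabeled value has no identifiable short axis
  one <- new_finding("P1", "E1", "2024-01-01", "mediastinal_lymph_node",
                     data.frame(value = 20, unit = "mm"),
                     entity_kind = "lymph_node", finding_id = "ln1d")
  ct2 <- candidate_targets(list(one))
  expect_equal(nrow(ct2), 0)
  expect_equal(attr(ct2, "excluded")$finding_id, "ln1d")

  # unlabeled two-dimensional lymph node: short axis is the second largest
  two <- new_finding("P1", "E1", "2024-01-01", "mediastinal_lymph_node",
                     data.frame(value = c(22, 16), unit = "mm"),
                     entity_kind = "lymph_node", finding_id = "ln2d",
                     lesion_id = "ln2d")
  expect_equal(candidate_targets(list(two))$diameter_mm, 16)
})

test_that("selection verification enforces the 5-lesion and 2-per-organ limits", {
  sel5 <- data.frame(lesion_id = paste0("L", 1:5),
                     organ_id = c("liver", "lung", "RID86", "RID205", "neck"))
  expect_true(verify_selection(sel5)$pass)

  sel6 <- rbind(sel5, data.frame(lesion_id = "L6", organ_id = "axilla"))
  v6 <- verify_selection(sel6)
  expect_false(v6$pass)
  expect_match(v6$violations, "at most 5")

  sel_org <- data.frame(lesion_id = paste0("L", 1:4),
                        organ_id = c("liver", "liver", "liver", "lung"))
  vo <- verify_selection(sel_org)
  expect_false(vo$pass)
  expect_match(vo$violations, "liver appears 3")
})

test_that("diameter sums add per-lesion contributions", {
  s <- recist_sum(data.frame(lesion_id = c("ln", "le"),
                             diameter_mm = c(20, 30), present = TRUE), "E1")
  expect_equal(s$value_mm, 50)
  expect_equal(s$contributions, c(ln = 20, le = 30))

  expect_equal(recist_sum(data.frame(lesion_id = character(),
                                     diameter_mm = numeric()))$value_mm, 0)
  expect_equal(recist_sum(data.frame(lesion_id = c("a", "b"),
                                     diameter_mm = c(0, 12),
                                     present = c(FALSE, TRUE)))$value_mm, 12)
  expect_error(recist_sum(data.frame(lesion_id = "a", diameter_mm = NA_real_)),
               "missing measurement.*a")
})

test_that("response classification follows the four criteria with precedence", {
  expect_equal(classify_response(c(100, 70))$label, "PR")      # exactly -30 %
  expect_equal(classify_response(c(100, 70.1))$label, "SD")
  expect_equal(classify_response(c(100, 50, 61))$label, "PD")  # +22 %, +11 mm
  expect_equal(classify_response(c(30, 20, 24))$label, "SD")   # +20 % but +4 mm
  expect_equal(classify_response(c(100, 101), new_lesions = TRUE)$label, "PD")
  expect_equal(classify_response(c(100, 0))$label, "CR")
  expect_equal(classify_response(c(100, 0),
                                 lymph_node_short_axes_mm = 10)$label, "PR")
  expect_equal(classify_response(c(100, 0),
                                 lymph_node_short_axes_mm = 9.9)$label, "CR")
  expect_error(classify_response(numeric(0)), "empty timeline")
  expect_error(classify_response(100), "baseline")

  r <- classify_response(c(100, 80, 90), exam_id = "E3")
  expect_equal(r$nadir_sum, 80)
  expect_equal(r$baseline_sum, 100)
  expect_equal(r$current_sum, 90)
})

test_that("percent rules are scale-invariant but the 5 mm rule is not", {
  base <- c(50, 61)                       # +22 %, +11 mm: PD
  expect_equal(classify_response(base)$label, "PD")
  expect_equal(classify_response(base * 10)$label, "PD")
  # shrinking by k = 0.3 drops the absolute increase to 3.3 mm < 5 mm
  expect_equal(classify_response(base * 0.3)$label, "SD")
})

test_that("the nadir never increases as exams are appended", {
  set.seed(99)
  for (i in 1:20) {
    sums <- round(stats::runif(6, 5, 150), 1)
    nadirs <- vapply(2:6, function(k) classify_response(sums[1:k])$nadir_sum,
                     numeric(1))
    expect_true(all(diff(nadirs) <= 0 + 1e-12))
  }
})

test_that("1000 random timelines agree with a direct rule transcription", {
  set.seed(2024)
  for (i in 1:1000) {
    n <- sample(2:6, 1)
    sums <- round(stats::runif(n, 0, 150), 1)
    if (stats::runif(1) < 0.15) sums[n] <- 0
    ln <- if (stats::runif(1) < 0.3) round(stats::runif(sample(1:3, 1), 4, 20), 1)
          else numeric(0)
    new <- stats::runif(1) < 0.1
    expect_equal(classify_response(sums, ln, new)$label,
                 response_oracle(sums, ln, new),
                 label = paste("timeline", i))
  }
})

test_that("timelines assemble sums and labels per exam", {
  kb <- test_kb()
  co <- generate_cohort(scenario("PR", n_patients = 2, seed = 17, noise = 0))
  pid <- "P001"
  f1 <- co$findings[vapply(co$findings, function(f) f$patient_id == pid, logical(1))]
  fl <- co$new_lesion_flags[co$new_lesion_flags$patient_id == pid, ]
  tl <- assess_timeline(f1, co$selection[[pid]],
                        stats::setNames(fl$new_lesions, fl$exam_id), graph = kb$graph)
  expect_equal(nrow(tl), 3)
  expect_true(is.na(tl$label[1]))
  expect_equal(tl$label[3], "PR")
  expect_true(all(diff(tl$sum_mm) < 0))
})
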