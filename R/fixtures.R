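#' Packaged mini knowledge base
#'
#' Loads the anatomy graph (~36 concepts: a lymph-node subtree with eight
#' subclasses, spleen, kidney, gallbladder wall, ureter, aorta segments,
#' a lesion branch, and the thorax/abdomen/mediastinum regions) and the
#' packaged normal-size specifications from the package's plain-text data
#' files.
#'
#' @return A list with elements `graph` (`rad_anatomy`) and `specs`
#'   (`rad_specs`).
#' @examples
#' kb <- packaged_kb()
#' most_specific_spec(kb$graph, kb$specs, "mediastinal_lymph_node", "short axis")
#' @export
packaged_kb <- function() {
  graph <- read_anatomy(
    system.file("extdata", "anatomy_edges.tsv", package = "radsize"),
    system.file("extdata", "anatomy_labels.tsv", package = "radsize")
  )
  specs <- read_specs(
    system.file("extdata", "size_specs.yaml", package = "radsize"), graph)
  list(graph = graph, specs = specs)
}

#' Define a synthetic cohort scenario
#'
#' A scenario fixes the response course every patient follows (per-exam
#' scale factors applied to baseline lesion sizes), the cohort size, and
#' the measurement noise. Noise is multiplicative uniform in
#' `[1 - noise, 1 + noise]`: sizes are positive and ratio-scaled, and
#' repeat measurements in practice vary by a few percent.
#'
#' @param name `"CR"`, `"PR"`, `"PD"`, `"SD"`, or `"mixed"` (per-patient
#'   course sampled among the four).
#' @param n_patients Number of patients.
#' @param exams_per_patient Number of exams (>= 2); the first is baseline.
#' @param noise Half-width of the multiplicative noise band (default 0.02).
#' @param seed Integer seed; identical scenarios generate identical
#'   cohorts bit for bit.
#' @param factors Optional numeric vector of per-exam scale factors
#'   (length `exams_per_patient`, first element 1); defaults per `name`:
#'   CR ends at 0, PR at 0.65, PD at 1.45, SD at 1.04.
#' @return An object of class `rad_scenario`.
#' @export
scenario <- function(name = c("PR", "CR", "PD", "SD", "mixed"),
                     n_patients = 8, exams_per_patient = 3,
                     noise = 0.02, seed = 1, factors = NULL) {
  name <- match.arg(name)
  stopifnot(n_patients >= 1, exams_per_patient >= 2, noise >= 0, noise < 1)
  if (!is.null(factors)) {
    if (length(factors) != exams_per_patient || any(factors < 0) || factors[1] != 1) {
      stop("factors must have one positive entry per exam, starting at 1 ",
           "(0 allowed only for disappearance)")
    }
  }
  structure(list(name = name, n_patients = n_patients,
                 exams_per_patient = exams_per_patient,
                 noise = noise, seed = as.integer(seed), factors = factors),
            class = "rad_scenario")
}

scenario_factors <- function(name, n_exams) {
  final <- c(CR = 0, PR = 0.65, PD = 1.45, SD = 1.04)[[name]]
  f <- seq(1, final, length.out = n_exams)
  if (name == "CR") f[n_exams] <- 0
  f
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# draw inside a normal range with a safety margin, or outside it
draw_in <- function(lo, hi) stats::runif(1, lo, hi)

#' Generate a synthetic cohort of measurement findings
#'
#' Emulates the finding stream of a follow-up study: per patient one
#' three-dimensional spleen measurement, labeled kidney / gallbladder-wall
#' / ureter measurements, non-target lymph nodes, occasionally an entity
#' the knowledge base does not cover (rib), and 2-4 target lesions
#' (lymph nodes and liver/lung lesions) whose sizes follow the scenario's
#' per-exam scale factors times multiplicative noise. Baseline targets
#' respect the RECIST candidacy thresholds. Gold normality labels are
#' computed from the generating parameters (which band a value was drawn
#' from), never from the classifier; values are drawn with a 5 % margin
#' away from the specification bounds so that at zero noise the gold label
#' is unambiguous.
#'
#' @param sc A `rad_scenario` (see [scenario()]).
#' @return A list with `findings` (list of `rad_finding`), `gold`
#'   (data.frame: `finding_id`, `gold_label`; `NA` for entities the KB does
#'   not cover and for lesion findings whose abnormality is definitional),
#'   `selection` (named list: patient id -> selected target lesion ids),
#'   `new_lesion_flags` (data.frame: `patient_id`, `exam_id`,
#'   `new_lesions`), `expected_response` (named character: patient id ->
#'   scenario course), and `scenario`.
#' @export
generate_cohort <- function(sc) {
  stopifnot(inherits(sc, "rad_scenario"))
  with_local_seed(sc$seed, {
    n_ex <- sc$exams_per_patient
    dates <- as.Date("2024-01-15") + 56 * (seq_len(n_ex) - 1)
    exam_ids <- sprintf("E%02d", seq_len(n_ex))
    noise <- function() stats::runif(1, 1 - sc$noise, 1 + sc$noise)

    findings <- list()
    gold <- list()
    selection <- list()
    flags <- list()
    expected <- character()

    add <- function(f, g) {
      findings[[length(findings) + 1L]] <<- f
      gold[[length(gold) + 1L]] <<- data.frame(
        finding_id = f$finding_id, gold_label = g, stringsAsFactors = FALSE)
    }
    cm1 <- function(mm) round(mm / 10, 1)   # report in cm, 1 decimal
    mm1 <- function(mm) round(mm, 1)

    ln_entities <- c("mediastinal_lymph_node", "axillary_lymph_node",
                     "aortopulmonary_lymph_node", "abdominal_lymph_node")
    de_tpl <- paste0("Die LK im aortopulmonalen Fenster und prätracheal ",
                     "größenunverändert mit einer Größe ",
                     "von bis zu %s cm.")

    for (p in seq_len(sc$n_patients)) {
      pid <- sprintf("P%03d", p)
      course <- if (sc$name == "mixed") {
        sample(c("CR", "PR", "PD", "SD"), 1)
      } else sc$name
      expected[pid] <- course
      factors <- sc$factors %||% scenario_factors(course, n_ex)

      for (k in seq_len(n_ex)) {
        ex <- exam_ids[k]; dt <- dates[k]
        fid <- function(tag) sprintf("%s-%s-%s", pid, tag, ex)

        # spleen, three unlabeled dimensions (height, length, width)
        ab_spleen <- stats::runif(1) < 0.3
        h <- if (ab_spleen && stats::runif(1) < 0.5) draw_in(156, 190) else draw_in(112, 148)
        l <- draw_in(71.5, 98.5)
        w <- if (ab_spleen && h < 150) draw_in(20, 36) else draw_in(41, 59)
        g_spleen <- if (h > 150 || w < 40) "abnormal" else "normal"
        v <- c(h, l, w) * c(noise(), noise(), noise())
        add(new_finding(pid, ex, dt, "RID86",
              data.frame(value = cm1(v), unit = "cm"),
              entity_kind = "anatomical_structure", entity_label = "spleen",
              sentence = sprintf("Milz ca. %s × %s × %s cm.",
                                 cm1(v)[1], cm1(v)[2], cm1(v)[3]),
              finding_id = fid("SPL")), g_spleen)

        # labeled kidney craniocaudal diameter (interval 80-130 mm)
        ab_k <- stats::runif(1) < 0.25
        kd <- if (ab_k) draw_in(137, 170) else draw_in(84, 126)
        add(new_finding(pid, ex, dt, "RID205",
              data.frame(value = cm1(kd * noise()), unit = "cm",
                         quality = "craniocaudal diameter", plane = "coronal"),
              entity_kind = "anatomical_structure", entity_label = "kidney",
              sentence = sprintf("Niere kraniokaudal %s cm.", cm1(kd)),
              finding_id = fid("KID")), if (ab_k) "abnormal" else "normal")

        # labeled gallbladder wall thickness (interval 1-3 mm)
        ab_g <- stats::runif(1) < 0.25
        gw <- if (ab_g) draw_in(3.3, 6) else draw_in(1.2, 2.8)
        add(new_finding(pid, ex, dt, "RID33779",
              data.frame(value = mm1(gw * noise()), unit = "mm",
                         quality = "thickness"),
              entity_kind = "anatomical_structure",
              entity_label = "wall of gallbladder",
              sentence = sprintf("Gallenblasenwand %s mm.", mm1(gw)),
              finding_id = fid("GBW")), if (ab_g) "abnormal" else "normal")

        # non-target lymph node, labeled short axis; shrinks with the course
        if (k == 1) pat_ln <- draw_in(12, 30)
        lnv <- if (course == "CR" && k == n_ex) draw_in(6, 9.3)
               else max(pat_ln * factors[k], 3)
        lnv <- lnv * noise()
        # guard band wider than the 0.5 mm quantization of cm reporting
        g_ln <- if (lnv >= 10.6) "abnormal" else if (lnv <= 9.4) "normal" else NA
        add(new_finding(pid, ex, dt, ln_entities[(p + k) %% length(ln_entities) + 1],
              data.frame(value = cm1(c(lnv * 1.5, lnv)), unit = "cm",
                         quality = c("longest axis", "short axis"),
                         plane = "axial"),
              entity_kind = "lymph_node", entity_label = "lymph node",
              sentence = sprintf(de_tpl, paste(cm1(c(lnv * 1.5, lnv)), collapse = " × ")),
              finding_id = fid("LNN")), g_ln)

        # occasionally an entity the KB does not cover
        if ((p + k) %% 5 == 0) {
          add(new_finding(pid, ex, dt, "rib",
                data.frame(value = cm1(c(draw_in(20, 35), draw_in(5, 9))), unit = "cm"),
                entity_kind = "anatomical_structure", entity_label = "rib",
                sentence = "Rippe unauffällig.",
                finding_id = fid("RIB")), NA_character_)
        }
      }

      # target lesions: 2-4, distinct organs
      n_t <- sample(2:4, 1)
      t_entities <- c("liver_lesion", "lung_lesion",
                      "mediastinal_lymph_node", "axillary_lymph_node")[seq_len(n_t)]
      t_kinds <- c("lesion", "lesion", "lymph_node", "lymph_node")[seq_len(n_t)]
      sel <- character()
      for (t in seq_len(n_t)) {
        lid <- sprintf("%s-T%d", pid, t)
        sel <- c(sel, lid)
        d0 <- if (t_kinds[t] == "lymph_node") draw_in(16, 35) else draw_in(12, 50)
        for (k in seq_len(n_ex)) {
          dk <- d0 * factors[k]
          if (dk <= 0) next   # disappeared: no finding at this exam
          dk <- dk * noise()
          meas <- if (t_kinds[t] == "lymph_node") {
            data.frame(value = mm1(c(dk * 1.4, dk)), unit = "mm",
                       quality = c("longest axis", "short axis"), plane = "axial")
          } else {
            data.frame(value = mm1(dk), unit = "mm", quality = "longest axis",
                       plane = "axial")
          }
          add(new_finding(pid, exam_ids[k], dates[k], t_entities[t], meas,
                entity_kind = t_kinds[t],
                entity_label = concept_label(packaged_fixture_graph(), t_entities[t]),
                sentence = sprintf("Zielläsion %s: %s mm.", lid, mm1(dk)),
                finding_id = sprintf("%s-%s", lid, exam_ids[k]),
                lesion_id = lid),
              if (t_kinds[t] == "lesion") NA_character_
              else if (dk >= 10.6) "abnormal"
              else if (dk <= 9.4) "normal" else NA_character_)
        }
      }
      selection[[pid]] <- sel

      new_at_last <- course == "PD" && stats::runif(1) < 0.25
      flags[[length(flags) + 1L]] <- data.frame(
        patient_id = pid, exam_id = exam_ids,
        new_lesions = c(rep(FALSE, n_ex - 1), new_at_last),
        stringsAsFactors = FALSE)
    }

    list(findings = findings,
         gold = do.call(rbind, gold),
         selection = selection,
         new_lesion_flags = do.call(rbind, flags),
         expected_response = expected,
         scenario = sc)
  })
}

# cached copy of the packaged graph for labelling inside the generator
packaged_fixture_graph <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- packaged_kb()$graph
    g
  }
})

#' Write a generated cohort to plain-text files
#'
#' Writes `findings.jsonl` (JSON-Lines finding stream), `gold.csv`
#' (radiologist-style gold labels), `selection.json` (target lesion ids per
#' patient), and `new_lesions.csv` (per-exam new-lesion flags).
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_findings(cohort$findings, file.path(dir, "findings.jsonl"))
  utils::write.csv(cohort$gold, file.path(dir, "gold.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$selection, file.path(dir, "selection.json"))
  utils::write.csv(cohort$new_lesion_flags, file.path(dir, "new_lesions.csv"),
                   row.names = FALSE)
  invisible(dir)
}
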