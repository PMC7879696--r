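# The built-in analysis battery, its controls, and the forest rendering.

test_that("the built-in plan encodes the analysis battery", {
  plan <- builtin_plan()
  expect_length(plan$controls, 5L)
  nms <- names(plan$analyses)
  expect_false(anyDuplicated(nms) > 0)
  # main, primary-suspect, HCP, by-sex, five exclusion analyses, all
  # combined, plus diabetes-restricted duplicates of the exclusion battery
  expect_true(all(c("main", "primary_suspect_only", "hcp_reporters",
                    "sex_male", "sex_female", "no_antiarrhythmics",
                    "no_renal_indication", "no_insulin_comparator",
                    "no_insulin_no_cvd", "no_competing_ae", "all_filters",
                    "main_dm", "all_filters_dm") %in% nms))
  # insulin exclusion applies to the comparator group only
  ins <- plan$analyses$no_insulin_comparator$spec$filters[[1]]
  expect_identical(ins$set_name, "insulin")
  expect_identical(ins$scope, "comparator")
  # diabetes-restricted variants prepend the require filter
  dm <- plan$analyses$main_dm$spec$filters[[1]]
  expect_identical(dm$action, "require_report")
  expect_identical(dm$set_name, "diabetes_indication")
  # primary-suspect analysis restricts roles in both groups
  expect_identical(plan$analyses$primary_suspect_only$spec$drug_roles,
                   "primary_suspect")
  # control directions
  dirs <- vapply(plan$controls, `[[`, character(1), "expected_direction")
  names(dirs) <- vapply(plan$controls, `[[`, character(1), "name")
  expect_identical(dirs[["ibrutinib_af"]], "increase")
  expect_identical(dirs[["sglt2i_appendicitis"]], "null")
  expect_identical(dirs[["sglt2i_stroke"]], "null")
  expect_identical(dirs[["sglt2i_heart_failure"]], "decrease")
  expect_identical(dirs[["sglt2i_ckd"]], "decrease")
})

test_that("run_plan recovers the generator truth across the battery", {
  # competing events disabled so no analysis is biased by masking
  cfg <- generator_config(
    n_exposed = 30000, n_comparator = 120000, n_ibrutinib = 3000,
    competing_ae_probs = data.frame(term = "urinary tract infection",
                                    p_exposed = 0, p_comparator = 0),
    seed = 42)
  g <- generate(cfg)
  s <- suppressMessages(dedup_latest(g$store))
  res <- run_plan(s)
  ana <- res[res$type == "analysis", ]
  expect_true(all(ana$analyzable))
  # the interconnected analyses are highly correlated; allow two of the
  # eighteen 95% intervals to miss the truth
  covered <- ana$ci_low <= 0.55 & ana$ci_high >= 0.55
  expect_gte(sum(covered), nrow(ana) - 2L)
  expect_true(covered[ana$analysis == "main"])
  # controls come out in their expected directions
  verdicts <- evaluate_controls(res, builtin_plan())
  expect_true(all(verdicts$verdict == "pass"))
  # attrition recorded for filtered analyses
  att <- attr(res, "attrition")
  expect_true(nrow(att$no_insulin_comparator) == 1L)
  expect_gt(att$no_insulin_comparator$comparator_removed, 0)
  expect_equal(att$no_insulin_comparator$exposed_removed, 0)
})

test_that("run_plan is deterministic and flags unanalyzable cohorts", {
  cfg <- generator_config(n_exposed = 500, n_comparator = 1000,
                          n_ibrutinib = 0, seed = 5)
  g <- generate(cfg)
  s <- suppressMessages(dedup_latest(g$store))
  r1 <- run_plan(s)
  r2 <- run_plan(s)
  expect_identical(r1, r2)
  # no ibrutinib arm: the positive control has an empty exposure group
  expect_false(r1$analyzable[r1$analysis == "ibrutinib_af"])
  expect_true(is.na(r1$prr[r1$analysis == "ibrutinib_af"]))
  # an empty store is all flagged rows, not a crash
  empty <- tiny_store(
    demo = data.frame(primaryid = character(0), caseid = character(0),
                      caseversion = integer(0), quarter = character(0),
                      age_band = character(0), sex = character(0),
                      occp_cod = character(0)),
    drug = data.frame(primaryid = character(0), drug_seq = integer(0),
                      drugname = character(0), role_cod = character(0)),
    reac = data.frame(primaryid = character(0), pt = character(0)))
  r0 <- run_plan(empty)
  expect_false(any(r0$analyzable))
})

test_that("a filter matching no report leaves every statistic unchanged", {
  cfg <- generator_config(n_exposed = 1000, n_comparator = 2000,
                          n_ibrutinib = 0, p_antiarrhythmic = 0, seed = 8)
  g <- generate(cfg)
  s <- suppressMessages(dedup_latest(g$store))
  base <- cohort_spec("sglt2i", "atc_a10_other")
  with_noop <- cohort_spec("sglt2i", "atc_a10_other", filters = list(
    filter_spec("noop", "exclude_report", "drug_in_set", "antiarrhythmics")))
  t1 <- count_events(s, build_cohort(s, base), "af")
  t2 <- count_events(s, build_cohort(s, with_noop), "af")
  r1 <- compute_prr(t1); r2 <- compute_prr(t2)
  expect_equal(unclass(r1), unclass(r2))
})

test_that("by-sex strata split the store and drop unknown sex", {
  cfg <- generator_config(n_exposed = 2000, n_comparator = 4000,
                          n_ibrutinib = 0, seed = 21)
  g <- generate(cfg)
  s <- suppressMessages(dedup_latest(g$store))
  res <- run_plan(s)
  nm <- res[res$analysis == "sex_male", ]
  nf <- res[res$analysis == "sex_female", ]
  main <- res[res$analysis == "main", ]
  n_unknown <- sum(s$demo$sex == "unknown")
  expect_lt(nm$exposed_n + nf$exposed_n + nm$comparator_n + nf$comparator_n,
            main$exposed_n + main$comparator_n)
  expect_equal(main$exposed_n + main$comparator_n -
                 (nm$exposed_n + nf$exposed_n + nm$comparator_n +
                    nf$comparator_n), n_unknown)
})

test_that("control verdict logic follows the expected direction", {
  plan <- analysis_plan(
    analyses = list(dummy = list(spec = cohort_spec("sglt2i",
                                                    "atc_a10_other"))),
    controls = list(
      control_spec("pos", "ibrutinib", NULL, "af", "increase"),
      control_spec("neg", "sglt2i", "atc_a10_other", "appendicitis", "null"),
      control_spec("dec", "sglt2i", "atc_a10_other", "heart_failure",
                   "decrease")))
  results <- data.frame(
    analysis = c("pos", "neg", "dec"),
    prr = c(10.6, 1.18, 1.0),
    ci_low = c(10.2, 0.78, 0.9),
    ci_high = c(11.1, 1.79, 1.1))
  v <- evaluate_controls(results, plan)
  expect_identical(v$verdict, c("pass", "pass", "fail"))
})

test_that("forest renderings preserve plan order and the reference line", {
  res <- data.frame(
    analysis = c("main", "second"),
    prr = c(1.0, 0.55), ci_low = c(0.5, 0.49), ci_high = c(2.0, 0.62),
    analyzable = TRUE)
  p <- render_forest(res)
  expect_s3_class(p, "ggplot")
  expect_identical(levels(p$data$analysis), rev(res$analysis))
  txt <- render_forest_text(res)
  expect_length(txt, 2L)
  # PRR = 1 sits on the reference column (read the column off the second
  # row, whose interval lies left of the line and leaves it visible)
  ref_col <- as.integer(regexpr("|", txt[2], fixed = TRUE))
  star_col <- as.integer(regexpr("*", txt[1], fixed = TRUE))
  expect_equal(star_col, ref_col)
  # the worked-example interval renders strictly left of the reference line
  we <- as.data.frame(compute_prr(contingency_table(295, 61803, 5565,
                                                    636466)))
  we$analysis <- "main"; we$analyzable <- TRUE
  txt2 <- render_forest_text(we)
  band <- sub("^main +", "", txt2)
  expect_lt(regexpr("*", band, fixed = TRUE),
            regexpr("|", band, fixed = TRUE))
})
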