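# Cohort assignment, the filter cascade and event counting, each checked
# against brute-force set algebra.

test_that("overlap policy resolves reports listing both drug groups", {
  s <- bind_reports(
    one_report(pid = "P1", caseid = "P1", drugs = c("dapagliflozin",
                                                    "metformin"),
               roles = c("concomitant", "suspect")),
    one_report(pid = "P2", caseid = "P2", drugs = "metformin",
               roles = "suspect")
  )
  spec <- cohort_spec("sglt2i", "atc_a10_other")
  co <- assign_exposure(s, spec)
  expect_setequal(co$exposed_ids, "P1")
  expect_setequal(co$comparator_ids, "P2")

  co2 <- assign_exposure(s, cohort_spec("sglt2i", "atc_a10_other",
                                        overlap_policy = "allow"))
  expect_setequal(co2$exposed_ids, "P1")
  expect_setequal(co2$comparator_ids, c("P1", "P2"))

  co3 <- assign_exposure(s, cohort_spec("sglt2i", "atc_a10_other",
                                        overlap_policy = "exclude_from_both"))
  expect_length(co3$exposed_ids, 0L)
  expect_setequal(co3$comparator_ids, "P2")
})

test_that("drug roles restrict group membership", {
  s <- bind_reports(
    one_report(pid = "R1", caseid = "R1", drugs = "empagliflozin",
               roles = "concomitant"),
    one_report(pid = "R2", caseid = "R2", drugs = "empagliflozin",
               roles = "primary_suspect")
  )
  co <- assign_exposure(s, cohort_spec("sglt2i", "atc_a10_other",
                                       drug_roles = "primary_suspect"))
  expect_setequal(co$exposed_ids, "R2")
  co_all <- assign_exposure(s, cohort_spec("sglt2i", "atc_a10_other"))
  expect_setequal(co_all$exposed_ids, c("R1", "R2"))
  expect_error(assign_exposure(s, cohort_spec("nope", "atc_a10_other")),
               "unknown term set")
})

test_that("group assignment recovers the generator's labels", {
  cfg <- generator_config(n_exposed = 800, n_comparator = 1200,
                          n_ibrutinib = 50, seed = 11)
  g <- generate(cfg)
  s <- suppressMessages(dedup_latest(g$store))
  co <- assign_exposure(s, cohort_spec("sglt2i", "atc_a10_other"))
  truth_exp <- g$truth$caseid[g$truth$group == "exposed"]
  truth_cmp <- g$truth$caseid[g$truth$group == "comparator"]
  to_case <- function(ids) unique(s$demo$caseid[s$demo$primaryid %in% ids])
  expect_setequal(to_case(co$exposed_ids), truth_exp)
  expect_setequal(to_case(co$comparator_ids), truth_cmp)
})

test_that("exclude and require filters act on the right reports", {
  s <- bind_reports(
    one_report(pid = "F1", caseid = "F1",
               drugs = c("canagliflozin", "amiodarone"),
               roles = c("suspect", "concomitant"),
               reactions = "atrial fibrillation"),
    one_report(pid = "F2", caseid = "F2", drugs = "canagliflozin",
               roles = "suspect", indications = "type 2 diabetes mellitus"),
    one_report(pid = "F3", caseid = "F3", drugs = "metformin",
               roles = "suspect")
  )
  co <- assign_exposure(s, cohort_spec("sglt2i", "atc_a10_other"))
  # anti-arrhythmic co-medication removes the whole report from its group
  co1 <- apply_filters(s, co, list(
    filter_spec("no_aa", "exclude_report", "drug_in_set", "antiarrhythmics")))
  expect_setequal(co1$exposed_ids, "F2")
  expect_equal(co1$attrition$exposed_removed, 1L)
  # requiring the diabetes indication removes reports without one
  co2 <- apply_filters(s, co, list(
    filter_spec("dm", "require_report", "indication_in_set",
                "diabetes_indication")))
  expect_setequal(co2$exposed_ids, "F2")
  expect_length(co2$comparator_ids, 0L)
  # comparator-scoped filter leaves the exposed group alone
  s2 <- bind_reports(
    one_report(pid = "G1", caseid = "G1", drugs = "insulin glargine",
               roles = "suspect"),
    one_report(pid = "G2", caseid = "G2", drugs = "dapagliflozin",
               roles = "suspect"),
    one_report(pid = "G3", caseid = "G3", drugs = "metformin",
               roles = "suspect")
  )
  cox <- assign_exposure(s2, cohort_spec("sglt2i", "atc_a10_other"))
  co3 <- apply_filters(s2, cox, list(
    filter_spec("no_ins", "exclude_report", "drug_in_set", "insulin",
                scope = "comparator")))
  expect_setequal(co3$exposed_ids, "G2")
  expect_setequal(co3$comparator_ids, "G3")
})

test_that("filters are idempotent and never grow a group", {
  cfg <- generator_config(n_exposed = 400, n_comparator = 600,
                          n_ibrutinib = 0, seed = 17)
  g <- generate(cfg)
  s <- suppressMessages(dedup_latest(g$store))
  co <- assign_exposure(s, cohort_spec("sglt2i", "atc_a10_other"))
  fs <- list(
    filter_spec("aa", "exclude_report", "drug_in_set", "antiarrhythmics"),
    filter_spec("dm", "require_report", "indication_in_set",
                "diabetes_indication"),
    filter_spec("comp", "exclude_report", "reaction_in_set", "competing_ae"))
  prev_e <- length(co$exposed_ids); prev_c <- length(co$comparator_ids)
  cur <- co
  for (f in fs) {
    nxt <- apply_filters(s, cur, list(f))
    expect_lte(length(nxt$exposed_ids), prev_e)
    expect_lte(length(nxt$comparator_ids), prev_c)
    # idempotent: applying the same filter again changes nothing
    again <- apply_filters(s, nxt, list(f))
    expect_setequal(again$exposed_ids, nxt$exposed_ids)
    expect_setequal(again$comparator_ids, nxt$comparator_ids)
    prev_e <- length(nxt$exposed_ids); prev_c <- length(nxt$comparator_ids)
    cur <- nxt
  }
  # attrition sums to initial minus final sizes
  expect_equal(sum(cur$attrition$exposed_removed),
               length(co$exposed_ids) - length(cur$exposed_ids))
  expect_equal(sum(cur$attrition$comparator_removed),
               length(co$comparator_ids) - length(cur$comparator_ids))
})

test_that("random filter cascades agree with brute-force set algebra", {
  v <- builtin_term_sets()
  pool <- list(
    list(f = filter_spec("aa", "exclude_report", "drug_in_set",
                         "antiarrhythmics"),
         o = list(action = "exclude_report", kind = "drug",
                  terms = v$antiarrhythmics$terms, mode = "substring",
                  scope = "both", roles = c("primary_suspect", "suspect",
                                            "concomitant", "interacting"))),
    list(f = filter_spec("ins", "exclude_report", "drug_in_set", "insulin",
                         scope = "comparator"),
         o = list(action = "exclude_report", kind = "drug",
                  terms = v$insulin$terms, mode = "substring",
                  scope = "comparator", roles = c("primary_suspect",
                                                  "suspect", "concomitant",
                                                  "interacting"))),
    list(f = filter_spec("dm", "require_report", "indication_in_set",
                         "diabetes_indication"),
         o = list(action = "require_report", kind = "indication",
                  terms = v$diabetes_indication$terms, mode = "substring",
                  scope = "both")),
    list(f = filter_spec("comp", "exclude_report", "reaction_in_set",
                         "competing_ae"),
         o = list(action = "exclude_report", kind = "reaction",
                  terms = v$competing_ae$terms, mode = "exact",
                  scope = "both")),
    list(f = filter_spec("renal", "exclude_report", "indication_in_set",
                         "renal_indication"),
         o = list(action = "exclude_report", kind = "indication",
                  terms = v$renal_indication$terms, mode = "substring",
                  scope = "both"))
  )
  set.seed(404)
  for (rep in 1:8) {
    cfg <- generator_config(n_exposed = sample(100:300, 1),
                            n_comparator = sample(200:500, 1),
                            n_ibrutinib = 0,
                            p_event_comparator = 0.05,
                            seed = sample.int(10000, 1))
    g <- generate(cfg)
    s <- suppressMessages(dedup_latest(g$store))
    picks <- pool[sample(length(pool), sample(0:3, 1))]
    co <- apply_filters(s, assign_exposure(
      s, cohort_spec("sglt2i", "atc_a10_other")), lapply(picks, `[[`, "f"))
    tab <- count_events(s, co, "af")
    want <- oracle_pipeline(g$store, list(
      exposure_terms = v$sglt2i$terms,
      comparator_terms = v$atc_a10_other$terms,
      roles = c("primary_suspect", "suspect", "concomitant"),
      overlap = "exclude_from_comparator",
      event_terms = v$af$terms,
      filters = lapply(picks, `[[`, "o")))
    expect_equal(c(a = tab$a, b = tab$b, c = tab$c, d = tab$d), want)
  }
})

test_that("count_events tallies the 2x2 margins", {
  s <- bind_reports(
    one_report(pid = "E1", caseid = "E1", drugs = "dapagliflozin",
               reactions = "atrial fibrillation"),
    one_report(pid = "E2", caseid = "E2", drugs = "dapagliflozin",
               reactions = "headache"),
    one_report(pid = "E3", caseid = "E3", drugs = "metformin",
               reactions = c("atrial flutter", "nausea"))
  )
  co <- assign_exposure(s, cohort_spec("sglt2i", "atc_a10_other"))
  tab <- count_events(s, co, "af")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 1, 1, 0))
  # event matched by no report
  tab2 <- count_events(s, co, "appendicitis")
  expect_equal(c(tab2$a, tab2$c), c(0, 0))
  # empty group is unanalyzable
  s3 <- bind_reports(one_report(pid = "E9", caseid = "E9",
                                drugs = "dapagliflozin"))
  co3 <- assign_exposure(s3, cohort_spec("sglt2i", "atc_a10_other"))
  expect_error(count_events(s3, co3, "af"), "unanalyzable")
})

test_that("cohort specifications round-trip through YAML", {
  spec <- cohort_spec(
    "sglt2i", "atc_a10_other", drug_roles = "primary_suspect",
    overlap_policy = "exclude_from_both",
    filters = list(
      filter_spec("ins", "exclude_report", "drug_in_set", "insulin",
                  scope = "comparator"),
      filter_spec("dm", "require_report", "indication_in_set",
                  "diabetes_indication")))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_spec(spec, path)
  spec2 <- read_cohort_spec(path)
  expect_equal(spec2, spec)
})
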