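# The analysis battery: the main disproportionality analysis plus the
# cascade of sensitivity analyses and internal validity controls, run as one
# deterministic plan over a deduplicated store.

#' Specify an internal control analysis
#'
#' A control is a drug–event pair with a known expected direction, used to
#' check internal validity of the database and method: `"increase"` passes
#' when the CI lower bound exceeds 1, `"decrease"` when the upper bound is
#' below 1, `"null"` when the CI contains 1.
#'
#' @param name control label.
#' @param exposure_set drug term-set name for the control exposure.
#' @param comparator_set drug term-set name for the comparator, or `NULL`
#'   for "all other reports" (used for the ibrutinib positive control,
#'   whose natural comparator is the rest of the database).
#' @param event_set reaction term-set name.
#' @param expected_direction `"increase"`, `"decrease"` or `"null"`.
#' @return an object of class `control_spec`.
#' @export
control_spec <- function(name, exposure_set, comparator_set, event_set,
                         expected_direction = c("increase", "decrease",
                                                "null")) {
  expected_direction <- match.arg(expected_direction)
  structure(
    list(name = name, exposure_set = exposure_set,
         comparator_set = comparator_set, event_set = event_set,
         expected_direction = expected_direction),
    class = "control_spec"
  )
}

#' Assemble an analysis plan
#'
#' @param analyses named list; each element is a list with fields `spec` (a
#'   [cohort_spec()]), optional `subset` (`NULL`, `"hcp_only"`,
#'   `"sex_male"`, `"sex_female"`) and `event_set` (reaction set name,
#'   default `"af"`).
#' @param controls list of [control_spec()] objects.
#' @return an object of class `analysis_plan`.
#' @export
analysis_plan <- function(analyses, controls = list()) {
  if (is.null(names(analyses)) || anyDuplicated(names(analyses)))
    stop("analyses must be a uniquely named list")
  cn <- vapply(controls, `[[`, character(1), "name")
  if (anyDuplicated(cn)) stop("control names must be unique")
  structure(list(analyses = analyses, controls = controls),
            class = "analysis_plan")
}

#' The built-in SGLT2i / atrial-fibrillation analysis battery
#'
#' Returns the full plan: (1) the main analysis (SGLT2i vs other ATC-A10
#' drugs, suspect-or-concomitant roles); (2) primary-suspect-only roles in
#' both groups; (3) healthcare-professional reporters only; (4) stratified
#' by sex; (5) excluding anti-arrhythmic co-medication from both groups;
#' (6) excluding renal-disease indications; (7) excluding insulin from the
#' comparator; (8) additionally excluding cardiovascular-disease
#' indications; (9) excluding reports for competing adverse events
#' (genitourinary infections, ketoacidosis, Fournier's gangrene,
#' amputations); (10) all filters combined. The main analysis and each of
#' (5)–(10) are duplicated with the diabetes-indication restriction
#' (suffix `_dm`). Controls: ibrutinib → AF (expect increase), SGLT2i →
#' appendicitis (null), → stroke (null), → heart failure (decrease), →
#' chronic kidney disease (decrease).
#'
#' @param overlap_policy passed to every [cohort_spec()].
#' @return an [analysis_plan()].
#' @export
builtin_plan <- function(overlap_policy = "exclude_from_comparator") {
  base_spec <- function(filters = list(), drug_roles = c("primary_suspect",
                                                         "suspect",
                                                         "concomitant")) {
    cohort_spec("sglt2i", "atc_a10_other", drug_roles = drug_roles,
                filters = filters, overlap_policy = overlap_policy)
  }
  f_antiarr <- filter_spec("exclude_antiarrhythmics", "exclude_report",
                           "drug_in_set", "antiarrhythmics")
  f_renal   <- filter_spec("exclude_renal_indication", "exclude_report",
                           "indication_in_set", "renal_indication")
  f_insulin <- filter_spec("exclude_insulin_comparator", "exclude_report",
                           "drug_in_set", "insulin", scope = "comparator")
  f_cvd     <- filter_spec("exclude_cvd_indication", "exclude_report",
                           "indication_in_set", "cvd_indication")
  f_compet  <- filter_spec("exclude_competing_ae", "exclude_report",
                           "reaction_in_set", "competing_ae")
  f_dm      <- filter_spec("require_diabetes_indication", "require_report",
                           "indication_in_set", "diabetes_indication")

  core <- list(
    main = list(spec = base_spec()),
    primary_suspect_only = list(spec = base_spec(
      drug_roles = "primary_suspect")),
    hcp_reporters = list(spec = base_spec(), subset = "hcp_only"),
    sex_male = list(spec = base_spec(), subset = "sex_male"),
    sex_female = list(spec = base_spec(), subset = "sex_female"),
    no_antiarrhythmics = list(spec = base_spec(list(f_antiarr))),
    no_renal_indication = list(spec = base_spec(list(f_renal))),
    no_insulin_comparator = list(spec = base_spec(list(f_insulin))),
    no_insulin_no_cvd = list(spec = base_spec(list(f_insulin, f_cvd))),
    no_competing_ae = list(spec = base_spec(list(f_compet))),
    all_filters = list(spec = base_spec(list(f_antiarr, f_renal, f_insulin,
                                             f_cvd, f_compet)))
  )
  # analyses repeated under the diabetes-indication restriction
  dm_variants <- c("main", "no_antiarrhythmics", "no_renal_indication",
                   "no_insulin_comparator", "no_insulin_no_cvd",
                   "no_competing_ae", "all_filters")
  for (nm in dm_variants) {
    a <- core[[nm]]
    a$spec$filters <- c(list(f_dm), a$spec$filters)
    core[[paste0(nm, "_dm")]] <- a
  }

  controls <- list(
    control_spec("ibrutinib_af", "ibrutinib", NULL, "af", "increase"),
    control_spec("sglt2i_appendicitis", "sglt2i", "atc_a10_other",
                 "appendicitis", "null"),
    control_spec("sglt2i_stroke", "sglt2i", "atc_a10_other", "stroke",
                 "null"),
    control_spec("sglt2i_heart_failure", "sglt2i", "atc_a10_other",
                 "heart_failure", "decrease"),
    control_spec("sglt2i_ckd", "sglt2i", "atc_a10_other",
                 "chronic_kidney_disease", "decrease")
  )
  analysis_plan(core, controls)
}

.subset_store <- function(store, subset) {
  if (is.null(subset)) return(store)
  demo <- switch(subset,
    hcp_only = store$demo[occp_cod %in% c("physician", "other_hcp",
                                          "pharmacist")],
    sex_male = store$demo[sex == "male"],
    sex_female = store$demo[sex == "female"],
    stop("unknown subset: ", subset)
  )
  ids <- demo$primaryid
  .new_store(demo, store$drug[primaryid %in% ids],
             store$reac[primaryid %in% ids],
             store$indi[primaryid %in% ids], store$provenance)
}

# cohort for a control: comparator_set NULL means "all other valid reports"
.control_cohort <- function(store, ctrl, vocab) {
  if (!is.null(ctrl$comparator_set)) {
    return(build_cohort(store,
                        cohort_spec(ctrl$exposure_set, ctrl$comparator_set),
                        vocab))
  }
  exp_set <- .get_set(vocab, ctrl$exposure_set, "drug")
  valid <- intersect(unique(store$drug$primaryid),
                     unique(store$reac$primaryid))
  exp_ids <- intersect(
    unique(store$drug$primaryid[matches(exp_set, store$drug$drugname)]),
    valid)
  structure(list(exposed_ids = exp_ids,
                 comparator_ids = setdiff(valid, exp_ids),
                 attrition = data.frame()),
            class = "cohort_result")
}

#' Run an analysis plan over a store
#'
#' Executes every analysis and every control of the plan against the
#' (deduplicated) store and returns one row per analysis. An analysis whose
#' cohort is unanalyzable (an empty group) yields a flagged row with `NA`
#' statistics rather than an error. Output is a pure function of
#' `(store, plan, vocab)`.
#'
#' @param store a deduplicated [report_store()].
#' @param plan an [analysis_plan()], default [builtin_plan()].
#' @param vocab a [vocabulary()].
#' @param event_set default reaction set name for analyses that do not name
#'   one.
#' @return data.frame with columns `analysis`, `type`
#'   (`"analysis"`/`"control"`), `exposed_n`, `comparator_n`, the 2x2
#'   counts, rates, `prr`, `ci_low`, `ci_high`, `chi2`, `p_value`,
#'   `significant`, `analyzable`. Per-analysis attrition tables are attached
#'   as the `"attrition"` attribute.
#' @export
run_plan <- function(store, plan = builtin_plan(),
                     vocab = builtin_term_sets(), event_set = "af") {
  stopifnot(inherits(store, "report_store"), inherits(plan, "analysis_plan"))
  rows <- list()
  attrition <- list()
  na_row <- function(name, type) data.frame(
    analysis = name, type = type, exposed_n = NA_integer_,
    comparator_n = NA_integer_, a = NA_integer_, b = NA_integer_,
    c = NA_integer_, d = NA_integer_, rate_exposed = NA_real_,
    rate_comparator = NA_real_, prr = NA_real_, ci_low = NA_real_,
    ci_high = NA_real_, chi2 = NA_real_, p_value = NA_real_,
    significant = NA, analyzable = FALSE)

  run_one <- function(name, type, cohort_fun, ev_set) {
    tryCatch({
      cohort <- cohort_fun()
      tab <- count_events(store_local, cohort, ev_set, vocab)
      res <- compute_prr(tab)
      df <- cbind(
        data.frame(analysis = name, type = type,
                   exposed_n = length(cohort$exposed_ids),
                   comparator_n = length(cohort$comparator_ids)),
        as.data.frame(res)[, c("a", "b", "c", "d", "rate_exposed",
                               "rate_comparator", "prr", "ci_low", "ci_high",
                               "chi2", "p_value", "significant")])
      df$analyzable <- TRUE
      attrition[[name]] <<- cohort$attrition
      df
    }, error = function(e) na_row(name, type))
  }

  for (nm in names(plan$analyses)) {
    a <- plan$analyses[[nm]]
    store_local <- .subset_store(store, a$subset)
    ev <- if (is.null(a$event_set)) event_set else a$event_set
    rows[[nm]] <- run_one(nm, "analysis",
                          function() build_cohort(store_local, a$spec, vocab),
                          ev)
  }
  store_local <- store
  for (ctrl in plan$controls) {
    rows[[ctrl$name]] <- run_one(
      ctrl$name, "control",
      function() .control_cohort(store, ctrl, vocab), ctrl$event_set)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "attrition") <- attrition
  out
}

#' Evaluate internal controls against their expected direction
#'
#' @param results output of [run_plan()] (or any data.frame with `analysis`,
#'   `prr`, `ci_low`, `ci_high` columns containing the control rows).
#' @param plan the [analysis_plan()] the results came from.
#' @return data.frame with columns `control`, `expected_direction`, `prr`,
#'   `ci_low`, `ci_high`, `verdict` (`"pass"`/`"fail"`; `NA` when the
#'   control row was unanalyzable).
#' @export
evaluate_controls <- function(results, plan) {
  stopifnot(inherits(plan, "analysis_plan"))
  out <- lapply(plan$controls, function(ctrl) {
    row <- results[results$analysis == ctrl$name, , drop = FALSE]
    if (nrow(row) == 0L)
      stop("results are missing control row '", ctrl$name, "'")
    lo <- row$ci_low[1]; hi <- row$ci_high[1]
    verdict <- if (is.na(lo) || is.na(hi)) NA_character_ else {
      ok <- switch(ctrl$expected_direction,
                   increase = lo > 1,
                   decrease = hi < 1,
                   null = lo <= 1 && hi >= 1)
      if (ok) "pass" else "fail"
    }
    data.frame(control = ctrl$name,
               expected_direction = ctrl$expected_direction,
               prr = row$prr[1], ci_low = lo, ci_high = hi,
               verdict = verdict)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a plan-results table to disk
#'
#' @param results output of [run_plan()].
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("json output requires the jsonlite package")
    writeLines(jsonlite::toJSON(results, dataframe = "rows", digits = NA,
                                pretty = TRUE, na = "null"), path)
  }
  invisible(path)
}
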