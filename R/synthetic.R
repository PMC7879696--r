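# Seeded generator of FAERS-like report stores with known ground truth.
#
# The generator emulates the statistical structure the disproportionality
# analysis relies on: two exposure arms (SGLT2i vs other ATC-A10
# glucose-lowering drugs) plus an optional ibrutinib arm for the positive
# AF control, per-report focal-event draws at a configurable reporting-rate
# ratio, competing adverse events that can mask the focal event,
# co-medications, per-drug indications, demographics, and injected
# case-version duplicates. Defaults mirror the SGLT2i/AF study conditions:
# arm sizes 62,098 and 642,031, comparator AF rate 8.7/1000, true reporting
# ratio 0.55, insulin on 31% of comparator reports.

.INSULIN_PRODUCTS <- c("insulin glargine", "insulin aspart", "insulin lispro",
                       "insulin detemir", "insulin human")
.FILLER_REACTIONS <- c("headache", "nausea", "dizziness", "fatigue", "rash",
                       "arthralgia", "insomnia")
.QUARTERS <- as.vector(outer(2014:2019, 1:4, function(y, q) paste0(y, "q", q)))

#' Configuration for the synthetic report-store generator
#'
#' All probabilities are per report. `true_ratio` is the ratio of
#' focal-event reporting *rates* (not odds) between the exposed and
#' comparator arms — the quantity the PRR estimates. Competing adverse
#' events mask the focal event: a report carrying a competing AE drops its
#' focal reaction with probability `masking_suppression`, which is the
#' mechanism by which competing events dilute the exposed arm's apparent
#' event rate.
#'
#' @param n_exposed,n_comparator reports per arm.
#' @param true_ratio target focal-event reporting-rate ratio
#'   (exposed / comparator).
#' @param p_event_comparator focal-event probability in the comparator arm.
#' @param p_insulin_comparator probability that a comparator report's index
#'   drug is an insulin.
#' @param p_antiarrhythmic probability of an anti-arrhythmic co-medication
#'   (concomitant) on any report.
#' @param p_cvd_indication,p_renal_indication,p_diabetes_indication
#'   probabilities of the respective indication on the index drug.
#' @param competing_ae_probs data.frame with columns `term`, `p_exposed`,
#'   `p_comparator`: per-report probability of each competing reaction.
#' @param masking_suppression probability that a competing-AE report's focal
#'   reaction is suppressed (not recorded).
#' @param control_event_probs data.frame with columns `term`,
#'   `p_comparator`, `ratio`: independent control reactions drawn at
#'   `p_comparator` in the comparator and `ratio * p_comparator` in the
#'   exposed arm.
#' @param role_probs_exposed,role_probs_comparator named numeric vectors
#'   (primary_suspect / suspect / concomitant) giving the index-drug role
#'   distribution per arm.
#' @param n_ibrutinib reports in the ibrutinib arm (positive AF control).
#' @param ibrutinib_af_ratio focal-event rate ratio for ibrutinib vs the
#'   comparator rate.
#' @param duplicate_rate probability that a case receives an extra (revised)
#'   case version.
#' @param age_probs,sex_probs,reporter_probs named categorical distributions
#'   for the demographics.
#' @param seed integer seed; fixed seed implies a fully reproducible store.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(
    n_exposed = 62098,
    n_comparator = 642031,
    true_ratio = 0.55,
    p_event_comparator = 0.0087,
    p_insulin_comparator = 0.31,
    p_antiarrhythmic = 0.03,
    p_cvd_indication = 0.15,
    p_renal_indication = 0.05,
    p_diabetes_indication = 0.60,
    competing_ae_probs = data.frame(
      term = c("urinary tract infection", "diabetic ketoacidosis",
               "toe amputation", "fournier's gangrene"),
      p_exposed = c(0.015, 0.010, 0.003, 0.0006),
      p_comparator = c(0.003, 0.002, 0.0008, 0.0001)),
    masking_suppression = 0.8,
    control_event_probs = data.frame(
      term = c("appendicitis", "cerebrovascular accident", "cardiac failure",
               "chronic kidney disease"),
      p_comparator = c(0.0012, 0.010, 0.020, 0.010),
      ratio = c(1.0, 1.0, 0.16, 0.32)),
    role_probs_exposed = c(primary_suspect = 0.56, suspect = 0.14,
                           concomitant = 0.30),
    role_probs_comparator = c(primary_suspect = 0.297, suspect = 0.15,
                              concomitant = 0.553),
    n_ibrutinib = 5000,
    ibrutinib_af_ratio = 10.6,
    duplicate_rate = 0.10,
    age_probs = c("<18" = 0.01, "18-64" = 0.38, ">=65" = 0.54,
                  "unknown" = 0.07),
    sex_probs = c(male = 0.50, female = 0.44, unknown = 0.06),
    reporter_probs = c(physician = 0.35, other_hcp = 0.20, pharmacist = 0.05,
                       consumer = 0.30, other = 0.05, unknown = 0.05),
    seed = 1L) {
  cfg <- list(
    n_exposed = n_exposed, n_comparator = n_comparator,
    true_ratio = true_ratio, p_event_comparator = p_event_comparator,
    p_insulin_comparator = p_insulin_comparator,
    p_antiarrhythmic = p_antiarrhythmic,
    p_cvd_indication = p_cvd_indication,
    p_renal_indication = p_renal_indication,
    p_diabetes_indication = p_diabetes_indication,
    competing_ae_probs = competing_ae_probs,
    masking_suppression = masking_suppression,
    control_event_probs = control_event_probs,
    role_probs_exposed = role_probs_exposed,
    role_probs_comparator = role_probs_comparator,
    n_ibrutinib = n_ibrutinib, ibrutinib_af_ratio = ibrutinib_af_ratio,
    duplicate_rate = duplicate_rate,
    age_probs = age_probs, sex_probs = sex_probs,
    reporter_probs = reporter_probs, seed = as.integer(seed))
  .validate_config(cfg)
  structure(cfg, class = "generator_config")
}

.validate_config <- function(cfg) {
  p01 <- c(cfg$p_event_comparator, cfg$p_insulin_comparator,
           cfg$p_antiarrhythmic, cfg$p_cvd_indication,
           cfg$p_renal_indication, cfg$p_diabetes_indication,
           cfg$masking_suppression, cfg$duplicate_rate,
           cfg$competing_ae_probs$p_exposed,
           cfg$competing_ae_probs$p_comparator,
           cfg$control_event_probs$p_comparator)
  if (anyNA(p01) || any(p01 < 0) || any(p01 > 1))
    stop("config error: probabilities must lie in [0, 1]")
  if (cfg$true_ratio <= 0) stop("config error: true_ratio must be positive")
  if (cfg$true_ratio * cfg$p_event_comparator > 1)
    stop("config error: true_ratio * p_event_comparator exceeds 1")
  if (cfg$n_exposed < 0 || cfg$n_comparator < 0 || cfg$n_ibrutinib < 0)
    stop("config error: negative arm size")
  for (p in list(cfg$role_probs_exposed, cfg$role_probs_comparator)) {
    if (abs(sum(p) - 1) > 1e-8 || !all(names(p) %in% .DRUG_ROLES))
      stop("config error: role probabilities must be named and sum to 1")
  }
  invisible(TRUE)
}

#' Scale competing-event probabilities in the exposed arm
#'
#' Returns a copy of `config` with every competing-AE probability in the
#' exposed arm multiplied by `masking_strength` (capped at 1); everything
#' else is unchanged. `masking_strength = 1` is the identity;
#' `masking_strength = 0` removes competing events from the exposed arm.
#' Used to study dilution of the focal-event rate by competing adverse
#' events.
#'
#' @param config a [generator_config()].
#' @param masking_strength non-negative multiplier.
#' @return a modified `generator_config`.
#' @export
masking_scenario <- function(config, masking_strength) {
  stopifnot(inherits(config, "generator_config"), masking_strength >= 0)
  config$competing_ae_probs$p_exposed <-
    pmin(1, config$competing_ae_probs$p_exposed * masking_strength)
  .validate_config(config)
  config
}

#' Generate a synthetic report store with ground truth
#'
#' Draws a full FAERS-like store under `config`: exposed reports carry one
#' SGLT2i-set drug, comparator reports one other ATC-A10 drug (an insulin
#' with probability `p_insulin_comparator`), the optional ibrutinib arm its
#' own drug. The focal event (atrial fibrillation / atrial flutter) is drawn
#' per report at the arm's rate; competing and control reactions,
#' anti-arrhythmic co-medication, indications and demographics are drawn
#' independently; every report receives a filler reaction from an innocuous
#' vocabulary asserted disjoint from all analytic reaction sets; duplicate
#' case versions are injected at `duplicate_rate`. Output is fully
#' determined by `config` (including its seed).
#'
#' @param config a [generator_config()].
#' @return list with elements `store` (a [report_store()]) and `truth` (a
#'   data.frame of per-case labels: group, realized focal event, competing
#'   events, insulin index drug, co-medication, indications, demographics,
#'   duplicate flag).
#' @export
generate <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  .validate_config(config)
  .assert_filler_disjoint()

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n_e <- config$n_exposed; n_c <- config$n_comparator
  n_i <- config$n_ibrutinib
  n <- n_e + n_c + n_i
  if (n == 0L) stop("config error: empty store requested")
  group <- rep(c("exposed", "comparator", "ibrutinib"), c(n_e, n_c, n_i))
  caseid <- sprintf("C%08d", seq_len(n))

  # index drug and role ----------------------------------------------------
  drugname <- character(n)
  is_e <- group == "exposed"; is_c <- group == "comparator"
  is_i <- group == "ibrutinib"
  drugname[is_e] <- sample(.sglt2i_terms, n_e, replace = TRUE)
  ins <- logical(n)
  if (n_c > 0L) {
    ins[is_c] <- stats::runif(n_c) < config$p_insulin_comparator
    drugname[is_c & ins] <- sample(.INSULIN_PRODUCTS, sum(is_c & ins),
                                   replace = TRUE)
    drugname[is_c & !ins] <- sample(.a10_noninsulin_terms, sum(is_c & !ins),
                                    replace = TRUE)
  }
  drugname[is_i] <- "ibrutinib"
  role <- character(n)
  if (n_e > 0L)
    role[is_e] <- sample(names(config$role_probs_exposed), n_e, replace = TRUE,
                         prob = config$role_probs_exposed)
  if (n_c > 0L)
    role[is_c] <- sample(names(config$role_probs_comparator), n_c,
                         replace = TRUE, prob = config$role_probs_comparator)
  role[is_i] <- "primary_suspect"

  # focal event ------------------------------------------------------------
  p_evt <- rep(config$p_event_comparator, n)
  p_evt[is_e] <- config$true_ratio * config$p_event_comparator
  p_evt[is_i] <- min(1, config$ibrutinib_af_ratio * config$p_event_comparator)
  focal <- stats::runif(n) < p_evt
  focal_term <- sample(c("atrial fibrillation", "atrial flutter"), n,
                       replace = TRUE)

  # competing adverse events, masking the focal event ----------------------
  comp <- config$competing_ae_probs
  comp_flags <- matrix(FALSE, n, nrow(comp))
  for (k in seq_len(nrow(comp))) {
    p <- rep(comp$p_comparator[k], n)
    p[is_e] <- comp$p_exposed[k]
    comp_flags[, k] <- stats::runif(n) < p
  }
  has_comp <- rowSums(comp_flags) > 0L
  suppressed <- has_comp & focal &
    (stats::runif(n) < config$masking_suppression)
  focal[suppressed] <- FALSE

  # independent control reactions ------------------------------------------
  ctrl <- config$control_event_probs
  ctrl_flags <- matrix(FALSE, n, nrow(ctrl))
  for (k in seq_len(nrow(ctrl))) {
    p <- rep(ctrl$p_comparator[k], n)
    p[is_e] <- min(1, ctrl$ratio[k] * ctrl$p_comparator[k])
    ctrl_flags[, k] <- stats::runif(n) < p
  }

  # co-medication and indications ------------------------------------------
  antiarr <- stats::runif(n) < config$p_antiarrhythmic
  ind_dm <- stats::runif(n) < config$p_diabetes_indication
  ind_dm[is_i] <- FALSE
  ind_cvd <- stats::runif(n) < config$p_cvd_indication
  ind_renal <- stats::runif(n) < config$p_renal_indication

  # demographics ------------------------------------------------------------
  age <- sample(names(config$age_probs), n, replace = TRUE,
                prob = config$age_probs)
  sex <- sample(names(config$sex_probs), n, replace = TRUE,
                prob = config$sex_probs)
  reporter <- sample(names(config$reporter_probs), n, replace = TRUE,
                     prob = config$reporter_probs)
  quarter <- sample(.QUARTERS, n, replace = TRUE)

  # duplicate case versions -------------------------------------------------
  dup <- stats::runif(n) < config$duplicate_rate

  demo1 <- data.table::data.table(
    caseid = caseid, caseversion = 1L, quarter = quarter, age_band = age,
    sex = sex, occp_cod = reporter)
  demo <- rbind(demo1, demo1[dup][, caseversion := 2L])
  demo[, primaryid := paste0(caseid, caseversion)]

  # child rows are defined per case, then replicated for each case version:
  # every row once with version 1, rows of duplicated cases again with 2
  dup_cases <- caseid[dup]
  per_version <- function(dt) {
    i2 <- which(dt$caseid %in% dup_cases)
    idx <- c(seq_len(nrow(dt)), i2)
    out <- dt[idx]
    out[, primaryid := paste0(caseid,
                              rep(c("1", "2"), c(nrow(dt), length(i2))))]
    out
  }

  drug_case <- data.table::data.table(
    caseid = caseid, drug_seq = 1L, drugname = drugname, role_cod = role)
  if (any(antiarr)) {
    drug_case <- rbind(drug_case, data.table::data.table(
      caseid = caseid[antiarr], drug_seq = 2L, drugname = "amiodarone",
      role_cod = "concomitant"))
  }

  filler <- sample(.FILLER_REACTIONS, n, replace = TRUE)
  reac_parts <- list(data.table::data.table(caseid = caseid, pt = filler))
  if (any(focal)) {
    reac_parts[[length(reac_parts) + 1L]] <-
      data.table::data.table(caseid = caseid[focal], pt = focal_term[focal])
  }
  for (k in seq_len(nrow(comp))) {
    hit <- comp_flags[, k]
    if (any(hit))
      reac_parts[[length(reac_parts) + 1L]] <-
        data.table::data.table(caseid = caseid[hit], pt = comp$term[k])
  }
  for (k in seq_len(nrow(ctrl))) {
    hit <- ctrl_flags[, k]
    if (any(hit))
      reac_parts[[length(reac_parts) + 1L]] <-
        data.table::data.table(caseid = caseid[hit], pt = ctrl$term[k])
  }
  reac_case <- data.table::rbindlist(reac_parts)

  indi_case <- data.table::data.table(
    caseid = character(0), drug_seq = integer(0), indi_pt = character(0))
  add_ind <- function(flag, term) {
    if (any(flag)) data.table::data.table(
      caseid = caseid[flag], drug_seq = 1L, indi_pt = term)
  }
  indi_case <- data.table::rbindlist(list(
    indi_case,
    add_ind(ind_dm, "type 2 diabetes mellitus"),
    add_ind(ind_cvd, "coronary artery disease"),
    add_ind(ind_renal, "chronic kidney disease"),
    add_ind(is_i, "mantle cell lymphoma")))

  # generated tables are well-formed by construction; use the fast path
  store <- .new_store(
    demo = demo[, .(primaryid, caseid, caseversion, quarter, age_band, sex,
                    occp_cod)],
    drug = per_version(drug_case)[, .(primaryid, drug_seq, drugname,
                                      role_cod)],
    reac = per_version(reac_case)[, .(primaryid, pt)],
    indi = per_version(indi_case)[, .(primaryid, drug_seq, indi_pt)],
    provenance = sprintf("synthetic(seed=%d)", config$seed))

  truth <- data.frame(
    caseid = caseid, group = group, has_focal_event = focal,
    has_competing_ae = has_comp, focal_suppressed = suppressed,
    index_insulin = ins, has_antiarrhythmic = antiarr,
    has_diabetes_indication = ind_dm, has_cvd_indication = ind_cvd,
    has_renal_indication = ind_renal, age_band = age, sex = sex,
    reporter = reporter, duplicated_case = dup,
    stringsAsFactors = FALSE)
  list(store = store, truth = truth)
}

# filler reactions must never collide with any analytic reaction set
.assert_filler_disjoint <- function() {
  v <- builtin_term_sets()
  for (s in v) {
    if (s$kind != "reaction") next
    if (any(matches(s, .FILLER_REACTIONS)))
      stop("filler reaction vocabulary overlaps analytic set '", s$name, "'")
  }
  invisible(TRUE)
}

#' Write a synthetic store and its ground truth to disk
#'
#' Emits the FAERS-dialect file bundle via [write_faers_ascii()] plus a
#' `TRUTH.tsv` with the generator's per-case labels.
#'
#' @param config a [generator_config()].
#' @param dir output directory.
#' @return invisibly, the output directory.
#' @export
write_synthetic_bundle <- function(config, dir) {
  g <- generate(config)
  write_faers_ascii(g$store, dir)
  utils::write.table(g$truth, file.path(dir, "TRUTH.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
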