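# Cohort construction: classify deduplicated reports into exposure and
# comparator groups by drug term-set membership, then apply an ordered
# cascade of exclusion / restriction filters with per-step attrition
# accounting.

#' Specify an exposure / comparator cohort
#'
#' @param exposure_set name of the drug term set defining exposure.
#' @param comparator_set name of the drug term set defining the comparator.
#' @param drug_roles drug roles that count towards group membership; default
#'   primary suspect, suspect and concomitant (the usual "suspect or
#'   concomitant" reading, with primary suspect a sub-type of suspect). Use
#'   `"primary_suspect"` alone for a primary-suspect-only sub-analysis.
#' @param filters ordered list of [filter_spec()] objects.
#' @param overlap_policy how to treat reports matching both sets:
#'   `"exclude_from_comparator"` (a report listing an exposure drug is
#'   exposure, never comparator; the default), `"exclude_from_both"`
#'   (overlapping reports are dropped from both groups), or `"allow"`.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(exposure_set, comparator_set,
                        drug_roles = c("primary_suspect", "suspect",
                                       "concomitant"),
                        filters = list(),
                        overlap_policy = c("exclude_from_comparator",
                                           "exclude_from_both", "allow")) {
  overlap_policy <- match.arg(overlap_policy)
  stopifnot(is.character(exposure_set), is.character(comparator_set))
  if (identical(exposure_set, comparator_set))
    stop("exposure_set and comparator_set must differ")
  if (!all(drug_roles %in% .DRUG_ROLES))
    stop("unknown drug role")
  ok <- vapply(filters, inherits, logical(1), what = "filter_spec")
  if (length(filters) && !all(ok)) stop("filters must be filter_spec objects")
  structure(
    list(exposure_set = exposure_set, comparator_set = comparator_set,
         drug_roles = drug_roles, filters = filters,
         overlap_policy = overlap_policy),
    class = "cohort_spec"
  )
}

#' Specify one exclusion / restriction filter
#'
#' A filter either removes every report where its predicate holds
#' (`action = "exclude_report"`) or keeps only reports where it holds
#' (`action = "require_report"`; used for the diabetes-indication
#' restriction). The predicate tests whether any drug / indication /
#' reaction of the report matches a named term set. `scope` limits the
#' filter to one group — the insulin exclusion, for instance, applies to the
#' comparator group only.
#'
#' @param name filter label used in attrition accounting.
#' @param action `"exclude_report"` or `"require_report"`.
#' @param predicate_kind `"drug_in_set"`, `"indication_in_set"` or
#'   `"reaction_in_set"`.
#' @param set_name term-set name; its kind must be compatible with
#'   `predicate_kind`.
#' @param scope `"both"` (default), `"exposed"` or `"comparator"`.
#' @param drug_roles for `drug_in_set` predicates, roles considered; default
#'   all roles.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(name,
                        action = c("exclude_report", "require_report"),
                        predicate_kind = c("drug_in_set", "indication_in_set",
                                           "reaction_in_set"),
                        set_name,
                        scope = c("both", "exposed", "comparator"),
                        drug_roles = .DRUG_ROLES) {
  action <- match.arg(action)
  predicate_kind <- match.arg(predicate_kind)
  scope <- match.arg(scope)
  stopifnot(is.character(name), nzchar(name), is.character(set_name))
  structure(
    list(name = name, action = action, predicate_kind = predicate_kind,
         set_name = set_name, scope = scope, drug_roles = drug_roles),
    class = "filter_spec"
  )
}

.get_set <- function(vocab, name, kind = NULL) {
  s <- vocab[[name]]
  if (is.null(s)) stop("unknown term set: '", name, "'")
  if (!is.null(kind) && s$kind != kind)
    stop("term set '", name, "' has kind '", s$kind,
         "' but a ", kind, " set is required")
  s
}

# reports whose drugs/indications/reactions satisfy a filter predicate
.predicate_ids <- function(store, f, vocab) {
  switch(f$predicate_kind,
    drug_in_set = {
      set <- .get_set(vocab, f$set_name, "drug")
      dt <- store$drug[role_cod %in% f$drug_roles]
      unique(dt$primaryid[matches(set, dt$drugname)])
    },
    indication_in_set = {
      set <- .get_set(vocab, f$set_name, "indication")
      unique(store$indi$primaryid[matches(set, store$indi$indi_pt)])
    },
    reaction_in_set = {
      set <- .get_set(vocab, f$set_name, "reaction")
      unique(store$reac$primaryid[matches(set, store$reac$pt)])
    }
  )
}

#' Assign reports to exposure and comparator groups
#'
#' A report is exposure-eligible iff any of its drugs with a role in
#' `spec$drug_roles` matches the exposure set; comparator-eligible likewise
#' for the comparator set. Overlapping reports are resolved per
#' `spec$overlap_policy`. Only valid analysis reports — at least one drug row
#' and one reaction row — are classified. The store should be deduplicated
#' first (see [dedup_latest()]).
#'
#' @param store a deduplicated [report_store()].
#' @param spec a [cohort_spec()].
#' @param vocab a [vocabulary()]; defaults to [builtin_term_sets()].
#' @return an object of class `cohort_result`: list with `exposed_ids`,
#'   `comparator_ids` (primaryid character vectors) and an `attrition`
#'   data.frame.
#' @export
assign_exposure <- function(store, spec, vocab = builtin_term_sets()) {
  stopifnot(inherits(store, "report_store"), inherits(spec, "cohort_spec"))
  exp_set <- .get_set(vocab, spec$exposure_set, "drug")
  cmp_set <- .get_set(vocab, spec$comparator_set, "drug")

  valid <- intersect(unique(store$drug$primaryid),
                     unique(store$reac$primaryid))
  dt <- store$drug[role_cod %in% spec$drug_roles]
  exp_ids <- intersect(unique(dt$primaryid[matches(exp_set, dt$drugname)]),
                       valid)
  cmp_ids <- intersect(unique(dt$primaryid[matches(cmp_set, dt$drugname)]),
                       valid)
  both <- intersect(exp_ids, cmp_ids)
  if (spec$overlap_policy == "exclude_from_comparator") {
    cmp_ids <- setdiff(cmp_ids, both)
  } else if (spec$overlap_policy == "exclude_from_both") {
    exp_ids <- setdiff(exp_ids, both)
    cmp_ids <- setdiff(cmp_ids, both)
  }
  structure(
    list(exposed_ids = exp_ids, comparator_ids = cmp_ids,
         attrition = data.frame(step = integer(0), filter = character(0),
                                exposed_n = integer(0),
                                comparator_n = integer(0),
                                exposed_removed = integer(0),
                                comparator_removed = integer(0))),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> exposed %d, comparator %d reports\n",
              length(x$exposed_ids), length(x$comparator_ids)))
  if (nrow(x$attrition)) {
    cat("attrition:\n")
    print(x$attrition, row.names = FALSE)
  }
  invisible(x)
}

#' Apply an ordered filter cascade to a cohort
#'
#' Filters are applied in list order. `exclude_report` removes every report
#' (within the filter's scope) where the predicate holds for any drug,
#' indication or reaction; `require_report` keeps only reports where it
#' holds. Each step appends a row to the attrition table recording how many
#' reports each group lost.
#'
#' @param store the [report_store()] the cohort was built from.
#' @param cohort a [cohort_result()] from [assign_exposure()].
#' @param filters list of [filter_spec()] objects.
#' @param vocab a [vocabulary()].
#' @return an updated `cohort_result`.
#' @export
apply_filters <- function(store, cohort, filters,
                          vocab = builtin_term_sets()) {
  stopifnot(inherits(cohort, "cohort_result"))
  exp_ids <- cohort$exposed_ids
  cmp_ids <- cohort$comparator_ids
  att <- cohort$attrition
  step0 <- if (nrow(att)) max(att$step) else 0L
  for (i in seq_along(filters)) {
    f <- filters[[i]]
    hit <- .predicate_ids(store, f, vocab)
    ne0 <- length(exp_ids); nc0 <- length(cmp_ids)
    if (f$action == "exclude_report") {
      if (f$scope %in% c("both", "exposed"))
        exp_ids <- setdiff(exp_ids, hit)
      if (f$scope %in% c("both", "comparator"))
        cmp_ids <- setdiff(cmp_ids, hit)
    } else { # require_report
      if (f$scope %in% c("both", "exposed"))
        exp_ids <- intersect(exp_ids, hit)
      if (f$scope %in% c("both", "comparator"))
        cmp_ids <- intersect(cmp_ids, hit)
    }
    att <- rbind(att, data.frame(
      step = step0 + i, filter = f$name,
      exposed_n = length(exp_ids), comparator_n = length(cmp_ids),
      exposed_removed = ne0 - length(exp_ids),
      comparator_removed = nc0 - length(cmp_ids)))
  }
  structure(list(exposed_ids = exp_ids, comparator_ids = cmp_ids,
                 attrition = att),
            class = "cohort_result")
}

#' Count focal events and build the 2x2 table
#'
#' @param store the [report_store()].
#' @param cohort a final [cohort_result()].
#' @param event_set a reaction [term_set()] (or its name in `vocab`).
#' @param vocab a [vocabulary()], used when `event_set` is a name.
#' @return a [contingency_table()] with `a + b = |exposed|` and
#'   `c + d = |comparator|`.
#' @export
count_events <- function(store, cohort, event_set,
                         vocab = builtin_term_sets()) {
  stopifnot(inherits(store, "report_store"), inherits(cohort, "cohort_result"))
  if (is.character(event_set)) event_set <- .get_set(vocab, event_set, "reaction")
  stopifnot(inherits(event_set, "term_set"))
  if (length(cohort$exposed_ids) == 0L || length(cohort$comparator_ids) == 0L)
    stop("unanalyzable cohort: empty exposed or comparator group")
  ev_ids <- unique(store$reac$primaryid[matches(event_set, store$reac$pt)])
  a <- sum(cohort$exposed_ids %in% ev_ids)
  cc <- sum(cohort$comparator_ids %in% ev_ids)
  contingency_table(a, length(cohort$exposed_ids) - a,
                    cc, length(cohort$comparator_ids) - cc)
}

#' Build a cohort end to end
#'
#' Convenience wrapper: [assign_exposure()] then [apply_filters()] with the
#' spec's own filter list.
#'
#' @inheritParams assign_exposure
#' @return a [cohort_result()].
#' @export
build_cohort <- function(store, spec, vocab = builtin_term_sets()) {
  cohort <- assign_exposure(store, spec, vocab)
  if (length(spec$filters))
    cohort <- apply_filters(store, cohort, spec$filters, vocab)
  cohort
}

#' Read / write a cohort specification as YAML
#'
#' The same structured-text format as the term-set config: a mapping with
#' `exposure_set`, `comparator_set`, optional `drug_roles` and
#' `overlap_policy`, and an ordered `filters` list of mappings with `name`,
#' `action`, `predicate_kind`, `set_name` and optional `scope` /
#' `drug_roles`.
#'
#' @param path file path.
#' @return `read_cohort_spec()` returns a [cohort_spec()];
#'   `write_cohort_spec()` returns `path` invisibly.
#' @export
read_cohort_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  filters <- lapply(doc$filters, function(f) {
    filter_spec(f$name, action = f$action,
                predicate_kind = f$predicate_kind, set_name = f$set_name,
                scope = if (is.null(f$scope)) "both" else f$scope,
                drug_roles = if (is.null(f$drug_roles)) .DRUG_ROLES
                             else unlist(f$drug_roles))
  })
  cohort_spec(
    doc$exposure_set, doc$comparator_set,
    drug_roles = if (is.null(doc$drug_roles))
      c("primary_suspect", "suspect", "concomitant")
    else unlist(doc$drug_roles),
    filters = filters,
    overlap_policy = if (is.null(doc$overlap_policy))
      "exclude_from_comparator" else doc$overlap_policy)
}

#' @rdname read_cohort_spec
#' @param spec a [cohort_spec()] to serialize.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  doc <- list(
    exposure_set = spec$exposure_set, comparator_set = spec$comparator_set,
    drug_roles = as.list(spec$drug_roles),
    overlap_policy = spec$overlap_policy,
    filters = lapply(spec$filters, function(f)
      list(name = f$name, action = f$action,
           predicate_kind = f$predicate_kind, set_name = f$set_name,
           scope = f$scope, drug_roles = as.list(f$drug_roles))))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Write an attrition table as TSV
#'
#' @param cohort a [cohort_result()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_attrition <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_result"))
  utils::write.table(cohort$attrition, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
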