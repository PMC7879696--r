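# Independent oracles used to validate the pipeline. Everything here is
# deliberately naive (per-report loops, base R set algebra, a different
# arithmetic formulation for the PRR) and shares no code with the package
# internals it checks.

# naive normalization, re-stated independently of normalize_term()
oracle_norm <- function(x) {
  x <- tolower(x)
  x <- gsub("[®™©]", "", x)
  trimws(gsub("[ \t\r\n]+", " ", x))
}

oracle_term_hit <- function(terms, value, mode) {
  v <- oracle_norm(value)
  if (mode == "exact") v %in% terms
  else any(vapply(terms, function(t) grepl(t, v, fixed = TRUE), logical(1)))
}

# per-report view of a store: list of reports, each a list of fields
oracle_reports <- function(store) {
  demo <- as.data.frame(store$demo)
  drug <- as.data.frame(store$drug)
  reac <- as.data.frame(store$reac)
  indi <- as.data.frame(store$indi)
  dsp <- split(seq_len(nrow(drug)), drug$primaryid)
  rsp <- split(reac$pt, reac$primaryid)
  isp <- split(indi$indi_pt, indi$primaryid)
  lapply(seq_len(nrow(demo)), function(i) {
    pid <- demo$primaryid[i]
    di <- dsp[[pid]]
    list(primaryid = pid, caseid = demo$caseid[i],
         caseversion = demo$caseversion[i], quarter = demo$quarter[i],
         drugs = if (is.null(di)) character(0) else drug$drugname[di],
         roles = if (is.null(di)) character(0) else drug$role_cod[di],
         reactions = if (is.null(rsp[[pid]])) character(0) else rsp[[pid]],
         indications = if (is.null(isp[[pid]])) character(0) else isp[[pid]])
  })
}

# brute-force latest-version grouping: per caseid keep max version (ties by
# later quarter, then first encountered)
oracle_dedup_ids <- function(store) {
  reports <- oracle_reports(store)
  by_case <- split(reports, vapply(reports, `[[`, character(1), "caseid"))
  vapply(by_case, function(rs) {
    vmax <- max(vapply(rs, `[[`, integer(1), "caseversion"))
    rs <- rs[vapply(rs, `[[`, integer(1), "caseversion") == vmax]
    qmax <- max(vapply(rs, `[[`, character(1), "quarter"))
    rs <- rs[vapply(rs, `[[`, character(1), "quarter") == qmax]
    rs[[1]]$primaryid
  }, character(1))
}

# one-pass enumeration of the whole pipeline: dedup, group assignment,
# ordered filters, 2x2 counts. `spec` is a plain list:
#   exposure_terms / comparator_terms (normalized, substring-matched),
#   roles, overlap ("exclude_from_comparator" | "exclude_from_both" |
#   "allow"), event_terms (exact-matched), filters = list of
#   list(action, kind, terms, mode, scope, roles)
oracle_pipeline <- function(store, spec) {
  keep_ids <- oracle_dedup_ids(store)
  reports <- oracle_reports(store)
  reports <- reports[vapply(reports, `[[`, character(1), "primaryid") %in%
                       keep_ids]
  valid <- vapply(reports, function(r)
    length(r$drugs) > 0 && length(r$reactions) > 0, logical(1))
  reports <- reports[valid]

  in_drug_set <- function(r, terms, roles) {
    sel <- r$roles %in% roles
    any(vapply(r$drugs[sel], function(d)
      oracle_term_hit(terms, d, "substring"), logical(1)))
  }
  exp_flag <- vapply(reports, in_drug_set, logical(1),
                     terms = spec$exposure_terms, roles = spec$roles)
  cmp_flag <- vapply(reports, in_drug_set, logical(1),
                     terms = spec$comparator_terms, roles = spec$roles)
  if (spec$overlap == "exclude_from_comparator") {
    cmp_flag <- cmp_flag & !exp_flag
  } else if (spec$overlap == "exclude_from_both") {
    both <- exp_flag & cmp_flag
    exp_flag <- exp_flag & !both
    cmp_flag <- cmp_flag & !both
  }

  pred <- function(r, f) {
    switch(f$kind,
      drug = in_drug_set(r, f$terms, f$roles),
      indication = any(vapply(r$indications, function(x)
        oracle_term_hit(f$terms, x, f$mode), logical(1))),
      reaction = any(vapply(r$reactions, function(x)
        oracle_term_hit(f$terms, x, f$mode), logical(1)))
    )
  }
  for (f in spec$filters) {
    hit <- vapply(reports, pred, logical(1), f = f)
    rm_exp <- if (f$scope %in% c("both", "exposed")) {
      if (f$action == "exclude_report") hit else !hit
    } else rep(FALSE, length(hit))
    rm_cmp <- if (f$scope %in% c("both", "comparator")) {
      if (f$action == "exclude_report") hit else !hit
    } else rep(FALSE, length(hit))
    exp_flag <- exp_flag & !rm_exp
    cmp_flag <- cmp_flag & !rm_cmp
  }

  has_event <- vapply(reports, function(r)
    any(vapply(r$reactions, function(x)
      oracle_term_hit(spec$event_terms, x, "exact"), logical(1))),
    logical(1))
  c(a = sum(exp_flag & has_event), b = sum(exp_flag & !has_event),
    c = sum(cmp_flag & has_event), d = sum(cmp_flag & !has_event))
}

# independent re-evaluation of the PRR statistics using a different
# arithmetic route: log-space point estimate, smallest-first summation for
# the variance
oracle_prr <- function(a, b, c, d, z = 1.959964) {
  lp <- (log(a) - log(a + b)) - (log(c) - log(c + d))
  terms <- sort(c(1 / a, -1 / (a + b), 1 / c, -1 / (c + d)))
  se <- sqrt(sum(terms))
  list(prr = exp(lp), ci_low = exp(lp - z * se), ci_high = exp(lp + z * se))
}

# chi-square by explicit expected-count enumeration
oracle_chi2 <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  n <- sum(obs)
  ex <- outer(rowSums(obs), colSums(obs)) / n
  sum((obs - ex)^2 / ex)
}

n_sig_digits_agree <- function(x, y) {
  if (x == y) return(Inf)
  -log10(abs(x - y) / abs(x))
}
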