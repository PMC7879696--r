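# Term sets and normalization for drug names, reaction preferred terms and
# indication terms. FAERS verbatim strings are messy (case, whitespace,
# trademark glyphs); every string entering a comparison goes through
# normalize_term() exactly once.

#' Normalize a drug, reaction or indication term
#'
#' Lowercases, strips trademark punctuation (\code{®}, \code{™},
#' \code{©}), collapses internal whitespace runs to a single space and
#' trims. Deterministic and idempotent; empty input maps to empty output.
#'
#' @param x character vector of raw terms.
#' @return character vector of normalized terms, same length as `x`.
#' @examples
#' normalize_term("  Atrial   Fibrillation ")
#' normalize_term("CANAGLIFLOZIN®")
#' @export
normalize_term <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- tolower(as.character(x))
  x <- gsub("[®™©]", "", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Create a named term set
#'
#' A term set is a named, normalized collection of drug, reaction or
#' indication terms plus a matching mode. Drug sets default to substring
#' matching because FAERS drugname fields carry salts, brands and combination
#' product strings; reaction and indication preferred terms are matched
#' exactly unless configured otherwise.
#'
#' @param name set name (unique within a vocabulary).
#' @param kind one of `"drug"`, `"reaction"`, `"indication"`.
#' @param terms character vector of terms; normalized on construction.
#' @param match_mode `"exact"` or `"substring"`.
#' @return an object of class `term_set`.
#' @export
term_set <- function(name, kind = c("drug", "reaction", "indication"),
                     terms, match_mode = c("exact", "substring")) {
  kind <- match.arg(kind)
  match_mode <- match.arg(match_mode)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  terms <- unique(normalize_term(terms))
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L) stop("term_set '", name, "': terms must be nonempty")
  structure(
    list(name = name, kind = kind, terms = sort(terms), match_mode = match_mode),
    class = "term_set"
  )
}

#' @export
print.term_set <- function(x, ...) {
  cat(sprintf("<term_set '%s'> kind=%s mode=%s, %d terms\n",
              x$name, x$kind, x$match_mode, length(x$terms)))
  invisible(x)
}

#' Test terms for membership in a term set
#'
#' In exact mode a term matches iff its normalized form is in the set. In
#' substring mode it matches iff any set member occurs as a substring of the
#' normalized term (so `"dapagliflozin propanediol"` matches a set containing
#' `"dapagliflozin"`). Matching is invariant under [normalize_term()] of the
#' query.
#'
#' @param set a [term_set()].
#' @param terms character vector of query terms (raw or normalized).
#' @return logical vector, same length as `terms`.
#' @export
matches <- function(set, terms) {
  stopifnot(inherits(set, "term_set"))
  if (length(terms) == 0L) return(logical(0))
  # dispatch on unique raw values: verbatim drug fields repeat heavily
  q_raw <- as.character(terms)
  u_raw <- unique(q_raw)
  u <- normalize_term(u_raw)
  if (set$match_mode == "exact") {
    hit_u <- u %in% set$terms
  } else {
    hit_u <- rep(FALSE, length(u))
    for (m in set$terms) {
      hit_u <- hit_u | grepl(m, u, fixed = TRUE)
    }
  }
  hit_u[match(q_raw, u_raw)]
}

#' Assemble a vocabulary from term sets
#'
#' @param ... [term_set()] objects.
#' @return an object of class `vocabulary`: a named list of term sets.
#' @export
vocabulary <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "term_set")) {
    sets <- sets[[1]]
  }
  ok <- vapply(sets, inherits, logical(1), what = "term_set")
  if (!all(ok)) stop("vocabulary() accepts only term_set objects")
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(names(sets))) stop("term set names must be unique")
  structure(sets, class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d term sets\n", length(x)))
  for (s in x) {
    cat(sprintf("  %-22s %-10s %-9s %3d terms\n",
                s$name, s$kind, s$match_mode, length(s$terms)))
  }
  invisible(x)
}

# Main-text drug group: the ten SGLT2 inhibitor products (single agents and
# fixed-dose combinations) searched as an OR-list.
.sglt2i_terms <- c(
  "canagliflozin", "empagliflozin", "dapagliflozin",
  "metformin and canagliflozin", "linagliptin and empagliflozin",
  "metformin and empagliflozin", "ertugliflozin", "ipragliflozin",
  "metformin and dapagliflozin", "sotagliflozin"
)

# Placeholder lists. Only the SGLT2i group and the AF reaction pair are
# verbatim from the study's main definitions; the comparator, co-medication
# and indication lists below are plausible stand-ins for an externally
# curated appendix and are meant to be overridden via read_term_sets() for
# real-data use.
.a10_noninsulin_terms <- c(
  "metformin", "glimepiride", "glipizide", "glyburide", "glibenclamide",
  "gliclazide", "sitagliptin", "saxagliptin", "linagliptin", "alogliptin",
  "vildagliptin", "liraglutide", "exenatide", "dulaglutide", "semaglutide",
  "lixisenatide", "pioglitazone", "rosiglitazone", "acarbose", "miglitol",
  "nateglinide", "repaglinide"
)

.antiarrhythmic_terms <- c(
  "amiodarone", "dronedarone", "flecainide", "propafenone", "sotalol",
  "dofetilide", "ibutilide", "quinidine", "disopyramide", "mexiletine"
)

.competing_ae_terms <- c(
  # genitourinary tract infections
  "urinary tract infection", "genitourinary tract infection",
  "genital infection fungal", "vulvovaginal mycotic infection",
  "balanoposthitis", "urosepsis",
  # ketoacidosis
  "diabetic ketoacidosis", "ketoacidosis",
  # Fournier's gangrene
  "fournier's gangrene", "necrotising fasciitis",
  # amputations
  "amputation", "toe amputation", "foot amputation", "leg amputation"
)

#' Built-in term sets for the SGLT2i / atrial-fibrillation analysis
#'
#' Returns the vocabulary used throughout the built-in analysis battery. The
#' SGLT2 inhibitor drug group (10 products, including fixed-dose
#' combinations) and the atrial-fibrillation reaction pair
#' (`atrial fibrillation`, `atrial flutter`) are the study's main-text
#' definitions. The remaining sets — ATC-A10 comparator drugs, insulin,
#' anti-arrhythmics, renal / cardiovascular / diabetes indications, competing
#' adverse events (genitourinary infections, diabetic ketoacidosis,
#' Fournier's gangrene, amputations), and the control drug/event sets
#' (ibrutinib, appendicitis, stroke, heart failure, chronic kidney disease) —
#' are documented placeholders standing in for an externally curated term
#' appendix; override any of them via [read_term_sets()] for production use.
#'
#' Required disjointness (SGLT2i vs insulin; AF vs competing events) is
#' asserted on construction.
#'
#' @return a [vocabulary()] object.
#' @export
builtin_term_sets <- function() {
  v <- vocabulary(
    term_set("sglt2i", "drug", .sglt2i_terms, "substring"),
    # comparator: any other ATC-A10 glucose-lowering drug, insulin included
    term_set("atc_a10_other", "drug",
             c(.a10_noninsulin_terms, "insulin"), "substring"),
    term_set("insulin", "drug", "insulin", "substring"),
    term_set("antiarrhythmics", "drug", .antiarrhythmic_terms, "substring"),
    term_set("ibrutinib", "drug", "ibrutinib", "substring"),
    term_set("af", "reaction", c("atrial fibrillation", "atrial flutter"),
             "exact"),
    term_set("competing_ae", "reaction", .competing_ae_terms, "exact"),
    term_set("appendicitis", "reaction", "appendicitis", "exact"),
    term_set("stroke", "reaction",
             c("cerebrovascular accident", "ischaemic stroke",
               "haemorrhagic stroke", "stroke"), "exact"),
    term_set("heart_failure", "reaction",
             c("cardiac failure", "cardiac failure congestive",
               "cardiac failure acute", "heart failure"), "exact"),
    term_set("chronic_kidney_disease", "reaction",
             c("chronic kidney disease", "renal failure chronic"), "exact"),
    term_set("diabetes_indication", "indication", "diabetes", "substring"),
    term_set("renal_indication", "indication",
             c("renal failure", "renal impairment", "chronic kidney disease",
               "acute kidney injury", "nephropathy"), "substring"),
    term_set("cvd_indication", "indication",
             c("coronary artery disease", "myocardial infarction",
               "cardiac failure", "angina pectoris", "atherosclerosis"),
             "substring")
  )
  .assert_disjoint(v$sglt2i, v$insulin)
  .assert_disjoint(v$af, v$competing_ae)
  v
}

# no term of one set equal to, or (for substring sets) contained in, a term
# of the other
.assert_disjoint <- function(s1, s2) {
  if (length(intersect(s1$terms, s2$terms)) > 0L ||
      any(matches(s1, s2$terms)) || any(matches(s2, s1$terms))) {
    stop("term sets '", s1$name, "' and '", s2$name,
         "' are required to be disjoint")
  }
  invisible(TRUE)
}

#' Read / write term-set configuration
#'
#' Term sets are exchanged as a YAML document: a mapping of set name to
#' `{kind, match_mode, terms}`. Sets read from file are normalized on load.
#'
#' @param path file path.
#' @return `read_term_sets()` returns a [vocabulary()]; `write_term_sets()`
#'   returns `path` invisibly.
#' @export
read_term_sets <- function(path) {
  doc <- yaml::read_yaml(path)
  sets <- lapply(names(doc), function(nm) {
    d <- doc[[nm]]
    term_set(nm, kind = d$kind, terms = unlist(d$terms),
             match_mode = if (is.null(d$match_mode)) "exact" else d$match_mode)
  })
  vocabulary(sets)
}

#' @rdname read_term_sets
#' @param vocab a [vocabulary()] to serialize.
#' @export
write_term_sets <- function(vocab, path) {
  stopifnot(inherits(vocab, "vocabulary"))
  doc <- lapply(unclass(vocab), function(s) {
    list(kind = s$kind, match_mode = s$match_mode, terms = as.list(s$terms))
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}
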