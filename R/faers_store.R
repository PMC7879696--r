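# Report store: the in-memory model of a set of spontaneous adverse-event
# reports, mirroring the public FAERS quarterly layout — one DEMO row per
# report revision plus orthogonal DRUG / REAC / INDI tables joined on
# primaryid. A primaryid identifies one revision of one case; caseid plus
# caseversion recover the case identity.

.DRUG_ROLES <- c("primary_suspect", "suspect", "concomitant", "interacting")
.AGE_BANDS  <- c("<18", "18-64", ">=65", "unknown")
.SEXES      <- c("male", "female", "unknown")
.REPORTERS  <- c("physician", "other_hcp", "pharmacist", "consumer",
                 "other", "unknown")

# FAERS-style short codes accepted on read
.ROLE_CODES     <- c(PS = "primary_suspect", SS = "suspect", C = "concomitant",
                     I = "interacting")
.SEX_CODES      <- c(M = "male", F = "female", UNK = "unknown")
.REPORTER_CODES <- c(MD = "physician", HP = "other_hcp", PH = "pharmacist",
                     CN = "consumer", OT = "other", LW = "other",
                     RN = "other_hcp", UNK = "unknown")

#' Construct a report store
#'
#' A report store bundles the four FAERS-style tables plus provenance. Each
#' report (one DEMO row) aggregates all DRUG, REAC and INDI rows that share
#' its `primaryid`.
#'
#' @param demo data.frame with columns `primaryid`, `caseid`, `caseversion`
#'   (non-negative integer), `quarter` (e.g. `"2014q1"`), `age_band`, `sex`,
#'   `occp_cod` (reporter type).
#' @param drug data.frame with columns `primaryid`, `drug_seq`, `drugname`,
#'   `role_cod` (one of primary_suspect / suspect / concomitant /
#'   interacting).
#' @param reac data.frame with columns `primaryid`, `pt`.
#' @param indi data.frame with columns `primaryid`, `drug_seq`, `indi_pt`.
#' @param provenance character vector of source labels.
#' @return an object of class `report_store`.
#' @export
report_store <- function(demo, drug, reac, indi, provenance = character(0)) {
  demo <- data.table::as.data.table(demo)
  drug <- data.table::as.data.table(drug)
  reac <- data.table::as.data.table(reac)
  indi <- data.table::as.data.table(indi)
  .check_cols(demo, c("primaryid", "caseid", "caseversion", "quarter",
                      "age_band", "sex", "occp_cod"), "demo")
  .check_cols(drug, c("primaryid", "drug_seq", "drugname", "role_cod"), "drug")
  .check_cols(reac, c("primaryid", "pt"), "reac")
  .check_cols(indi, c("primaryid", "drug_seq", "indi_pt"), "indi")
  demo[, `:=`(primaryid = as.character(primaryid),
              caseid = as.character(caseid),
              caseversion = as.integer(caseversion),
              quarter = as.character(quarter))]
  drug[, `:=`(primaryid = as.character(primaryid),
              drug_seq = as.integer(drug_seq))]
  reac[, primaryid := as.character(primaryid)]
  indi[, `:=`(primaryid = as.character(primaryid),
              drug_seq = as.integer(drug_seq))]
  if (nrow(demo)) {
    if (anyNA(demo$caseversion) || any(demo$caseversion < 0L))
      stop("caseversion must be a non-negative integer")
    if (any(!nzchar(demo$caseid))) stop("caseid must be nonempty")
    if (anyDuplicated(demo$primaryid))
      stop("duplicate primaryid in demo table")
    bad_q <- !grepl("^[0-9]{4}q[1-4]$", demo$quarter)
    if (any(bad_q)) stop("malformed quarter label, e.g. expected '2014q1'")
    demo[!(age_band %in% .AGE_BANDS), age_band := "unknown"]
    demo[!(sex %in% .SEXES), sex := "unknown"]
    demo[!(occp_cod %in% .REPORTERS), occp_cod := "unknown"]
  }
  if (nrow(drug)) {
    if (any(!nzchar(drug$drugname))) stop("drugname must be nonempty")
    if (!all(drug$role_cod %in% .DRUG_ROLES))
      stop("role_cod must be one of: ", paste(.DRUG_ROLES, collapse = ", "))
  }
  .new_store(demo, drug, reac, indi, provenance)
}

# internal fast path: trusted, already well-formed data.tables
.new_store <- function(demo, drug, reac, indi, provenance = character(0)) {
  structure(
    list(demo = demo, drug = drug, reac = reac, indi = indi,
         provenance = provenance),
    class = "report_store"
  )
}

.check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " table is missing columns: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.report_store <- function(x, ...) {
  cat(sprintf(
    "<report_store> %d reports (%d cases), %d drug rows, %d reaction rows, %d indication rows\n",
    nrow(x$demo), data.table::uniqueN(x$demo$caseid), nrow(x$drug),
    nrow(x$reac), nrow(x$indi)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = ", "), "\n")
  invisible(x)
}

#' Number of reports in a store
#' @param store a [report_store()].
#' @return integer count of DEMO rows.
#' @export
n_reports <- function(store) {
  stopifnot(inherits(store, "report_store"))
  nrow(store$demo)
}

#' Read a FAERS-style ASCII file bundle
#'
#' Reads the `$`-delimited, single-header-line dialect of the public FAERS
#' quarterly archives. `paths` is a named vector/list tagging each file as
#' one of `demo`, `drug`, `reac`, `indi`; alternatively a single directory
#' containing files named `DEMO*`, `DRUG*`, `REAC*`, `INDI*`
#' (case-insensitive). A missing DEMO file is a hard error (there is nothing
#' to join onto); DRUG/REAC/INDI rows whose key is absent from DEMO are
#' skipped with a warning; rows with a missing key are counted and dropped
#' with a message. Term strings (drugname, reaction pt, indication pt) are
#' passed through [normalize_term()]; FAERS short codes for role
#' (PS/SS/C/I), sex (M/F) and reporter occupation (MD/HP/PH/CN/OT/LW/RN) are
#' mapped to their long labels; blank or unrecognized age band, sex and
#' reporter values map to `"unknown"`.
#'
#' @param paths named character vector (`demo`, `drug`, `reac`, `indi`) or a
#'   directory path.
#' @return a [report_store()].
#' @export
read_faers_ascii <- function(paths) {
  if (length(paths) == 1L && is.null(names(paths)) && dir.exists(paths[[1]])) {
    files <- list.files(paths[[1]], full.names = TRUE)
    pick <- function(tag) {
      hit <- files[grepl(paste0("^", tag), basename(files), ignore.case = TRUE)]
      if (length(hit)) hit[[1]] else NA_character_
    }
    paths <- c(demo = pick("demo"), drug = pick("drug"),
               reac = pick("reac"), indi = pick("indi"))
    paths <- paths[!is.na(paths)]
  }
  paths <- unlist(paths)
  names(paths) <- tolower(names(paths))
  if (!("demo" %in% names(paths)))
    stop("no DEMO file: nothing to join drug/reaction rows onto")

  rd <- function(p) {
    dt <- data.table::fread(p, sep = "$", quote = "", colClasses = "character",
                            header = TRUE, fill = TRUE, na.strings = NULL)
    names(dt) <- tolower(names(dt))
    dt
  }
  drop_keyless <- function(dt, what) {
    if (!nrow(dt)) return(dt)
    bad <- is.na(dt$primaryid) | !nzchar(dt$primaryid)
    if (any(bad)) {
      message(sum(bad), " ", what, " row(s) without a primaryid were skipped")
      dt <- dt[!bad]
    }
    dt
  }

  demo <- rd(paths[["demo"]])
  .check_cols(demo, c("primaryid", "caseid", "caseversion", "quarter",
                      "age_band", "sex", "occp_cod"), "DEMO")
  extra <- setdiff(names(demo), c("primaryid", "caseid", "caseversion",
                                  "quarter", "age_band", "sex", "occp_cod"))
  if (length(extra))
    message("ignoring unmodeled DEMO column(s): ", paste(extra, collapse = ", "))
  demo <- drop_keyless(demo, "DEMO")
  demo[, caseversion := suppressWarnings(as.integer(caseversion))]
  demo[is.na(caseversion), caseversion := 0L]
  demo[, sex := .decode(sex, .SEX_CODES, .SEXES)]
  demo[, occp_cod := .decode(occp_cod, .REPORTER_CODES, .REPORTERS)]
  demo[!(age_band %in% .AGE_BANDS), age_band := "unknown"]

  known <- demo$primaryid
  rd_child <- function(tag, cols) {
    if (!(tag %in% names(paths)))
      return(data.table::as.data.table(
        stats::setNames(rep(list(character(0)), length(cols)), cols)))
    dt <- rd(paths[[tag]])
    .check_cols(dt, cols, toupper(tag))
    dt <- drop_keyless(dt, toupper(tag))
    orphan <- !(dt$primaryid %in% known)
    if (any(orphan)) {
      warning(sum(orphan), " ", toupper(tag),
              " row(s) reference a primaryid absent from DEMO; skipped")
      dt <- dt[!orphan]
    }
    dt[, cols, with = FALSE]
  }

  drug <- rd_child("drug", c("primaryid", "drug_seq", "drugname", "role_cod"))
  reac <- rd_child("reac", c("primaryid", "pt"))
  indi <- rd_child("indi", c("primaryid", "drug_seq", "indi_pt"))
  if (nrow(drug)) {
    drug[, drugname := normalize_term(drugname)]
    drug[, role_cod := .decode(role_cod, .ROLE_CODES, .DRUG_ROLES)]
    drug[!(role_cod %in% .DRUG_ROLES), role_cod := "concomitant"]
  }
  if (nrow(reac)) reac[, pt := normalize_term(pt)]
  if (nrow(indi)) indi[, indi_pt := normalize_term(indi_pt)]

  report_store(demo, drug, reac, indi,
               provenance = unname(vapply(paths, basename, character(1))))
}

.decode <- function(x, codes, labels) {
  x <- trimws(x)
  hit <- match(toupper(x), names(codes))
  out <- ifelse(is.na(hit), tolower(x), unname(codes[hit]))
  out[!(out %in% labels)] <- "unknown"
  out
}

#' Write a report store as a FAERS-style ASCII bundle
#'
#' Emits `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `INDI.txt` in the same
#' `$`-delimited dialect [read_faers_ascii()] consumes. Lossless for every
#' modeled field; rows are written in key order so repeated writes of the
#' same store are byte-identical.
#'
#' @param store a [report_store()].
#' @param dir output directory (created if absent).
#' @return invisibly, the four file paths.
#' @export
write_faers_ascii <- function(store, dir) {
  stopifnot(inherits(store, "report_store"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir)
  }
  if (file.access(dir, mode = 2L) != 0L)
    stop("directory not writable: ", dir)
  wr <- function(dt, name) {
    p <- file.path(dir, paste0(name, ".txt"))
    data.table::fwrite(dt, p, sep = "$", quote = FALSE, col.names = TRUE)
    p
  }
  out <- c(
    wr(store$demo[order(primaryid)], "DEMO"),
    wr(store$drug[order(primaryid, drug_seq)], "DRUG"),
    wr(store$reac[order(primaryid, pt)], "REAC"),
    wr(store$indi[order(primaryid, drug_seq, indi_pt)], "INDI")
  )
  invisible(out)
}

#' Deduplicate a store to the latest case version
#'
#' FAERS cases are revised over time; each revision is a separate report row
#' sharing the caseid. Analysis must see one report per case: the one with
#' the highest `caseversion`. Ties on version are broken by later `quarter`;
#' a remaining tie keeps the first row encountered and raises a warning. The
#' number of removed revisions is attached as attribute `n_removed` and
#' reported via a message.
#'
#' Idempotent: `dedup_latest(dedup_latest(s))` equals `dedup_latest(s)`.
#'
#' @param store a [report_store()].
#' @return a deduplicated [report_store()] (at most one report per caseid).
#' @export
dedup_latest <- function(store) {
  stopifnot(inherits(store, "report_store"))
  demo <- store$demo
  if (!nrow(demo)) return(store)
  # only cases with more than one revision need resolving
  multi <- duplicated(demo$caseid) | duplicated(demo$caseid, fromLast = TRUE)
  removed <- 0L
  drop_ids <- character(0)
  if (any(multi)) {
    d <- demo[multi, .(primaryid, caseid, caseversion, quarter)]
    d[, .row := .I]
    data.table::setorder(d, caseid, -caseversion, -quarter, .row)
    # after ordering, the first row per caseid is the keeper; a tie exists
    # when the next row of the same case repeats its (caseversion, quarter)
    first <- !duplicated(d$caseid)
    fi <- which(first)
    nx <- pmin(fi + 1L, nrow(d))
    tie <- !first[nx] & d$caseversion[fi] == d$caseversion[nx] &
      d$quarter[fi] == d$quarter[nx]
    if (any(tie)) {
      warning(sum(tie),
              " case(s) had tied (caseversion, quarter); kept first encountered")
    }
    drop_ids <- d$primaryid[!first]
    removed <- length(drop_ids)
  }
  if (removed > 0L)
    message("dedup_latest: removed ", removed, " superseded case revision(s)")
  out <- .new_store(
    demo = demo[!(primaryid %in% drop_ids)],
    drug = store$drug[!(primaryid %in% drop_ids)],
    reac = store$reac[!(primaryid %in% drop_ids)],
    indi = store$indi[!(primaryid %in% drop_ids)],
    provenance = store$provenance
  )
  attr(out, "n_removed") <- removed
  attr(out, "deduplicated") <- TRUE
  out
}
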