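# Compact constructors for hand-written fixture stores.

tiny_store <- function(demo, drug, reac, indi = NULL, provenance = "fixture") {
  if (is.null(indi))
    indi <- data.frame(primaryid = character(0), drug_seq = integer(0),
                       indi_pt = character(0))
  report_store(demo, drug, reac, indi, provenance)
}

# one report with given drugs/roles and reactions
one_report <- function(pid = "C11", caseid = "C1", version = 1L,
                       quarter = "2015q2", drugs = "metformin",
                       roles = "suspect", reactions = "headache",
                       indications = character(0),
                       sex = "male", age = "18-64", reporter = "physician") {
  list(
    demo = data.frame(primaryid = pid, caseid = caseid,
                      caseversion = version, quarter = quarter,
                      age_band = age, sex = sex, occp_cod = reporter),
    drug = data.frame(primaryid = pid, drug_seq = seq_along(drugs),
                      drugname = drugs, role_cod = roles),
    reac = data.frame(primaryid = pid, pt = reactions),
    indi = if (length(indications))
      data.frame(primaryid = pid, drug_seq = 1L, indi_pt = indications)
    else data.frame(primaryid = character(0), drug_seq = integer(0),
                    indi_pt = character(0))
  )
}

bind_reports <- function(...) {
  parts <- list(...)
  tiny_store(
    demo = do.call(rbind, lapply(parts, `[[`, "demo")),
    drug = do.call(rbind, lapply(parts, `[[`, "drug")),
    reac = do.call(rbind, lapply(parts, `[[`, "reac")),
    indi = do.call(rbind, lapply(parts, `[[`, "indi"))
  )
}

# store equality on all modeled fields, ignoring row order
expect_store_equal <- function(x, y) {
  ord <- function(dt, cols) as.data.frame(dt)[do.call(order, as.data.frame(dt)[cols]), ,
                                              drop = FALSE]
  for (tb in c("demo", "drug", "reac", "indi")) {
    cols <- intersect(c("primaryid", "drug_seq", "pt", "indi_pt"),
                      names(x[[tb]]))
    a <- ord(x[[tb]], cols); b <- ord(y[[tb]], cols)
    rownames(a) <- NULL; rownames(b) <- NULL
    expect_equal(a, b, ignore_attr = TRUE)
  }
}
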