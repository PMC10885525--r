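make_claims_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c("patient_id,service_date,system,code,setting", lines), path)
  path
}

test_that("claims reader parses, normalizes and validates", {
  path <- make_claims_file(c(
    "p1,2016-03-15,ICD10CM-DX,B20,outpatient",
    "p1,2016-03-15,ICD10CM-DX,O98.712,inpatient",
    "p2,2014-01-02,ICD9CM-DX,042,outpatient"
  ))
  df <- read_claims(path)
  expect_identical(nrow(df), 3L)
  expect_identical(df$code, c("B20", "O98712", "042"))
  expect_s3_class(df$service_date, "Date")

  expect_error(read_claims(make_claims_file("p1,2016-03-15,ICD11,B20,outpatient")),
               "unknown code system.*row 1")
  expect_error(read_claims(make_claims_file("p1,15/03/2016,ICD10CM-DX,B20,outpatient")),
               "unparseable")
  bad_col <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,service_date,system,code", "p1,2016-03-15,CPT,86360"),
             bad_col)
  expect_error(read_claims(bad_col), "missing required column")
})

test_that("claims write/read round-trips exactly", {
  set.seed(7)
  df <- claims(
    patient_id = sprintf("p%02d", sample(1:20, 50, replace = TRUE)),
    service_date = as.Date("2010-01-01") + sample(0:4000, 50, replace = TRUE),
    system = sample(c("ICD9CM-DX", "ICD10CM-DX", "CPT"), 50, replace = TRUE),
    code = sample(c("042", "B20", "86360", "V08"), 50, replace = TRUE),
    setting = sample(c("inpatient", "outpatient"), 50, replace = TRUE)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(df, path)
  expect_equal(read_claims(path), df, ignore_attr = TRUE)
})

test_that("enrollment spans merge when overlapping or adjacent", {
  spans <- data.frame(
    patient_id = c("p1", "p1", "p2", "p2", "p3"),
    start = as.Date(c("2010-01-01", "2010-07-01", "2010-01-01", "2010-03-01",
                      "2012-01-01")),
    end = as.Date(c("2010-06-30", "2011-01-01", "2010-05-01", "2010-08-01",
                    "2012-12-31"))
  )
  expect_warning(merged <- merge_spans(spans), "overlapping")
  expect_identical(nrow(merged), 3L)
  p1 <- merged[merged$patient_id == "p1", ]
  expect_identical(p1$start, as.Date("2010-01-01")) # adjacency merged silently
  expect_identical(p1$end, as.Date("2011-01-01"))
  p2 <- merged[merged$patient_id == "p2", ]
  expect_identical(p2$end, as.Date("2010-08-01"))
  # a 1-day gap is NOT adjacent and stays split
  split2 <- merge_spans(data.frame(
    patient_id = "q", start = as.Date(c("2010-01-01", "2010-07-02")),
    end = as.Date(c("2010-06-30", "2011-01-01"))
  ))
  expect_identical(nrow(split2), 2L)
})

test_that("chart-review reader enforces the evidence invariant", {
  ok <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,target_code_date,confirmed,evidence,evidence_date",
    "p1,2016-03-15,TRUE,clinician_note,2016-03-20",
    "p1,2016-05-15,FALSE,none,"
  ), ok)
  df <- read_chart_reviews(ok)
  expect_identical(df$confirmed, c(TRUE, FALSE))
  expect_true(is.na(df$evidence_date[2]))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,target_code_date,confirmed,evidence,evidence_date",
    "p1,2016-03-15,TRUE,none,"
  ), bad)
  expect_error(read_chart_reviews(bad), "evidence invariant")
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,target_code_date,confirmed,evidence,evidence_date",
    "p1,2016-03-15,FALSE,clinician_note,2016-03-20"
  ), bad2)
  expect_error(read_chart_reviews(bad2), "evidence invariant")
})

test_that("distinct code days collapse same-day claims and respect windows", {
  sets <- hiv_codesets()
  df <- claims(
    patient_id = c("p1", "p1", "p1", "p1", "p2"),
    service_date = as.Date(c("2016-03-15", "2016-03-15", "2016-03-15",
                             "2016-04-01", "2016-03-15")),
    system = c("ICD10CM-DX", "ICD10CM-DX", "ICD10CM-DX", "ICD10CM-DX", "CPT"),
    code = c("B20", "B20", "Z21", "B20", "86360"),
    setting = "outpatient"
  )
  days <- distinct_code_days(df, sets$all_hiv)
  expect_identical(days$p1, as.Date(c("2016-03-15", "2016-04-01")))
  expect_null(days$p2) # CD4-only patient has no HIV code day
  windowed <- distinct_code_days(df, sets$all_hiv,
                                 window = as.Date(c("2016-04-01", "2016-12-31")))
  expect_identical(windowed$p1, as.Date("2016-04-01"))
})

test_that("distinct code days never exceed matching claims, equality iff distinct dates", {
  sets <- hiv_codesets()
  set.seed(42)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    df <- claims(
      patient_id = "p1",
      service_date = as.Date("2016-01-01") + sample(0:9, n, replace = TRUE),
      system = "ICD10CM-DX",
      code = sample(c("B20", "Z21"), n, replace = TRUE),
      setting = "outpatient"
    )
    days <- distinct_code_days(df, sets$all_hiv)$p1
    expect_lte(length(days), n)
    expect_false(is.unsorted(days, strictly = TRUE))
    expect_identical(length(days) == n,
                     !anyDuplicated(df$service_date) > 0)
  }
})
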