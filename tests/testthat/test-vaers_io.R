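test_that("data file parsing keeps missingness and never invents numbers", {
  dir <- withr::local_tempdir()
  df <- mini_data(c("1", "2", "3"), ages = c("0.5", "", "17"),
                  numdays = c("4", "", "not-a-number"))
  path <- file.path(dir, "1999VAERSDATA.csv")
  write.csv(df, path, row.names = FALSE)

  rec <- read_vaers_data(path)
  expect_equal(rec$vaers_id, c("1", "2", "3"))
  expect_equal(rec$age_years, c(0.5, NA, 17))
  expect_equal(rec$onset_interval_days, c(4L, NA, NA))
  # count of missing ages equals count of empty/unparseable cells
  expect_identical(sum(is.na(rec$age_years)), 1L)
  expect_identical(sum(is.na(rec$onset_interval_days)), 2L)
})

test_that("header-only files give empty record sets", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "d.csv")
  write.csv(mini_data(character()), path, row.names = FALSE)
  expect_equal(nrow(read_vaers_data(path)), 0)
})

test_that("missing required header column is a fatal error naming it", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.csv")
  write.csv(data.frame(VAERS_ID = "1", AGE_YRS = "2"), path,
            row.names = FALSE)
  expect_error(read_vaers_data(path), "NUMDAYS")
})

test_that("duplicated VAERS_ID within a file warns and keeps the first", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "d.csv")
  write.csv(mini_data(c("7", "7"), ages = c("1", "2")), path,
            row.names = FALSE)
  expect_warning(rec <- read_vaers_data(path), "duplicated")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$age_years, 1)
})

test_that("symptom rows carry 1-5 terms verbatim and drop empty cells", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "s.csv")
  write.csv(mini_sym(c("1", "2"),
                     s1 = c("Pyrexia", "Rash"),
                     s3 = c("", "Kawasaki's disease")),
            path, row.names = FALSE)
  rec <- read_vaers_symptoms(path)
  expect_equal(rec$terms[[1]], "Pyrexia")
  # apostrophe preserved verbatim
  expect_equal(rec$terms[[2]], c("Rash", "Kawasaki's disease"))
})

test_that("vaccine codes are upper-cased and stripped on ingest", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "v.csv")
  write.csv(mini_vax(c("1", "1", "1", "2"),
                     type = c("menb", " covid19 ", "RV1", "UNK")),
            path, row.names = FALSE)
  rec <- read_vaers_vax(path)
  expect_equal(rec$vax_type, c("MENB", "COVID19", "RV1", "UNK"))
  # one record per row, shared id allowed
  expect_equal(sum(rec$vaers_id == "1"), 3)
})

test_that("join pools continuation rows, de-duplicates, keeps zero-symptom reports", {
  dir <- write_mini_triplet(
    mini_data(c("1", "2", "3")),
    mini_sym(c("1", "1", "2"),
             s1 = c("A1", "A1", "B1"), s2 = c("A2", "A6", ""),
             s3 = c("A3", "A7", ""), s4 = c("A4", "", ""),
             s5 = c("A5", "", "")),
    mini_vax(c("1", "2", "3", "9"), type = c("MENB", "MMR", "HEP", "RV1"))
  )
  rep <- load_vaers_years(dir, 1999, 1999)
  expect_s3_class(rep, "vaers_reports")
  expect_equal(nrow(rep), 3)
  # 5 + 3 terms across two rows, duplicate "A1" pooled once -> 7
  expect_setequal(rep$symptom_terms[[1]],
                  c("A1", "A2", "A3", "A4", "A5", "A6", "A7"))
  # report 3 has a vaccine but no symptom rows: retained, empty term set
  expect_length(rep$symptom_terms[[3]], 0)
  # orphan vax row for unknown id 9 is counted, not dropped silently
  expect_equal(attr(rep, "orphans")[["vax"]], 1)
})

test_that("join is idempotent on counts and order-invariant", {
  g <- generate_vaers(sim_config(
    vaccine_specs = data.frame(code = c("MENB", "MMR"), n_reports = 120,
                               age_min = 0, age_max = 6,
                               background_rate_per_100k = 500,
                               excess_rate_per_100k = 1500),
    seed = 99))
  rep <- load_vaers_years(g$dir, 2019, 2019)
  expect_equal(nrow(rep), g$truth$n_reports)
  # re-joining the same year range reproduces identical composition
  rep2 <- load_vaers_years(g$dir, 2019, 2019)
  expect_identical(rep$symptom_terms, rep2$symptom_terms)
  expect_identical(rep$vaccine_codes, rep2$vaccine_codes)
})

test_that("year-range loading concatenates, skips missing triplets, flags NonDomestic", {
  dir <- withr::local_tempdir()
  for (pre in c("1999", "2000", "NonDomestic")) {
    write_mini_triplet(mini_data(paste0(pre, "_", 1:5)),
                       mini_sym(paste0(pre, "_", 1:5)),
                       mini_vax(paste0(pre, "_", 1:5)),
                       prefix = pre, dir = dir)
  }
  expect_warning(rep <- load_vaers_years(dir, 1999, 2001), "2001")
  expect_equal(nrow(rep), 10)
  expect_false(any(rep$nondomestic))

  rep_nd <- suppressWarnings(
    load_vaers_years(dir, 1999, 2000, include_nondomestic = TRUE))
  expect_equal(nrow(rep_nd), 15)
  expect_equal(sum(rep_nd$nondomestic), 5)

  # empty range with skip policy: empty result plus one warning per year
  expect_warning(expect_warning(none <- load_vaers_years(dir, 1901, 1902)))
  expect_equal(nrow(none), 0)
  expect_error(load_vaers_years(dir, 1901, 1902, missing_year = "error"))
})

test_that("a report id in two year files is kept once, first year wins", {
  dir <- withr::local_tempdir()
  write_mini_triplet(mini_data("42", ages = "3"), mini_sym("42"),
                     mini_vax("42"), prefix = "1999", dir = dir)
  write_mini_triplet(mini_data("42", ages = "9"), mini_sym("42"),
                     mini_vax("42"), prefix = "2000", dir = dir)
  expect_warning(rep <- load_vaers_years(dir, 1999, 2000), "more than one")
  expect_equal(nrow(rep), 1)
  expect_equal(rep$age_years, 3)
  expect_equal(attr(rep, "cross_year_duplicates"), 1)
})

test_that("non-UTF-8 (cp1252) bytes are decoded via the latin1 fallback", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "d.csv")
  con <- file(path, open = "wb")
  writeLines(c("VAERS_ID,AGE_YRS,NUMDAYS,SYMPTOM_TEXT",
               "1,2,0,caf\xe9"), con, useBytes = TRUE)
  close(con)
  rec <- read_vaers_data(path)
  expect_equal(rec$SYMPTOM_TEXT, "café")
})
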