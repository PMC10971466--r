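test_that("normalized frequency honours both conventions and zero-count bounds", {
  expect_identical(normalized_frequency(91, 2790, "round_nearest"), 3262)
  expect_identical(normalized_frequency(3, 851, "truncate"), 352)
  expect_identical(normalized_frequency(19, 2117, "truncate"), 897)
  # conventions genuinely differ at a half: 1e5 * 1/8000 = 12.5
  expect_identical(normalized_frequency(1, 8000, "round_nearest"), 13)
  expect_identical(normalized_frequency(1, 8000, "truncate"), 12)
  expect_identical(normalized_frequency(0, 12456), "<8")
  expect_identical(normalized_frequency(0, 16084), "<6")
  expect_identical(normalized_frequency(0, 100000), "<1")
  expect_error(normalized_frequency(1, 0), "denominator")
  expect_error(normalized_frequency(-1, 10), "non-negative")
})

test_that("frequency is scale-free before rounding", {
  for (k in c(2, 7, 100)) {
    expect_equal(1e5 * (19 * k) / (2117 * k), 1e5 * 19 / 2117)
  }
})

test_that("published per-vaccine rows satisfy round-nearest; per-age rows truncate", {
  kd <- published_kd_table()
  recomputed <- vapply(seq_len(nrow(kd)), function(i) {
    normalized_frequency(kd$case_count[i], kd$denominator[i],
                         "round_nearest")
  }, numeric(1))
  expect_equal(recomputed, kd$frequency)

  covid <- published_covid_age_table()
  lab <- vapply(seq_len(nrow(covid)), function(i) {
    as.character(normalized_frequency(covid$case_count[i],
                                      covid$denominator[i], "truncate"))
  }, character(1))
  # the published age-29 cell (1/14700 -> printed 7) is the one cell that
  # follows round-nearest (6.80 truncates to 6); all others truncate
  inconsistent <- covid$stratum == 29
  expect_equal(lab[!inconsistent], covid$label[!inconsistent])
  expect_identical(normalized_frequency(1, 14700, "round_nearest"), 7)
})

test_that("vaccine table recovers planted counts, windows and attribution rules", {
  g <- generate_vaers(sim_config(seed = 2718))
  rep <- load_vaers_years(g$dir, 2019, 2019)
  cases <- extract_cases(rep)

  # all-ages table matches the sidecar truth exactly
  ft <- vaccine_frequency_table(rep, cases, "KD", min_cases = 0,
                                denominator_ages = NULL)
  m <- merge(ft, g$truth$per_vaccine, by.x = "stratum", by.y = "code")
  expect_equal(nrow(m), nrow(ft))
  expect_equal(m$case_count.x, m$case_count.y)
  expect_equal(m$denominator.x, m$denominator.y)

  # min_cases filter drops sparse rows
  ft5 <- vaccine_frequency_table(rep, cases, "KD", min_cases = 5,
                                 denominator_ages = NULL)
  expect_true(all(ft5$case_count >= 5))
  expect_setequal(ft5$stratum, ft$stratum[ft$case_count >= 5])

  # a flagged report with two codes contributes one case to each row
  dir <- write_mini_triplet(
    mini_data("1"), mini_sym("1", s1 = "Kawasaki's disease"),
    mini_vax(c("1", "1"), type = c("PNC13", "HIBV")))
  r1 <- load_vaers_years(dir, 1999, 1999)
  t1 <- vaccine_frequency_table(r1, extract_cases(r1), "KD", min_cases = 0,
                                denominator_ages = NULL)
  expect_equal(t1$case_count, c(1L, 1L))

  # asymmetric windows: adult case counts while the denominator is 0-5
  dir2 <- write_mini_triplet(
    mini_data(c("1", "2"), ages = c("40", "3")),
    mini_sym(c("1", "2"), s1 = c("Kawasaki's disease", "Pyrexia")),
    mini_vax(c("1", "2")))
  r2 <- load_vaers_years(dir2, 1999, 1999)
  t2 <- vaccine_frequency_table(r2, extract_cases(r2), "KD", min_cases = 0)
  expect_equal(t2$case_count, 1L)   # the 40-year-old case still counts
  expect_equal(t2$denominator, 1L)  # only the 3-year-old is in the window
})

test_that("onset table routes missing days to Blank and logs overflow", {
  dir <- write_mini_triplet(
    mini_data(as.character(1:4), numdays = c("0", "", "30", "45")),
    mini_sym(as.character(1:4), s1 = "Kawasaki's disease"),
    mini_vax(as.character(1:4)))
  rep <- load_vaers_years(dir, 1999, 1999)
  cases <- extract_cases(rep)
  ot <- onset_table(rep, cases, "KD", "MENB", max_day = 30)
  expect_equal(ot$onset_day[1], "Blank")
  expect_equal(ot$MENB[ot$onset_day == "Blank"], 1)
  expect_equal(ot$MENB[ot$onset_day == "0"], 1)
  expect_equal(ot$MENB[ot$onset_day == "30"], 1)
  expect_equal(attr(ot, "overflow")[["MENB"]], 1)
  # unflagged vaccine column is all zero
  ot2 <- onset_table(rep, cases, "Vasculitis", "MENB")
  expect_true(all(ot2$MENB == 0))
})

test_that("onset distribution from the generator decays with day", {
  g <- generate_vaers(sim_config(
    vaccine_specs = data.frame(code = "MENB", n_reports = 4000,
                               age_min = 0, age_max = 6,
                               background_rate_per_100k = 0,
                               excess_rate_per_100k = 50000),
    p_missing_onset = 0, seed = 31))
  rep <- load_vaers_years(g$dir, 2019, 2019)
  cases <- extract_cases(rep)
  ot <- onset_table(rep, cases, "KD", "MENB")
  counts <- ot$MENB[ot$onset_day != "Blank"]
  # geometric decay: early-day mass dominates middle and late mass
  expect_gt(sum(counts[1:5]), sum(counts[11:15]))
  expect_gt(sum(counts[1:5]), sum(counts[21:31]))
})

test_that("age table floors ages, buckets missing as N.A., conserves totals", {
  dir <- write_mini_triplet(
    mini_data(as.character(1:4), ages = c("0.4", "", "12.9", "2")),
    mini_sym(as.character(1:4),
             s1 = c("Kawasaki's disease", "Kawasaki's disease",
                    "Kawasaki's disease", "Vasculitis")),
    mini_vax(as.character(1:4)))
  rep <- load_vaers_years(dir, 1999, 1999)
  cases <- extract_cases(rep)
  at <- age_table(rep, cases, max_age = 20)
  expect_equal(at$age[1], "N.A.")
  expect_equal(at$KD[at$age == "N.A."], 1)
  expect_equal(at$KD[at$age == "0"], 1)    # 0.4 floors to 0
  expect_equal(at$KD[at$age == "12"], 1)   # 12.9 floors to 12
  expect_equal(sum(at$KD) + attr(at, "overflow")[["KD"]], sum(cases$KD))
  expect_equal(sum(at$Vasculitis), 1)
})

test_that("per-age frequency table matches generator truth and marks bounds", {
  g <- generate_vaers(sim_config(seed = 1618))
  rep <- load_vaers_years(g$dir, 2019, 2019)
  cases <- extract_cases(rep)
  af <- age_frequency_table(rep, cases, "KD", "MENB", ages = 0:6)
  # conservation within the age range: per-age counts sum to the code's
  # aged case total
  has_code <- vapply(rep$vaccine_codes, function(v) "MENB" %in% v,
                     logical(1))
  aged_cases <- sum(cases$KD & has_code & !is.na(rep$age_years) &
                      lengths(rep$symptom_terms) > 0)
  expect_equal(sum(af$case_count), aged_cases)
  # zero-count ages get "<k" labels, k = floor(100000/denominator)
  zero <- af$case_count == 0 & af$denominator > 0
  if (any(zero)) {
    expect_equal(af$label[zero],
                 paste0("<", floor(1e5 / af$denominator[zero])))
  }
  # empty-denominator ages are NA
  empty <- af$denominator == 0
  expect_true(all(is.na(af$label[empty])))
})

test_that("table writers emit CSV and aligned text with markers verbatim", {
  covid <- published_covid_age_table()
  dir <- withr::local_tempdir()
  p <- write_table_csv(covid, file.path(dir, "t.csv"))
  back <- read.csv(p, colClasses = c(label = "character"))
  expect_equal(back$label, covid$label)
  txt <- format_table_text(covid)
  expect_match(txt, "<8")
  expect_match(txt, "<6")
})
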