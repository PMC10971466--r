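# Frequency tabulations: per-vaccine normalized frequencies, onset-day
# distributions, age-of-onset counts, and per-age frequencies with
# zero-count upper bounds.
#
# The central statistic is the normalized frequency: adverse-event cases per
# 100,000 reports-with-symptoms in a stratum. Two integer conventions are in
# use in published VAERS tabulations and both are supported explicitly:
# round-to-nearest (half away from zero) for the per-vaccine table and
# truncation for the per-age table. When a stratum has zero cases the value
# is an upper-bound marker "<k" with k = floor(100000 / denominator), i.e.
# the frequency one case would not exceed.

# half-away-from-zero rounding of non-negative x
.round_half_away <- function(x) floor(x + 0.5)

#' Normalized reporting frequency per 100,000
#'
#' @param case_count Non-negative integer number of cases.
#' @param denominator Positive integer count of reports with at least one
#'   symptom in the stratum.
#' @param convention `"round_nearest"` (half away from zero) or
#'   `"truncate"`.
#' @return For `case_count > 0`, the integer frequency per 100,000 under the
#'   convention. For `case_count == 0`, the character upper-bound marker
#'   `"<k"` with `k = floor(100000 / denominator)`.
#' @examples
#' normalized_frequency(91, 2790, "round_nearest")  # 3262
#' normalized_frequency(3, 851, "truncate")         # 352
#' normalized_frequency(0, 12456)                   # "<8"
#' @export
normalized_frequency <- function(case_count, denominator,
                                 convention = c("round_nearest", "truncate")) {
  convention <- match.arg(convention)
  stopifnot(length(case_count) == 1L, length(denominator) == 1L)
  if (!is.finite(denominator) || denominator <= 0) {
    stop("denominator must be positive", call. = FALSE)
  }
  if (!is.finite(case_count) || case_count < 0) {
    stop("case_count must be non-negative", call. = FALSE)
  }
  if (case_count == 0) {
    return(paste0("<", floor(1e5 / denominator)))
  }
  raw <- 1e5 * case_count / denominator
  if (convention == "round_nearest") .round_half_away(raw) else trunc(raw)
}

# vectorized helpers used by the table builders
.freq_num <- function(count, denom, convention) {
  ifelse(count > 0,
         if (convention == "round_nearest") {
           .round_half_away(1e5 * count / denom)
         } else {
           trunc(1e5 * count / denom)
         },
         NA_real_)
}

.freq_label <- function(count, denom, convention) {
  ifelse(count > 0,
         as.character(.freq_num(count, denom, convention)),
         paste0("<", floor(1e5 / denom)))
}

.has_symptoms <- function(reports) lengths(reports$symptom_terms) > 0

.age_in_window <- function(age, window) {
  if (is.null(window)) rep(TRUE, length(age))
  else !is.na(age) & floor(age) >= window[1] & floor(age) <= window[2]
}

# report x vaccine incidence as a long index: (report row, code)
.vaccine_long <- function(reports) {
  data.frame(
    row = rep(seq_len(nrow(reports)), lengths(reports$vaccine_codes)),
    code = unlist(reports$vaccine_codes, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Per-vaccine normalized frequency table
#'
#' One row per vaccine code with at least `min_cases` case reports. A report
#' listing k distinct vaccine codes contributes once to each of the k rows
#' (no fractional attribution). The case-count and denominator age windows
#' are deliberately independent parameters: published VAERS vasculitis
#' tabulations pair an early-childhood (ages 0--5) reports-with-symptoms
#' denominator with an all-ages case count, and that asymmetric default is
#' reproduced here. Set both windows to `NULL` for a symmetric all-ages
#' table.
#'
#' @param reports A `vaers_reports` data frame.
#' @param cases A `case_table` from [extract_cases()].
#' @param category Category column name to tabulate.
#' @param min_cases Minimum case count for a row to be kept (default 5).
#' @param denominator_ages Inclusive integer age window `c(lo, hi)` applied
#'   to `floor(age_years)` for the denominator, or `NULL` for all ages
#'   (missing ages are excluded by a non-NULL window). Default `c(0, 5)`.
#' @param numerator_ages Same for the case count; default `NULL` (all ages).
#' @param convention Rounding convention, default `"round_nearest"`.
#' @return A `vaers_freq_table` data frame: `stratum`, `case_count`,
#'   `denominator`, `frequency` (numeric, `NA` when zero cases), `label`
#'   (character, with `"<k"` bounds).
#' @export
vaccine_frequency_table <- function(reports, cases, category,
                                    min_cases = 5,
                                    denominator_ages = c(0, 5),
                                    numerator_ages = NULL,
                                    convention = c("round_nearest",
                                                   "truncate")) {
  convention <- match.arg(convention)
  stopifnot(min_cases >= 0, nrow(reports) == nrow(cases))
  flag <- cases[[category]]
  if (is.null(flag)) stop("unknown category: ", category, call. = FALSE)

  vl <- .vaccine_long(reports)
  with_sym <- .has_symptoms(reports)
  denom_ok <- with_sym & .age_in_window(reports$age_years, denominator_ages)
  num_ok <- flag & with_sym & .age_in_window(reports$age_years,
                                             numerator_ages)

  codes <- sort(unique(vl$code))
  denom <- vapply(codes, function(cd) {
    sum(denom_ok[vl$row[vl$code == cd]])
  }, numeric(1))
  count <- vapply(codes, function(cd) {
    sum(num_ok[vl$row[vl$code == cd]])
  }, numeric(1))

  keep <- count >= min_cases & denom > 0
  out <- data.frame(
    stratum = codes[keep],
    case_count = as.integer(count[keep]),
    denominator = as.integer(denom[keep]),
    stringsAsFactors = FALSE
  )
  out$frequency <- .freq_num(out$case_count, out$denominator, convention)
  out$label <- .freq_label(out$case_count, out$denominator, convention)
  structure(out, class = c("vaers_freq_table", "data.frame"),
            convention = convention, category = category)
}

#' Onset-day distribution for one category across vaccines
#'
#' Rows are the missing-onset marker `"Blank"` followed by days
#' `0..max_day`; one count column per requested vaccine code, counting only
#' reports whose category flag is true. Flagged reports with onset beyond
#' `max_day` are excluded from the printed rows; their per-code counts are
#' kept in the `"overflow"` attribute.
#'
#' @param reports,cases,category As in [vaccine_frequency_table()].
#' @param vaccine_codes Character vector of codes to tabulate.
#' @param max_day Last onset day printed (default 30).
#' @return A data frame with `onset_day` plus one column per code.
#' @export
onset_table <- function(reports, cases, category, vaccine_codes,
                        max_day = 30) {
  stopifnot(max_day >= 0)
  flag <- cases[[category]]
  vl <- .vaccine_long(reports)
  onset <- reports$onset_interval_days

  out <- data.frame(onset_day = c("Blank", as.character(0:max_day)),
                    stringsAsFactors = FALSE)
  overflow <- integer(length(vaccine_codes))
  names(overflow) <- vaccine_codes
  for (cd in vaccine_codes) {
    rows <- vl$row[vl$code == cd]
    rows <- rows[flag[rows]]
    d <- onset[rows]
    blank <- sum(is.na(d))
    day_counts <- tabulate(d[!is.na(d) & d <= max_day] + 1L,
                           nbins = max_day + 1L)
    overflow[cd] <- sum(!is.na(d) & d > max_day)
    out[[cd]] <- c(blank, day_counts)
  }
  attr(out, "overflow") <- overflow
  attr(out, "category") <- category
  out
}

#' Age-of-onset count table across categories
#'
#' Ages are binned as `floor(age_years)`; reports with missing age go to the
#' `"N.A."` row, printed first. Flagged reports older than `max_age` are
#' excluded from the printed rows (counts kept in the `"overflow"`
#' attribute), so the column sums equal the total case counts whenever
#' `max_age` covers the oldest case.
#'
#' @param reports A `vaers_reports` data frame.
#' @param cases A `case_table`.
#' @param categories Category column names to tabulate (default: all columns
#'   of `cases`).
#' @param max_age Last single-year age printed (default 20).
#' @return A data frame with `age` (`"N.A."`, `"0"`, ..) plus one count
#'   column per category.
#' @export
age_table <- function(reports, cases, categories = NULL, max_age = 20) {
  stopifnot(max_age >= 0)
  if (is.null(categories)) categories <- setdiff(names(cases), "vaers_id")
  age_bin <- floor(reports$age_years)

  out <- data.frame(age = c("N.A.", as.character(0:max_age)),
                    stringsAsFactors = FALSE)
  overflow <- integer(length(categories))
  names(overflow) <- categories
  for (cat_name in categories) {
    flag <- cases[[cat_name]]
    if (is.null(flag)) stop("unknown category: ", cat_name, call. = FALSE)
    a <- age_bin[flag]
    na_count <- sum(is.na(a))
    counts <- tabulate(a[!is.na(a) & a <= max_age] + 1L,
                       nbins = max_age + 1L)
    overflow[cat_name] <- sum(!is.na(a) & a > max_age)
    out[[cat_name]] <- c(na_count, counts)
  }
  attr(out, "overflow") <- overflow
  out
}

#' Per-age normalized frequency for one vaccine
#'
#' Restricts to reports listing `vaccine_code` with at least one symptom
#' term, bins by `floor(age_years)` and computes the normalized frequency at
#' each single-year age under `convention` (truncation by default, the
#' behaviour of the published per-age tabulation). Ages with zero cases get
#' `"<k"` bound labels; ages with an empty denominator get `NA`.
#'
#' @param reports,cases,category As in [vaccine_frequency_table()].
#' @param vaccine_code Single vaccine code defining the stratum.
#' @param convention Rounding convention, default `"truncate"`.
#' @param ages Integer ages to report (default `0:30`).
#' @return A `vaers_freq_table` data frame with `stratum` = age.
#' @export
age_frequency_table <- function(reports, cases, category, vaccine_code,
                                convention = c("truncate", "round_nearest"),
                                ages = 0:30) {
  convention <- match.arg(convention)
  flag <- cases[[category]]
  if (is.null(flag)) stop("unknown category: ", category, call. = FALSE)
  has_vax <- vapply(reports$vaccine_codes, function(v) vaccine_code %in% v,
                    logical(1))
  base <- has_vax & .has_symptoms(reports)
  age_bin <- floor(reports$age_years)

  denom <- vapply(ages, function(a) sum(base & !is.na(age_bin) &
                                          age_bin == a), numeric(1))
  count <- vapply(ages, function(a) sum(base & flag & !is.na(age_bin) &
                                          age_bin == a), numeric(1))

  out <- data.frame(stratum = ages, case_count = as.integer(count),
                    denominator = as.integer(denom),
                    stringsAsFactors = FALSE)
  out$frequency <- ifelse(denom > 0, .freq_num(count, pmax(denom, 1),
                                               convention), NA_real_)
  out$label <- ifelse(denom > 0, .freq_label(count, pmax(denom, 1),
                                             convention), NA_character_)
  structure(out, class = c("vaers_freq_table", "data.frame"),
            convention = convention, category = category,
            vaccine_code = vaccine_code)
}

#' @export
print.vaers_freq_table <- function(x, ...) {
  cat("Normalized frequencies per 100,000 (",
      attr(x, "convention"), ", category ", attr(x, "category"), ")\n",
      sep = "")
  shown <- as.data.frame(x)
  shown$frequency <- ifelse(is.na(shown$frequency), NA,
                            format(shown$frequency, scientific = FALSE,
                                   trim = TRUE))
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Write a tabulation as CSV
#'
#' @param x A table from this package (any data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Format a tabulation as aligned plain text
#'
#' Mirrors the published layout: `Blank`/`N.A.` rows first and `"<k"`
#' markers verbatim.
#'
#' @param x A data frame table.
#' @return A single character string.
#' @export
format_table_text <- function(x) {
  m <- rbind(names(x), as.matrix(format(as.data.frame(x))))
  m[] <- trimws(m)
  m[is.na(m)] <- ""
  widths <- apply(nchar(m), 2, max)
  padded <- vapply(seq_len(ncol(m)), function(j) {
    formatC(m[, j], width = widths[j], flag = "-")
  }, character(nrow(m)))
  lines <- apply(padded, 1, paste, collapse = "  ")
  paste0(paste(trimws(lines, "right"), collapse = "\n"), "\n")
}
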