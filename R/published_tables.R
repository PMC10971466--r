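# Bundled reference tabulations from the public 1990 - 27 Oct 2023 VAERS
# snapshot (Kawasaki-disease reporting summaries). Shipped as printed
# integers only; used as worked-example inputs and to audit the two
# rounding conventions against independently published arithmetic.

#' Published per-vaccine Kawasaki-disease reporting summary
#'
#' Thirty vaccine codes with the early-childhood (ages 0--5)
#' reports-with-symptoms denominator, the all-ages KD case count, and the
#' printed normalized frequency per 100,000 (round-to-nearest convention).
#'
#' @return A `vaers_freq_table` data frame: `stratum`, `case_count`,
#'   `denominator`, `frequency`, `label`.
#' @export
published_kd_table <- function() {
  path <- system.file("extdata", "kd_vaccine_frequency_published.csv",
                      package = "vaersvasc", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(stratum = raw$vaccine,
                    case_count = raw$cases_all_ages,
                    denominator = raw$vaccinations_age_0_5,
                    frequency = as.numeric(raw$frequency_per_100k),
                    label = as.character(raw$frequency_per_100k),
                    stringsAsFactors = FALSE)
  structure(out, class = c("vaers_freq_table", "data.frame"),
            convention = "round_nearest", category = "KD")
}

#' Published per-age COVID-19 vasculitis-composite reporting summary
#'
#' Ages 1--30 for the combined KD / MIS / MIS-A / MIS-C category among
#' COVID-19 vaccine reports: case count, reports-with-symptoms
#' denominator, and the printed frequency per 100,000 (truncation
#' convention, with `"<k"` upper bounds at zero-count ages).
#'
#' @return A `vaers_freq_table` data frame with integer-age `stratum`.
#' @export
published_covid_age_table <- function() {
  path <- system.file("extdata", "covid_age_frequency_published.csv",
                      package = "vaersvasc", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(frequency_label = "character"))
  out <- data.frame(stratum = raw$age,
                    case_count = raw$cases,
                    denominator = raw$vaccinations,
                    frequency = suppressWarnings(
                      as.numeric(raw$frequency_label)),
                    label = raw$frequency_label,
                    stringsAsFactors = FALSE)
  structure(out, class = c("vaers_freq_table", "data.frame"),
            convention = "truncate",
            category = "KD, MIS, MIS-A, or MIS-C",
            vaccine_code = "COVID19")
}
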