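# Statistical layer: each vaccine's observed reporting frequency against a
# background incidence via a two-cell chi-squared goodness-of-fit test,
# family-wise Bonferroni control, and age-band summary statistics.
#
# The background comparison treats the background rate per 100,000 as a
# per-report proportion p0 and tests observed (cases, non-cases) against
# expected (n*p0, n*(1-p0)). The "per year" qualifier on published
# background incidences has no per-report analogue, so it is ignored by
# default; `year_scale` rescales the rate when a calendar interpretation is
# wanted.

#' Background incidence rate
#'
#' @param rate_per_100k Positive background rate per 100,000 (default 20,
#'   the upper published Kawasaki-disease background; 9 is the usual
#'   sensitivity value).
#' @param period_note Free-text note on the rate's reference period.
#' @return A `background_rate` list.
#' @export
background_rate <- function(rate_per_100k = 20, period_note = "per year") {
  stopifnot(is.numeric(rate_per_100k), length(rate_per_100k) == 1L,
            rate_per_100k > 0, rate_per_100k < 1e5)
  structure(list(rate_per_100k = rate_per_100k, period_note = period_note),
            class = "background_rate")
}

#' Chi-squared test of one stratum against the background rate
#'
#' Two-cell goodness-of-fit with df = 1: observed
#' `(count, denominator - count)` against expected
#' `(n p0, n (1 - p0))` with `p0 = rate_per_100k / 100000`, statistic
#' `sum((O - E)^2 / E)`, upper-tail p-value. An exact two-sided binomial
#' test is available for small expected counts. When any expected cell is
#' below 1 the result carries `expected_warning = TRUE` (approximation
#' caveat), not a failure.
#'
#' @param case_count Observed case count.
#' @param denominator Reports with symptoms in the stratum (> 0).
#' @param background A [background_rate()].
#' @param method `"chisq"` (default) or `"binomial"` (exact).
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @param year_scale Multiplier applied to the background rate (default 1:
#'   the rate is compared per report).
#' @return A `vaers_test` list: `statistic`, `df`, `p_value`, `expected`,
#'   `expected_warning`, `method`.
#' @export
chi_squared_vs_background <- function(case_count, denominator,
                                      background = background_rate(),
                                      method = c("chisq", "binomial"),
                                      correct = FALSE, year_scale = 1) {
  method <- match.arg(method)
  stopifnot(denominator > 0, case_count >= 0, case_count <= denominator)
  p0 <- background$rate_per_100k * year_scale / 1e5
  obs <- c(case_count, denominator - case_count)
  expd <- c(denominator * p0, denominator * (1 - p0))

  if (method == "binomial") {
    p <- stats::binom.test(case_count, denominator, p = p0)$p.value
    stat <- NA_real_
    df <- NA_integer_
  } else {
    dev <- abs(obs - expd)
    if (correct) dev <- pmax(dev - 0.5, 0)
    stat <- sum(dev^2 / expd)
    df <- 1L
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(stratum = NA_character_, statistic = stat, df = df,
                 p_value = p, expected = expd,
                 expected_warning = any(expd < 1), method = method),
            class = "vaers_test")
}

#' @export
print.vaers_test <- function(x, ...) {
  cat("Chi-squared test: statistic =", format(x$statistic, digits = 5),
      " df =", x$df, " p =", format(x$p_value, digits = 4), "\n")
  if (isTRUE(x$expected_warning)) {
    cat("  note: an expected cell is < 1; approximation is rough\n")
  }
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param m Number of tests, >= 1.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 30)  # 0.0016667
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is.numeric(m), length(m) == 1L, m >= 1)
  alpha / m
}

#' Test every vaccine stratum against the background rate
#'
#' Runs [chi_squared_vs_background()] on each retained row of a frequency
#' table and applies a uniform Bonferroni threshold `alpha / m` with `m`
#' the number of retained rows. The unknown-vaccine code `"UNK"` is
#' excluded by default (frequencies for an unidentified vaccine are not a
#' test of any vaccine).
#'
#' @param freq_table A `vaers_freq_table` from [vaccine_frequency_table()].
#' @param background A [background_rate()].
#' @param alpha Family-wise error rate (default 0.05).
#' @param exclude_codes Strata dropped before testing (default `"UNK"`).
#' @param ... Passed to [chi_squared_vs_background()].
#' @return A `vaers_screen` data frame: `stratum`, `case_count`,
#'   `denominator`, `frequency`, `statistic`, `df`, `p_value`,
#'   `alpha_corrected`, `significant`; attributes `n_tests`,
#'   `n_significant` and `min_significant_frequency`.
#' @export
evaluate_all_vaccines <- function(freq_table, background = background_rate(),
                                  alpha = 0.05, exclude_codes = "UNK", ...) {
  stopifnot(nrow(freq_table) > 0)
  rows <- freq_table[!(freq_table$stratum %in% exclude_codes), , drop = FALSE]
  m <- nrow(rows)
  if (m == 0) stop("no strata left after exclusions", call. = FALSE)
  thr <- bonferroni_threshold(alpha, m)

  tests <- lapply(seq_len(m), function(i) {
    chi_squared_vs_background(rows$case_count[i], rows$denominator[i],
                              background, ...)
  })
  out <- data.frame(
    stratum = rows$stratum,
    case_count = rows$case_count,
    denominator = rows$denominator,
    frequency = rows$frequency,
    statistic = vapply(tests, `[[`, numeric(1), "statistic"),
    df = vapply(tests, function(t) as.integer(t$df), integer(1)),
    p_value = vapply(tests, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  out$alpha_corrected <- thr
  out$significant <- out$p_value < thr
  sig_freq <- out$frequency[out$significant & !is.na(out$frequency)]
  structure(out, class = c("vaers_screen", "data.frame"),
            n_tests = m, n_significant = sum(out$significant),
            min_significant_frequency =
              if (length(sig_freq)) min(sig_freq) else NA_real_,
            alpha = alpha, rate_per_100k = background$rate_per_100k)
}

#' @export
print.vaers_screen <- function(x, ...) {
  cat("Background-rate screen: ", attr(x, "n_significant"), " of ",
      attr(x, "n_tests"), " strata significant at Bonferroni p < ",
      format(attr(x, "alpha") / attr(x, "n_tests"), digits = 3),
      " (background ", attr(x, "rate_per_100k"), "/100k)\n", sep = "")
  if (!is.na(attr(x, "min_significant_frequency"))) {
    cat("  minimum significant frequency:",
        attr(x, "min_significant_frequency"), "per 100,000\n")
  }
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write screen results as CSV
#'
#' @param x A `vaers_screen`.
#' @param path Output path.
#' @export
write_screen_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Mean and SD of per-age frequencies over an age band
#'
#' Sample statistics (n - 1 denominator) of the normalized frequencies in
#' an inclusive age band of a per-age frequency table. Ages with zero cases
#' are either excluded or represented by the integer of their `"<k"` upper
#' bound (`use_bound`, the convention of published age-band narratives for
#' bands containing zero-count ages).
#'
#' @param freq_rows A `vaers_freq_table` with integer-age strata
#'   ([age_frequency_table()] output or equivalent).
#' @param age_lo,age_hi Inclusive band limits.
#' @param zero_count_policy `"exclude"` or `"use_bound"`.
#' @return A `group_summary` list: `label`, `values`, `mean`, `sd`.
#' @export
group_summary <- function(freq_rows, age_lo, age_hi,
                          zero_count_policy = c("exclude", "use_bound")) {
  zero_count_policy <- match.arg(zero_count_policy)
  sel <- freq_rows$stratum >= age_lo & freq_rows$stratum <= age_hi &
    !is.na(freq_rows$label)
  rows <- freq_rows[sel, , drop = FALSE]
  vals <- rows$frequency
  if (zero_count_policy == "use_bound") {
    zero <- is.na(vals)
    vals[zero] <- as.numeric(sub("^<", "", rows$label[zero]))
  } else {
    vals <- vals[!is.na(vals)]
  }
  if (length(vals) < 2) {
    stop("fewer than 2 frequency values in ages [", age_lo, ", ", age_hi,
         "]", call. = FALSE)
  }
  structure(list(label = paste0("ages ", age_lo, "-", age_hi),
                 values = vals, mean = mean(vals), sd = stats::sd(vals)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(x$label, ": mean ", format(round(x$mean, 1), nsmall = 1),
      ", SD ", format(round(x$sd, 1), nsmall = 1),
      " (n = ", length(x$values), ")\n", sep = "")
  invisible(x)
}
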