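# Expected-count model of passive-surveillance reporting.
#
# For an adverse event X, reports accumulate over a collection horizon of n
# days from a population P_age (ages 0..100). Each person-day contributes a
# background event probability b_age, attenuated by a day-indexed reporting
# bias r_day in [0, 1] (reporting becomes less likely as onset moves away
# from vaccination day). The background-only expectation is
#
#   E_bg = sum_age P_age * sum_day r_day * b_age
#
# and a vaccine adds an age-indexed excess v_age inside the day sum:
#
#   E_vax = sum_age P_age * sum_day r_day * (v_age + b_age).
#
# Under the background-only hypothesis v_age = 0 and normalized reporting
# frequencies should be exchangeable across vaccines; the homogeneity test
# below operationalizes that check. The model states expectations only; the
# simulator adds a Poisson (or exact per-person binomial) distributional
# layer.

#' Reporting-model parameters
#'
#' @param P_age Population sizes by single-year age 0..100 (length 101).
#' @param r_day Reporting-bias multipliers by day 0..n, each in \[0, 1\].
#' @param b_age Background per-person per-day event probabilities by age
#'   (length 101).
#' @param v_age Vaccine-attributable additions by age (length 101; all
#'   zero under the background-only hypothesis). `b_age + v_age` must not
#'   exceed 1 anywhere.
#' @return A `vaers_model_params` list with `n_days = length(r_day) - 1`.
#' @export
background_params <- function(P_age, r_day, b_age,
                              v_age = rep(0, 101)) {
  stopifnot(length(P_age) == 101, length(b_age) == 101,
            length(v_age) == 101, length(r_day) >= 1)
  if (any(P_age < 0) || any(b_age < 0) || any(v_age < 0)) {
    stop("P_age, b_age and v_age must be non-negative", call. = FALSE)
  }
  if (any(r_day < 0) || any(r_day > 1)) {
    stop("r_day must lie in [0, 1]", call. = FALSE)
  }
  if (any(b_age + v_age > 1)) {
    stop("b_age + v_age must not exceed 1", call. = FALSE)
  }
  structure(list(P_age = as.numeric(P_age), r_day = as.numeric(r_day),
                 b_age = as.numeric(b_age), v_age = as.numeric(v_age),
                 n_days = length(r_day) - 1L),
            class = "vaers_model_params")
}

#' Convenience parameters for a simulation stratum
#'
#' Builds [background_params()] for one stratum of `n` reports spread
#' uniformly over ages 0..100, with geometric reporting decay
#' `r_day = rho^day` over a horizon of `n_days`, and a constant background
#' probability calibrated so that the stratum's expected case count equals
#' `n * rate_per_100k / 100000`.
#'
#' @param n Stratum size (reports).
#' @param rate_per_100k Target overall reporting rate per 100,000.
#' @param rho Geometric reporting-decay parameter in (0, 1\].
#' @param n_days Collection horizon in days (default 30).
#' @return A `vaers_model_params`.
#' @export
study_params <- function(n, rate_per_100k, rho = 0.85, n_days = 30) {
  stopifnot(n > 0, rate_per_100k >= 0, rho > 0, rho <= 1, n_days >= 0)
  r <- rho^(0:n_days)
  b <- (rate_per_100k / 1e5) / sum(r)
  background_params(P_age = rep(n / 101, 101), r_day = r,
                    b_age = rep(b, 101))
}

#' Expected background adverse-event count
#'
#' The double sum `sum_age P_age * sum_day r_day * b_age`; any
#' vaccine-attributable component of `params` is ignored.
#'
#' @param params A [background_params()].
#' @return A single expected count.
#' @export
expected_events_background <- function(params) {
  stopifnot(inherits(params, "vaers_model_params"))
  sum(params$r_day) * sum(params$P_age * params$b_age)
}

#' Expected adverse-event count under a vaccine
#'
#' `sum_age P_age * sum_day r_day * (v_age + b_age)`; reduces to
#' [expected_events_background()] when `v_age` is zero.
#'
#' @param params A [background_params()].
#' @return A single expected count.
#' @export
expected_events_vaccine <- function(params) {
  stopifnot(inherits(params, "vaers_model_params"))
  sum(params$r_day) * sum(params$P_age * (params$v_age + params$b_age))
}

# run expr with a private RNG stream seeded by `seed` (user RNG untouched);
# with seed NULL, use the current stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate an (age, day) matrix of reported events
#'
#' Independent draws per cell with mean
#' `P_age * r_day * (v_age + b_age)`: Poisson by default (the standard
#' rare-event approximation to the per-person Bernoulli process), or exact
#' per-person binomial (`method = "binomial"`, requiring integer `P_age`).
#' A fixed seed gives bit-identical output and leaves the caller's RNG
#' state untouched.
#'
#' @param params A [background_params()].
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param method `"poisson"` or `"binomial"`.
#' @return A `vaers_sim` list: `counts` (101 x (n_days + 1) integer
#'   matrix, ages in rows) and `total`.
#' @export
simulate_counts <- function(params, seed = NULL,
                            method = c("poisson", "binomial")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "vaers_model_params"))
  n_age <- length(params$P_age)
  n_day <- length(params$r_day)
  rate_age <- params$b_age + params$v_age

  counts <- .with_seed(seed, {
    if (method == "poisson") {
      mu <- outer(params$P_age * rate_age, params$r_day)
      matrix(stats::rpois(n_age * n_day, mu), nrow = n_age)
    } else {
      if (any(params$P_age != round(params$P_age))) {
        stop("binomial mode needs integer P_age", call. = FALSE)
      }
      p_cell <- outer(rate_age, params$r_day)
      size <- rep(as.integer(params$P_age), times = n_day)
      matrix(stats::rbinom(n_age * n_day, size, as.vector(p_cell)),
             nrow = n_age)
    }
  })
  dimnames(counts) <- list(age = 0:(n_age - 1), day = 0:(n_day - 1))
  structure(list(counts = counts, total = sum(counts)),
            class = "vaers_sim")
}

#' @export
print.vaers_sim <- function(x, ...) {
  cat("Simulated adverse-event counts:", x$total, "events over",
      nrow(x$counts), "ages x", ncol(x$counts), "days\n")
  invisible(x)
}

#' Cross-vaccine homogeneity test
#'
#' Pearson chi-squared test of independence on the K x 2 table of cases
#' versus non-cases per vaccine stratum (df = K - 1, no continuity
#' correction). Rejection means the reporting frequencies are not
#' exchangeable across vaccines, i.e. the data are inconsistent with a
#' shared background-only rate.
#'
#' @param case_counts Case counts per stratum (length K >= 2).
#' @param denominators Reports with symptoms per stratum, all > 0.
#' @return A `vaers_test` list (`statistic`, `df`, `p_value`).
#' @export
homogeneity_test <- function(case_counts, denominators) {
  stopifnot(length(case_counts) >= 2,
            length(case_counts) == length(denominators))
  if (any(denominators <= 0)) {
    stop("all denominators must be positive", call. = FALSE)
  }
  if (any(case_counts < 0) || any(case_counts > denominators)) {
    stop("case counts must lie in [0, denominator]", call. = FALSE)
  }
  k <- length(case_counts)
  if (sum(case_counts) == 0 || sum(case_counts) == sum(denominators)) {
    # degenerate margin: all strata identical in the tested dimension
    res <- list(statistic = 0, df = k - 1L, p_value = 1)
  } else {
    tab <- cbind(cases = case_counts,
                 non_cases = denominators - case_counts)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    res <- list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                p_value = ht$p.value)
  }
  structure(c(list(stratum = NA_character_), res,
              list(expected = NULL, expected_warning = FALSE,
                   method = "homogeneity")),
            class = "vaers_test")
}

#' Rejection-rate curve for the homogeneity test
#'
#' Monte-Carlo operationalization of the background-only versus
#' vaccine-augmented comparison. For each excess scale `v` in `v_grid`,
#' strata are simulated from the expected-count model: every stratum draws
#' its case count as Poisson with mean given by the model, with stratum 1's
#' vaccine-attributable rate set to `v` times the background rate
#' (`v = 0` is the background-only null, so its rejection rate estimates
#' the type-I error). Denominators are the stratum population
#' `sum(P_age)`.
#'
#' @param base_params A [background_params()] describing one background
#'   stratum (e.g. from [study_params()]).
#' @param v_grid Non-negative excess scales (multiples of the background
#'   rate) for stratum 1.
#' @param n_reps Replicates per grid point (>= 100).
#' @param alpha Test level (default 0.05).
#' @param seed Integer seed (or `NULL`).
#' @param n_strata Number of strata (default 10).
#' @return A data frame: `v_scale`, `rejection_rate`, `n_reps`.
#' @export
hypothesis_power_curve <- function(base_params, v_grid, n_reps = 1000,
                                   alpha = 0.05, seed = NULL,
                                   n_strata = 10) {
  stopifnot(inherits(base_params, "vaers_model_params"),
            n_reps >= 100, n_strata >= 2, all(v_grid >= 0))
  e_bg <- expected_events_background(base_params)
  denom <- sum(base_params$P_age)

  rates <- .with_seed(seed, vapply(v_grid, function(v) {
    e1 <- (1 + v) * e_bg  # v_age = v * b_age scales the expectation linearly
    rej <- 0L
    for (i in seq_len(n_reps)) {
      cases <- c(stats::rpois(1, e1), stats::rpois(n_strata - 1, e_bg))
      cases <- pmin(cases, denom)
      ht <- homogeneity_test(cases, rep(denom, n_strata))
      if (ht$p_value < alpha) rej <- rej + 1L
    }
    rej / n_reps
  }, numeric(1)))

  data.frame(v_scale = v_grid, rejection_rate = rates, n_reps = n_reps)
}
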