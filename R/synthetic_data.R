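# Synthetic VAERS generator: emits file triplets in the exact three-file
# dialect with a sidecar ground truth, so the whole pipeline is testable
# with no download. Reports are drawn from the vaccine-augmented
# expected-count model: each report is a case with probability
# (background + excess)/100,000 for its primary vaccine; onset days follow
# a truncated geometric law P(day = d) proportional to rho^d, the
# reporting-bias decay of the model. The truth is written beside the data
# files, never inside them, so the pipeline cannot read its own answers.

#' Configuration for the synthetic VAERS generator
#'
#' Defaults emulate the study conditions of the early-childhood vasculitis
#' tabulation: per-vaccine report volumes in the thousands, a
#' Kawasaki-disease background of 20 per 100,000 reports, per-vaccine excess
#' rates spanning the observed range from a few tens to a few thousand per
#' 100,000, ages 0--5, geometric onset decay, and realistic missingness
#' (about 8% of ages and 30% of onset days blank, the blank-onset share of
#' published onset tabulations).
#'
#' @param vaccine_specs Data frame with columns `code`, `n_reports`,
#'   `age_min`, `age_max` (uniform age draw), `background_rate_per_100k`,
#'   `excess_rate_per_100k`.
#' @param case_category Category name the planted cases belong to
#'   (default `"KD"`); its exact preferred term is taken from `categories`.
#' @param categories Category definitions (default [vaers_categories()]).
#' @param onset_decay Geometric onset parameter rho in (0, 1\].
#' @param max_onset_day Truncation horizon for onset days (default 30).
#' @param p_missing_age,p_missing_onset,p_coadmin,p_no_symptom
#'   Probabilities of a blank age, blank onset day, a co-administered
#'   second vaccine, and a report with no symptom row at all.
#' @param decoy_terms Filler preferred terms; includes the superstring
#'   decoy `"Cutaneous vasculitis"` so substring matching is exercised.
#' @param symptom_lambda,symptom_max The number of terms per report is
#'   `1 + min(rpois(lambda), symptom_max - 1)`; `symptom_max > 5` forces
#'   continuation rows.
#' @param year Synthetic year used in file names and report ids.
#' @param seed Integer seed (or `NULL`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(vaccine_specs = NULL,
                       case_category = "KD",
                       categories = vaers_categories(),
                       onset_decay = 0.85,
                       max_onset_day = 30,
                       p_missing_age = 0.08,
                       p_missing_onset = 0.30,
                       p_coadmin = 0.15,
                       p_no_symptom = 0.02,
                       decoy_terms = c("Pyrexia", "Rash", "Urticaria",
                                       "Vomiting", "Diarrhoea", "Headache",
                                       "Injection site erythema",
                                       "Cutaneous vasculitis"),
                       symptom_lambda = 2, symptom_max = 8,
                       year = 2019, seed = NULL) {
  if (is.null(vaccine_specs)) {
    vaccine_specs <- data.frame(
      code = c("MENB", "PNC13", "HIBV", "MMR", "DTP", "UNK"),
      n_reports = c(2000, 2000, 2000, 2000, 2000, 1000),
      age_min = 0, age_max = 6,
      background_rate_per_100k = 20,
      excess_rate_per_100k = c(3242, 661, 218, 88, 31, 0),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("code", "n_reports", "age_min", "age_max",
                  "background_rate_per_100k", "excess_rate_per_100k")
                %in% names(vaccine_specs)),
            all(vaccine_specs$n_reports >= 0),
            all(vaccine_specs$background_rate_per_100k >= 0),
            all(vaccine_specs$excess_rate_per_100k >= 0),
            onset_decay > 0, onset_decay <= 1,
            all(c(p_missing_age, p_missing_onset, p_coadmin,
                  p_no_symptom) >= 0),
            all(c(p_missing_age, p_missing_onset, p_coadmin,
                  p_no_symptom) <= 1),
            symptom_max >= 1)
  case_term <- categories[[case_category]]$terms[1]
  if (is.null(case_term)) {
    stop("case_category '", case_category, "' not found in categories",
         call. = FALSE)
  }
  structure(list(vaccine_specs = vaccine_specs,
                 case_category = case_category, case_term = case_term,
                 onset_decay = onset_decay, max_onset_day = max_onset_day,
                 p_missing_age = p_missing_age,
                 p_missing_onset = p_missing_onset,
                 p_coadmin = p_coadmin, p_no_symptom = p_no_symptom,
                 decoy_terms = decoy_terms,
                 symptom_lambda = symptom_lambda, symptom_max = symptom_max,
                 year = year, seed = seed),
            class = "sim_config")
}

# draw an onset day with P(d) proportional to rho^d on 0..max_day
.draw_onset <- function(n, rho, max_day) {
  days <- 0:max_day
  sample(days, n, replace = TRUE, prob = rho^days)
}

# write one symptom block (possibly several continuation rows of <= 5)
.symptom_rows <- function(id, terms) {
  if (length(terms) == 0) return(NULL)
  chunks <- split(terms, ceiling(seq_along(terms) / 5))
  do.call(rbind, lapply(chunks, function(ch) {
    row <- c(ch, rep("", 5 - length(ch)))
    data.frame(VAERS_ID = id,
               SYMPTOM1 = row[1], SYMPTOMVERSION1 = "26.0",
               SYMPTOM2 = row[2], SYMPTOMVERSION2 = "26.0",
               SYMPTOM3 = row[3], SYMPTOMVERSION3 = "26.0",
               SYMPTOM4 = row[4], SYMPTOMVERSION4 = "26.0",
               SYMPTOM5 = row[5], SYMPTOMVERSION5 = "26.0",
               stringsAsFactors = FALSE)
  }))
}

.write_triplet <- function(dir, prefix, data_df, sym_df, vax_df) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("VAERSDATA.csv",
                                           "VAERSSYMPTOMS.csv",
                                           "VAERSVAX.csv")))
  utils::write.csv(data_df, paths[1], row.names = FALSE, quote = TRUE)
  utils::write.csv(sym_df, paths[2], row.names = FALSE, quote = TRUE)
  utils::write.csv(vax_df, paths[3], row.names = FALSE, quote = TRUE)
  names(paths) <- c("data", "symptoms", "vax")
  paths
}

# per-vaccine truth from the in-memory report list, with the same
# attribution rules the tabulation uses (one count per distinct code)
.per_vaccine_truth <- function(reports) {
  codes <- sort(unique(unlist(reports$codes)))
  out <- data.frame(
    code = codes,
    case_count = vapply(codes, function(cd) {
      sum(vapply(seq_along(reports$codes), function(i) {
        cd %in% reports$codes[[i]] && reports$is_case[i] &&
          reports$n_terms[i] > 0
      }, logical(1)))
    }, numeric(1)),
    denominator = vapply(codes, function(cd) {
      sum(vapply(seq_along(reports$codes), function(i) {
        cd %in% reports$codes[[i]] && reports$n_terms[i] > 0
      }, logical(1)))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Generate a synthetic VAERS triplet with sidecar ground truth
#'
#' Emits `<year>VAERSDATA.csv`, `<year>VAERSSYMPTOMS.csv` and
#' `<year>VAERSVAX.csv` in the exact dialect [load_vaers_years()] reads,
#' plus a `<year>_truth.json` sidecar with the per-report flags and the
#' per-vaccine case counts and reports-with-symptoms denominators (all-age
#' attribution, one count per distinct vaccine code on a report). Case
#' reports carry the category's exact preferred term; filler reports carry
#' decoys only. Deterministic under a fixed seed.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return A list: `paths` (named file paths including `truth`), `truth`
#'   (the ground-truth list), `dir`.
#' @export
generate_vaers <- function(config, dir = tempfile("vaers_synth")) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$vaccine_specs
  all_codes <- sp$code

  draw <- .with_seed(config$seed, {
    rep_list <- list(id = character(), codes = list(), age = numeric(),
                     onset = integer(), is_case = logical(),
                     n_terms = integer(), terms = list())
    idx <- 0L
    for (v in seq_len(nrow(sp))) {
      n <- sp$n_reports[v]
      if (n == 0) next
      p_case <- (sp$background_rate_per_100k[v] +
                   sp$excess_rate_per_100k[v]) / 1e5
      for (i in seq_len(n)) {
        idx <- idx + 1L
        id <- sprintf("%04d%06d", config$year, idx)
        codes <- sp$code[v]
        if (length(all_codes) > 1 && stats::runif(1) < config$p_coadmin) {
          codes <- c(codes, sample(setdiff(all_codes, codes), 1))
        }
        age <- round(stats::runif(1, sp$age_min[v], sp$age_max[v]), 1)
        if (stats::runif(1) < config$p_missing_age) age <- NA_real_
        onset <- .draw_onset(1, config$onset_decay, config$max_onset_day)
        if (stats::runif(1) < config$p_missing_onset) onset <- NA_integer_
        is_case <- stats::runif(1) < p_case
        n_sym <- 1L + min(stats::rpois(1, config$symptom_lambda),
                          config$symptom_max - 1L)
        terms <- sample(config$decoy_terms,
                        min(n_sym, length(config$decoy_terms)))
        if (is_case) {
          terms <- c(config$case_term, terms[-1])
        } else if (stats::runif(1) < config$p_no_symptom) {
          terms <- character()
        }
        rep_list$id[idx] <- id
        rep_list$codes[[idx]] <- codes
        rep_list$age[idx] <- age
        rep_list$onset[idx] <- onset
        rep_list$is_case[idx] <- is_case
        rep_list$n_terms[idx] <- length(terms)
        rep_list$terms[[idx]] <- terms
      }
    }
    rep_list
  })

  n <- length(draw$id)
  data_df <- data.frame(
    VAERS_ID = draw$id,
    RECVDATE = rep(sprintf("07/01/%d", config$year), n),
    STATE = rep("CA", n),
    AGE_YRS = ifelse(is.na(draw$age), "",
                     vapply(draw$age, function(a) {
                       if (is.na(a)) "" else format(a, trim = TRUE)
                     }, character(1))),
    NUMDAYS = ifelse(is.na(draw$onset), "", as.character(draw$onset)),
    stringsAsFactors = FALSE
  )
  sym_rows <- Filter(Negate(is.null),
                     lapply(seq_len(n), function(i) {
                       .symptom_rows(draw$id[i], draw$terms[[i]])
                     }))
  sym_df <- if (length(sym_rows) > 0) {
    do.call(rbind, c(sym_rows, list(make.row.names = FALSE)))
  } else {
    .symptom_rows("x", "x")[0, ]
  }
  n_vax <- sum(lengths(draw$codes))
  vax_df <- data.frame(
    VAERS_ID = rep(draw$id, lengths(draw$codes)),
    VAX_TYPE = as.character(unlist(draw$codes)),
    VAX_MANU = rep("SYNTHETIC", n_vax),
    VAX_DOSE_SERIES = rep("1", n_vax),
    stringsAsFactors = FALSE
  )

  paths <- .write_triplet(dir, config$year, data_df, sym_df, vax_df)
  truth <- list(
    config = list(case_category = config$case_category,
                  case_term = config$case_term,
                  onset_decay = config$onset_decay,
                  seed = config$seed),
    n_reports = n,
    per_report = data.frame(vaers_id = draw$id,
                            is_case = draw$is_case,
                            age_years = draw$age,
                            onset_day = draw$onset,
                            n_terms = draw$n_terms,
                            stringsAsFactors = FALSE),
    per_vaccine = .per_vaccine_truth(draw)
  )
  truth_path <- file.path(dir, sprintf("%d_truth.json", config$year))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  list(paths = c(paths, truth = truth_path), truth = truth, dir = dir)
}

#' A hand-written 12-report fixture
#'
#' Small deterministic triplet covering the corner cases of the dialect:
#' a multi-vaccine report, a 7-term report split over continuation rows, a
#' duplicated term across continuation rows, missing age, missing onset
#' day, a report with no symptom rows, the `"UNK"` vaccine code, and the
#' `"Cutaneous vasculitis"` superstring decoy. It plants exactly 3
#' Kawasaki-disease cases and 3 exact-term vasculitis cases (4 under
#' substring matching, which also catches the decoy).
#'
#' @param dir Output directory (created if needed).
#' @return As [generate_vaers()]: `paths`, `truth`, `dir`.
#' @export
fixture_small <- function(dir = tempfile("vaers_fixture")) {
  yr <- 2001
  id <- sprintf("%04d%06d", yr, 1:12)
  data_df <- data.frame(
    VAERS_ID = id,
    RECVDATE = sprintf("06/15/%d", yr),
    STATE = "TX",
    AGE_YRS = c("0.5", "2", "", "30", "45", "1", "25", "4", "6", "3",
                "0.2", "17"),
    NUMDAYS = c("0", "1", "", "5", "2", "0", "3", "10", "0", "", "1",
                "30"),
    stringsAsFactors = FALSE
  )
  sym <- list(
    list(id[1], c("Kawasaki's disease", "Pyrexia")),
    list(id[2], "Kawasaki's disease"),
    list(id[3], c("Kawasaki's disease", "Rash")),
    list(id[4], "Vasculitis"),
    list(id[5], c("Vasculitis", "Headache")),
    list(id[6], "Vasculitis"),
    list(id[7], "Cutaneous vasculitis"),
    list(id[8], c("Pyrexia", "Rash", "Headache", "Vomiting", "Urticaria",
                  "Nausea", "Diarrhoea")),
    # id[9]: no symptom rows at all
    list(id[10], "Pyrexia"),
    list(id[10], c("Pyrexia", "Chills")),  # duplicate term, extra row
    list(id[11], "Injection site erythema"),
    list(id[12], "Rash")
  )
  sym_df <- do.call(rbind, c(
    lapply(sym, function(s) .symptom_rows(s[[1]], s[[2]])),
    list(make.row.names = FALSE)
  ))
  vax <- list(
    list(id[1], "MENB"), list(id[2], c("PNC13", "HIBV")),
    list(id[3], "UNK"), list(id[4], "COVID19"), list(id[5], "FLU3"),
    list(id[6], "MMR"), list(id[7], "COVID19"), list(id[8], "DTAP"),
    list(id[9], "HEP"), list(id[10], "PNC"), list(id[11], "MENB"),
    list(id[12], "VARCEL")
  )
  vax_df <- data.frame(
    VAERS_ID = unlist(lapply(vax, function(v) rep(v[[1]], length(v[[2]])))),
    VAX_TYPE = unlist(lapply(vax, `[[`, 2)),
    VAX_MANU = "SYNTHETIC",
    VAX_DOSE_SERIES = "1",
    stringsAsFactors = FALSE
  )
  paths <- .write_triplet(dir, yr, data_df, sym_df, vax_df)
  truth <- list(
    n_reports = 12L,
    kd_cases_exact = id[1:3],
    vasculitis_cases_exact = id[4:6],
    vasculitis_cases_substring = id[c(4:6, 7)],
    no_symptom_reports = id[9],
    multi_vaccine_reports = id[2],
    pooled_term_count = stats::setNames(7L, id[8])
  )
  list(paths = paths, truth = truth, dir = dir)
}
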