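# End-to-end orchestration: one call produces the full table set plus the
# background-rate screen, with a manifest recording the configuration so a
# rerun reproduces the outputs byte for byte. Logging goes to stderr via
# message(); output files carry only machine-readable content.

.require_fields <- function(config, fields, where) {
  miss <- setdiff(fields, names(config))
  if (length(miss) > 0) {
    stop(where, " config is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

#' Run the full tabulation pipeline on a VAERS directory
#'
#' Loads the year range, extracts cases, and writes the per-vaccine
#' frequency table, onset-day table, age-count table, per-age frequency
#' table, the background-rate screen, and a `manifest.json` recording the
#' configuration (with an MD5 hash) and output row counts.
#'
#' @param config A list with required fields `data_root`, `year_start`,
#'   `year_end`, `output_dir`, and optional `include_nondomestic` (FALSE),
#'   `match_mode` ("exact"), `category` ("KD"), `min_cases` (5),
#'   `denominator_ages` (c(0, 5)), `numerator_ages` (NULL), `max_day` (30),
#'   `max_age` (20), `age_freq_category` ("KD, MIS, MIS-A, or MIS-C"),
#'   `age_freq_vaccine` ("COVID19"), `age_freq_convention` ("truncate"),
#'   `ages` (0:30), `background_rate_per_100k` (20), `alpha` (0.05),
#'   `exclude_codes` ("UNK"). A YAML file path is also accepted.
#' @return Named character vector of output paths, invisibly.
#' @export
run_tables <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  .require_fields(config, c("data_root", "year_start", "year_end",
                            "output_dir"), "run_tables")
  cfg <- utils::modifyList(list(
    include_nondomestic = FALSE, match_mode = "exact", category = "KD",
    min_cases = 5, denominator_ages = c(0, 5), numerator_ages = NULL,
    max_day = 30, max_age = 20,
    age_freq_category = "KD, MIS, MIS-A, or MIS-C",
    age_freq_vaccine = "COVID19", age_freq_convention = "truncate",
    ages = 0:30, background_rate_per_100k = 20, alpha = 0.05,
    exclude_codes = "UNK"
  ), config)

  reports <- load_vaers_years(cfg$data_root, cfg$year_start, cfg$year_end,
                              include_nondomestic = cfg$include_nondomestic)
  message("loaded ", nrow(reports), " reports")
  cases <- extract_cases(reports, policy = term_policy(cfg$match_mode))

  freq <- vaccine_frequency_table(
    reports, cases, cfg$category, min_cases = cfg$min_cases,
    denominator_ages = cfg$denominator_ages,
    numerator_ages = cfg$numerator_ages
  )
  if (nrow(freq) == 0) {
    warning("no vaccine reaches min_cases = ", cfg$min_cases, call. = FALSE)
  }
  onset_codes <- if (nrow(freq) > 0) {
    freq$stratum[order(-freq$case_count)][seq_len(min(9, nrow(freq)))]
  } else {
    character()
  }
  onset <- onset_table(reports, cases, cfg$category, onset_codes,
                       max_day = cfg$max_day)
  ages_tab <- age_table(reports, cases, max_age = cfg$max_age)
  age_freq <- age_frequency_table(reports, cases, cfg$age_freq_category,
                                  cfg$age_freq_vaccine,
                                  convention = cfg$age_freq_convention,
                                  ages = cfg$ages)
  screen <- if (nrow(freq) > 0) {
    evaluate_all_vaccines(freq,
                          background_rate(cfg$background_rate_per_100k),
                          alpha = cfg$alpha,
                          exclude_codes = cfg$exclude_codes)
  } else {
    NULL
  }

  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- c(
    vaccine_frequency = write_table_csv(
      freq, file.path(cfg$output_dir, "vaccine_frequency.csv")),
    onset = write_table_csv(onset, file.path(cfg$output_dir, "onset.csv")),
    age_counts = write_table_csv(
      ages_tab, file.path(cfg$output_dir, "age_counts.csv")),
    age_frequency = write_table_csv(
      age_freq, file.path(cfg$output_dir, "age_frequency.csv"))
  )
  if (!is.null(screen)) {
    out["inference"] <- write_screen_csv(
      screen, file.path(cfg$output_dir, "inference.csv"))
  }

  cfg_path <- file.path(cfg$output_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  manifest <- list(
    config = cfg,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_reports = nrow(reports),
    rows = list(vaccine_frequency = nrow(freq), onset = nrow(onset),
                age_counts = nrow(ages_tab), age_frequency = nrow(age_freq),
                inference = if (is.null(screen)) 0L else nrow(screen))
  )
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  out["manifest"] <- manifest_path
  message("wrote ", length(out), " files to ", cfg$output_dir)
  invisible(out)
}

#' Run the homogeneity power/type-I simulation study
#'
#' Wraps [hypothesis_power_curve()]; writes `power_curve.csv` and a short
#' human-readable `power_summary.txt`.
#'
#' @param config A list (or YAML path) with required fields `seed` and
#'   `output_dir`, and optional `v_grid` (c(0, 1, 4, 9)), `n_reps` (1000),
#'   `alpha` (0.05), `n_strata` (10), `n_per_stratum` (5000),
#'   `rate_per_100k` (350), `rho` (0.85), `n_days` (30).
#' @return Named character vector of output paths, invisibly.
#' @export
run_simulation <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  .require_fields(config, c("seed", "output_dir"), "run_simulation")
  cfg <- utils::modifyList(list(
    v_grid = c(0, 1, 4, 9), n_reps = 1000, alpha = 0.05, n_strata = 10,
    n_per_stratum = 5000, rate_per_100k = 350, rho = 0.85, n_days = 30
  ), config)

  params <- study_params(cfg$n_per_stratum, cfg$rate_per_100k,
                         rho = cfg$rho, n_days = cfg$n_days)
  curve <- hypothesis_power_curve(params, cfg$v_grid, n_reps = cfg$n_reps,
                                  alpha = cfg$alpha, seed = cfg$seed,
                                  n_strata = cfg$n_strata)

  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  csv_path <- file.path(cfg$output_dir, "power_curve.csv")
  utils::write.csv(curve, csv_path, row.names = FALSE)
  txt_path <- file.path(cfg$output_dir, "power_summary.txt")
  lines <- c(
    sprintf("Homogeneity-test rejection rates (%d strata of %d, %g/100k, alpha %g, %d reps, seed %d)",
            cfg$n_strata, cfg$n_per_stratum, cfg$rate_per_100k, cfg$alpha,
            cfg$n_reps, cfg$seed),
    sprintf("  excess %gx background -> rejection rate %.3f%s",
            curve$v_scale, curve$rejection_rate,
            ifelse(curve$v_scale == 0, "  (type-I error)", ""))
  )
  writeLines(lines, txt_path)
  invisible(c(power_curve = csv_path, power_summary = txt_path))
}
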