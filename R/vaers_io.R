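# Reading and joining the VAERS three-file CSV exports.
#
# VAERS distributes each year as VAERSDATA / VAERSSYMPTOMS / VAERSVAX comma-
# separated files joined on VAERS_ID. Real exports are Windows-1252, not
# UTF-8, so decoding is sniffed per file.

# Read a VAERS-dialect CSV as all-character columns with upper-cased header.
# `required` names columns that must be present (case-insensitive).
.read_vaers_csv <- function(path, required) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  n <- file.info(path)$size
  txt <- rawToChar(readBin(path, "raw", n = n))
  # real exports are cp1252; fall back to it whenever the bytes are not UTF-8
  if (!validUTF8(txt)) {
    txt <- iconv(txt, from = "latin1", to = "UTF-8")
  }
  df <- utils::read.csv(
    text = txt, colClasses = "character", check.names = FALSE,
    stringsAsFactors = FALSE, na.strings = NULL, blank.lines.skip = TRUE
  )
  names(df) <- toupper(trimws(names(df)))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("VAERS file ", basename(path), " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

# numeric parse in which anything unparseable becomes NA, never 0
.parse_num <- function(x) {
  suppressWarnings(as.numeric(trimws(x)))
}

#' Read a VAERSDATA file
#'
#' Parses one per-report VAERS data file. Numeric fields that fail to parse
#' become missing (`NA`), never zero; ages outside \[0, 120\] years and
#' negative onset intervals are treated as missing. Row order is preserved,
#' and a `VAERS_ID` duplicated within the file is kept once (first
#' occurrence) with a warning.
#'
#' @param path Path to a `*VAERSDATA.csv` file. Must contain (at least, and
#'   case-insensitively) the columns `VAERS_ID`, `AGE_YRS` and `NUMDAYS`.
#' @return A data frame with one row per report: `vaers_id`,
#'   `received_date` (`Date` or `NA`), `age_years`, `onset_interval_days`,
#'   plus every remaining source column passed through as character.
#' @export
read_vaers_data <- function(path) {
  df <- .read_vaers_csv(path, c("VAERS_ID", "AGE_YRS", "NUMDAYS"))
  id <- trimws(df[["VAERS_ID"]])
  if (anyDuplicated(id)) {
    warning("duplicated VAERS_ID in ", basename(path),
            ": keeping first occurrence of ",
            sum(duplicated(id)), " duplicate row(s)", call. = FALSE)
    keep <- !duplicated(id)
    df <- df[keep, , drop = FALSE]
    id <- id[keep]
  }
  age <- .parse_num(df[["AGE_YRS"]])
  age[!is.na(age) & (age < 0 | age > 120)] <- NA_real_
  onset <- .parse_num(df[["NUMDAYS"]])
  onset[!is.na(onset) & onset < 0] <- NA_real_
  recv <- if ("RECVDATE" %in% names(df)) {
    as.Date(trimws(df[["RECVDATE"]]), format = "%m/%d/%Y")
  } else {
    as.Date(rep(NA_character_, nrow(df)))
  }
  extra <- setdiff(names(df), c("VAERS_ID", "AGE_YRS", "NUMDAYS", "RECVDATE"))
  out <- data.frame(
    vaers_id = id,
    received_date = recv,
    age_years = age,
    onset_interval_days = as.integer(onset),
    stringsAsFactors = FALSE
  )
  for (col in extra) out[[col]] <- df[[col]]
  out
}

#' Read a VAERSSYMPTOMS file
#'
#' Each physical row of a VAERS symptom file carries up to five MedDRA
#' preferred terms (`SYMPTOM1`..`SYMPTOM5`); reports with more than five
#' terms span several continuation rows with the same `VAERS_ID`. Empty
#' term cells are dropped, and rows whose five cells are all empty are
#' discarded (their count is kept in the `"empty_rows"` attribute).
#'
#' @param path Path to a `*VAERSSYMPTOMS.csv` file.
#' @return A data frame with one row per physical file row: `vaers_id` and a
#'   list column `terms` of non-empty symptom strings (1--5 per row,
#'   preserved verbatim).
#' @export
read_vaers_symptoms <- function(path) {
  sym_cols <- paste0("SYMPTOM", 1:5)
  df <- .read_vaers_csv(path, c("VAERS_ID", sym_cols))
  id <- trimws(df[["VAERS_ID"]])
  terms <- lapply(seq_len(nrow(df)), function(i) {
    v <- trimws(as.character(df[i, sym_cols]))
    v[nzchar(v)]
  })
  keep <- lengths(terms) > 0
  out <- data.frame(vaers_id = id[keep], stringsAsFactors = FALSE)
  out$terms <- terms[keep]
  attr(out, "empty_rows") <- sum(!keep)
  out
}

#' Read a VAERSVAX file
#'
#' One row per administered vaccine; a report given several vaccines has
#' several rows. Vaccine type codes are upper-cased and trimmed on ingest
#' (VAERS uses e.g. `"MENB"`, `"COVID19"`, `"UNK"` for unknown type).
#'
#' @param path Path to a `*VAERSVAX.csv` file.
#' @return A data frame: `vaers_id`, `vax_type`, plus remaining source
#'   columns passed through.
#' @export
read_vaers_vax <- function(path) {
  df <- .read_vaers_csv(path, c("VAERS_ID", "VAX_TYPE"))
  out <- data.frame(
    vaers_id = trimws(df[["VAERS_ID"]]),
    vax_type = toupper(trimws(df[["VAX_TYPE"]])),
    stringsAsFactors = FALSE
  )
  for (col in setdiff(names(df), c("VAERS_ID", "VAX_TYPE"))) {
    out[[col]] <- df[[col]]
  }
  out[nzchar(out$vax_type), , drop = FALSE]
}

#' Join the three VAERS files into per-report records
#'
#' Left join anchored on the data file: every data row yields exactly one
#' joined report. Symptom terms are pooled over all (continuation) rows of a
#' report and de-duplicated; vaccine codes likewise. Symptom or vaccine rows
#' whose `vaers_id` has no data row are counted in the `"orphans"` attribute
#' rather than silently dropped. A report with no symptom rows is retained
#' with an empty term set (it is excluded from reports-with-symptoms
#' denominators downstream, not from the data).
#'
#' @param data Data frame from [read_vaers_data()].
#' @param symptoms Data frame from [read_vaers_symptoms()].
#' @param vax Data frame from [read_vaers_vax()].
#' @return A `vaers_reports` data frame: `vaers_id`, `received_date`,
#'   `age_years`, `onset_interval_days`, `nondomestic`, and list columns
#'   `vaccine_codes` and `symptom_terms`.
#' @export
join_vaers_reports <- function(data, symptoms, vax) {
  ids <- data$vaers_id

  orphan_sym <- sum(!(symptoms$vaers_id %in% ids))
  orphan_vax <- sum(!(vax$vaers_id %in% ids))

  sym_long <- data.frame(
    vaers_id = rep(symptoms$vaers_id, lengths(symptoms$terms)),
    term = as.character(unlist(symptoms$terms, use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  sym_by_id <- split(sym_long$term, factor(sym_long$vaers_id, levels = ids))
  vax_by_id <- split(vax$vax_type, factor(vax$vaers_id, levels = ids))

  out <- data.frame(
    vaers_id = ids,
    received_date = data$received_date,
    age_years = data$age_years,
    onset_interval_days = data$onset_interval_days,
    nondomestic = if (is.null(data$nondomestic)) {
      rep(FALSE, length(ids))
    } else {
      data$nondomestic
    },
    stringsAsFactors = FALSE
  )
  out$vaccine_codes <- lapply(vax_by_id, unique)
  out$symptom_terms <- lapply(sym_by_id, unique)
  class(out) <- c("vaers_reports", "data.frame")
  attr(out, "orphans") <- c(symptoms = orphan_sym, vax = orphan_vax)
  out
}

#' @export
print.vaers_reports <- function(x, ...) {
  n_sym <- sum(lengths(x$symptom_terms) > 0)
  cat("VAERS joined reports:", nrow(x), "reports,",
      n_sym, "with >=1 symptom term\n")
  orph <- attr(x, "orphans")
  if (!is.null(orph) && sum(orph) > 0) {
    cat("  orphan rows ignored: ", orph[["symptoms"]], " symptom, ",
        orph[["vax"]], " vaccine\n", sep = "")
  }
  invisible(x)
}

#' Load and join a range of VAERS years
#'
#' Reads `<YEAR>VAERSDATA.csv`, `<YEAR>VAERSSYMPTOMS.csv` and
#' `<YEAR>VAERSVAX.csv` for each year of the range (plus the
#' `NonDomestic*` triplet when requested), joins each triplet, and
#' concatenates. A report id seen in more than one year is kept once, first
#' year wins; the number dropped is recorded in the `"cross_year_duplicates"`
#' attribute.
#'
#' @param root_dir Directory containing the per-year files.
#' @param year_start,year_end Inclusive year range.
#' @param include_nondomestic Also load the `NonDomestic` triplet; those
#'   reports get `nondomestic = TRUE`.
#' @param missing_year `"skip"` (default) warns and skips a year whose
#'   triplet is incomplete; `"error"` makes that fatal.
#' @return A `vaers_reports` data frame (possibly with zero rows).
#' @export
load_vaers_years <- function(root_dir, year_start, year_end,
                             include_nondomestic = FALSE,
                             missing_year = c("skip", "error")) {
  missing_year <- match.arg(missing_year)
  prefixes <- as.character(seq(year_start, year_end))
  if (include_nondomestic) prefixes <- c(prefixes, "NonDomestic")

  pieces <- list()
  for (pre in prefixes) {
    paths <- file.path(root_dir, paste0(pre, c("VAERSDATA.csv",
                                               "VAERSSYMPTOMS.csv",
                                               "VAERSVAX.csv")))
    if (!all(file.exists(paths))) {
      msg <- paste0("incomplete VAERS triplet for '", pre, "' under ",
                    root_dir)
      if (missing_year == "error") stop(msg, call. = FALSE)
      warning(msg, " - skipped", call. = FALSE)
      next
    }
    d <- read_vaers_data(paths[1])
    d$nondomestic <- rep(identical(pre, "NonDomestic"), nrow(d))
    pieces[[pre]] <- join_vaers_reports(d, read_vaers_symptoms(paths[2]),
                                        read_vaers_vax(paths[3]))
  }

  if (length(pieces) == 0) {
    out <- join_vaers_reports(
      data.frame(vaers_id = character(), received_date = as.Date(character()),
                 age_years = numeric(), onset_interval_days = integer(),
                 stringsAsFactors = FALSE),
      data.frame(vaers_id = character(), terms = I(list())),
      data.frame(vaers_id = character(), vax_type = character(),
                 stringsAsFactors = FALSE)
    )
    attr(out, "cross_year_duplicates") <- 0L
    return(out)
  }

  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  dup <- duplicated(out$vaers_id)
  if (any(dup)) {
    warning(sum(dup), " report id(s) present in more than one year file; ",
            "keeping the first year", call. = FALSE)
    out <- out[!dup, , drop = FALSE]
  }
  class(out) <- c("vaers_reports", "data.frame")
  attr(out, "orphans") <- Reduce(`+`, lapply(pieces, attr, "orphans"))
  attr(out, "cross_year_duplicates") <- sum(dup)
  out
}
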