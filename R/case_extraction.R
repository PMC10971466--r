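# Flagging reports whose symptom terms match the studied adverse-event
# categories. Matching is on MedDRA preferred terms, exact by default:
# a substring policy would sweep "Cutaneous vasculitis" and dozens of other
# distinct preferred terms into "Vasculitis", so substring mode exists only
# as an explicit sensitivity switch.

#' Term-matching policy
#'
#' @param match_mode `"exact"` (default) requires the whole normalized
#'   symptom string to equal the category term; `"substring"` requires only
#'   containment. Normalization is case-folding, trimming, and collapsing of
#'   internal whitespace.
#' @param case_sensitive Keep case distinctions (default `FALSE`).
#' @return A `term_policy` list.
#' @export
term_policy <- function(match_mode = c("exact", "substring"),
                        case_sensitive = FALSE) {
  structure(list(match_mode = match.arg(match_mode),
                 case_sensitive = isTRUE(case_sensitive)),
            class = "term_policy")
}

.normalize_term <- function(x, case_sensitive = FALSE) {
  x <- gsub("[[:space:]]+", " ", trimws(x))
  if (!case_sensitive) x <- tolower(x)
  x
}

#' Match one symptom string against one category term
#'
#' @param symptom Character vector of reported symptom strings.
#' @param term Single category term.
#' @param policy A [term_policy()].
#' @return Logical vector, one element per symptom.
#' @export
match_term <- function(symptom, term, policy = term_policy()) {
  stopifnot(inherits(policy, "term_policy"), length(term) == 1L)
  s <- .normalize_term(symptom, policy$case_sensitive)
  t <- .normalize_term(term, policy$case_sensitive)
  if (policy$match_mode == "exact") {
    s == t
  } else {
    grepl(t, s, fixed = TRUE)
  }
}

.category <- function(name, terms = character(), composite_of = NULL) {
  if (length(terms) == 0 && is.null(composite_of)) {
    stop("category '", name, "' needs terms or composite_of", call. = FALSE)
  }
  list(name = name, terms = terms, composite_of = composite_of)
}

#' The default vasculitis adverse-event categories
#'
#' Six atomic categories, one per searched MedDRA preferred term (the VAERS
#' spelling "Kawasaki's disease", with apostrophe, is the canonical KD
#' term), plus the composite "KD, MIS, MIS-A, or MIS-C" used for the
#' COVID-19 age tabulations. Composites have union semantics: the composite
#' flag is true when any member flag is.
#'
#' @return A named list of category definitions (`name`, `terms`,
#'   `composite_of`).
#' @export
vaers_categories <- function() {
  defs <- list(
    .category("KD", "Kawasaki's disease"),
    .category("MIS", "Multisystem Inflammatory Syndrome"),
    .category("MIS-A", "Multisystem Inflammatory Syndrome in adults"),
    .category("MIS-C", "Multisystem Inflammatory Syndrome in children"),
    .category("HS", "Henoch-Schonlein purpura"),
    .category("Vasculitis", "Vasculitis"),
    .category("KD, MIS, MIS-A, or MIS-C",
              composite_of = c("KD", "MIS", "MIS-A", "MIS-C"))
  )
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}

#' Load category definitions from a YAML or JSON config
#'
#' The config is a list of blocks with `name`, optional `terms`, optional
#' `composite_of`, in the same shape [vaers_categories()] returns.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of category definitions.
#' @export
categories_from_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  defs <- lapply(raw, function(b) {
    .category(b$name, as.character(b$terms %||% character()),
              if (!is.null(b$composite_of)) as.character(b$composite_of))
  })
  names(defs) <- vapply(defs, `[[`, "", "name")
  .check_composites(defs)
  defs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# validate composite references and acyclicity; return topological order
.check_composites <- function(categories) {
  nm <- names(categories)
  order <- character()
  state <- setNames(rep(0L, length(nm)), nm)  # 0 unseen, 1 visiting, 2 done
  visit <- function(n) {
    if (state[[n]] == 1L) {
      stop("cyclic composite category definition at '", n, "'",
           call. = FALSE)
    }
    if (state[[n]] == 2L) return(invisible())
    state[[n]] <<- 1L
    for (m in categories[[n]]$composite_of) {
      if (!m %in% nm) {
        stop("composite '", n, "' references unknown category '", m, "'",
             call. = FALSE)
      }
      visit(m)
    }
    state[[n]] <<- 2L
    order <<- c(order, n)
  }
  for (n in nm) visit(n)
  order
}

#' Flag case reports per adverse-event category
#'
#' One row per report, one logical column per category. A report is one
#' case per category however many of its terms match; reports with no
#' symptom terms get all-false flags; composite flags are the union of
#' their members, computed after the atomic flags.
#'
#' @param reports A `vaers_reports` data frame from [join_vaers_reports()].
#' @param categories Category definitions (default [vaers_categories()]).
#' @param policy A [term_policy()].
#' @return A `case_table` data frame: `vaers_id` plus one logical column per
#'   category.
#' @export
extract_cases <- function(reports, categories = vaers_categories(),
                          policy = term_policy()) {
  topo <- .check_composites(categories)
  out <- data.frame(vaers_id = reports$vaers_id, stringsAsFactors = FALSE)

  norm_terms <- lapply(reports$symptom_terms, .normalize_term,
                       case_sensitive = policy$case_sensitive)

  for (n in topo) {
    cat_def <- categories[[n]]
    if (is.null(cat_def$composite_of)) {
      pats <- .normalize_term(cat_def$terms, policy$case_sensitive)
      flag <- vapply(norm_terms, function(tt) {
        if (length(tt) == 0) return(FALSE)
        if (policy$match_mode == "exact") {
          any(tt %in% pats)
        } else {
          any(vapply(pats, function(p) any(grepl(p, tt, fixed = TRUE)),
                     logical(1)))
        }
      }, logical(1))
    } else {
      member <- as.matrix(out[, cat_def$composite_of, drop = FALSE])
      flag <- rowSums(member) > 0
    }
    out[[n]] <- as.logical(flag)
  }
  # restore the caller's category order
  out <- out[, c("vaers_id", names(categories)), drop = FALSE]
  class(out) <- c("case_table", "data.frame")
  out
}

#' @export
print.case_table <- function(x, ...) {
  counts <- colSums(as.matrix(x[, -1, drop = FALSE]))
  cat("Case table:", nrow(x), "reports\n")
  print(counts)
  invisible(x)
}
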