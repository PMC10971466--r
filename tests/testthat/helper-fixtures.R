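# Shared fixtures built in code at test time.

# write a minimal VAERS triplet from explicit row content; returns dir
write_mini_triplet <- function(data_rows, sym_rows, vax_rows,
                               prefix = "1999", dir = tempfile("mini")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data_rows, file.path(dir, paste0(prefix, "VAERSDATA.csv")),
            row.names = FALSE)
  write.csv(sym_rows, file.path(dir, paste0(prefix, "VAERSSYMPTOMS.csv")),
            row.names = FALSE)
  write.csv(vax_rows, file.path(dir, paste0(prefix, "VAERSVAX.csv")),
            row.names = FALSE)
  dir
}

mini_data <- function(ids, ages = "1", numdays = "0") {
  n <- length(ids)
  data.frame(VAERS_ID = ids, RECVDATE = rep_len("01/02/1999", n),
             STATE = rep_len("CA", n), AGE_YRS = rep_len(ages, n),
             NUMDAYS = rep_len(numdays, n), stringsAsFactors = FALSE)
}

mini_sym <- function(ids, s1 = "Pyrexia", s2 = "", s3 = "", s4 = "",
                     s5 = "") {
  n <- length(ids)
  data.frame(VAERS_ID = ids, SYMPTOM1 = rep_len(s1, n),
             SYMPTOM2 = rep_len(s2, n), SYMPTOM3 = rep_len(s3, n),
             SYMPTOM4 = rep_len(s4, n), SYMPTOM5 = rep_len(s5, n),
             stringsAsFactors = FALSE)
}

mini_vax <- function(ids, type = "MENB") {
  data.frame(VAERS_ID = ids, VAX_TYPE = rep_len(type, length(ids)),
             stringsAsFactors = FALSE)
}

# brute-force double-loop oracle for the expected-count model
brute_force_expected <- function(params, include_vaccine) {
  total <- 0
  for (a in seq_along(params$P_age)) {
    inner <- 0
    for (d in seq_along(params$r_day)) {
      rate <- params$b_age[a] +
        if (include_vaccine) params$v_age[a] else 0
      inner <- inner + params$r_day[d] * rate
    }
    total <- total + params$P_age[a] * inner
  }
  total
}

# random valid model parameters for property tests
random_params <- function() {
  background_params(
    P_age = runif(101, 0, 5000),
    r_day = runif(sample(1:40, 1)),
    b_age = runif(101, 0, 0.3),
    v_age = runif(101, 0, 0.3)
  )
}
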