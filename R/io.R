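# Delimited-text cohort serialization with validation.
#
# A cohort is two (optionally three) comma-separated files with header rows
# and a leading "# seed: N" comment:
#   patients:      patient_id, arm, weight_kg, stratum
#   observations:  patient_id, cycle, study_day, anc
#   temperatures:  patient_id, cycle, study_day, temp_c   (optional)
# Day numbering is 1-based with Day 1 = chemotherapy day.

#' Write a cohort to delimited text files
#'
#' @param cohort An `anc_cohort`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix; files are `<prefix>_patients.csv`,
#'   `<prefix>_observations.csv` and, when temperature events exist,
#'   `<prefix>_temperatures.csv`.
#' @return Invisibly, the named character vector of paths written.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "anc_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  header <- if (!is.null(cohort$seed)) sprintf("# seed: %d", cohort$seed) else "# seed: NA"
  paths <- c(patients = file.path(dir, paste0(prefix, "_patients.csv")),
             observations = file.path(dir, paste0(prefix, "_observations.csv")))
  write_one <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  write_one(cohort$patients, paths[["patients"]])
  write_one(cohort$observations, paths[["observations"]])
  if (nrow(cohort$temperatures) > 0L) {
    paths <- c(paths, temperatures = file.path(dir, paste0(prefix, "_temperatures.csv")))
    write_one(cohort$temperatures, paths[["temperatures"]])
  }
  invisible(paths)
}

# Reads a csv with leading '#' comments; returns df plus the file line number
# of each data row for error messages.
read_commented_csv <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  n_comment <- 0L
  while (n_comment < length(raw) && startsWith(raw[n_comment + 1L], "#")) {
    n_comment <- n_comment + 1L
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "))
  }
  attr(df, "line_of_row") <- n_comment + 1L + seq_len(nrow(df))
  df
}

#' Read and validate a cohort from delimited text files
#'
#' Rows with negative ANC or duplicate (patient, cycle, day) keys are rejected
#' with messages naming the offending file line; observations out of day order
#' are accepted, sorted, and flagged with a warning.
#'
#' @param patients_file,observations_file,temperatures_file Paths as written
#'   by [write_cohort()]; `temperatures_file` may be `NULL`.
#' @return An `anc_cohort`.
#' @export
read_cohort <- function(patients_file, observations_file,
                        temperatures_file = NULL) {
  pat <- read_commented_csv(patients_file,
                            c("patient_id", "arm", "weight_kg", "stratum"))
  obs <- read_commented_csv(observations_file,
                            c("patient_id", "cycle", "study_day", "anc"))
  pat_lines <- attr(pat, "line_of_row")
  obs_lines <- attr(obs, "line_of_row")

  if (any(!is.finite(pat$weight_kg) | pat$weight_kg <= 0)) {
    bad <- which(!is.finite(pat$weight_kg) | pat$weight_kg <= 0)[1L]
    stop(patients_file, " line ", pat_lines[bad],
         ": weight_kg must be positive")
  }
  if (anyDuplicated(pat$patient_id)) {
    bad <- which(duplicated(pat$patient_id))[1L]
    stop(patients_file, " line ", pat_lines[bad], ": duplicate patient_id ",
         pat$patient_id[bad])
  }
  if (!is.numeric(obs$study_day) || !is.numeric(obs$anc)) {
    stop(observations_file, ": study_day and anc must be numeric")
  }
  if (any(obs$anc < 0)) {
    bad <- which(obs$anc < 0)[1L]
    stop(observations_file, " line ", obs_lines[bad], ": negative ANC")
  }
  key <- paste(obs$patient_id, obs$cycle, obs$study_day, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1L]
    stop(observations_file, " line ", obs_lines[bad],
         ": duplicate (patient, cycle, day) record for ", obs$patient_id[bad],
         " cycle ", obs$cycle[bad], " day ", obs$study_day[bad])
  }
  unknown <- setdiff(unique(obs$patient_id), pat$patient_id)
  if (length(unknown)) {
    stop(observations_file, ": observations for patient(s) absent from ",
         patients_file, ": ", paste(unknown, collapse = ", "))
  }
  grp <- paste(obs$patient_id, obs$cycle, sep = "\r")
  unsorted_within <- any(vapply(split(obs$study_day, grp), is.unsorted,
                                logical(1)))
  if (unsorted_within) {
    warning(observations_file, ": observations out of day order; sorted")
    obs <- obs[order(obs$patient_id, obs$cycle, obs$study_day), , drop = FALSE]
    rownames(obs) <- NULL
  }

  temps <- NULL
  if (!is.null(temperatures_file)) {
    temps <- read_commented_csv(temperatures_file,
                                c("patient_id", "cycle", "study_day", "temp_c"))
    attr(temps, "line_of_row") <- NULL
  }
  attr(pat, "line_of_row") <- NULL
  attr(obs, "line_of_row") <- NULL

  seed <- NA_integer_
  first <- readLines(patients_file, n = 1L)
  m <- regmatches(first, regexec("^# seed: (-?[0-9]+)", first))[[1L]]
  if (length(m) == 2L) seed <- as.integer(m[2L])
  new_cohort(pat, obs, temps, seed = if (is.na(seed)) NULL else seed)
}
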