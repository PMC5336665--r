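# Participant record schema and CSV round-trip.
#
# A cohort is a plain data.frame, one row per participant, wide format:
# raw test scores appear as "<test>_w3" / "<test>_w4" columns.  Tri-state
# (yes/no/unknown) fields are character vectors with values "yes", "no" or
# NA; in files they are written as "yes"/"no"/"" so that unknown stays
# distinguishable from no.

# Informant behaviour endorsements: the first four index social/behavioural
# change, the last three everyday praxis and object recognition / topographic
# orientation.
SOCIAL_FLAGS <- c("behave_out_of_character", "unaware_others_feelings",
                  "less_social_participation", "lost_skills_hobbies")
PRAXIS_FLAGS <- c("difficulty_familiar_tasks", "difficulty_familiar_tools",
                  "lost_in_familiar_places")
BEHAVIOR_FLAGS <- c(SOCIAL_FLAGS, PRAXIS_FLAGS)
DEXQ_COLS  <- paste0("dexq_item", c(9, 11, 13, 20))
BAYER_ITEM_COLS <- paste0("bayer_item", c(2, 4, 11), "_difficulty")

# Informant-sourced fields, all of which must be missing/unknown when
# informant_available is FALSE.
INFORMANT_COLS <- c("iqcode_mean", "bayer_iadl_mean", BAYER_ITEM_COLS,
                    DEXQ_COLS, BEHAVIOR_FLAGS, "informant_worsening",
                    "doctor_consult_cognition", "history_psychosis",
                    "onset_months_ago", "delirium_signs",
                    "delirium_duration_months")

#' Column schema for a cohort data frame
#'
#' Returns the data dictionary implied by a battery: every column name in
#' canonical order together with its type (`character`, `integer`, `numeric`,
#' `tristate`, `logical`, `factor`-like enumerations) and, where applicable,
#' its valid range.
#'
#' @param battery an `ncd_battery`.
#' @return data.frame with columns `name`, `type`, `min`, `max`.
#' @export
cohort_schema <- function(battery = default_battery()) {
  score_cols <- as.vector(t(outer(battery$tests, c("_w3", "_w4"), paste0)))
  col <- function(name, type, min = NA, max = NA) {
    data.frame(name = name, type = type, min = min, max = max)
  }
  rbind(
    col("participant_id", "character"),
    col("sex", "sex"),
    col("education_years", "integer", 0, 40),
    col("age_years", "integer", 0, 120),
    col(score_cols, "numeric"),
    col("mmse_w3", "integer", 0, 30),
    col("mmse_w4", "integer", 0, 30),
    col("macq_total", "integer", 7, 35),
    col("phq9_total", "integer", 0, 27),
    col("hrs_iadl_memory_problem", "tristate"),
    col("needs_care_help", "tristate"),
    col("informant_available", "logical"),
    col("iqcode_mean", "numeric", 1, 5),
    col("bayer_iadl_mean", "numeric", 1, 10),
    col(BAYER_ITEM_COLS, "tristate"),
    col(DEXQ_COLS, "integer", 0, 4),
    col(BEHAVIOR_FLAGS, "tristate"),
    col("informant_worsening", "tristate"),
    col("doctor_consult_cognition", "tristate"),
    col("history_psychosis", "tristate"),
    col("prior_path_diagnosis", "prior"),
    col("onset_months_ago", "numeric", 0, Inf),
    col("delirium_signs", "tristate"),
    col("delirium_duration_months", "numeric", 0, Inf))
}

#' Validate a cohort data frame against the record schema
#'
#' Checks column presence, types, value ranges (e.g. MMSE in 0--30, PHQ-9 in
#' 0--27, IQCODE in 1--5, MAC-Q in 7--35), enumerated values, and the
#' informant invariant: when `informant_available` is `FALSE` every
#' informant-sourced field must be missing/unknown.  Errors name the
#' offending row and field.
#'
#' @param cohort data.frame, one row per participant.
#' @param battery an `ncd_battery`.
#' @return the cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort, battery = default_battery()) {
  schema <- cohort_schema(battery)
  missing_cols <- setdiff(schema$name, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(cohort), schema$name)
  if (length(extra) > 0) {
    stop("unknown columns (not in the battery/data dictionary): ",
         paste(extra, collapse = ", "))
  }
  bad <- function(rows, fieldname) {
    if (any(rows)) {
      stop(sprintf("invalid value for '%s' in row(s) %s", fieldname,
                   paste(utils::head(which(rows), 5), collapse = ", ")))
    }
  }
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]; type <- schema$type[i]
    x <- cohort[[nm]]
    switch(type,
      numeric = , integer = {
        if (!is.numeric(x)) stop("column '", nm, "' must be numeric")
        if (type == "integer") bad(!is.na(x) & x != round(x), nm)
        if (!is.na(schema$min[i])) {
          bad(!is.na(x) & (x < schema$min[i] | x > schema$max[i]), nm)
        }
      },
      tristate = bad(!is.na(x) & !x %in% c("yes", "no"), nm),
      sex = bad(is.na(x) | !x %in% c("male", "female"), nm),
      prior = bad(is.na(x) | !x %in% c("none", "mci_like", "dementia"), nm),
      logical = {
        if (!is.logical(x)) stop("column '", nm, "' must be logical")
        bad(is.na(x), nm)
      },
      character = bad(is.na(x) | grepl(",", x), nm))
  }
  no_inf <- !cohort$informant_available
  if (any(no_inf)) {
    for (nm in INFORMANT_COLS) {
      bad_rows <- no_inf & !is.na(cohort[[nm]])
      if (any(bad_rows)) {
        stop(sprintf(
          "informant field '%s' present in row(s) %s although informant_available is FALSE",
          nm, paste(utils::head(which(bad_rows), 5), collapse = ", ")))
      }
    }
  }
  invisible(cohort)
}

#' Read a cohort case file
#'
#' Reads a comma-separated UTF-8 case file (one row per participant, wide
#' format, empty cell = missing) and returns a validated cohort data frame.
#' Unknown columns are a hard error listing the offending names; out-of-range
#' scale values are an error naming the row and field.  Missing cells become
#' `NA`, never zero.
#'
#' @param path path to the CSV file.
#' @param battery an `ncd_battery` describing the expected test columns.
#' @return a validated cohort data.frame in canonical column order.
#' @export
read_cohort <- function(path, battery = default_battery()) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  schema <- cohort_schema(battery)
  extra <- setdiff(names(raw), schema$name)
  if (length(extra) > 0) {
    stop("unknown columns in ", path, ": ", paste(extra, collapse = ", "))
  }
  missing_cols <- setdiff(schema$name, names(raw))
  if (length(missing_cols) > 0) {
    stop("columns missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    x <- raw[[nm]]
    x[x == ""] <- NA
    out[[nm]] <- switch(schema$type[i],
      numeric = as.numeric(x),
      integer = as.numeric(x),   # kept numeric; integrality checked below
      logical = as.logical(x),
      x)
  }
  rownames(out) <- NULL
  validate_cohort(out, battery)
  out
}

#' Write a cohort case file
#'
#' Writes the cohort in canonical column order as comma-separated UTF-8 with
#' missing values as empty cells (never the text "NA"/"nan").  Numeric cells
#' are formatted with `as.character()`, i.e. up to 15 significant digits,
#' so `read_cohort(write_cohort(x))` reproduces `x` for any cohort whose
#' scores carry at most that precision (all package simulators round to 3
#' decimals).  Writing is deterministic: the same cohort always produces a
#' byte-identical file.
#'
#' @param cohort a validated cohort data.frame.
#' @param path output path.
#' @param battery an `ncd_battery`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, battery = default_battery()) {
  validate_cohort(cohort, battery)
  schema <- cohort_schema(battery)
  out <- cohort[, schema$name, drop = FALSE]
  cols <- lapply(out, function(x) {
    s <- if (is.logical(x)) ifelse(x, "TRUE", "FALSE") else as.character(x)
    s[is.na(s)] <- ""
    s
  })
  header <- paste(schema$name, collapse = ",")
  if (nrow(out) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  body <- do.call(paste, c(cols, sep = ","))
  writeLines(c(header, body), path)
  invisible(path)
}
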