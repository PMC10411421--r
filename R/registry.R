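#' Assemble and validate a four-table EHR registry
#'
#' The registry is the package's in-memory form of an EHR extract: a patient
#' table, a serum-creatinine laboratory table, an ICD-10 diagnosis table and
#' a CPT procedure table, anchored at the extraction ("as-of")
#' `reference_date`. All downstream windows (12-month lookback, 90-day gap,
#' 6-month follow-up) are measured from that date.
#'
#' @param patients Tibble with `patient_id`, `sex` (`"male"`/`"female"`),
#'   `race` (`"black"`/`"white"`/`"other"`), `enrolled` (logical), and either
#'   `birth_date` (Date) or `age_years` (age at `reference_date`).
#' @param labs Tibble with `patient_id`, `collection_date`,
#'   `creatinine_mg_dl` (> 0) and optionally a derived `egfr` column.
#' @param diagnoses,procedures Tibbles with `patient_id`, `event_date`,
#'   `code`; a `system` column (`"ICD10"`/`"CPT"`) is added when absent.
#' @param reference_date Extraction date.
#' @param horizon_days Follow-up horizon retained in the extract; events
#'   later than `reference_date + horizon_days` fail validation.
#' @return An object of class `ehr_registry`.
#' @seealso [read_registry()], [write_registry()], [validate_registry()]
#' @export
ehr_registry <- function(patients, labs, diagnoses, procedures, reference_date,
                         horizon_days = 180) {
  reference_date <- assert_scalar_date(reference_date, "reference_date")
  reg <- structure(
    list(
      patients = coerce_patients(patients),
      labs = coerce_labs(labs),
      diagnoses = coerce_events(diagnoses, default_system = "ICD10"),
      procedures = coerce_events(procedures, default_system = "CPT"),
      reference_date = reference_date,
      horizon_days = as.integer(horizon_days)
    ),
    class = "ehr_registry"
  )
  problems <- validate_registry(reg)
  if (nrow(problems) > 0) {
    abort(c(
      sprintf("Registry validation failed (%d problem rows).", nrow(problems)),
      utils::capture.output(print(problems, n = 10))
    ))
  }
  reg
}

coerce_patients <- function(patients) {
  patients <- as_tibble(patients)
  required <- c("patient_id", "sex", "race", "enrolled")
  missing <- setdiff(required, names(patients))
  if (length(missing)) {
    abort(sprintf("Patient table is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!any(c("birth_date", "age_years") %in% names(patients))) {
    abort("Patient table needs either `birth_date` or `age_years`.")
  }
  patients$patient_id <- as.character(patients$patient_id)
  if ("birth_date" %in% names(patients)) {
    patients$birth_date <- as_date_strict(patients$birth_date)
  }
  patients$enrolled <- as.logical(patients$enrolled)
  patients
}

coerce_labs <- function(labs) {
  labs <- as_tibble(labs)
  required <- c("patient_id", "collection_date", "creatinine_mg_dl")
  missing <- setdiff(required, names(labs))
  if (length(missing)) {
    abort(sprintf("Lab table is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  labs$patient_id <- as.character(labs$patient_id)
  labs$collection_date <- as_date_strict(labs$collection_date)
  labs$creatinine_mg_dl <- as.numeric(labs$creatinine_mg_dl)
  if ("egfr" %in% names(labs)) {
    labs$egfr <- as.numeric(labs$egfr)
  }
  labs
}

coerce_events <- function(events, default_system) {
  events <- as_tibble(events)
  required <- c("patient_id", "event_date", "code")
  missing <- setdiff(required, names(events))
  if (length(missing)) {
    abort(sprintf("Event table is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!"system" %in% names(events)) {
    events$system <- if (nrow(events)) default_system else character()
  }
  events$patient_id <- as.character(events$patient_id)
  events$event_date <- as_date_strict(events$event_date)
  events$system <- toupper(as.character(events$system))
  events$code <- as.character(events$code)
  events[c("patient_id", "event_date", "system", "code")]
}

#' Enumerate registry validation problems
#'
#' Checks referential integrity (every lab/diagnosis/procedure patient id
#' exists in the patient table), value constraints (positive creatinine,
#' non-negative age at every event, non-empty codes, known code systems,
#' unique patient ids) and the date horizon. Every failing row is reported;
#' nothing is dropped or repaired.
#'
#' @param registry An `ehr_registry` (or an unvalidated list with the same
#'   shape).
#' @return Tibble with columns `table`, `row`, `patient_id`, `problem`;
#'   zero rows when the registry is valid.
#' @export
validate_registry <- function(registry) {
  p <- registry$patients
  probs <- list()
  note <- function(table, rows, ids, problem) {
    if (length(rows) == 0) {
      return(NULL)
    }
    tibble(
      table = table, row = as.integer(rows),
      patient_id = as.character(ids), problem = problem
    )
  }
  dup <- duplicated(p$patient_id)
  probs$dup <- note("patients", which(dup), p$patient_id[dup], "duplicate patient_id")
  bad_sex <- !p$sex %in% c("male", "female")
  probs$sex <- note("patients", which(bad_sex), p$patient_id[bad_sex], "sex must be male/female")
  bad_race <- !p$race %in% c("black", "white", "other")
  probs$race <- note("patients", which(bad_race), p$patient_id[bad_race], "race must be black/white/other")

  late <- registry$reference_date + registry$horizon_days
  check_events <- function(tab, name, date_col) {
    orphan <- !tab$patient_id %in% p$patient_id
    out <- list(
      note(name, which(orphan), tab$patient_id[orphan], "patient_id not in patient table"),
      note(
        name, which(is.na(tab[[date_col]])), tab$patient_id[is.na(tab[[date_col]])],
        sprintf("unparseable %s", date_col)
      ),
      note(
        name, which(tab[[date_col]] > late), tab$patient_id[tab[[date_col]] > late],
        sprintf("%s after reference_date + horizon", date_col)
      )
    )
    if ("birth_date" %in% names(p)) {
      bd <- p$birth_date[match(tab$patient_id, p$patient_id)]
      neg <- !is.na(bd) & !is.na(tab[[date_col]]) & tab[[date_col]] < bd
      out <- c(out, list(note(name, which(neg), tab$patient_id[neg], "event precedes birth_date")))
    }
    out
  }
  probs <- c(probs, check_events(registry$labs, "labs", "collection_date"))
  probs <- c(probs, check_events(registry$diagnoses, "diagnoses", "event_date"))
  probs <- c(probs, check_events(registry$procedures, "procedures", "event_date"))

  bad_cr <- is.na(registry$labs$creatinine_mg_dl) | registry$labs$creatinine_mg_dl <= 0
  probs$cr <- note(
    "labs", which(bad_cr), registry$labs$patient_id[bad_cr],
    "creatinine_mg_dl must be > 0"
  )
  for (nm in c("diagnoses", "procedures")) {
    tab <- registry[[nm]]
    empty <- is.na(tab$code) | !nzchar(trimws(tab$code))
    probs[[paste0(nm, "_code")]] <- note(nm, which(empty), tab$patient_id[empty], "empty code")
    bad_sys <- !tab$system %in% c("ICD10", "CPT")
    probs[[paste0(nm, "_sys")]] <- note(
      nm, which(bad_sys), tab$patient_id[bad_sys],
      "system must be ICD10 or CPT"
    )
  }
  out <- bind_rows(probs[!vapply(probs, is.null, logical(1))])
  if (nrow(out) == 0) {
    tibble(
      table = character(), row = integer(),
      patient_id = character(), problem = character()
    )
  } else {
    arrange(out, .data$table, .data$row)
  }
}

#' @export
print.ehr_registry <- function(x, ...) {
  cat("<ehr_registry> as of", format(x$reference_date), "\n")
  cat(sprintf(
    "  patients: %d  labs: %d  diagnoses: %d  procedures: %d\n",
    nrow(x$patients), nrow(x$labs), nrow(x$diagnoses), nrow(x$procedures)
  ))
  if (!is.null(attr(x, "truth"))) {
    cat("  carries synthetic ground-truth labels (see truth_table())\n")
  }
  invisible(x)
}

registry_file_names <- c(
  patients = "patients.csv", labs = "labs.csv",
  diagnoses = "diagnoses.csv", procedures = "procedures.csv"
)

#' Read a four-table registry from delimited files
#'
#' Reads the patient/lab/diagnosis/procedure tables (comma- or tab-separated,
#' sniffed from the header line), applies optional column renaming from a
#' schema config, parses dates, and validates the assembled registry.
#' Validation problems are raised as an error that enumerates the failing
#' rows; nothing is silently dropped.
#'
#' @param dir Directory holding the four files (default names
#'   `patients.csv`, `labs.csv`, `diagnoses.csv`, `procedures.csv`).
#' @param reference_date Extraction date; when `NULL`, read from
#'   `registry.yaml` in `dir` (written by [write_registry()]).
#' @param paths Optional named list/vector overriding individual file paths
#'   (`patients`, `labs`, `diagnoses`, `procedures`).
#' @param schema Optional schema config: a YAML path or named list with, per
#'   table, a mapping of canonical column name to source column name.
#' @param horizon_days Follow-up horizon for validation (default 180).
#' @return An `ehr_registry`.
#' @export
read_registry <- function(dir = NULL, reference_date = NULL, paths = NULL,
                          schema = NULL, horizon_days = 180) {
  files <- as.list(registry_file_names)
  if (!is.null(dir)) {
    files <- lapply(files, function(f) file.path(dir, f))
  }
  if (!is.null(paths)) {
    files[names(paths)] <- paths
  }
  missing <- !vapply(files, file.exists, logical(1))
  if (any(missing)) {
    abort(sprintf(
      "Registry file(s) not found: %s",
      paste(unlist(files[missing]), collapse = ", ")
    ))
  }
  if (is.character(schema) && length(schema) == 1) {
    schema <- yaml::read_yaml(schema)
  }
  read_one <- function(path, table) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
    tab <- readr::read_delim(path,
      delim = delim, col_types = readr::cols(),
      progress = FALSE, show_col_types = FALSE
    )
    map <- schema[[table]]
    if (!is.null(map)) {
      for (canonical in names(map)) {
        src <- map[[canonical]]
        if (!src %in% names(tab)) {
          abort(sprintf(
            "Schema error in %s: configured column `%s` (for `%s`) not found.",
            path, src, canonical
          ))
        }
        names(tab)[names(tab) == src] <- canonical
      }
    }
    tab
  }
  if (is.null(reference_date)) {
    meta_path <- file.path(dirname(files$patients), "registry.yaml")
    if (file.exists(meta_path)) {
      meta <- yaml::read_yaml(meta_path)
      reference_date <- meta$reference_date
      horizon_days <- meta$horizon_days %||% horizon_days
    } else {
      abort("`reference_date` must be given (no registry.yaml found alongside the tables).")
    }
  }
  ehr_registry(
    patients = read_one(files$patients, "patients"),
    labs = read_one(files$labs, "labs"),
    diagnoses = read_one(files$diagnoses, "diagnoses"),
    procedures = read_one(files$procedures, "procedures"),
    reference_date = reference_date,
    horizon_days = horizon_days
  )
}

#' Write a registry to delimited files
#'
#' Emits the four tables as CSV (dates in ISO `YYYY-MM-DD`) plus a small
#' `registry.yaml` carrying the reference date and horizon, so that
#' [read_registry()] on the directory reproduces the registry field for
#' field.
#'
#' @param registry An `ehr_registry`.
#' @param dir Output directory (created if absent).
#' @param delim Field delimiter, `","` or `"\t"`.
#' @return Invisibly, the named vector of written file paths.
#' @export
write_registry <- function(registry, dir, delim = ",") {
  stopifnot(inherits(registry, "ehr_registry"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(dir, registry_file_names)
  names(out) <- names(registry_file_names)
  for (nm in names(out)) {
    readr::write_delim(registry[[nm]], out[nm], delim = delim, na = "")
  }
  yaml::write_yaml(
    list(
      reference_date = format(registry$reference_date),
      horizon_days = registry$horizon_days
    ),
    file.path(dir, "registry.yaml")
  )
  invisible(out)
}
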