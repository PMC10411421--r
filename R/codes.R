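#' Construct a diagnosis/procedure code set
#'
#' A code set bundles the ICD-10 and CPT codes that define one clinical
#' concept (advanced CKD, acute kidney injury, dialysis). ICD-10 codes are
#' stored dot-normalized (`"N18.4"` and `"N184"` are the same code) and are
#' matched by prefix, so `"N17"` covers `N17.0`, `N17.1`, ... CPT codes are
#' matched exactly.
#'
#' @param name Short label for the concept.
#' @param icd10 Character vector of ICD-10 codes (prefix-match semantics).
#' @param cpt Character vector of CPT codes (exact-match semantics).
#' @return An object of class `code_set`.
#' @examples
#' code_set("advanced_ckd", icd10 = c("N18.4", "N18.5"))
#' @export
code_set <- function(name, icd10 = character(), cpt = character()) {
  icd10 <- unique(normalize_icd10(as.character(icd10)))
  cpt <- unique(toupper(trimws(as.character(cpt))))
  icd10 <- icd10[nzchar(icd10)]
  cpt <- cpt[nzchar(cpt)]
  if (length(icd10) + length(cpt) == 0) {
    abort("A code set must contain at least one ICD-10 or CPT code.")
  }
  structure(
    list(name = as.character(name)[1], icd10 = icd10, cpt = cpt),
    class = "code_set"
  )
}

#' @export
print.code_set <- function(x, ...) {
  cat("<code_set>", x$name, "\n")
  cat("  ICD-10 (prefix):", if (length(x$icd10)) paste(x$icd10, collapse = ", ") else "-", "\n")
  cat("  CPT (exact):    ", if (length(x$cpt)) paste(x$cpt, collapse = ", ") else "-", "\n")
  invisible(x)
}

#' Normalize ICD-10 code spelling
#'
#' Uppercases and removes the optional dot, so the common EHR dialects
#' (`"N18.4"`, `"n184"`) compare equal.
#'
#' @param codes Character vector.
#' @return Character vector of normalized codes.
#' @export
normalize_icd10 <- function(codes) {
  gsub(".", "", toupper(trimws(as.character(codes))), fixed = TRUE)
}

#' Default code sets used by the phenotype
#'
#' Reads the code-set configuration shipped with the package (or a
#' user-supplied YAML file with the same layout). The advanced-CKD set is
#' N18.4/N18.5 and the AKI set is the N17 category. The dialysis/ESKD
#' exclusion list is a synthetic stand-in (ICD-10 Z99.2, N18.6, Z49 prefix;
#' CPT 90935-90999): health systems maintain their own dialysis lists, so
#' this set exists to make the exclusion logic runnable and should be
#' replaced with local codes in production use.
#'
#' @param path Optional path to a YAML file mapping set names to
#'   `icd10:`/`cpt:` code lists.
#' @return Named list of [code_set] objects.
#' @examples
#' default_code_sets()$advanced_ckd
#' @export
default_code_sets <- function(path = NULL) {
  path <- path %||% system.file("extdata", "codesets_synthetic_default.yaml",
    package = "ckdtier"
  )
  read_code_sets(path)
}

#' Read code sets from a YAML file
#'
#' @param path YAML file; top level maps set names to lists with optional
#'   `icd10` and `cpt` entries.
#' @return Named list of [code_set] objects.
#' @export
read_code_sets <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Code-set file not found: %s", path))
  }
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    code_set(nm,
      icd10 = unlist(raw[[nm]]$icd10) %||% character(),
      cpt = expand_cpt_ranges(as.character(unlist(raw[[nm]]$cpt) %||% character()))
    )
  })
  setNames(out, names(raw))
}

# "90935-90999" in a config expands to the inclusive run of 5-digit codes.
expand_cpt_ranges <- function(cpt) {
  is_range <- grepl("^[0-9]{5}-[0-9]{5}$", cpt)
  if (!any(is_range)) {
    return(cpt)
  }
  expanded <- lapply(cpt[is_range], function(r) {
    ends <- as.integer(strsplit(r, "-", fixed = TRUE)[[1]])
    sprintf("%05d", seq(ends[1], ends[2]))
  })
  c(cpt[!is_range], unlist(expanded))
}

#' Patients with a matching coded event in a date window
#'
#' Scans coded events (diagnoses or procedures) for codes belonging to a
#' [code_set] within a closed date window and returns the distinct patient
#' ids. ICD-10 events match any set code as a dot-normalized prefix; CPT
#' events match exactly.
#'
#' @param events Tibble with columns `patient_id`, `event_date`, `system`
#'   (`"ICD10"` or `"CPT"`), `code`.
#' @param codes A [code_set].
#' @param window_start,window_end Closed window bounds (dates).
#' @return Sorted character vector of patient ids.
#' @examples
#' ev <- tibble::tibble(
#'   patient_id = c("p1", "p2"),
#'   event_date = as.Date("2021-01-10"),
#'   system = "ICD10", code = c("N184", "N18.3")
#' )
#' match_codes(ev, code_set("adv", icd10 = c("N18.4", "N18.5")),
#'   as.Date("2020-04-15"), as.Date("2021-04-15")
#' )
#' @export
match_codes <- function(events, codes, window_start, window_end) {
  stopifnot(inherits(codes, "code_set"))
  window_start <- assert_scalar_date(window_start, "window_start")
  window_end <- assert_scalar_date(window_end, "window_end")
  if (window_start > window_end) {
    abort("`window_start` must not be after `window_end`.")
  }
  if (is.null(events) || nrow(events) == 0) {
    return(character())
  }
  ev <- events[events$event_date >= window_start & events$event_date <= window_end, ,
    drop = FALSE
  ]
  if (nrow(ev) == 0) {
    return(character())
  }
  hit <- rep(FALSE, nrow(ev))
  is_icd <- ev$system == "ICD10"
  if (any(is_icd) && length(codes$icd10)) {
    norm <- normalize_icd10(ev$code[is_icd])
    m <- Reduce(`|`, lapply(codes$icd10, function(p) startsWith(norm, p)))
    hit[is_icd] <- m
  }
  is_cpt <- ev$system == "CPT"
  if (any(is_cpt) && length(codes$cpt)) {
    hit[is_cpt] <- toupper(trimws(ev$code[is_cpt])) %in% codes$cpt
  }
  sort(unique(ev$patient_id[hit]))
}
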