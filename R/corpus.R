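#' Longitudinal EHR corpus
#'
#' A corpus is a tibble with one row per patient and columns
#' `patient_id` (character), `observation_end_age_months` (integer age in
#' months at the end of follow-up), `attributes` (list of named lists of
#' latent labels, e.g. a binary gender-analog used only for audits) and
#' `visits` (list of tibbles with columns `age_months` — integer patient age
#' in months, non-decreasing across visits — and `codes`, a list column of
#' non-empty character vectors of diagnosis codes). Diagnosis-free visits are
#' not representable: every visit carries at least one code.
#'
#' @param patients A list of patient records, each a list with fields
#'   `patient_id`, `observation_end_age_months`, `attributes` and `visits`
#'   (list of `list(age_months =, codes =)`).
#' @return An `ehr_corpus` tibble.
#' @export
ehr_corpus <- function(patients) {
  rows <- lapply(patients, function(p) {
    visits <- tibble::tibble(
      age_months = vapply(p$visits, function(v) as.integer(v$age_months), integer(1)),
      codes = lapply(p$visits, function(v) as.character(v$codes))
    )
    tibble::tibble(
      patient_id = as.character(p$patient_id),
      observation_end_age_months = as.integer(p$observation_end_age_months),
      attributes = list(p$attributes %||% list()),
      visits = list(visits)
    )
  })
  corpus <- dplyr::bind_rows(rows)
  if (nrow(corpus) == 0L) {
    corpus <- tibble::tibble(
      patient_id = character(), observation_end_age_months = integer(),
      attributes = list(), visits = list()
    )
  }
  validate_corpus(new_ehr_corpus(corpus))
}

new_ehr_corpus <- function(x) {
  class(x) <- unique(c("ehr_corpus", class(x)))
  x
}

validate_corpus <- function(corpus) {
  for (i in seq_len(nrow(corpus))) {
    v <- corpus$visits[[i]]
    pid <- corpus$patient_id[[i]]
    if (nrow(v) == 0L) stop("patient ", pid, " has no visits", call. = FALSE)
    if (any(lengths(v$codes) == 0L)) {
      stop("patient ", pid, " has a diagnosis-free visit", call. = FALSE)
    }
    if (any(v$age_months < 0L)) stop("patient ", pid, " has a negative visit age", call. = FALSE)
    if (is.unsorted(v$age_months)) {
      stop("visit ages not non-decreasing for patient ", pid, call. = FALSE)
    }
    # observation_end may precede late visits (e.g. reliable follow-up in a
    # linked source ends while encounters are still recorded); horizon-task
    # eligibility guards against using such windows
    if (corpus$observation_end_age_months[[i]] < 0L) {
      stop("negative observation end for patient ", pid, call. = FALSE)
    }
  }
  corpus
}

#' Keep patients with enough visits
#'
#' Cohort inclusion requires a minimum medical-history length: only patients
#' with at least `min_visits` (diagnosis-carrying) visits are retained, in
#' their original order.
#'
#' @param corpus An [ehr_corpus()] tibble.
#' @param min_visits Minimum number of visits (default 5).
#' @return The filtered `ehr_corpus`.
#' @examples
#' corp <- generate_corpus(sim_config(n_patients = 50, seed = 1))$corpus
#' nrow(filter_inclusion(corp, min_visits = 8))
#' @export
filter_inclusion <- function(corpus, min_visits = 5L) {
  stopifnot(inherits(corpus, "ehr_corpus"))
  keep <- vapply(corpus$visits, nrow, integer(1)) >= min_visits
  new_ehr_corpus(corpus[keep, , drop = FALSE])
}

#' Read / write a corpus as JSON Lines
#'
#' One patient object per line:
#' `{"patient_id": str, "observation_end_age_months": int,`
#' `"attributes": {...}, "visits": [{"age": int, "codes": [str, ...]}, ...]}`
#' where `"age"` is the patient age in months at the visit. Writing then
#' reading reproduces the corpus field-by-field; malformed lines and
#' out-of-order visit ages are rejected with the offending line number or
#' patient id.
#'
#' @param corpus An [ehr_corpus()] tibble.
#' @param path File path.
#' @return `read_corpus()` returns an `ehr_corpus`; `write_corpus()` returns
#'   `path` invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "ehr_corpus"))
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    v <- corpus$visits[[i]]
    obj <- list(
      patient_id = corpus$patient_id[[i]],
      observation_end_age_months = corpus$observation_end_age_months[[i]],
      attributes = corpus$attributes[[i]],
      visits = lapply(seq_len(nrow(v)), function(j) {
        list(age = v$age_months[[j]], codes = as.list(v$codes[[j]]))
      })
    )
    jsonlite::toJSON(obj, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  patients <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) stop("malformed corpus line ", i, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    for (field in c("patient_id", "observation_end_age_months", "visits")) {
      if (is.null(obj[[field]])) {
        stop("malformed corpus line ", i, ": missing field '", field, "'",
             call. = FALSE)
      }
    }
    list(
      patient_id = obj$patient_id,
      observation_end_age_months = obj$observation_end_age_months,
      attributes = obj$attributes %||% list(),
      visits = lapply(obj$visits, function(v) {
        list(age_months = v$age, codes = unlist(v$codes))
      })
    )
  })
  ehr_corpus(patients)
}

#' Summary statistics of a corpus
#'
#' Mirrors the population-statistics tables reported for EHR cohorts:
#' patient and visit counts, the distribution of visits per patient and codes
#' per visit, and the per-code prevalence (fraction of patients that ever
#' carry the code).
#'
#' @param corpus A non-empty [ehr_corpus()].
#' @return A list with `n_patients`, `n_visits`, `visits_per_patient` and
#'   `codes_per_visit` (numeric summaries as tibbles) and `prevalence`
#'   (tibble: `code`, `n_patients`, `prevalence`).
#' @export
summarize_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "ehr_corpus"), nrow(corpus) > 0L)
  n_visits_per <- vapply(corpus$visits, nrow, integer(1))
  codes_per_visit <- unlist(lapply(corpus$visits, function(v) lengths(v$codes)))
  carried <- lapply(corpus$visits, function(v) unique(unlist(v$codes)))
  tab <- table(unlist(carried))
  prevalence <- tibble::tibble(
    code = names(tab),
    n_patients = as.integer(tab),
    prevalence = as.integer(tab) / nrow(corpus)
  ) |> dplyr::arrange(.data$code)
  list(
    n_patients = nrow(corpus),
    n_visits = sum(n_visits_per),
    visits_per_patient = dist_summary(n_visits_per),
    codes_per_visit = dist_summary(codes_per_visit),
    prevalence = prevalence
  )
}

dist_summary <- function(x) {
  tibble::tibble(
    mean = mean(x), sd = stats::sd(x),
    min = min(x), median = stats::median(x), max = max(x)
  )
}
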