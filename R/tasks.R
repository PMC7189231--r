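#' Patient-level train/test split
#'
#' Random, seeded, exhaustive partition of patients into train and test
#' sets (default 80% / 20%).
#'
#' @param corpus An [ehr_corpus()].
#' @param test_fraction Fraction of patients assigned to the test set.
#' @param seed Integer seed.
#' @return List with `train` and `test`, both `ehr_corpus` tibbles.
#' @export
split_patients <- function(corpus, test_fraction = 0.2, seed = 0L) {
  stopifnot(inherits(corpus, "ehr_corpus"))
  n <- nrow(corpus)
  set.seed(seed)
  n_test <- round(test_fraction * n)
  test_idx <- sort(sample.int(n, n_test))
  list(
    train = new_ehr_corpus(corpus[setdiff(seq_len(n), test_idx), , drop = FALSE]),
    test = new_ehr_corpus(corpus[test_idx, , drop = FALSE])
  )
}

#' Build one next-visit (T1) example for a patient
#'
#' Draws a split index `j` uniformly over the integers with `3 < j < n_p`,
#' takes visits `1..j` as input and the distinct codes of visit `j + 1` as
#' the multi-hot label. Patients with fewer than 5 visits yield no example.
#' Each patient contributes at most one example.
#'
#' @param record One row of an [ehr_corpus()].
#' @param vocab A [disease_vocab][build_vocab].
#' @return A one-row example tibble (see [make_task_examples()]) or `NULL`.
#' @export
make_t1_example <- function(record, vocab) {
  visits <- record$visits[[1]]
  n_p <- nrow(visits)
  if (n_p < 5L) return(NULL)
  j <- draw_uniform_int(4L, n_p - 1L)
  label <- sort(unique(match(visits$codes[[j + 1L]], vocab$codes)))
  label <- label[!is.na(label)]
  if (length(label) == 0L) return(NULL)
  example_row(record, j, label, "T1")
}

#' Build one horizon (T2/T3) example for a patient
#'
#' A patient is eligible only if observation continues at least
#' `horizon_months` past visit 4. Let `n*` be the largest visit index such
#' that `observation_end_age_months >= age(visit n*) + horizon`; `j` is
#' drawn uniformly over `3 < j <= n*` and the label collects the distinct
#' codes of all visits whose month-age lies in
#' `(age(visit j), age(visit j) + horizon]`. Patients whose label would be
#' empty are excluded.
#'
#' @param record One row of an [ehr_corpus()].
#' @param horizon_months 6 (T2) or 12 (T3).
#' @param vocab A [disease_vocab][build_vocab].
#' @return A one-row example tibble or `NULL`.
#' @export
make_horizon_example <- function(record, horizon_months, vocab) {
  stopifnot(horizon_months %in% c(6L, 12L))
  visits <- record$visits[[1]]
  n_p <- nrow(visits)
  if (n_p < 5L) return(NULL)
  obs_end <- record$observation_end_age_months[[1]]
  if (obs_end < visits$age_months[[4L]] + horizon_months) return(NULL)
  n_star <- max(which(obs_end >= visits$age_months + horizon_months))
  if (n_star < 4L) return(NULL)
  j <- draw_uniform_int(4L, n_star)
  anchor <- visits$age_months[[j]]
  in_window <- visits$age_months > anchor & visits$age_months <= anchor + horizon_months
  codes <- unique(unlist(visits$codes[in_window]))
  label <- sort(match(codes, vocab$codes))
  label <- label[!is.na(label)]
  if (length(label) == 0L) return(NULL)
  example_row(record, j, label, if (horizon_months == 6L) "T2" else "T3")
}

draw_uniform_int <- function(lo, hi) {
  if (hi < lo) stop("empty index range", call. = FALSE)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

example_row <- function(record, j, label, task_tag) {
  visits <- record$visits[[1]]
  tibble::tibble(
    patient_id = record$patient_id[[1]],
    task = task_tag,
    j = j,
    input_visits = list(visits[seq_len(j), , drop = FALSE]),
    label = list(as.integer(label)),
    attributes = record$attributes
  )
}

#' Build the task-example set for a corpus
#'
#' Applies [make_t1_example()] or [make_horizon_example()] to every patient
#' (one example per patient; ineligible patients contribute none). Labels
#' are stored as 1-based indices into the vocabulary's `G` disease codes.
#'
#' @param corpus An [ehr_corpus()].
#' @param vocab A [disease_vocab][build_vocab].
#' @param task One of `"t1"`, `"t2"`, `"t3"`.
#' @param seed Integer seed for the index draws.
#' @return A tibble with columns `patient_id`, `task`, `j`, `input_visits`
#'   (list of visit tibbles), `label` (list of integer vectors) and
#'   `attributes`; the vocabulary is recorded in attribute `vocab_codes`.
#' @export
make_task_examples <- function(corpus, vocab, task = c("t1", "t2", "t3"),
                               seed = 0L) {
  task <- match.arg(task)
  set.seed(seed)
  rows <- lapply(seq_len(nrow(corpus)), function(i) {
    rec <- corpus[i, , drop = FALSE]
    switch(task,
           t1 = make_t1_example(rec, vocab),
           t2 = make_horizon_example(rec, 6L, vocab),
           t3 = make_horizon_example(rec, 12L, vocab))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "vocab_codes") <- vocab$codes
  out
}

#' Serialize / read task examples as JSON Lines
#'
#' @param examples A task-example tibble.
#' @param vocab On read: the vocabulary the examples were built with (labels
#'   are stored as indices into its codes).
#' @param path File path.
#' @return `read_examples()` returns the tibble; `write_examples()` returns
#'   `path` invisibly.
#' @export
write_examples <- function(examples, path) {
  lines <- vapply(seq_len(nrow(examples)), function(i) {
    v <- examples$input_visits[[i]]
    jsonlite::toJSON(list(
      patient_id = examples$patient_id[[i]],
      task = examples$task[[i]],
      j = examples$j[[i]],
      label = as.list(examples$label[[i]]),
      attributes = examples$attributes[[i]],
      input_visits = lapply(seq_len(nrow(v)), function(k)
        list(age = v$age_months[[k]], codes = as.list(v$codes[[k]])))
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_examples
#' @export
read_examples <- function(path, vocab) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    visits <- tibble::tibble(
      age_months = vapply(obj$input_visits, function(v) as.integer(v$age), integer(1)),
      codes = lapply(obj$input_visits, function(v) unlist(v$codes))
    )
    tibble::tibble(patient_id = obj$patient_id, task = obj$task,
                   j = as.integer(obj$j),
                   input_visits = list(visits),
                   label = list(as.integer(unlist(obj$label))),
                   attributes = list(obj$attributes %||% list()))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "vocab_codes") <- vocab$codes
  out
}
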