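#' Tokenize a patient record into a four-channel sequence
#'
#' Builds the model input: `CLS, v^1 codes, SEP, v^2 codes, SEP, ...`,
#' right-padded with `PAD` to `max_len`. All tokens of a visit — its disease
#' codes and the trailing `SEP` — share the same age id (completed years at
#' the visit), segment id (`(j - 1) mod 2` for the j-th retained visit) and
#' position id (the visit ordinal j). `CLS` takes the first retained visit's
#' age, segment 0 and position 0, so every channel is constant within a
#' visit span and the encoder is order-invariant to intra-visit code order.
#' If the full sequence would exceed `max_len`, whole *oldest* visits are
#' dropped (CLS kept) until it fits; a visit is never split.
#'
#' @param record One row of an [ehr_corpus()] (a one-row tibble), or a list
#'   with fields `patient_id` and `visits`.
#' @param vocab A [disease_vocab][build_vocab]; unknown codes map to `UNK`.
#' @param max_len Maximum sequence length in tokens (default 256).
#' @return A `tokenized_sequence`: list with equal-length integer vectors
#'   `token_ids`, `age_ids`, `segment_ids`, `position_ids` (0-based ids),
#'   logical `padding_mask` (TRUE at real tokens) and `patient_id`.
#' @examples
#' corp <- generate_corpus(sim_config(n_patients = 5, seed = 1))$corpus
#' vocab <- build_vocab(corp)
#' seq <- encode_patient(corp[1, ], vocab)
#' head(seq$token_ids)
#' @export
encode_patient <- function(record, vocab, max_len = 256L) {
  if (inherits(record, "data.frame")) {
    stopifnot(nrow(record) == 1L)
    visits <- record$visits[[1]]
    pid <- record$patient_id[[1]]
  } else {
    visits <- record$visits
    pid <- record$patient_id
  }
  n_codes <- lengths(visits$codes)
  # tokens contributed by visit j: its codes + one SEP
  widths <- n_codes + 1L
  if (any(widths > max_len - 2L)) {
    stop("patient ", pid, " has a visit with ", max(n_codes),
         " codes, too long for max_len = ", max_len, call. = FALSE)
  }
  n <- nrow(visits)
  first <- 1L
  while (1L + sum(widths[first:n]) > max_len) first <- first + 1L
  kept <- first:n

  token_ids <- vocab$specials[["CLS"]]
  age_ids <- age_months_to_id(visits$age_months[[first]])
  segment_ids <- 0L
  position_ids <- 0L
  for (k in seq_along(kept)) {
    j <- kept[[k]]
    ids <- c(code_to_id(vocab, visits$codes[[j]]), vocab$specials[["SEP"]])
    token_ids <- c(token_ids, ids)
    age_ids <- c(age_ids, rep(age_months_to_id(visits$age_months[[j]]), length(ids)))
    segment_ids <- c(segment_ids, rep((k - 1L) %% 2L, length(ids)))
    position_ids <- c(position_ids, rep(k, length(ids)))
  }
  n_real <- length(token_ids)
  pad <- max_len - n_real
  structure(
    list(
      token_ids = c(token_ids, rep(vocab$specials[["PAD"]], pad)),
      age_ids = c(age_ids, rep(0L, pad)),
      segment_ids = c(segment_ids, rep(0L, pad)),
      position_ids = c(position_ids, rep(0L, pad)),
      padding_mask = c(rep(TRUE, n_real), rep(FALSE, pad)),
      patient_id = pid
    ),
    class = "tokenized_sequence"
  )
}

#' Tokenize a whole corpus
#'
#' Applies [encode_patient()] to every patient, padding each sequence only to
#' its own length (batching pads further as needed).
#'
#' @inheritParams encode_patient
#' @param corpus An [ehr_corpus()].
#' @return A list of `tokenized_sequence` objects.
#' @export
encode_corpus <- function(corpus, vocab, max_len = 256L) {
  lapply(seq_len(nrow(corpus)), function(i) {
    seq <- encode_patient(corpus[i, ], vocab, max_len)
    trim_sequence(seq)
  })
}

# drop trailing padding; batch assembly re-pads to the batch maximum
trim_sequence <- function(seq) {
  n <- sum(seq$padding_mask)
  for (f in c("token_ids", "age_ids", "segment_ids", "position_ids", "padding_mask")) {
    seq[[f]] <- seq[[f]][seq_len(n)]
  }
  seq
}

# stack sequences into matrices [n_seq x max_len] for the batched forward pass
pad_batch <- function(seqs) {
  lens <- vapply(seqs, function(s) length(s$token_ids), integer(1))
  L <- max(lens)
  B <- length(seqs)
  take <- function(field, fill) {
    m <- matrix(fill, nrow = B, ncol = L)
    for (b in seq_len(B)) m[b, seq_len(lens[[b]])] <- seqs[[b]][[field]]
    m
  }
  list(
    token_ids = take("token_ids", 0L),
    age_ids = take("age_ids", 0L),
    segment_ids = take("segment_ids", 0L),
    position_ids = take("position_ids", 0L),
    mask = take("padding_mask", FALSE),
    patient_id = vapply(seqs, function(s) s$patient_id, character(1)),
    B = B, L = L
  )
}
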