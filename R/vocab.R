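#' Disease vocabulary
#'
#' A `disease_vocab` maps every observed diagnosis code, plus the five special
#' tokens `PAD`, `CLS`, `SEP`, `MASK` and `UNK`, bijectively onto contiguous
#' integer ids starting at 0. Special tokens occupy ids 0--4; the `G` disease
#' codes (sorted lexicographically for determinism) occupy ids `5 .. G + 4`.
#'
#' @param corpus An `ehr_corpus` tibble (see [ehr_corpus()]).
#' @return An object of class `disease_vocab` with elements `codes` (sorted
#'   disease codes), `specials` (named integer ids of the special tokens),
#'   `code_ids` (named integer vector code -> id) and `n_total`
#'   (`G + 5`, the full id count).
#' @examples
#' corp <- generate_corpus(sim_config(n_patients = 20, seed = 1))$corpus
#' vocab <- build_vocab(corp)
#' vocab$n_total
#' @export
build_vocab <- function(corpus) {
  stopifnot(inherits(corpus, "ehr_corpus"))
  if (nrow(corpus) == 0L) {
    stop("cannot build a vocabulary from an empty corpus", call. = FALSE)
  }
  codes <- sort(unique(unlist(lapply(corpus$visits, function(v) unlist(v$codes)))))
  new_vocab(codes)
}

SPECIAL_TOKENS <- c(PAD = 0L, CLS = 1L, SEP = 2L, MASK = 3L, UNK = 4L)
N_SPECIALS <- 5L

new_vocab <- function(codes) {
  codes <- as.character(codes)
  if (anyDuplicated(codes)) stop("duplicate disease codes in vocabulary", call. = FALSE)
  code_ids <- seq_along(codes) + N_SPECIALS - 1L  # 0-based ids 5..G+4
  names(code_ids) <- codes
  structure(
    list(
      codes = codes,
      specials = SPECIAL_TOKENS,
      code_ids = code_ids,
      n_total = length(codes) + N_SPECIALS
    ),
    class = "disease_vocab"
  )
}

#' @export
print.disease_vocab <- function(x, ...) {
  cat("<disease_vocab> ", length(x$codes), " disease codes + ",
      N_SPECIALS, " specials (", x$n_total, " ids)\n", sep = "")
  invisible(x)
}

#' @export
length.disease_vocab <- function(x) length(x$codes)

#' Map codes to integer ids and back
#'
#' Unknown codes map to the `UNK` id. Ids are 0-based to match the embedding
#' table layout; `id_to_code()` returns special-token names for ids below 5.
#'
#' @param vocab A [disease_vocab][build_vocab].
#' @param codes Character vector of disease codes.
#' @param ids Integer vector of 0-based token ids.
#' @return Integer ids, respectively character codes.
#' @export
code_to_id <- function(vocab, codes) {
  ids <- unname(vocab$code_ids[codes])
  ids[is.na(ids)] <- vocab$specials[["UNK"]]
  as.integer(ids)
}

#' @rdname code_to_id
#' @export
id_to_code <- function(vocab, ids) {
  out <- character(length(ids))
  sp <- ids < N_SPECIALS
  out[sp] <- names(vocab$specials)[ids[sp] + 1L]
  out[!sp] <- vocab$codes[ids[!sp] - N_SPECIALS + 1L]
  out
}

#' Read / write a vocabulary as plain text
#'
#' One disease code per line; the special tokens are implicit and re-added on
#' read.
#'
#' @param vocab A [disease_vocab][build_vocab].
#' @param path File path.
#' @return `read_vocab()` returns a `disease_vocab`; `write_vocab()` returns
#'   `path` invisibly.
#' @export
write_vocab <- function(vocab, path) {
  writeLines(vocab$codes, path)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  new_vocab(readLines(path))
}
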