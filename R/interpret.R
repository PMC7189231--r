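#' Attention association map for one patient
#'
#' Extracts the chosen layer's attention weights (last layer by default,
#' where the learned disease associations live), averages them over heads,
#' strips padding, and labels every token with its code, visit ordinal and
#' age. Rows of the aggregated matrix remain stochastic over real tokens.
#' The map is interpreted non-directionally (association strength), but the
#' raw row-stochastic matrix is kept.
#'
#' @param model A trained `ehrt_model`.
#' @param seq A `tokenized_sequence` from [encode_patient()].
#' @param layer Layer index (default: last).
#' @param head_aggregation `"mean"` to average heads, or a head index.
#' @return An `attention_map`: list with `patient_id`, `labels` and
#'   `matrix` (`n_real x n_real`).
#' @export
attention_map <- function(model, seq, layer = model$config$n_layers,
                          head_aggregation = "mean") {
  if (layer < 1L || layer > model$config$n_layers) {
    stop("layer index out of range (1..", model$config$n_layers, ")", call. = FALSE)
  }
  enc <- ehrt_encode(model, seq, want_attentions = TRUE)
  heads <- enc$attentions[[layer]]
  agg <- if (identical(head_aggregation, "mean")) {
    Reduce(`+`, heads) / length(heads)
  } else {
    heads[[head_aggregation]]
  }
  real <- which(seq$padding_mask)
  agg <- agg[real, real, drop = FALSE]
  labels <- sprintf("%s@v%d/a%dy",
                    id_to_code(model$vocab, seq$token_ids[real]),
                    seq$position_ids[real], seq$age_ids[real])
  structure(list(patient_id = seq$patient_id, labels = labels, matrix = agg),
            class = "attention_map")
}

#' Write an attention map as JSON
#'
#' @param map An [attention_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_attention_map <- function(map, path) {
  jsonlite::write_json(
    list(patient_id = map$patient_id, labels = map$labels,
         matrix = unname(apply(map$matrix, 1L, as.numeric, simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Nearest diseases by embedding cosine similarity
#'
#' Ranks all other disease codes (special tokens excluded) by cosine
#' similarity of their learned embeddings to the query code's embedding;
#' ties break by vocabulary order. The published analysis uses the top 10
#' neighbours of every sufficiently prevalent disease.
#'
#' @param model A trained `ehrt_model` (or a numeric embedding matrix with
#'   codes as rownames).
#' @param query_code Disease code to query.
#' @param k Number of neighbours (capped at `G - 1`).
#' @return Tibble: `query`, `rank`, `code`, `cosine`.
#' @export
nearest_diseases <- function(model, query_code, k = 10L) {
  emb <- if (inherits(model, "ehrt_model")) disease_embeddings(model) else model
  codes <- rownames(emb)
  if (!query_code %in% codes) stop("unknown query code: ", query_code, call. = FALSE)
  qi <- match(query_code, codes)
  q <- emb[qi, ]
  norms <- sqrt(rowSums(emb^2))
  sims <- as.numeric(emb %*% q) / (norms * sqrt(sum(q^2)))
  sims[qi] <- -Inf  # exclude the query itself
  k <- min(k, length(codes) - 1L)
  ord <- order(sims, decreasing = TRUE)[seq_len(k)]
  tibble::tibble(query = query_code, rank = seq_len(k),
                 code = codes[ord], cosine = unname(sims[ord]))
}

#' Within- versus between-group embedding cosine
#'
#' Summarizes how well learned disease embeddings recover a planted group
#' structure: the mean cosine similarity over all within-group code pairs
#' against the mean over between-group pairs.
#'
#' @param model A trained `ehrt_model`.
#' @param group_of_code Named integer vector (code -> group), e.g. from
#'   [generate_corpus()]'s ground truth.
#' @return List with `within`, `between` and `gap` (within - between).
#' @export
embedding_group_separation <- function(model, group_of_code) {
  emb <- disease_embeddings(model)
  codes <- rownames(emb)
  grp <- group_of_code[codes]
  normed <- emb / sqrt(rowSums(emb^2))
  S <- tcrossprod(normed)
  same <- outer(grp, grp, `==`)
  ut <- upper.tri(S)
  list(within = mean(S[ut & same]), between = mean(S[ut & !same]),
       gap = mean(S[ut & same]) - mean(S[ut & !same]))
}
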