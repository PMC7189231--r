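#' Masking policy for MLM pretraining
#'
#' Each disease token independently stays unchanged with probability
#' `p_keep`, is replaced by `MASK` with `p_mask`, or is replaced by a
#' uniformly drawn disease code with `p_random`. The published proportions
#' are 86.5% / 12% / 1.5%, so only 13.5% of disease tokens are ever
#' corrupted and only those carry a prediction label. Special tokens and
#' padding are never touched.
#'
#' @param p_keep,p_mask,p_random Category probabilities; must sum to 1.
#' @return A `masking_policy` list.
#' @export
masking_policy <- function(p_keep = 0.865, p_mask = 0.12, p_random = 0.015) {
  if (abs(p_keep + p_mask + p_random - 1) > 1e-12) {
    stop("masking probabilities must sum to 1", call. = FALSE)
  }
  if (min(p_keep, p_mask, p_random) < 0) stop("negative masking probability", call. = FALSE)
  structure(list(p_keep = p_keep, p_mask = p_mask, p_random = p_random),
            class = "masking_policy")
}

#' Corrupt tokenized sequences for MLM training
#'
#' Draws one uniform variate per eligible (disease) token to pick its
#' category under `policy`, then replaces masked tokens by `MASK` and
#' random-category tokens by a uniform draw over the `G` disease ids (which
#' may coincidentally redraw the original). Age, segment and position
#' channels and the sequence length are untouched. Labels hold the original
#' 0-based disease id at corrupted (mask/random) positions and `NA`
#' elsewhere.
#'
#' Randomness comes from the current R RNG stream; seed with `set.seed()`
#' for reproducibility. Per sequence, exactly `n_eligible` category uniforms
#' are consumed first (one `runif` call), then the random replacements.
#'
#' @param seqs A list of `tokenized_sequence` objects (or a single one).
#' @param vocab The [disease_vocab][build_vocab] the sequences were encoded
#'   with.
#' @param policy A [masking_policy()].
#' @return A `masked_batch`: list with `seqs` (corrupted copies) and
#'   `labels` (list of integer vectors aligned with each sequence).
#' @export
corrupt_batch <- function(seqs, vocab, policy = masking_policy()) {
  if (inherits(seqs, "tokenized_sequence")) seqs <- list(seqs)
  G <- length(vocab$codes)
  mask_id <- vocab$specials[["MASK"]]
  out_seqs <- vector("list", length(seqs))
  out_labels <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    eligible <- which(s$padding_mask & s$token_ids >= N_SPECIALS)
    labels <- rep(NA_integer_, length(s$token_ids))
    if (length(eligible) > 0L) {
      u <- stats::runif(length(eligible))
      to_mask <- eligible[u < policy$p_mask]
      to_random <- eligible[u >= policy$p_mask & u < policy$p_mask + policy$p_random]
      labels[to_mask] <- s$token_ids[to_mask]
      labels[to_random] <- s$token_ids[to_random]
      s$token_ids[to_mask] <- mask_id
      if (length(to_random) > 0L) {
        s$token_ids[to_random] <-
          N_SPECIALS + sample.int(G, length(to_random), replace = TRUE) - 1L
      }
    }
    out_seqs[[i]] <- s
    out_labels[[i]] <- labels
  }
  structure(list(seqs = out_seqs, labels = out_labels), class = "masked_batch")
}

#' Masked-language-model loss
#'
#' Mean softmax cross-entropy over the labeled (corrupted) positions;
#' defined as 0 when there are no labels.
#'
#' @param scores `n_labeled x vocab_size` score matrix from the MLM head.
#' @param labels Integer vector of 0-based true token ids, one per row.
#' @return Scalar loss.
#' @export
mlm_loss <- function(scores, labels) {
  stopifnot(nrow(scores) == length(labels))
  if (length(labels) == 0L) return(0)
  mx <- row_max(scores)
  lse <- mx + log(rowSums(exp(scores - mx)))
  true <- scores[cbind(seq_along(labels), labels + 1L)]
  mean(lse - true)
}

mlm_loss_grad <- function(scores, labels) {
  n <- length(labels)
  P <- row_softmax(scores)
  P[cbind(seq_len(n), labels + 1L)] <- P[cbind(seq_len(n), labels + 1L)] - 1
  P / n
}

#' MLM precision at threshold 0.5
#'
#' The pretraining metric: at every labeled position each vocabulary entry's
#' score passes through an elementwise sigmoid and counts as predicted
#' positive above `threshold`; a true positive is a predicted positive that
#' equals the position's label. Precision (true positives over predicted
#' positives) is computed per patient over all its labeled positions and
#' then averaged over patients; patients with no predicted positives are
#' skipped. With no labeled positions at all the metric is undefined and
#' `NA_real_` is returned.
#'
#' @param scores `n_labeled x vocab_size` score matrix.
#' @param labels Integer vector of 0-based true ids, one per row.
#' @param patient Vector of patient identifiers, one per row.
#' @param threshold Decision threshold on the sigmoid scores.
#' @return Mean per-patient precision, or `NA_real_` if undefined.
#' @export
mlm_precision <- function(scores, labels, patient = rep("p", length(labels)),
                          threshold = 0.5) {
  stopifnot(nrow(scores) %||% 0L == length(labels), length(patient) == length(labels))
  if (length(labels) == 0L) return(NA_real_)
  pos <- sigmoid(scores) > threshold
  pp <- rowSums(pos)
  tp <- as.numeric(pos[cbind(seq_along(labels), labels + 1L)])
  per <- tapply(seq_along(labels), patient, function(idx) {
    denom <- sum(pp[idx])
    if (denom == 0) NA_real_ else sum(tp[idx]) / denom
  })
  per <- per[!is.na(per)]
  if (length(per) == 0L) return(NA_real_)
  mean(per)
}
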