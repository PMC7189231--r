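# Ranking metrics for multi-hot labels. APS is the standard average
# precision (precision at each positive's rank, averaged over positives;
# ranking ties broken deterministically by vocabulary order). AUROC is the
# rank (Mann-Whitney) form: the probability a positive outranks a negative,
# with 0.5 credit per tied pair.

#' Average precision of one score vector
#'
#' @param scores Numeric vector of per-disease scores.
#' @param positives Integer indices of the true (positive) diseases.
#' @return Scalar APS in `[0, 1]`; `NA_real_` with no positives.
#' @export
average_precision <- function(scores, positives) {
  if (length(positives) == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  is_pos <- seq_along(scores) %in% positives
  hits <- is_pos[ord]
  precision_at <- cumsum(hits) / seq_along(hits)
  mean(precision_at[hits])
}

#' AUROC of one score vector
#'
#' @param scores Numeric vector of per-disease scores.
#' @param positives Integer indices of the true diseases.
#' @return Scalar AUROC in `[0, 1]`; `NA_real_` when there are no positives
#'   or no negatives (undefined).
#' @export
auroc <- function(scores, positives) {
  n_pos <- length(positives)
  n_neg <- length(scores) - n_pos
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positives]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a fine-tuned model on task examples
#'
#' Computes APS and AUROC for each patient against their multi-hot label,
#' then averages over patients. Patients whose AUROC is undefined (label
#' covers every disease) are excluded from the AUROC mean and counted.
#'
#' @param model A fine-tuned `ehrt_model`.
#' @param examples A task-example tibble from [make_task_examples()].
#' @param probs Optional precomputed `n x G` probability matrix (skips the
#'   forward pass).
#' @return An `eval_report`: list with `mean_aps`, `mean_auroc`,
#'   `n_patients`, `n_auroc_excluded`, and `per_patient` (tibble:
#'   `patient_id`, `aps`, `auroc`, `n_positive`).
#' @export
evaluate_model <- function(model, examples, probs = NULL) {
  stopifnot(nrow(examples) > 0L)
  if (is.null(probs)) probs <- predict(model, examples)
  per <- tibble::tibble(
    patient_id = examples$patient_id,
    aps = vapply(seq_len(nrow(examples)), function(i)
      average_precision(probs[i, ], examples$label[[i]]), numeric(1)),
    auroc = vapply(seq_len(nrow(examples)), function(i)
      auroc(probs[i, ], examples$label[[i]]), numeric(1)),
    n_positive = lengths(examples$label)
  )
  structure(
    list(
      mean_aps = mean(per$aps),
      mean_auroc = mean(per$auroc, na.rm = TRUE),
      n_patients = nrow(per),
      n_auroc_excluded = sum(is.na(per$auroc)),
      per_patient = per
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$n_patients, " patients\n",
      sprintf("  mean per-patient APS   %.4f\n", x$mean_aps),
      sprintf("  mean per-patient AUROC %.4f (%d undefined, excluded)\n",
              x$mean_auroc, x$n_auroc_excluded), sep = "")
  invisible(x)
}

#' Disease-wise evaluation
#'
#' For every disease whose label prevalence in the example set reaches
#' `prevalence_floor`, computes APS and AUROC of that disease's predicted
#' probability across patients, plus its occurrence ratio. Diseases with no
#' positive (or no negative) patients are excluded.
#'
#' @inheritParams evaluate_model
#' @param prevalence_floor Minimum label prevalence (default 0.01, i.e.
#'   diseases rarer than 1% of evaluated patients are dropped).
#' @return Tibble: `code`, `prevalence`, `aps`, `auroc`.
#' @export
disease_wise_eval <- function(model, examples, prevalence_floor = 0.01,
                              probs = NULL) {
  stopifnot(nrow(examples) > 0L)
  if (is.null(probs)) probs <- predict(model, examples)
  G <- ncol(probs)
  n <- nrow(examples)
  Y <- label_matrix(examples, G)
  rows <- lapply(seq_len(G), function(g) {
    pos <- sum(Y[, g])
    prev <- pos / n
    if (pos == 0L || pos == n || prev < prevalence_floor) return(NULL)
    tibble::tibble(
      code = model$vocab$codes[[g]],
      prevalence = prev,
      aps = average_precision(probs[, g], which(Y[, g] == 1)),
      auroc = auroc(probs[, g], which(Y[, g] == 1))
    )
  })
  dplyr::bind_rows(rows)
}

#' First-incidence evaluation
#'
#' Restricts every patient's label to diseases absent from their input
#' history (new diagnoses only), drops patients whose restricted label is
#' empty, and evaluates as [evaluate_model()].
#'
#' @inheritParams evaluate_model
#' @return An `eval_report`; also carries `n_dropped`, the patients whose
#'   entire label was already in their history.
#' @export
first_incidence_eval <- function(model, examples, probs = NULL) {
  stopifnot(nrow(examples) > 0L)
  if (is.null(probs)) probs <- predict(model, examples)
  codes <- attr(examples, "vocab_codes")
  restricted <- lapply(seq_len(nrow(examples)), function(i) {
    hist_codes <- unique(unlist(examples$input_visits[[i]]$codes))
    hist_idx <- match(hist_codes, codes)
    setdiff(examples$label[[i]], hist_idx)
  })
  keep <- lengths(restricted) > 0L
  ex2 <- examples[keep, , drop = FALSE]
  ex2$label <- restricted[keep]
  attr(ex2, "vocab_codes") <- codes
  if (nrow(ex2) == 0L) stop("no patient has a first-incidence label", call. = FALSE)
  report <- evaluate_model(model, ex2, probs = probs[keep, , drop = FALSE])
  report$n_dropped <- sum(!keep)
  report
}
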