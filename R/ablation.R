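#' Embedding-channel ablation study
#'
#' Trains one model per requested channel subset (the disease channel is
#' always active) on identical data with identical seeds, then evaluates
#' each on the same test examples. Arms train from the same random
#' initialization so the comparison isolates the contribution of the
#' deactivated channels. A deactivated channel contributes exactly zero to
#' the input embedding, so each arm is provably invariant to that channel's
#' ids.
#'
#' @param train_examples,test_examples Task-example tibbles from
#'   [make_task_examples()] (train and held-out patients).
#' @param vocab The [disease_vocab][build_vocab] the examples use.
#' @param channel_subsets List of character vectors, each a subset of
#'   `c("disease", "age", "segment", "position")` containing `"disease"`.
#' @param model_config Base [ehrt_config()]; `active_channels` is overridden
#'   per arm.
#' @param tc A [train_config()] shared by all arms.
#' @return Tibble with one row per subset: `channels`, `mean_aps`,
#'   `mean_auroc`, plus the fitted models in attribute `"models"`.
#' @export
ablation_suite <- function(train_examples, test_examples, vocab,
                           channel_subsets = list(
                             c("disease", "age", "segment", "position"),
                             c("disease")),
                           model_config = ehrt_config(),
                           tc = train_config(epochs = 40L, lr = 5e-3)) {
  rows <- vector("list", length(channel_subsets))
  models <- vector("list", length(channel_subsets))
  for (k in seq_along(channel_subsets)) {
    ch <- channel_subsets[[k]]
    cfg <- model_config
    cfg$active_channels <- ch
    model <- ehrt_init(cfg, vocab, seed = tc$seed)
    model <- finetune(model, train_examples, tc)
    report <- evaluate_model(model, test_examples)
    rows[[k]] <- tibble::tibble(
      channels = paste(sort(ch), collapse = "+"),
      mean_aps = report$mean_aps,
      mean_auroc = report$mean_auroc
    )
    models[[k]] <- model
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "models") <- models
  out
}

#' Attribute-consistency audit
#'
#' Checks that a fine-tuned model avoids predicting codes that the
#' patient's latent attribute rules out (the gender-analog audit): for each
#' patient, the mean predicted probability over codes *disallowed* for
#' their attribute is compared with the mean over allowed codes, and
#' disallowed codes appearing among the top-`k` predictions are counted.
#'
#' @param model A fine-tuned `ehrt_model`.
#' @param examples Task examples whose `attributes` carry the latent
#'   `attribute` level.
#' @param ground_truth The `ground_truth` list of [generate_corpus()] (needs
#'   `allowed_attribute`).
#' @param top_k Size of the top-prediction list scanned per patient.
#' @param probs Optional precomputed probability matrix.
#' @return List with `per_patient` (tibble: `patient_id`, `attribute`,
#'   `mean_allowed`, `mean_disallowed`, `ratio`, `n_disallowed_topk`),
#'   `mean_allowed`, `mean_disallowed` and `n_disallowed_in_topk`.
#' @export
attribute_consistency_audit <- function(model, examples, ground_truth,
                                        top_k = 10L, probs = NULL) {
  allowed <- ground_truth$allowed_attribute[model$vocab$codes]
  if (!any(allowed != "both", na.rm = TRUE)) {
    stop("ground truth contains no attribute-exclusive codes", call. = FALSE)
  }
  if (is.null(probs)) probs <- predict(model, examples)
  rows <- lapply(seq_len(nrow(examples)), function(i) {
    attr_level <- examples$attributes[[i]]$attribute
    if (is.null(attr_level)) return(NULL)
    disallowed <- which(!(allowed == "both" | allowed == as.character(attr_level)))
    ok <- setdiff(seq_along(allowed), disallowed)
    topk <- order(probs[i, ], decreasing = TRUE)[seq_len(top_k)]
    tibble::tibble(
      patient_id = examples$patient_id[[i]],
      attribute = attr_level,
      mean_allowed = mean(probs[i, ok]),
      mean_disallowed = mean(probs[i, disallowed]),
      ratio = mean(probs[i, disallowed]) / mean(probs[i, ok]),
      n_disallowed_topk = sum(topk %in% disallowed)
    )
  })
  per <- dplyr::bind_rows(rows)
  if (nrow(per) == 0L) stop("examples carry no attribute labels", call. = FALSE)
  list(
    per_patient = per,
    mean_allowed = mean(per$mean_allowed),
    mean_disallowed = mean(per$mean_disallowed),
    n_disallowed_in_topk = sum(per$n_disallowed_topk)
  )
}
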