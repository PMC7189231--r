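# AdamW with linear warmup then linear decay, the optimizer contract used
# for both pretraining and fine-tuning. Weight decay applies to matrix
# parameters (projection weights and embedding tables), not to biases or
# layer-norm parameters — the convention of the BERT lineage.

#' Training configuration
#'
#' @param epochs Number of passes over the data.
#' @param batch_size Sequences per optimizer step.
#' @param lr Peak learning rate.
#' @param warmup_frac Fraction of total steps spent in linear warmup; the
#'   rate then decays linearly to zero.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param seed Seed covering shuffling, corruption and dropout.
#' @param verbose Print one line per epoch?
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30L, batch_size = 32L, lr = 2e-3,
                         warmup_frac = 0.1, weight_decay = 0.01,
                         seed = 0L, verbose = FALSE) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, warmup_frac = warmup_frac, weight_decay = weight_decay,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

adamw_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

adamw_step <- function(params, grads, state, lr_t, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && is.matrix(params[[nm]])) {
      upd <- upd + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr_t * upd
  }
  list(params = params, state = state)
}

lr_at <- function(step, total_steps, lr, warmup_frac) {
  warmup <- max(1, ceiling(warmup_frac * total_steps))
  if (step <= warmup) return(lr * step / warmup)
  lr * max(0, (total_steps - step) / max(1, total_steps - warmup))
}

# one MLM forward/backward on a padded batch; returns loss, grads and the
# per-position prediction bookkeeping used by the precision metric
mlm_batch_pass <- function(model, seqs, policy, training = TRUE) {
  corrupted <- corrupt_batch(seqs, model$vocab, policy)
  batch <- pad_batch(corrupted$seqs)
  L <- batch$L
  lab_mat <- matrix(NA_integer_, batch$B, L)
  for (b in seq_len(batch$B)) {
    lab <- corrupted$labels[[b]]
    lab_mat[b, seq_along(lab)] <- lab
  }
  lab_vec <- as.integer(t(lab_mat))
  labeled <- which(!is.na(lab_vec))

  X0 <- embed_batch(model, batch)
  enc <- encoder_fwd(model$params, model$config, X0, batch$mask, training = training)
  if (length(labeled) == 0L) {
    return(list(loss = 0, grads = NULL, scores = NULL, labels = integer(0),
                patient = character(0)))
  }
  head <- mlm_head_fwd(model$params, enc$H[labeled, , drop = FALSE])
  labels <- lab_vec[labeled]
  loss <- mlm_loss(head$S, labels)
  if (!is.finite(loss)) stop("MLM loss diverged (non-finite)", call. = FALSE)

  dS <- mlm_loss_grad(head$S, labels)
  hb <- mlm_head_bwd(dS, head, model$params)
  dH <- matrix(0, nrow(enc$H), ncol(enc$H))
  dH[labeled, ] <- hb$dH
  eb <- encoder_bwd(dH, enc$cache, model$params, model$config)
  grads <- c(hb$grads, eb$grads, embedding_bwd(eb$dX0, batch, model))
  patient <- rep(batch$patient_id, each = L)[labeled]
  list(loss = loss, grads = grads, scores = head$S, labels = labels,
       patient = patient)
}

# one classification forward/backward on a padded batch;
# Y is a B x G 0/1 label matrix
cls_batch_pass <- function(model, seqs, Y, training = TRUE) {
  batch <- pad_batch(seqs)
  X0 <- embed_batch(model, batch)
  enc <- encoder_fwd(model$params, model$config, X0, batch$mask, training = training)
  pooled <- pool_rows_fwd(enc$H, batch, model$config$pooling)
  out <- classifier_fwd(model$params, pooled)
  P <- pmin(pmax(out$P2, 1e-12), 1 - 1e-12)
  loss <- -mean(Y * log(P) + (1 - Y) * log(1 - P))
  if (!is.finite(loss)) stop("classification loss diverged (non-finite)", call. = FALSE)
  dlogits <- (out$P2 - Y) / length(Y)
  cb <- classifier_bwd(dlogits, out, model$params)
  dH <- pool_rows_bwd(cb$dHc, batch, model$config$pooling,
                      nrow(enc$H), ncol(enc$H))
  eb <- encoder_bwd(dH, enc$cache, model$params, model$config)
  grads <- c(cb$grads, eb$grads, embedding_bwd(eb$dX0, batch, model))
  list(loss = loss, grads = grads, probs = out$P2)
}

run_training <- function(model, seqs, tc, mode = c("mlm", "cls"),
                         Y = NULL, policy = NULL) {
  mode <- match.arg(mode)
  n <- length(seqs)
  set.seed(tc$seed)
  steps_per_epoch <- ceiling(n / tc$batch_size)
  total_steps <- steps_per_epoch * tc$epochs
  state <- adamw_init(model$params)
  step <- 0L
  history <- vector("list", tc$epochs)
  lens <- vapply(seqs, function(s) length(s$token_ids), integer(1))
  for (epoch in seq_len(tc$epochs)) {
    # shuffle, then bucket by length (random ties) and shuffle batch order:
    # batches of near-equal length waste little padding compute
    ord <- sample.int(n)
    ord <- ord[order(lens[ord])]
    batch_of <- ceiling(seq_len(n) / tc$batch_size)
    ord <- ord[order(sample.int(steps_per_epoch)[batch_of])]
    losses <- numeric(0)
    ep_tp <- list(); ep_pp <- list(); ep_pid <- list()
    for (s in seq_len(steps_per_epoch)) {
      idx <- ord[((s - 1L) * tc$batch_size + 1L):min(s * tc$batch_size, n)]
      if (mode == "mlm") {
        pass <- mlm_batch_pass(model, seqs[idx], policy)
        if (!is.null(pass$scores)) {
          pos <- sigmoid(pass$scores) > 0.5
          ep_pp[[s]] <- rowSums(pos)
          ep_tp[[s]] <- as.numeric(pos[cbind(seq_along(pass$labels), pass$labels + 1L)])
          ep_pid[[s]] <- pass$patient
        }
      } else {
        pass <- cls_batch_pass(model, seqs[idx], Y[idx, , drop = FALSE])
      }
      losses <- c(losses, pass$loss)
      if (!is.null(pass$grads)) {
        step <- step + 1L
        upd <- adamw_step(model$params, pass$grads, state,
                          lr_at(step, total_steps, tc$lr, tc$warmup_frac),
                          tc$weight_decay)
        model$params <- upd$params
        state <- upd$state
      }
    }
    if (mode == "mlm") {
      sums <- rowsum(cbind(unlist(ep_tp), unlist(ep_pp)), unlist(ep_pid))
      den <- sums[, 2]
      ratio <- sums[den > 0, 1] / den[den > 0]
      precision <- if (length(ratio) > 0) mean(ratio) else NA_real_
      history[[epoch]] <- tibble::tibble(epoch = epoch, loss = mean(losses),
                                         precision = precision)
    } else {
      history[[epoch]] <- tibble::tibble(epoch = epoch, loss = mean(losses))
    }
    if (tc$verbose) {
      cat(sprintf("epoch %d/%d loss %.4f%s\n", epoch, tc$epochs, mean(losses),
                  if (mode == "mlm") sprintf(" precision %.4f",
                                             history[[epoch]]$precision) else ""))
    }
  }
  model$history <- dplyr::bind_rows(history)
  model
}

#' Pretrain with the masked-language-model objective
#'
#' Encodes the (inclusion-filtered) corpus, then trains the embedding
#' tables, encoder and MLM head with AdamW under a linear warmup / linear
#' decay schedule. Corruption is resampled fresh every epoch. The epoch
#' history records the mean masked cross-entropy and the per-patient
#' precision-at-0.5 of the MLM predictions.
#'
#' @param corpus An [ehr_corpus()]; patients with fewer than 5 visits are
#'   dropped by [filter_inclusion()].
#' @param vocab Optional [disease_vocab][build_vocab]; built from the corpus
#'   when omitted.
#' @param model_config An [ehrt_config()].
#' @param tc A [train_config()].
#' @param policy A [masking_policy()].
#' @param max_len Tokenizer cap passed to [encode_corpus()].
#' @return A fitted `ehrt_model`; `$history` is a tibble
#'   (`epoch`, `loss`, `precision`).
#' @export
pretrain <- function(corpus, vocab = NULL, model_config = ehrt_config(),
                     tc = train_config(), policy = masking_policy(),
                     max_len = 256L) {
  corpus <- filter_inclusion(corpus)
  if (nrow(corpus) == 0L) stop("no patients pass inclusion filtering", call. = FALSE)
  if (is.null(vocab)) vocab <- build_vocab(corpus)
  seqs <- encode_corpus(corpus, vocab, max_len)
  model <- ehrt_init(model_config, vocab, seed = tc$seed)
  model <- run_training(model, seqs, tc, mode = "mlm", policy = policy)
  model$stage <- "pretrained"
  model
}

#' Fine-tune for multi-label disease prediction
#'
#' Starts from a (pretrained or freshly initialized) model, re-initializes
#' the pooling and classifier head, and trains everything end-to-end with
#' mean per-disease binary cross-entropy against each example's multi-hot
#' label.
#'
#' @param model An `ehrt_model` (checkpoint); its vocabulary must match the
#'   one the examples were built with.
#' @param examples A task-example tibble from [make_task_examples()].
#' @param tc A [train_config()].
#' @param max_len Tokenizer cap.
#' @return The fine-tuned `ehrt_model`; `$history` is a tibble
#'   (`epoch`, `loss`).
#' @export
finetune <- function(model, examples, tc = train_config(epochs = 40L, lr = 5e-3),
                     max_len = 256L) {
  stopifnot(inherits(model, "ehrt_model"), nrow(examples) > 0L)
  if (!identical(attr(examples, "vocab_codes"), model$vocab$codes)) {
    stop("example set was built with a different vocabulary", call. = FALSE)
  }
  H <- model$config$hidden_size
  G <- length(model$vocab$codes)
  set.seed(tc$seed + 1L)
  model$params$pool_W <- matrix(stats::rnorm(H * H, sd = sqrt(1 / H)), H, H)
  model$params$pool_b <- numeric(H)
  model$params$cls_W <- matrix(stats::rnorm(H * G, sd = sqrt(2 / (H + G))), H, G)
  model$params$cls_b <- numeric(G)

  seqs <- encode_examples(examples, model$vocab, max_len)
  Y <- label_matrix(examples, G)
  model <- run_training(model, seqs, tc, mode = "cls", Y = Y)
  model$stage <- "finetuned"
  model
}

# tokenize the input prefix of every example
encode_examples <- function(examples, vocab, max_len = 256L) {
  lapply(seq_len(nrow(examples)), function(i) {
    rec <- list(patient_id = examples$patient_id[[i]],
                visits = examples$input_visits[[i]])
    trim_sequence(encode_patient(rec, vocab, max_len))
  })
}

label_matrix <- function(examples, G) {
  Y <- matrix(0, nrow(examples), G)
  for (i in seq_len(nrow(examples))) Y[i, examples$label[[i]]] <- 1
  Y
}

#' Predict disease probabilities for task examples
#'
#' @param object A fine-tuned `ehrt_model`.
#' @param examples A task-example tibble from [make_task_examples()].
#' @param batch_size Sequences per forward pass.
#' @param ... Unused.
#' @return `n_examples x G` matrix of probabilities, columns named by code.
#' @export
predict.ehrt_model <- function(object, examples, batch_size = 128L, ...) {
  seqs <- encode_examples(examples, object$vocab)
  n <- length(seqs)
  G <- length(object$vocab$codes)
  out <- matrix(NA_real_, n, G, dimnames = list(NULL, object$vocab$codes))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    batch <- pad_batch(seqs[idx])
    X0 <- embed_batch(object, batch)
    enc <- encoder_fwd(object$params, object$config, X0, batch$mask)
    pooled <- pool_rows_fwd(enc$H, batch, object$config$pooling)
    out[idx, ] <- classifier_fwd(object$params, pooled)$P2
  }
  out
}
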