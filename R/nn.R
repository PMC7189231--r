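# Forward and backward passes of the encoder, written against flat matrices:
# a batch of B sequences padded to length L is one (B*L) x H matrix whose
# row (b-1)*L + t is token t of sequence b. Padding rows never enter any
# loss and are masked out of attention as keys, so their gradient is zero.

#' Four-channel input embedding
#'
#' Sums the lookups of the active channels — learned disease, age and
#' segment tables plus the fixed sinusoidal position table — token by token.
#' Deactivated channels contribute exactly zero.
#'
#' @param model An `ehrt_model`.
#' @param seq A `tokenized_sequence` from [encode_patient()].
#' @return A `seq_len x hidden_size` matrix.
#' @export
ehrt_embed <- function(model, seq) {
  batch <- pad_batch(list(seq))
  embed_batch(model, batch)
}

embed_batch <- function(model, batch) {
  cfg <- model$config
  H <- cfg$hidden_size
  ids <- function(m) as.integer(t(m))  # row (b-1)*L + t ordering
  tok <- ids(batch$token_ids); age <- ids(batch$age_ids)
  seg <- ids(batch$segment_ids); pos <- ids(batch$position_ids)
  if (any(tok >= model$vocab$n_total) || any(age >= AGE_VOCAB_SIZE) ||
      any(seg >= 2L) || any(pos >= cfg$max_position)) {
    stop("channel id out of table range", call. = FALSE)
  }
  X <- matrix(0, length(tok), H)
  ch <- cfg$active_channels
  if ("disease" %in% ch) X <- X + model$params$tok_emb[tok + 1L, , drop = FALSE]
  if ("age" %in% ch) X <- X + model$params$age_emb[age + 1L, , drop = FALSE]
  if ("segment" %in% ch) X <- X + model$params$seg_emb[seg + 1L, , drop = FALSE]
  if ("position" %in% ch) X <- X + model$pos_table[pos + 1L, , drop = FALSE]
  X
}

# LayerNorm over the hidden dimension, eps 1e-12 (BERT convention)
LN_EPS <- 1e-12

layer_norm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc * inv
  list(Y = add_bias(xhat * rep(g, each = nrow(X)), b), xhat = xhat, inv = inv)
}

layer_norm_bwd <- function(dY, xhat, inv, g) {
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- dY * rep(g, each = nrow(dY))
  dX <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

# Encoder stack. mask is B x L logical; dropout masks are sampled here when
# training and returned in the cache for the backward pass.
encoder_fwd <- function(params, cfg, X0, mask, want_attn = FALSE, training = FALSE) {
  B <- nrow(mask); L <- ncol(mask)
  H <- cfg$hidden_size; nh <- cfg$n_heads; dh <- H %/% nh
  N <- B * L
  p_drop <- if (training) cfg$dropout else 0
  drop_mask <- function() {
    if (p_drop > 0) matrix((stats::runif(N * H) >= p_drop) / (1 - p_drop), N, H)
    else NULL
  }
  D0 <- drop_mask()
  X <- if (is.null(D0)) X0 else X0 * D0
  layers <- vector("list", cfg$n_layers)
  attns <- if (want_attn) vector("list", cfg$n_layers) else NULL

  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("L%d_", l)
    Xin <- X
    Q <- add_bias(Xin %*% params[[paste0(pre, "Wq")]], params[[paste0(pre, "bq")]])
    K <- add_bias(Xin %*% params[[paste0(pre, "Wk")]], params[[paste0(pre, "bk")]])
    V <- add_bias(Xin %*% params[[paste0(pre, "Wv")]], params[[paste0(pre, "bv")]])
    Ctx <- matrix(0, N, H)
    A_list <- vector("list", B)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      pad_cols <- !mask[b, ]
      A_list[[b]] <- vector("list", nh)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        S <- tcrossprod(Q[rows, cols, drop = FALSE], K[rows, cols, drop = FALSE]) / sqrt(dh)
        if (any(pad_cols)) S[, pad_cols] <- -1e30
        A <- row_softmax(S)
        Ctx[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
        A_list[[b]][[h]] <- A
      }
    }
    O <- add_bias(Ctx %*% params[[paste0(pre, "Wo")]], params[[paste0(pre, "bo")]])
    D1 <- drop_mask()
    if (!is.null(D1)) O <- O * D1
    R1 <- Xin + O
    ln1 <- layer_norm_fwd(R1, params[[paste0(pre, "ln1_g")]], params[[paste0(pre, "ln1_b")]])
    X1 <- ln1$Y
    F1 <- add_bias(X1 %*% params[[paste0(pre, "Wf1")]], params[[paste0(pre, "bf1")]])
    th1 <- tanh(GELU_C * (F1 + 0.044715 * F1^3))  # tanh reused in backward
    G1 <- 0.5 * F1 * (1 + th1)
    F2 <- add_bias(G1 %*% params[[paste0(pre, "Wf2")]], params[[paste0(pre, "bf2")]])
    D2 <- drop_mask()
    if (!is.null(D2)) F2 <- F2 * D2
    R2 <- X1 + F2
    ln2 <- layer_norm_fwd(R2, params[[paste0(pre, "ln2_g")]], params[[paste0(pre, "ln2_b")]])
    X <- ln2$Y
    layers[[l]] <- list(Xin = Xin, Q = Q, K = K, V = V, A = A_list, Ctx = Ctx,
                        ln1 = ln1, X1 = X1, F1 = F1, G1 = G1, th1 = th1,
                        ln2 = ln2, D1 = D1, D2 = D2)
    if (want_attn) attns[[l]] <- A_list
  }
  list(H = X, cache = list(layers = layers, D0 = D0, B = B, L = L, mask = mask),
       attentions = attns)
}

encoder_bwd <- function(dH, cache, params, cfg) {
  B <- cache$B; L <- cache$L
  H <- cfg$hidden_size; nh <- cfg$n_heads; dh <- H %/% nh
  grads <- list()
  dX <- dH
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- sprintf("L%d_", l)
    cc <- cache$layers[[l]]
    lb2 <- layer_norm_bwd(dX, cc$ln2$xhat, cc$ln2$inv, params[[paste0(pre, "ln2_g")]])
    grads[[paste0(pre, "ln2_g")]] <- lb2$dg
    grads[[paste0(pre, "ln2_b")]] <- lb2$db
    dR2 <- lb2$dX
    dF2 <- if (is.null(cc$D2)) dR2 else dR2 * cc$D2
    dX1 <- dR2
    grads[[paste0(pre, "Wf2")]] <- crossprod(cc$G1, dF2)
    grads[[paste0(pre, "bf2")]] <- colSums(dF2)
    dG1 <- tcrossprod(dF2, params[[paste0(pre, "Wf2")]])
    dF1 <- dG1 * (0.5 * (1 + cc$th1) + 0.5 * cc$F1 * (1 - cc$th1^2) *
                    GELU_C * (1 + 3 * 0.044715 * cc$F1^2))
    grads[[paste0(pre, "Wf1")]] <- crossprod(cc$X1, dF1)
    grads[[paste0(pre, "bf1")]] <- colSums(dF1)
    dX1 <- dX1 + tcrossprod(dF1, params[[paste0(pre, "Wf1")]])
    lb1 <- layer_norm_bwd(dX1, cc$ln1$xhat, cc$ln1$inv, params[[paste0(pre, "ln1_g")]])
    grads[[paste0(pre, "ln1_g")]] <- lb1$dg
    grads[[paste0(pre, "ln1_b")]] <- lb1$db
    dR1 <- lb1$dX
    dO <- if (is.null(cc$D1)) dR1 else dR1 * cc$D1
    dXin <- dR1
    grads[[paste0(pre, "Wo")]] <- crossprod(cc$Ctx, dO)
    grads[[paste0(pre, "bo")]] <- colSums(dO)
    dCtx <- tcrossprod(dO, params[[paste0(pre, "Wo")]])
    dQ <- matrix(0, B * L, H); dK <- matrix(0, B * L, H); dV <- matrix(0, B * L, H)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        A <- cc$A[[b]][[h]]
        dCb <- dCtx[rows, cols, drop = FALSE]
        dA <- tcrossprod(dCb, cc$V[rows, cols, drop = FALSE])
        dV[rows, cols] <- crossprod(A, dCb)
        dS <- A * (dA - rowSums(dA * A))
        dS <- dS / sqrt(dh)
        dQ[rows, cols] <- dS %*% cc$K[rows, cols, drop = FALSE]
        dK[rows, cols] <- crossprod(dS, cc$Q[rows, cols, drop = FALSE])
      }
    }
    grads[[paste0(pre, "Wq")]] <- crossprod(cc$Xin, dQ)
    grads[[paste0(pre, "bq")]] <- colSums(dQ)
    grads[[paste0(pre, "Wk")]] <- crossprod(cc$Xin, dK)
    grads[[paste0(pre, "bk")]] <- colSums(dK)
    grads[[paste0(pre, "Wv")]] <- crossprod(cc$Xin, dV)
    grads[[paste0(pre, "bv")]] <- colSums(dV)
    dXin <- dXin + tcrossprod(dQ, params[[paste0(pre, "Wq")]]) +
      tcrossprod(dK, params[[paste0(pre, "Wk")]]) +
      tcrossprod(dV, params[[paste0(pre, "Wv")]])
    dX <- dXin
  }
  if (!is.null(cache$D0)) dX <- dX * cache$D0
  list(dX0 = dX, grads = grads)
}

# scatter embedding gradients back to the lookup tables
embedding_bwd <- function(dX0, batch, model) {
  cfg <- model$config
  ch <- cfg$active_channels
  grads <- list()
  scatter <- function(ids_mat, n_rows) {
    ids <- as.integer(t(ids_mat)) + 1L
    rs <- rowsum(dX0, ids)
    out <- matrix(0, n_rows, cfg$hidden_size)
    out[as.integer(rownames(rs)), ] <- rs
    out
  }
  if ("disease" %in% ch) grads$tok_emb <- scatter(batch$token_ids, model$vocab$n_total)
  if ("age" %in% ch) grads$age_emb <- scatter(batch$age_ids, AGE_VOCAB_SIZE)
  if ("segment" %in% ch) grads$seg_emb <- scatter(batch$segment_ids, 2L)
  grads
}

#' Run the encoder over one tokenized sequence
#'
#' Embeds the sequence and applies the full self-attention stack, returning
#' every position's final hidden state and, on request, all attention maps.
#' Rows of each attention matrix are softmax-normalized over the real
#' (non-padding) positions.
#'
#' @param model An `ehrt_model`.
#' @param seq A `tokenized_sequence`.
#' @param want_attentions Keep per-layer, per-head attention matrices?
#' @return A list with `hidden_states` (`seq_len x hidden_size`) and
#'   `attentions` (list over layers of lists over heads of `seq_len x
#'   seq_len` matrices, or `NULL`).
#' @export
ehrt_encode <- function(model, seq, want_attentions = FALSE) {
  batch <- pad_batch(list(seq))
  X0 <- embed_batch(model, batch)
  out <- encoder_fwd(model$params, model$config, X0, batch$mask,
                     want_attn = want_attentions)
  attn <- NULL
  if (want_attentions) {
    attn <- lapply(out$attentions, function(layer) layer[[1]])
  }
  list(hidden_states = out$H, attentions = attn)
}

#' Masked-language-model head
#'
#' Dense transform with GELU nonlinearity followed by an output projection
#' onto the full token vocabulary, applied position-wise.
#'
#' @param model An `ehrt_model`.
#' @param hidden_states Matrix of encoder outputs (`n x hidden_size`).
#' @return `n x vocab_size` score matrix (unnormalized logits).
#' @export
ehrt_mlm_head <- function(model, hidden_states) {
  p <- model$params
  A1 <- add_bias(hidden_states %*% p$mlm_Wt, p$mlm_bt)
  add_bias(gelu(A1) %*% p$mlm_Wd, p$mlm_bd)
}

mlm_head_fwd <- function(params, Hrows) {
  A1 <- add_bias(Hrows %*% params$mlm_Wt, params$mlm_bt)
  G <- gelu(A1)
  S <- add_bias(G %*% params$mlm_Wd, params$mlm_bd)
  list(S = S, A1 = A1, G = G, Hrows = Hrows)
}

mlm_head_bwd <- function(dS, cache, params) {
  grads <- list(
    mlm_Wd = crossprod(cache$G, dS),
    mlm_bd = colSums(dS)
  )
  dG <- tcrossprod(dS, params$mlm_Wd)
  dA1 <- dG * gelu_grad(cache$A1)
  grads$mlm_Wt <- crossprod(cache$Hrows, dA1)
  grads$mlm_bt <- colSums(dA1)
  list(dH = tcrossprod(dA1, params$mlm_Wt), grads = grads)
}

#' Pool the encoder output and classify diseases
#'
#' The patient representation is either the CLS (first-token) hidden state
#' or the mean hidden state over real tokens, per the model configuration's
#' `pooling`; it passes through a dense + tanh pooling layer, then a single
#' feed-forward classifier with a per-disease sigmoid, giving `G`
#' independent probabilities.
#'
#' @param model An `ehrt_model`.
#' @param hidden_states Encoder output rows for the real (non-padding)
#'   tokens, CLS first.
#' @return Numeric vector of `G` probabilities in (0, 1), named by code.
#' @export
ehrt_classify <- function(model, hidden_states) {
  p <- model$params
  pooled <- if (identical(model$config$pooling, "cls")) {
    hidden_states[1, , drop = FALSE]
  } else {
    matrix(colMeans(hidden_states), 1)
  }
  out <- classifier_fwd(p, pooled)
  stats::setNames(as.numeric(out$P2), model$vocab$codes)
}

# pooled representation rows for a padded batch, and the scatter of its
# gradient back onto hidden-state rows
pool_rows_fwd <- function(H, batch, pooling) {
  if (identical(pooling, "cls")) {
    return(H[(seq_len(batch$B) - 1L) * batch$L + 1L, , drop = FALSE])
  }
  grp <- rep(seq_len(batch$B), each = batch$L)
  real <- as.logical(t(batch$mask))
  n_real <- rowSums(batch$mask)
  rowsum(H[real, , drop = FALSE], grp[real]) / n_real
}

pool_rows_bwd <- function(dHc, batch, pooling, N, H_width) {
  dH <- matrix(0, N, H_width)
  if (identical(pooling, "cls")) {
    dH[(seq_len(batch$B) - 1L) * batch$L + 1L, ] <- dHc
    return(dH)
  }
  n_real <- rowSums(batch$mask)
  real <- as.logical(t(batch$mask))
  grp <- rep(seq_len(batch$B), each = batch$L)
  dH[real, ] <- (dHc / n_real)[grp[real], , drop = FALSE]
  dH
}

classifier_fwd <- function(params, Hc) {
  Pa <- add_bias(Hc %*% params$pool_W, params$pool_b)
  P <- tanh(Pa)
  logits <- add_bias(P %*% params$cls_W, params$cls_b)
  list(P2 = sigmoid(logits), logits = logits, P = P, Hc = Hc)
}

classifier_bwd <- function(dlogits, cache, params) {
  grads <- list(
    cls_W = crossprod(cache$P, dlogits),
    cls_b = colSums(dlogits)
  )
  dP <- tcrossprod(dlogits, params$cls_W)
  dPa <- dP * (1 - cache$P^2)
  grads$pool_W <- crossprod(cache$Hc, dPa)
  grads$pool_b <- colSums(dPa)
  list(dHc = tcrossprod(dPa, params$pool_W), grads = grads)
}
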