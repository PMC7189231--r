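test_that("sinusoidal table matches its closed form", {
  tab <- positional_table(5, 8)
  expect_equal(tab[1, ], rep(c(0, 1), 4))          # p = 0
  expect_true(all(tab >= -1 & tab <= 1))
  # scalar re-computation for row p = 3
  p <- 3
  for (col in seq_len(8)) {
    i <- (col - 1) %/% 2
    ang <- p / 10000^(2 * i / 8)
    expected <- if (col %% 2 == 1) sin(ang) else cos(ang)
    expect_equal(tab[p + 1, col], expected)
  }
  expect_error(positional_table(4, 7), "even")
})

test_that("embedding is the sum of active channel lookups", {
  gen <- small_sim(n = 10, seed = 3)
  vocab <- build_vocab(gen$corpus)
  model <- tiny_model(vocab)
  s <- encode_patient(gen$corpus[1, ], vocab, 24L)

  # zero learned tables leave only the positional rows
  m0 <- model
  m0$params$tok_emb[] <- 0; m0$params$age_emb[] <- 0; m0$params$seg_emb[] <- 0
  X <- ehrt_embed(m0, s)
  expect_equal(X, m0$pos_table[s$position_ids + 1, ])

  # naive per-token lookup-and-add oracle
  X2 <- ehrt_embed(model, s)
  for (t in sample(length(s$token_ids), 6)) {
    expected <- model$params$tok_emb[s$token_ids[t] + 1, ] +
      model$params$age_emb[s$age_ids[t] + 1, ] +
      model$params$seg_emb[s$segment_ids[t] + 1, ] +
      model$pos_table[s$position_ids[t] + 1, ]
    expect_equal(X2[t, ], expected)
  }

  # disease-only model ignores the other channels entirely
  md <- tiny_model(vocab, active_channels = "disease")
  s2 <- s
  s2$age_ids <- rev(s2$age_ids)
  s2$segment_ids <- 1L - s2$segment_ids
  s2$position_ids <- sample(s2$position_ids)
  expect_identical(ehrt_embed(md, s), ehrt_embed(md, s2))

  s_bad <- s
  s_bad$token_ids[2] <- vocab$n_total
  expect_error(ehrt_embed(model, s_bad), "out of table range")
})

test_that("attention rows over real tokens sum to one", {
  gen <- small_sim(n = 5, seed = 4)
  vocab <- build_vocab(gen$corpus)
  model <- ehrt_init(ehrt_config(dropout = 0), vocab, seed = 1)
  s <- encode_patient(gen$corpus[1, ], vocab, 64L)  # padded
  enc <- ehrt_encode(model, s, want_attentions = TRUE)
  real <- which(s$padding_mask)
  for (layer in enc$attentions) {
    for (A in layer) {
      expect_equal(rowSums(A[real, , drop = FALSE]), rep(1, length(real)),
                   tolerance = 1e-5)
      expect_true(all(A[real, !s$padding_mask] == 0))
    }
  }
})

test_that("encoder matches an independently coded naive attention block", {
  gen <- small_sim(n = 5, seed = 5)
  vocab <- build_vocab(gen$corpus)
  model <- tiny_model(vocab, seed = 11)
  # one visit, one code -> exactly 3 real tokens (CLS, code, SEP)
  corp1 <- corpus_of(make_patient("x", list(list(41, vocab$codes[3]))))
  s <- ehrformer:::trim_sequence(encode_patient(corp1[1, ], vocab, 16L))
  got <- ehrt_encode(model, s)$hidden_states

  # independent straight-line recomputation
  p <- model$params
  X <- matrix(NA_real_, 3, 4)
  for (t in 1:3) {
    X[t, ] <- p$tok_emb[s$token_ids[t] + 1, ] + p$age_emb[s$age_ids[t] + 1, ] +
      p$seg_emb[s$segment_ids[t] + 1, ] + model$pos_table[s$position_ids[t] + 1, ]
  }
  lnorm <- function(x, g, b) {
    (x - mean(x)) / sqrt(mean((x - mean(x))^2) + 1e-12) * g + b
  }
  Q <- X %*% p$L1_Wq + matrix(p$L1_bq, 3, 4, byrow = TRUE)
  K <- X %*% p$L1_Wk + matrix(p$L1_bk, 3, 4, byrow = TRUE)
  V <- X %*% p$L1_Wv + matrix(p$L1_bv, 3, 4, byrow = TRUE)
  S <- Q %*% t(K) / 2  # sqrt(d_head) = sqrt(4)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  O <- (A %*% V) %*% p$L1_Wo + matrix(p$L1_bo, 3, 4, byrow = TRUE)
  X1 <- t(vapply(1:3, function(t) lnorm(X[t, ] + O[t, ], p$L1_ln1_g, p$L1_ln1_b),
                 numeric(4)))
  F1 <- X1 %*% p$L1_Wf1 + matrix(p$L1_bf1, 3, 8, byrow = TRUE)
  F2 <- ref_gelu(F1) %*% p$L1_Wf2 + matrix(p$L1_bf2, 3, 4, byrow = TRUE)
  want <- t(vapply(1:3, function(t) lnorm(X1[t, ] + F2[t, ], p$L1_ln2_g, p$L1_ln2_b),
                   numeric(4)))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("permuting same-visit tokens permutes exactly their hidden rows", {
  gen <- small_sim(n = 20, seed = 6)
  vocab <- build_vocab(gen$corpus)
  model <- ehrt_init(ehrt_config(dropout = 0), vocab, seed = 2)
  # find a patient with a multi-code visit
  for (i in seq_len(nrow(gen$corpus))) {
    v <- gen$corpus$visits[[i]]
    wide <- which(lengths(v$codes) >= 2)
    if (length(wide) > 0) break
  }
  s1 <- ehrformer:::trim_sequence(encode_patient(gen$corpus[i, ], vocab, 64L))
  span <- which(s1$position_ids == wide[1] & s1$token_ids >= 5L)
  s2 <- s1
  s2$token_ids[span[1:2]] <- s2$token_ids[span[2:1]]
  h1 <- ehrt_encode(model, s1)$hidden_states
  h2 <- ehrt_encode(model, s2)$hidden_states
  expect_equal(h1[span[1], ], h2[span[2], ], tolerance = 1e-5)
  expect_equal(h1[span[2], ], h2[span[1], ], tolerance = 1e-5)
  expect_equal(h1[-span[1:2], ], h2[-span[1:2], ], tolerance = 1e-5)
})

test_that("mlm head and classifier heads match naive arithmetic", {
  gen <- small_sim(n = 5, seed = 8)
  vocab <- build_vocab(gen$corpus)
  model <- tiny_model(vocab, seed = 3)
  Hs <- matrix(rnorm(12), 3, 4)

  scores <- ehrt_mlm_head(model, Hs)
  expect_equal(dim(scores), c(3L, vocab$n_total))
  p <- model$params
  for (t in 1:3) {
    tr <- ref_gelu(as.numeric(Hs[t, ] %*% p$mlm_Wt) + p$mlm_bt)
    expect_equal(scores[t, ], as.numeric(tr %*% p$mlm_Wd) + p$mlm_bd)
  }
  m0 <- model
  m0$params$mlm_Wd[] <- 0; m0$params$mlm_bd[] <- 0
  expect_true(all(ehrt_mlm_head(m0, Hs) == 0))

  # mean pooling (default) and CLS pooling against naive arithmetic
  probs <- ehrt_classify(model, Hs)
  expect_length(probs, length(vocab$codes))
  expect_true(all(probs > 0 & probs < 1))
  pooled <- tanh(as.numeric(colMeans(Hs) %*% p$pool_W) + p$pool_b)
  logits <- as.numeric(pooled %*% p$cls_W) + p$cls_b
  expect_equal(unname(probs), 1 / (1 + exp(-logits)))

  mc <- model; mc$config$pooling <- "cls"
  pooled_c <- tanh(as.numeric(Hs[1, ] %*% p$pool_W) + p$pool_b)
  logits_c <- as.numeric(pooled_c %*% p$cls_W) + p$cls_b
  expect_equal(unname(ehrt_classify(mc, Hs)), 1 / (1 + exp(-logits_c)))

  m0$params$cls_W[] <- 0; m0$params$cls_b[] <- 0
  expect_equal(unname(ehrt_classify(m0, Hs)), rep(0.5, length(vocab$codes)))
})

test_that("parameter count is a deterministic function of the configuration", {
  gen <- small_sim(n = 5, seed = 9)
  vocab <- build_vocab(gen$corpus)
  G <- length(vocab$codes); V <- G + 5L
  cfg <- ehrt_config(n_layers = 2, n_heads = 2, hidden_size = 32,
                     intermediate_size = 64)
  model <- ehrt_init(cfg, vocab)
  H <- 32; I <- 64
  per_layer <- 4 * (H * H + H) +        # q, k, v, o projections
    (H * I + I) + (I * H + H) +         # feed-forward in/out
    4 * H                               # two layer norms
  expected <- (V + 112 + 2) * H +       # disease + age + segment tables
    2 * per_layer +
    (H * H + H) + (H * V + V) +         # mlm transform + decoder
    (H * H + H) + (H * G + G)           # pooler + classifier
  expect_equal(param_count(model), expected)
})

test_that("deactivated channels give exact output invariance", {
  gen <- small_sim(n = 10, seed = 10)
  vocab <- build_vocab(gen$corpus)
  s <- ehrformer:::trim_sequence(encode_patient(gen$corpus[1, ], vocab, 64L))
  for (dropped in c("age", "segment", "position")) {
    keep <- setdiff(c("disease", "age", "segment", "position"), dropped)
    model <- ehrt_init(ehrt_config(dropout = 0, active_channels = keep),
                       vocab, seed = 4)
    s2 <- s
    field <- c(age = "age_ids", segment = "segment_ids",
               position = "position_ids")[[dropped]]
    s2[[field]] <- sample(s2[[field]])
    h1 <- ehrt_encode(model, s)$hidden_states
    h2 <- ehrt_encode(model, s2)$hidden_states
    expect_identical(h1, h2)
  }
})

test_that("analytic gradients match finite differences on a tiny model", {
  gen <- small_sim(n = 6, seed = 12)
  vocab <- build_vocab(gen$corpus)
  model <- tiny_model(vocab, seed = 13)
  seqs <- encode_corpus(gen$corpus[1:3, ], vocab, 32L)
  ns <- asNamespace("ehrformer")

  check_grads <- function(pass, loss_fn) {
    eps <- 1e-5
    set.seed(20)
    for (nm in names(pass$grads)) {
      g <- pass$grads[[nm]]
      for (i in sample(length(g), min(3, length(g)))) {
        p1 <- model$params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- model$params; p2[[nm]][i] <- p2[[nm]][i] - eps
        fd <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
        expect_equal(g[i], fd, tolerance = 1e-4,
                     label = sprintf("d/d%s[%d] analytic", nm, i),
                     expected.label = "finite difference")
      }
    }
  }

  # masked-language-model loss
  set.seed(55)
  pass <- ns$mlm_batch_pass(model, seqs, masking_policy(0.5, 0.35, 0.15),
                            training = FALSE)
  check_grads(pass, function(params) {
    m <- model; m$params <- params
    set.seed(55)
    ns$mlm_batch_pass(m, seqs, masking_policy(0.5, 0.35, 0.15),
                      training = FALSE)$loss
  })

  # multi-label classification loss, both pooling modes
  set.seed(56)
  Y <- matrix(rbinom(3 * length(vocab$codes), 1, 0.3), 3)
  for (pool in c("mean", "cls")) {
    model$config$pooling <- pool
    pass2 <- ns$cls_batch_pass(model, seqs, Y, training = FALSE)
    check_grads(pass2, function(params) {
      m <- model; m$params <- params
      ns$cls_batch_pass(m, seqs, Y, training = FALSE)$loss
    })
  }
})

test_that("checkpoints round-trip through disk", {
  gen <- small_sim(n = 5, seed = 14)
  vocab <- build_vocab(gen$corpus)
  model <- tiny_model(vocab)
  tmp <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(model, tmp)
  back <- read_checkpoint(tmp)
  expect_equal(back$params, model$params)
  expect_equal(back$config, model$config)
  s <- ehrformer:::trim_sequence(encode_patient(gen$corpus[1, ], vocab, 32L))
  expect_identical(ehrt_encode(model, s)$hidden_states,
                   ehrt_encode(back, s)$hidden_states)
})
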