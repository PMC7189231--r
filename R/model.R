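#' Model configuration
#'
#' Architecture of the bidirectional self-attention encoder. The published
#' full-scale architecture is 6 layers, 12 heads, hidden size 288 and
#' intermediate size 512 (`ehrt_config(n_layers = 6, n_heads = 12,
#' hidden_size = 288, intermediate_size = 512)`); the default here is a
#' desk-scale model (2 layers, 2 heads, hidden 32, intermediate 64) that the
#' test-suite experiments use.
#'
#' @param n_layers Number of encoder blocks.
#' @param n_heads Attention heads; must divide `hidden_size`.
#' @param hidden_size Width of all hidden representations (even).
#' @param intermediate_size Width of the position-wise feed-forward layer.
#' @param max_position Highest representable visit ordinal + 1; rows of the
#'   fixed sinusoidal table.
#' @param dropout Dropout probability applied during training to the summed
#'   embedding and to each sub-layer output.
#' @param active_channels Subset of `c("disease", "age", "segment",
#'   "position")`; deactivated channels contribute exactly zero to the input
#'   embedding, making the model provably invariant to their ids.
#' @param pooling How the patient representation is formed for
#'   classification: `"cls"` pools the first (CLS) token's hidden state,
#'   `"mean"` averages the hidden states of all real tokens. Both then pass
#'   through the dense + tanh pooling layer.
#' @return An `ehrt_config` list.
#' @export
ehrt_config <- function(n_layers = 2L, n_heads = 2L, hidden_size = 32L,
                        intermediate_size = 64L, max_position = 128L,
                        dropout = 0.1,
                        active_channels = c("disease", "age", "segment", "position"),
                        pooling = c("mean", "cls")) {
  pooling <- match.arg(pooling)
  if (hidden_size %% n_heads != 0) stop("hidden_size must be divisible by n_heads", call. = FALSE)
  if (hidden_size %% 2L != 0) stop("hidden_size must be even", call. = FALSE)
  active_channels <- match.arg(active_channels,
                               c("disease", "age", "segment", "position"),
                               several.ok = TRUE)
  if (!"disease" %in% active_channels) {
    stop("the disease channel is always active", call. = FALSE)
  }
  structure(
    list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
         hidden_size = as.integer(hidden_size),
         intermediate_size = as.integer(intermediate_size),
         max_position = as.integer(max_position), dropout = dropout,
         active_channels = active_channels, pooling = pooling),
    class = "ehrt_config"
  )
}

#' Fixed sinusoidal positional table
#'
#' Row `p` (0-based), column pair `(2i, 2i + 1)` (0-based) holds
#' `sin(p / 10000^(2i / hidden_size))` and `cos(p / 10000^(2i /
#' hidden_size))`. The table is pre-determined, never trained, and indexed by
#' *visit ordinal*, shared by every token of a visit.
#'
#' @param max_position Number of rows (positions `0 .. max_position - 1`).
#' @param hidden_size Even table width.
#' @return A `max_position x hidden_size` matrix.
#' @examples
#' positional_table(4, 8)[1, ]  # position 0: sin 0 = 0, cos 0 = 1 alternating
#' @export
positional_table <- function(max_position, hidden_size) {
  if (hidden_size %% 2L != 0) stop("hidden_size must be even", call. = FALSE)
  p <- seq_len(max_position) - 1L
  i <- seq_len(hidden_size %/% 2L) - 1L
  arg <- outer(p, 1 / 10000^(2 * i / hidden_size))
  out <- matrix(0, max_position, hidden_size)
  out[, 2L * i + 1L] <- sin(arg)
  out[, 2L * i + 2L] <- cos(arg)
  out
}

#' Initialize a model
#'
#' Dense projection weights use Glorot-scaled normal draws,
#' `N(0, 2 / (fan_in + fan_out))`, so signal propagation does not depend on
#' the hidden size; embedding tables use `N(0, 1/hidden_size)`; biases and
#' layer-norm parameters start at their identities; the positional table is
#' fixed. The returned object carries the configuration, the vocabulary and
#' a flat named parameter list.
#'
#' @param config An [ehrt_config()].
#' @param vocab A [disease_vocab][build_vocab]; fixes the token and output
#'   vocabulary sizes.
#' @param seed Integer seed for the initialization draw.
#' @return An `ehrt_model`.
#' @export
ehrt_init <- function(config, vocab, seed = 0L) {
  stopifnot(inherits(config, "ehrt_config"), inherits(vocab, "disease_vocab"))
  H <- config$hidden_size
  V <- vocab$n_total
  G <- length(vocab$codes)
  set.seed(seed)
  mat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
  emb <- function(nr) matrix(stats::rnorm(nr * H, sd = sqrt(1 / H)), nr, H)
  params <- list(
    tok_emb = emb(V),
    age_emb = emb(AGE_VOCAB_SIZE),
    seg_emb = emb(2L)
  )
  for (l in seq_len(config$n_layers)) {
    pre <- sprintf("L%d_", l)
    params[[paste0(pre, "Wq")]] <- mat(H, H); params[[paste0(pre, "bq")]] <- numeric(H)
    params[[paste0(pre, "Wk")]] <- mat(H, H); params[[paste0(pre, "bk")]] <- numeric(H)
    params[[paste0(pre, "Wv")]] <- mat(H, H); params[[paste0(pre, "bv")]] <- numeric(H)
    params[[paste0(pre, "Wo")]] <- mat(H, H); params[[paste0(pre, "bo")]] <- numeric(H)
    params[[paste0(pre, "ln1_g")]] <- rep(1, H); params[[paste0(pre, "ln1_b")]] <- numeric(H)
    params[[paste0(pre, "Wf1")]] <- mat(H, config$intermediate_size)
    params[[paste0(pre, "bf1")]] <- numeric(config$intermediate_size)
    params[[paste0(pre, "Wf2")]] <- mat(config$intermediate_size, H)
    params[[paste0(pre, "bf2")]] <- numeric(H)
    params[[paste0(pre, "ln2_g")]] <- rep(1, H); params[[paste0(pre, "ln2_b")]] <- numeric(H)
  }
  params$mlm_Wt <- mat(H, H); params$mlm_bt <- numeric(H)
  params$mlm_Wd <- mat(H, V); params$mlm_bd <- numeric(V)
  params$pool_W <- mat(H, H); params$pool_b <- numeric(H)
  params$cls_W <- mat(H, G); params$cls_b <- numeric(G)
  structure(
    list(config = config, vocab = vocab, params = params,
         pos_table = positional_table(config$max_position, H),
         history = NULL, stage = "initialized"),
    class = "ehrt_model"
  )
}

#' @export
print.ehrt_model <- function(x, ...) {
  cfg <- x$config
  cat("<ehrt_model> ", cfg$n_layers, " layers, ", cfg$n_heads, " heads, hidden ",
      cfg$hidden_size, ", intermediate ", cfg$intermediate_size, "\n",
      "  vocab: ", length(x$vocab$codes), " diseases + specials; channels: ",
      paste(cfg$active_channels, collapse = "+"), "\n",
      "  parameters: ", param_count(x), "; stage: ", x$stage, "\n", sep = "")
  invisible(x)
}

#' Number of learned parameters
#'
#' A deterministic function of the configuration and vocabulary sizes; the
#' frozen positional table is not counted.
#'
#' @param model An `ehrt_model`.
#' @return Integer parameter count.
#' @export
param_count <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing list (configuration, vocabulary,
#' named parameter arrays, training history) serialized with `saveRDS()`.
#'
#' @param model An `ehrt_model`.
#' @param path Checkpoint file path.
#' @return `read_checkpoint()` returns the model; `write_checkpoint()`
#'   returns `path` invisibly.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ehrt_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- readRDS(path)
  class(obj$config) <- "ehrt_config"
  class(obj$vocab) <- "disease_vocab"
  structure(obj, class = "ehrt_model")
}

#' Export learned disease embeddings as TSV
#'
#' One row per disease code: the code followed by its `hidden_size`
#' embedding coordinates. Special tokens are excluded. The file feeds any
#' external projector (t-SNE, UMAP) or similarity analysis.
#'
#' @param model An `ehrt_model`.
#' @param path Output TSV path.
#' @return The exported tibble, invisibly.
#' @export
export_embeddings <- function(model, path) {
  emb <- disease_embeddings(model)
  df <- tibble::as_tibble(as.data.frame(emb), .name_repair = ~ paste0("h", seq_along(.x)))
  df <- dplyr::bind_cols(tibble::tibble(code = rownames(emb)), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

# learned embedding rows of the disease codes only (specials dropped)
disease_embeddings <- function(model) {
  ids <- code_to_id(model$vocab, model$vocab$codes)
  emb <- model$params$tok_emb[ids + 1L, , drop = FALSE]
  rownames(emb) <- model$vocab$codes
  emb
}
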