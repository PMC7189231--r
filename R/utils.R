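`%||%` <- function(x, y) if (is.null(x)) y else x

# Age-embedding granularity: one id per completed year of life, 0..110,
# plus a catch-all id for implausible ages.
AGE_MAX_YEARS <- 110L
AGE_UNK_ID <- AGE_MAX_YEARS + 1L
AGE_VOCAB_SIZE <- AGE_MAX_YEARS + 2L

age_months_to_id <- function(age_months) {
  yrs <- age_months %/% 12L
  yrs[yrs > AGE_MAX_YEARS] <- AGE_UNK_ID
  as.integer(yrs)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# GELU, tanh approximation (Hendrycks & Gimpel), and its exact derivative
GELU_C <- sqrt(2 / pi)
gelu <- function(x) 0.5 * x * (1 + tanh(GELU_C * (x + 0.044715 * x^3)))
gelu_grad <- function(x) {
  inner <- GELU_C * (x + 0.044715 * x^3)
  th <- tanh(inner)
  0.5 * (1 + th) + 0.5 * x * (1 - th^2) * GELU_C * (1 + 3 * 0.044715 * x^2)
}

# add a length-ncol bias vector to every row of a matrix
add_bias <- function(m, b) m + rep(b, each = nrow(m))

row_max <- function(s) s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]

row_softmax <- function(s) {
  e <- exp(s - row_max(s))
  e / rowSums(e)
}
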