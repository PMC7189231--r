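# Fixtures are built in code; ages are integer months.

# one patient from a compact spec: list of (age_years, codes)
make_patient <- function(id, visits, follow_up = 18L, attributes = list()) {
  vs <- lapply(visits, function(v) list(age_months = as.integer(v[[1]] * 12), codes = v[[2]]))
  last_age <- vs[[length(vs)]]$age_months
  list(patient_id = id, observation_end_age_months = last_age + follow_up,
       attributes = attributes, visits = vs)
}

corpus_of <- function(...) ehr_corpus(list(...))

# small planted-structure corpus + vocab, shared across files
small_sim <- function(n = 80, seed = 1, ...) {
  generate_corpus(sim_config(n_patients = n, n_codes = 20, n_groups = 4,
                             codes_per_group = 5, seed = seed, ...))
}

tiny_model <- function(vocab, seed = 7, dropout = 0, ...) {
  ehrt_init(ehrt_config(n_layers = 1, n_heads = 1, hidden_size = 4,
                        intermediate_size = 8, dropout = dropout, ...),
            vocab, seed = seed)
}

# reference GELU used by independent oracles (tanh form)
ref_gelu <- function(x) 0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))

# vocabulary straight from a code list (no corpus needed)
new_vocab_for <- function(codes) ehrformer:::new_vocab(sort(codes))

# independent brute-force metric oracles
bf_aps <- function(scores, pos_idx) {
  ord <- order(scores, decreasing = TRUE)
  hits <- 0; total <- 0
  for (r in seq_along(ord)) {
    if (ord[r] %in% pos_idx) {
      hits <- hits + 1
      total <- total + hits / r
    }
  }
  total / length(pos_idx)
}
bf_auroc <- function(scores, pos_idx) {
  neg_idx <- setdiff(seq_along(scores), pos_idx)
  s <- 0
  for (i in pos_idx) for (j in neg_idx) {
    s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  s / (length(pos_idx) * length(neg_idx))
}

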