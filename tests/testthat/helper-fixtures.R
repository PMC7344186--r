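# Shared fixtures. Heavy objects (trained models on the default synthetic
# corpus) are memoized so several test files can reuse one training run.

.fixtures <- new.env(parent = emptyenv())

# small hand-built raw corpus: 2 patients, mixed categories
tiny_corpus <- function() {
  list(
    patient_record("p1", list(
      visit_event(0L, c("fever", "hcq", "ana_test"),
                  c("symptom", "medication", "lab_test")),
      visit_event(30L, c("fever", "nephritis"), c("symptom", "diagnosis")))),
    patient_record("p2", list(
      visit_event("2011-02-01", c("rash", "prednisone"),
                  c("symptom", "medication")),
      visit_event("2011-01-01", c("rash", "ana_test"),
                  c("symptom", "lab_test")))))
}

# indexed two-visit record over a 3-code vocabulary, for loss/gradient tests
tiny_vocab <- function() {
  ehrvec:::new_vocabulary(c("a", "b", "c"),
                          c("symptom", "medication", "diagnosis"),
                          c(2L, 2L, 1L))
}

tiny_indexed_record <- function() {
  patient_record("p1", list(list(timestamp = 0L, entities = c(1L, 2L)),
                            list(timestamp = 5L, entities = c(1L, 3L))))
}

# default-conditions synthetic corpus and the model trained on it
default_sim <- function(seed = 7L) {
  key <- paste0("sim", seed)
  if (is.null(.fixtures[[key]])) {
    sim <- generate_corpus(sim_config(seed = seed))
    recs <- suppressMessages(filter_patients(sim$records))
    recs <- lapply(recs, sort_visits_temporally)
    vocab <- build_vocabulary(recs)
    indexed <- suppressMessages(index_corpus(recs, vocab))
    .fixtures[[key]] <- list(sim = sim, records = recs, vocab = vocab,
                             indexed = indexed,
                             truth = sim$truth[vocab$codes])
  }
  .fixtures[[key]]
}

desk_config <- function(seed = 7L, epochs = 20L) {
  train_config(dim = 32L, n_heads = 4L, ff_dim = 128L, epochs = epochs,
               optimizer = "adam", seed = seed)
}

trained_model <- function(seed = 7L) {
  key <- paste0("model", seed)
  if (is.null(.fixtures[[key]])) {
    d <- default_sim(seed)
    .fixtures[[key]] <- train_ehr2vec(d$indexed, d$vocab,
                                      desk_config(seed = seed))
  }
  .fixtures[[key]]
}

# cosine matrix with NA diagonal
cosine_matrix <- function(W) {
  Wn <- W / sqrt(rowSums(W * W))
  Cs <- tcrossprod(Wn)
  diag(Cs) <- NA
  Cs
}

# fraction of non-background entities whose top-1 neighbor shares the topic
nn_topic_purity <- function(W, truth) {
  Cs <- cosine_matrix(W)
  nonbg <- which(!is.na(truth))
  mean(vapply(nonbg, function(i) {
    j <- which.max(replace(Cs[i, ], i, -Inf))
    !is.na(truth[[j]]) && truth[[j]] == truth[[i]]
  }, logical(1)))
}

topic_cosine_means <- function(W, truth) {
  Cs <- cosine_matrix(W)
  same <- outer(truth, truth, function(a, b) !is.na(a) & !is.na(b) & a == b)
  diff <- outer(truth, truth, function(a, b) !is.na(a) & !is.na(b) & a != b)
  diag(same) <- FALSE
  c(within = mean(Cs[same], na.rm = TRUE),
    between = mean(Cs[diff], na.rm = TRUE))
}

# brute-force scalar-loop attention oracle, independent of the vectorized path
attention_oracle <- function(Q, K, V) {
  n <- nrow(Q); d <- ncol(Q)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    scores <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) {
      s <- 0
      for (k in seq_len(d)) s <- s + Q[i, k] * K[j, k]
      scores[j] <- s / sqrt(d)
    }
    w <- exp(scores - max(scores))
    w <- w / sum(w)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# brute-force ordered-pair corpus log-likelihood oracle
loglik_oracle <- function(W, records) {
  total <- 0; nv <- 0L
  for (rec in records) for (v in rec$visits) {
    nv <- nv + 1L
    idx <- v$entities
    for (i in idx) for (j in idx) {
      if (i != j) {
        num <- sum(W[i, ] * W[j, ])
        den <- log(sum(exp(W %*% W[i, ])))
        total <- total + num - den
      }
    }
  }
  if (nv == 0L) 0 else total / nv
}
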