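test_that("conditional co-occurrence probabilities follow the shared-matrix softmax", {
  # all rows identical -> uniform conditional p = 1/h
  W <- matrix(1, 4, 3)
  emb <- ehr_embedding(W, ehrvec:::new_vocabulary(
    paste0("e", 1:4), rep("symptom", 4), rep(1L, 4)))
  for (j in 2:4) expect_equal(cooccurrence_logprob(emb, 1L, j), log(1 / 4))

  # h = 2 identity embedding: p(e2|e1) = 1 / (1 + e)
  W2 <- diag(2)
  emb2 <- ehr_embedding(W2, ehrvec:::new_vocabulary(
    c("a", "b"), c("symptom", "symptom"), c(1L, 1L)))
  expect_equal(cooccurrence_logprob(emb2, 1L, 2L), log(1 / (1 + exp(1))))

  # the full conditional (diagonal included) sums to 1
  set.seed(2)
  W3 <- matrix(rnorm(15), 5, 3)
  emb3 <- ehr_embedding(W3, ehrvec:::new_vocabulary(
    paste0("e", 1:5), rep("symptom", 5), rep(1L, 5)))
  for (i in 1:5) {
    p_others <- sum(vapply(setdiff(1:5, i), function(j)
      exp(cooccurrence_logprob(emb3, i, j)), numeric(1)))
    s <- as.vector(W3 %*% W3[i, ])
    p_self <- exp(s[i] - ehrvec:::logsumexp(s))
    expect_equal(p_others + p_self, 1, tolerance = 1e-9)
  }

  expect_error(cooccurrence_logprob(emb2, 1L, 1L), "j = i")
})

test_that("corpus log-likelihood equals ordered-pair brute-force enumeration", {
  set.seed(5)
  W <- matrix(rnorm(6), 3, 2)
  emb <- ehr_embedding(W, tiny_vocab())
  recs <- list(patient_record("p", list(
    list(timestamp = 0L, entities = c(1L, 2L)),
    list(timestamp = 1L, entities = c(1L, 3L)))))
  expect_lt(abs(corpus_log_likelihood(emb, recs) - loglik_oracle(W, recs)),
            1e-10)

  # larger random corpus (still <= 20 pairs) against the oracle
  recs2 <- list(patient_record("q", list(
    list(timestamp = 0L, entities = c(1L, 2L, 3L)),
    list(timestamp = 2L, entities = c(2L, 3L)),
    list(timestamp = 5L, entities = 1L))))
  expect_lt(abs(corpus_log_likelihood(emb, recs2) - loglik_oracle(W, recs2)),
            1e-10)

  # single-entity visits contribute zero
  solo <- list(patient_record("s", list(
    list(timestamp = 0L, entities = 1L), list(timestamp = 1L, entities = 2L))))
  expect_identical(corpus_log_likelihood(emb, solo), 0)

  # duplicating the corpus leaves the per-visit mean unchanged
  expect_equal(corpus_log_likelihood(emb, c(recs, recs)),
               corpus_log_likelihood(emb, recs))
})

test_that("analytic gradients match central differences on tiny instances", {
  vocab <- tiny_vocab()
  rec <- tiny_indexed_record()
  # within + cross, 1 head
  cfg <- train_config(dim = 2L, n_heads = 1L, ff_dim = 3L, window = 1L,
                      lambda = 1.0, seed = 3L)
  expect_lt(numerical_gradient_check(list(rec), vocab, cfg), 1e-5)

  # within-visit loss only
  cfg0 <- train_config(dim = 2L, n_heads = 1L, ff_dim = 3L, window = 1L,
                       lambda = 0, seed = 3L)
  expect_lt(numerical_gradient_check(list(rec), vocab, cfg0), 1e-5)

  # cross-visit loss only (single-entity visits have no within pairs)
  solo <- patient_record("p2", list(
    list(timestamp = 0L, entities = 1L), list(timestamp = 5L, entities = 2L)))
  expect_lt(numerical_gradient_check(list(solo), vocab, cfg), 1e-5)

  # multi-head instance
  cfg2 <- train_config(dim = 4L, n_heads = 2L, ff_dim = 6L, window = 1L,
                       lambda = 0.5, seed = 5L)
  expect_lt(numerical_gradient_check(list(rec), vocab, cfg2), 1e-5)

  # lambda = 0 reduces the total gradient to the within-visit gradient
  units <- ehrvec:::build_visit_units(list(rec), 1L)
  set.seed(7)
  W <- matrix(rnorm(6, sd = 0.3), 3, 2)
  p <- attention_params(dim = 2L, n_heads = 1L, ff_dim = 3L, dropout = 0,
                        seed = 7L)
  g_tot <- ehrvec:::ehr2vec_loss(W, p, units, lambda = 0,
                                 want_grads = TRUE)$grads
  units_nocross <- lapply(units, function(u) { u$cross <- integer(0); u })
  g_within <- ehrvec:::ehr2vec_loss(W, p, units_nocross, lambda = 1,
                                    want_grads = TRUE)$grads
  expect_equal(g_tot, g_within)
})

test_that("training is seeded, reproducible, and a no-op at zero epochs", {
  d <- default_sim()
  # epochs = 0 returns the seeded initialization
  cfg0 <- desk_config(epochs = 0L)
  fit0 <- train_ehr2vec(d$indexed, d$vocab, cfg0)
  W_init <- ehrvec:::with_seed(cfg0$seed, matrix(
    stats::runif(length(d$vocab$codes) * cfg0$dim, -0.5 / cfg0$dim,
                 0.5 / cfg0$dim), length(d$vocab$codes), cfg0$dim))
  expect_equal(unname(fit0$embedding$W), W_init)
  expect_identical(nrow(fit0$trace), 0L)

  # identical seeds -> bit-identical embeddings (short run)
  small <- d$indexed[1:40]
  fa <- train_ehr2vec(small, d$vocab, desk_config(epochs = 2L))
  fb <- train_ehr2vec(small, d$vocab, desk_config(epochs = 2L))
  expect_identical(fa$embedding$W, fb$embedding$W)
  expect_identical(fa$trace, fb$trace)
  # a different seed changes the result
  fc <- train_ehr2vec(small, d$vocab, desk_config(seed = 8L, epochs = 2L))
  expect_false(identical(fa$embedding$W, fc$embedding$W))

  # degenerate inputs refuse to train
  expect_error(train_ehr2vec(list(), d$vocab, desk_config()), "empty")

  # published defaults are recorded on the config object
  pub <- train_config()
  expect_identical(pub$epochs, 20L)
  expect_identical(pub$dropout, 0.1)
  expect_identical(pub$optimizer, "adadelta")
  expect_identical(pub$dim, 512L)
  expect_identical(pub$n_heads, 8L)
})

test_that("visit-attention training recovers the planted topic structure", {
  d <- default_sim()
  fit <- trained_model()
  # loss decreases over training
  expect_lt(fit$trace$total[nrow(fit$trace)], fit$trace$total[1])
  # within-topic cosine exceeds between-topic cosine
  tc <- topic_cosine_means(fit$embedding$W, d$truth)
  expect_gt(tc[["within"]], tc[["between"]])
  # nearest-neighbor topic purity on the default corpus
  expect_gte(nn_topic_purity(fit$embedding$W, d$truth), 0.70)
  # training also improves the co-occurrence log-likelihood it optimizes
  init <- train_ehr2vec(d$indexed, d$vocab, desk_config(epochs = 0L))
  expect_gt(corpus_log_likelihood(fit$embedding, d$indexed),
            corpus_log_likelihood(init$embedding, d$indexed))
})

test_that("skip-gram baseline trains, respects its window, and recovers topics", {
  d <- default_sim()
  # epochs = 0 -> seeded initialization
  cfg0 <- desk_config(epochs = 0L)
  sg0 <- train_skipgram_baseline(d$indexed, d$vocab, cfg0)
  W_init <- ehrvec:::with_seed(cfg0$seed, matrix(
    stats::runif(length(d$vocab$codes) * cfg0$dim, -0.5 / cfg0$dim,
                 0.5 / cfg0$dim), length(d$vocab$codes), cfg0$dim))
  expect_equal(unname(sg0$embedding$W), W_init)

  # window = 0 -> no context pairs, W unchanged after an epoch
  sgw0 <- train_skipgram_baseline(d$indexed, d$vocab, desk_config(epochs = 1L),
                                  window = 0L)
  expect_equal(unname(sgw0$embedding$W), W_init)

  # short training separates planted topics
  sg <- train_skipgram_baseline(d$indexed, d$vocab, desk_config(epochs = 5L),
                                window = 5L)
  tc <- topic_cosine_means(sg$embedding$W, d$truth)
  expect_gt(tc[["within"]], tc[["between"]])
  expect_lt(sg$trace$total[nrow(sg$trace)], sg$trace$total[1])
})

test_that("embedding text format and checkpoints round-trip losslessly", {
  d <- default_sim()
  fit <- train_ehr2vec(d$indexed[1:20], d$vocab, desk_config(epochs = 1L))
  path <- withr::local_tempfile(fileext = ".txt")
  vpath <- withr::local_tempfile(fileext = ".tsv")
  write_embeddings(fit$embedding, path, vocab_path = vpath)
  back <- read_embeddings(path, vpath)
  expect_identical(back$W, fit$embedding$W)
  expect_equal(back$vocab, fit$embedding$vocab)
  hdr <- strsplit(readLines(path, n = 1L), " ")[[1]]
  expect_identical(as.integer(hdr), c(nrow(fit$embedding$W),
                                      ncol(fit$embedding$W)))

  ck <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(fit, ck)
  back2 <- read_checkpoint(ck)
  expect_equal(unname(back2$embedding$W), unname(fit$embedding$W))
  expect_equal(back2$params$Wo, fit$params$Wo)
  expect_equal(back2$params$Wq, fit$params$Wq)
  expect_equal(back2$trace$total, fit$trace$total)
})
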