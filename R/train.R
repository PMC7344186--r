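#' Training configuration
#'
#' Defaults follow the method's published configuration (512 dimensions,
#' 8 heads, Adadelta, dropout 0.1, 20 epochs); tests and the bundled
#' examples use a desk-scale configuration (`dim = 32`, `n_heads = 4`,
#' Adam) that trains in seconds on one CPU.
#'
#' @param dim Embedding / model dimension `c`.
#' @param n_heads Attention heads; must divide `dim`.
#' @param ff_dim Feed-forward inner width (default `4 * dim`).
#' @param epochs Training epochs.
#' @param dropout Attention-weight dropout rate during training.
#' @param optimizer `"adadelta"` or `"adam"`.
#' @param rho,eps Adadelta decay and stabilizer.
#' @param lr Adam learning rate.
#' @param window Visit window `w` for the cross-visit objective: visit `t`
#'   predicts the entities of visits `s` with `|s - t| <= w`, `s != t`.
#' @param lambda Weight of the cross-visit loss term.
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(dim = 512L, n_heads = 8L, ff_dim = 4L * dim,
                         epochs = 20L, dropout = 0.1,
                         optimizer = c("adadelta", "adam"),
                         rho = 0.95, eps = 1e-6, lr = 0.002,
                         window = 1L, lambda = 1.0, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (epochs < 0L) stop("epochs must be >= 0", call. = FALSE)
  if (window < 0L) stop("window must be >= 0", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  structure(list(dim = as.integer(dim), n_heads = as.integer(n_heads),
                 ff_dim = as.integer(ff_dim), epochs = as.integer(epochs),
                 dropout = dropout, optimizer = optimizer, rho = rho,
                 eps = eps, lr = lr, window = as.integer(window),
                 lambda = lambda, seed = as.integer(seed)),
            class = "train_config")
}

#' Embedding container
#'
#' Wraps the `h x c` matrix `W` whose row `i` is the vector of vocabulary
#' entity `i`, together with its vocabulary.
#'
#' @param W Numeric matrix, one row per vocabulary entity.
#' @param vocab The matching [build_vocabulary()] object.
#' @return An object of class `ehr_embedding`.
#' @export
ehr_embedding <- function(W, vocab) {
  W <- as.matrix(W)
  if (nrow(W) != length(vocab$codes)) {
    stop("W must have one row per vocabulary entity", call. = FALSE)
  }
  stopifnot_finite(W, "W")
  rownames(W) <- vocab$codes
  structure(list(W = W, vocab = vocab), class = "ehr_embedding")
}

#' @export
print.ehr_embedding <- function(x, ...) {
  cat("<ehr_embedding> ", nrow(x$W), " entities x ", ncol(x$W),
      " dimensions\n", sep = "")
  invisible(x)
}

#' Log conditional co-occurrence probability under the embedding
#'
#' `log p(e_j | e_i) = W[i,] . W[j,] - log sum_k exp(W[k,] . W[i,])`,
#' the full-softmax skip-gram conditional over all vocabulary entities
#' (the denominator includes `k = i`), computed with a stable
#' log-sum-exp. The diagonal `i = j` is excluded by the objective and is
#' an error here.
#'
#' @param emb An [ehr_embedding()] (or a bare matrix).
#' @param i,j Center and context entity indices, `i != j`.
#' @return The log-probability (scalar).
#' @export
cooccurrence_logprob <- function(emb, i, j) {
  W <- if (inherits(emb, "ehr_embedding")) emb$W else as.matrix(emb)
  h <- nrow(W)
  if (i < 1L || i > h || j < 1L || j > h) stop("entity index out of range",
                                               call. = FALSE)
  if (i == j) stop("the objective excludes j = i", call. = FALSE)
  s <- as.vector(W %*% W[i, ])
  s[[j]] - logsumexp(s)
}

#' Mean per-visit co-occurrence log-likelihood of a corpus
#'
#' Averages, over the `T` visit events of the corpus, the sum over all
#' ordered pairs `(i, j)`, `i != j`, of distinct entities in each visit of
#' `log p(e_j | e_i)`. Single-entity visits contribute 0.
#'
#' @param emb An [ehr_embedding()].
#' @param records Index-form records from [index_corpus()].
#' @return Scalar mean log-likelihood per visit.
#' @export
corpus_log_likelihood <- function(emb, records) {
  W <- emb$W
  h <- nrow(W)
  total <- 0
  n_visits <- 0L
  for (rec in records) {
    for (v in rec$visits) {
      n_visits <- n_visits + 1L
      idx <- v$entities
      m <- length(idx)
      if (m < 2L) next
      S <- W[idx, , drop = FALSE] %*% t(W)          # m x h scores, row = center
      lse <- apply(S, 1L, logsumexp)
      invisit <- S[, idx, drop = FALSE]             # scores of in-visit contexts
      total <- total + (sum(invisit) - sum(diag(invisit))) - (m - 1L) * sum(lse)
    }
  }
  if (n_visits == 0L) return(0)
  total / n_visits
}

# ---- loss + gradients ------------------------------------------------------

# Precompute, per visit, the entity indices and the cross-visit target pool
# (entities of visits within `window` of it, same patient).
build_visit_units <- function(records, window) {
  units <- list()
  for (rec in records) {
    ents <- lapply(rec$visits, `[[`, "entities")
    nv <- length(ents)
    for (t in seq_len(nv)) {
      lo <- max(1L, t - window)
      hi <- min(nv, t + window)
      cross <- if (window > 0L && hi >= lo) {
        unlist(ents[setdiff(lo:hi, t)], use.names = FALSE)
      } else integer(0)
      units[[length(units) + 1L]] <- list(idx = ents[[t]], cross = cross)
    }
  }
  units
}

# Forward + loss (+ optionally gradients) for one visit unit.
# W: h x c embedding; params: attention_params; unit: list(idx, cross).
# Within-visit loss: -sum over ordered pairs (i, j != i) of
#   log softmax(z_i . W[j,]) over the vocabulary (z = contextualized rows).
# Cross-visit loss: -sum over j in the window pool of
#   log softmax(v . W[j,]), v = mean contextualized vector of the visit.
visit_loss_grads <- function(W, params, unit, lambda, train_mode = FALSE,
                             want_grads = TRUE) {
  idx <- unit$idx
  m <- length(idx)
  h <- nrow(W)
  cvec <- unit$cross
  fw <- encoder_forward(W[idx, , drop = FALSE], params, train_mode = train_mode)
  Z <- fw$Z

  loss_within <- 0
  dZ <- if (want_grads) matrix(0, m, ncol(W)) else NULL
  dW_out <- if (want_grads) matrix(0, h, ncol(W)) else NULL

  if (m >= 2L) {
    Sc <- Z %*% t(W)                               # m x h
    lse <- apply(Sc, 1L, logsumexp)
    Tm <- matrix(0, m, h)
    for (r in seq_len(m)) Tm[r, idx[-r]] <- 1
    loss_within <- (m - 1L) * sum(lse) - sum(Sc * Tm)
    if (want_grads) {
      P <- exp(sweep(Sc, 1L, lse, "-"))
      Gm <- (m - 1L) * P - Tm
      dZ <- dZ + Gm %*% W
      dW_out <- dW_out + crossprod(Gm, Z)
    }
  }

  loss_cross <- 0
  if (length(cvec) > 0L) {
    vbar <- colMeans(Z)
    s <- as.vector(W %*% vbar)
    lse <- logsumexp(s)
    nT <- length(cvec)
    tv <- tabulate(cvec, nbins = h)
    loss_cross <- nT * lse - sum(s[cvec])
    if (want_grads) {
      p <- exp(s - lse)
      g <- nT * p - tv
      dW_out <- dW_out + lambda * outer(g, vbar)
      dv <- as.vector(crossprod(W, g))
      dZ <- dZ + lambda * matrix(dv / m, m, ncol(W), byrow = TRUE)
    }
  }

  out <- list(loss_within = loss_within, loss_cross = loss_cross,
              loss = loss_within + lambda * loss_cross)
  if (want_grads) {
    bk <- encoder_backward(fw, params, dZ)
    dW <- dW_out
    dW[idx, ] <- dW[idx, , drop = FALSE] + bk$X    # input-side lookup grad
    out$grads <- list(W = dW, Wq = bk$Wq, Wk = bk$Wk, Wv = bk$Wv,
                      Wo = bk$Wo, W1 = bk$W1, W2 = bk$W2)
  }
  out
}

# total corpus loss (and summed gradients) with dropout off — used by the
# gradient check and by tests; not the training path's minibatch loop.
ehr2vec_loss <- function(W, params, units, lambda, want_grads = FALSE) {
  total <- list(loss = 0, loss_within = 0, loss_cross = 0)
  grads <- NULL
  for (u in units) {
    r <- visit_loss_grads(W, params, u, lambda, train_mode = FALSE,
                          want_grads = want_grads)
    total$loss <- total$loss + r$loss
    total$loss_within <- total$loss_within + r$loss_within
    total$loss_cross <- total$loss_cross + r$loss_cross
    if (want_grads) {
      grads <- if (is.null(grads)) r$grads else add_grads(grads, r$grads)
    }
  }
  total$grads <- grads
  total
}

add_grads <- function(a, b) {
  out <- a
  for (nm in c("W", "Wo", "W1", "W2")) out[[nm]] <- a[[nm]] + b[[nm]]
  for (nm in c("Wq", "Wk", "Wv")) {
    out[[nm]] <- mapply(`+`, a[[nm]], b[[nm]], SIMPLIFY = FALSE)
  }
  out
}

# ---- optimizers ------------------------------------------------------------

# Parameters are addressed as a flat named list of matrices; the attention
# head lists are flattened to Wq.1, Wq.2, ... for the optimizer state.
flatten_params <- function(W, params) {
  out <- list(W = W, Wo = params$Wo, W1 = params$W1, W2 = params$W2)
  for (nm in c("Wq", "Wk", "Wv")) {
    for (i in seq_along(params[[nm]])) {
      out[[paste0(nm, ".", i)]] <- params[[nm]][[i]]
    }
  }
  out
}

flatten_grads <- function(g, n_heads) {
  out <- list(W = g$W, Wo = g$Wo, W1 = g$W1, W2 = g$W2)
  for (nm in c("Wq", "Wk", "Wv")) {
    for (i in seq_len(n_heads)) out[[paste0(nm, ".", i)]] <- g[[nm]][[i]]
  }
  out
}

unflatten_params <- function(flat, params) {
  W <- flat$W
  params$Wo <- flat$Wo; params$W1 <- flat$W1; params$W2 <- flat$W2
  for (nm in c("Wq", "Wk", "Wv")) {
    for (i in seq_along(params[[nm]])) {
      params[[nm]][[i]] <- flat[[paste0(nm, ".", i)]]
    }
  }
  list(W = W, params = params)
}

opt_init <- function(config, flat) {
  state <- list(step = 0L)
  zero <- lapply(flat, function(m) m * 0)
  if (config$optimizer == "adadelta") {
    state$Eg <- zero; state$Ed <- zero
  } else {
    state$m <- zero; state$v <- zero
  }
  state
}

opt_step <- function(config, flat, gflat, state) {
  state$step <- state$step + 1L
  if (config$optimizer == "adadelta") {
    rho <- config$rho; eps <- config$eps
    for (nm in names(flat)) {
      g <- gflat[[nm]]
      state$Eg[[nm]] <- rho * state$Eg[[nm]] + (1 - rho) * g * g
      dx <- -sqrt(state$Ed[[nm]] + eps) / sqrt(state$Eg[[nm]] + eps) * g
      state$Ed[[nm]] <- rho * state$Ed[[nm]] + (1 - rho) * dx * dx
      flat[[nm]] <- flat[[nm]] + dx
    }
  } else {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    lr_t <- config$lr * sqrt(1 - b2^state$step) / (1 - b1^state$step)
    for (nm in names(flat)) {
      g <- gflat[[nm]]
      state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
      state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
      flat[[nm]] <- flat[[nm]] - lr_t * state$m[[nm]] /
        (sqrt(state$v[[nm]]) + eps)
    }
  }
  list(flat = flat, state = state)
}

# ---- trainers --------------------------------------------------------------

#' Train visit-attention embeddings
#'
#' Two coupled optimization layers per visit: the entity vectors of the
#' visit (rows of `W`) are contextualized by [multi_head_attention()] and
#' the position-wise [feed_forward()] sublayer; the contextualized vector
#' `z_i` then serves as the query side of a full-softmax co-occurrence
#' objective whose output side is `W` itself (shared input/output matrix).
#' Within a visit, every ordered pair of distinct entities contributes
#' `-log softmax(z_i . W[j,])`; across visits, the mean contextualized
#' vector of visit `t` predicts the entities of visits within `window` of
#' it, weighted by `lambda`. Batch unit is one visit; visits are shuffled
#' each epoch with the seeded generator.
#'
#' @param records Index-form records from [index_corpus()].
#' @param vocab The matching vocabulary (`h >= 2`).
#' @param config A [train_config()].
#' @return A list of class `ehr2vec_model`: `embedding`
#'   ([ehr_embedding()]), `params` ([attention_params()]), `trace`
#'   (data.frame epoch/within_loss/cross_loss/total, mean per visit), and
#'   `config`.
#' @export
train_ehr2vec <- function(records, vocab, config = train_config()) {
  h <- length(vocab$codes)
  if (length(records) == 0L) stop("cannot train on an empty corpus", call. = FALSE)
  if (h < 2L) stop("vocabulary must contain at least 2 entities", call. = FALSE)
  units <- build_visit_units(records, config$window)
  if (length(units) == 0L) stop("corpus has no visits", call. = FALSE)

  with_seed(config$seed, {
    W <- matrix(stats::runif(h * config$dim, -0.5 / config$dim,
                             0.5 / config$dim), h, config$dim)
    params <- attention_params(dim = config$dim, n_heads = config$n_heads,
                               ff_dim = config$ff_dim,
                               dropout = config$dropout,
                               seed = sample.int(.Machine$integer.max, 1L))
    flat <- flatten_params(W, params)
    state <- opt_init(config, flat)
    trace <- data.frame(epoch = integer(0), within_loss = numeric(0),
                        cross_loss = numeric(0), total = numeric(0))
    nu <- length(units)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(nu)
      ew <- ec <- 0
      for (ui in ord) {
        uf <- unflatten_params(flat, params)
        r <- visit_loss_grads(uf$W, uf$params, units[[ui]], config$lambda,
                              train_mode = TRUE, want_grads = TRUE)
        ew <- ew + r$loss_within
        ec <- ec + r$loss_cross
        gflat <- flatten_grads(r$grads, config$n_heads)
        st <- opt_step(config, flat, gflat, state)
        flat <- st$flat
        state <- st$state
      }
      trace <- rbind(trace, data.frame(epoch = ep, within_loss = ew / nu,
                                       cross_loss = ec / nu,
                                       total = (ew + config$lambda * ec) / nu))
    }
    uf <- unflatten_params(flat, params)
    structure(list(embedding = ehr_embedding(uf$W, vocab),
                   params = uf$params, trace = trace, config = config),
              class = "ehr2vec_model")
  })
}

#' @export
print.ehr2vec_model <- function(x, ...) {
  cat("<ehr2vec_model> h =", nrow(x$embedding$W), "| c =", x$config$dim,
      "| heads =", x$config$n_heads, "| epochs =", x$config$epochs, "\n")
  if (nrow(x$trace) > 0L) {
    cat("  loss:", sprintf("%.4f", x$trace$total[[1L]]), "->",
        sprintf("%.4f", x$trace$total[[nrow(x$trace)]]), "\n")
  }
  invisible(x)
}

#' Skip-gram baseline with full softmax
#'
#' Flattens each patient's visits (in time order) to one token sequence and
#' trains a plain skip-gram: every token predicts its neighbors within
#' `window` positions through the shared-matrix softmax of
#' [cooccurrence_logprob()]. Same container as [train_ehr2vec()] output for
#' like-for-like evaluation. Published comparator settings: window 5,
#' minimum frequency 5 (apply the latter in [build_vocabulary()]).
#'
#' @param records Index-form records.
#' @param vocab Vocabulary.
#' @param config A [train_config()]; `window` defaults here to 5 if the
#'   config leaves it at the visit-level default.
#' @param window Skip-gram window in token positions (default 5).
#' @return A list of class `skipgram_model` with `embedding` and `trace`.
#' @export
train_skipgram_baseline <- function(records, vocab, config = train_config(),
                                    window = 5L) {
  h <- length(vocab$codes)
  if (length(records) == 0L) stop("cannot train on an empty corpus", call. = FALSE)
  if (h < 2L) stop("vocabulary must contain at least 2 entities", call. = FALSE)
  seqs <- lapply(records, function(rec) {
    unlist(lapply(rec$visits, `[[`, "entities"), use.names = FALSE)
  })
  seqs <- seqs[vapply(seqs, length, integer(1L)) > 0L]

  with_seed(config$seed, {
    W <- matrix(stats::runif(h * config$dim, -0.5 / config$dim,
                             0.5 / config$dim), h, config$dim)
    flat <- list(W = W)
    state <- opt_init(config, flat)
    trace <- data.frame(epoch = integer(0), total = numeric(0))
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(seqs))
      eloss <- 0
      for (si in ord) {
        tok <- seqs[[si]]
        L <- length(tok)
        pairs_c <- integer(0); pairs_x <- integer(0)
        if (window > 0L && L >= 2L) {
          for (off in seq_len(min(window, L - 1L))) {
            pairs_c <- c(pairs_c, tok[seq_len(L - off)], tok[(off + 1L):L])
            pairs_x <- c(pairs_x, tok[(off + 1L):L], tok[seq_len(L - off)])
          }
          keep <- pairs_c != pairs_x   # objective excludes j = i
          pairs_c <- pairs_c[keep]; pairs_x <- pairs_x[keep]
        }
        if (length(pairs_c) == 0L) next
        W <- flat$W
        cpos <- sort(unique(pairs_c))
        crow <- match(pairs_c, cpos)
        S <- W[cpos, , drop = FALSE] %*% t(W)       # centers x h
        lse <- apply(S, 1L, logsumexp)
        P <- exp(sweep(S, 1L, lse, "-"))
        cnt <- tabulate(crow, nbins = length(cpos))
        Tm <- matrix(0, length(cpos), h)
        for (k in seq_along(pairs_c)) {
          Tm[crow[[k]], pairs_x[[k]]] <- Tm[crow[[k]], pairs_x[[k]]] + 1
        }
        eloss <- eloss + sum(cnt * lse) - sum(Tm * (S))
        Gm <- cnt * P - Tm
        dW <- crossprod(Gm, W[cpos, , drop = FALSE])  # output side
        dW[cpos, ] <- dW[cpos, , drop = FALSE] + Gm %*% W  # input side
        st <- opt_step(config, flat, list(W = dW), state)
        flat <- st$flat
        state <- st$state
      }
      trace <- rbind(trace, data.frame(epoch = ep, total = eloss))
    }
    structure(list(embedding = ehr_embedding(flat$W, vocab), trace = trace,
                   config = config, window = as.integer(window)),
              class = "skipgram_model")
  })
}

# ---- gradient check --------------------------------------------------------

#' Central-difference gradient check of the training objective
#'
#' Compares the analytic gradients of the within-visit + cross-visit loss
#' (dropout off) against central finite differences for every parameter
#' entry, on a tiny instance. Intended for `h <= 5`, `c <= 4`.
#'
#' @param records Index-form records (one or two visits is enough).
#' @param vocab Vocabulary.
#' @param config A [train_config()] (dim, heads, window, lambda used).
#' @param delta Finite-difference step.
#' @return Maximum relative discrepancy over all parameters.
#' @export
numerical_gradient_check <- function(records, vocab,
                                     config = train_config(dim = 2L,
                                                           n_heads = 1L,
                                                           ff_dim = 3L),
                                     delta = 1e-5) {
  h <- length(vocab$codes)
  units <- build_visit_units(records, config$window)
  with_seed(config$seed, {
    W <- matrix(stats::rnorm(h * config$dim, sd = 0.3), h, config$dim)
    params <- attention_params(dim = config$dim, n_heads = config$n_heads,
                               ff_dim = config$ff_dim, dropout = 0,
                               seed = sample.int(.Machine$integer.max, 1L))
    analytic <- ehr2vec_loss(W, params, units, config$lambda,
                             want_grads = TRUE)$grads
    aflat <- flatten_grads(analytic, config$n_heads)
    flat <- flatten_params(W, params)
    loss_at <- function(fl) {
      uf <- unflatten_params(fl, params)
      ehr2vec_loss(uf$W, uf$params, units, config$lambda)$loss
    }
    max_rel <- 0
    for (nm in names(flat)) {
      for (k in seq_along(flat[[nm]])) {
        fp <- flat; fp[[nm]][[k]] <- fp[[nm]][[k]] + delta
        fm <- flat; fm[[nm]][[k]] <- fm[[nm]][[k]] - delta
        num <- (loss_at(fp) - loss_at(fm)) / (2 * delta)
        ana <- aflat[[nm]][[k]]
        rel <- abs(ana - num) / max(1, abs(ana) + abs(num))
        max_rel <- max(max_rel, rel)
      }
    }
    max_rel
  })
}
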