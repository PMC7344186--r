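#' Cosine similarity of two vectors
#'
#' `u . v / (|u| |v|)`, clamped to `[-1, 1]` against rounding. Zero-norm
#' input is an error: a degenerate (all-zero) embedding vector signals a
#' training bug rather than a meaningful query.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length", call. = FALSE)
  nu <- sqrt(sum(u * u))
  nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) stop("cosine undefined for a zero-norm vector",
                               call. = FALSE)
  max(-1, min(1, sum(u * v) / (nu * nv)))
}

#' Rank entities by cosine similarity to a query entity
#'
#' Scores every *other* vocabulary entity against the query by cosine
#' similarity, sorts descending (ties broken by vocabulary index
#' ascending), optionally filters to one category *after* scoring (so the
#' reported cosines are unconditional), and returns the first `top_n`.
#'
#' @param emb An [ehr_embedding()].
#' @param query Entity code present in the vocabulary.
#' @param category Optional category filter (one of [entity_categories()]).
#' @param top_n Number of rows to return (default 20, the conventional
#'   per-category table depth).
#' @return A data.frame (`rank`, `code`, `category`, `cosine`) with the
#'   query code recorded in attribute `"query"`.
#' @export
rank_by_similarity <- function(emb, query, category = NULL, top_n = 20L) {
  vocab <- emb$vocab
  qi <- vocab_index(vocab, query)
  if (is.na(qi)) {
    near <- utils::head(agrep(query, vocab$codes, value = TRUE,
                              max.distance = 0.3), 5L)
    stop("unknown query code '", query, "'",
         if (length(near) > 0L) paste0("; near misses: ",
                                       paste(near, collapse = ", ")),
         call. = FALSE)
  }
  if (top_n < 1L) stop("top_n must be >= 1", call. = FALSE)
  if (!is.null(category) && !category %in% entity_categories()) {
    stop("unknown category: ", category, call. = FALSE)
  }
  W <- emb$W
  norms <- sqrt(rowSums(W * W))
  if (any(norms == 0)) stop("embedding contains a zero-norm vector", call. = FALSE)
  cs <- as.vector(W %*% W[qi, ]) / (norms * norms[[qi]])
  cs <- pmax(-1, pmin(1, cs))
  keep <- seq_len(nrow(W)) != qi
  ord <- order(-cs, seq_len(nrow(W)))
  ord <- ord[keep[ord]]
  if (!is.null(category)) ord <- ord[vocab$categories[ord] == category]
  ord <- utils::head(ord, top_n)
  out <- data.frame(rank = seq_along(ord), code = vocab$codes[ord],
                    category = vocab$categories[ord], cosine = cs[ord])
  attr(out, "query") <- query
  out
}

#' Top entities along one embedding dimension
#'
#' Interpretability probe: ranks the vocabulary by the value of embedding
#' column `dim` and returns the `k` largest (descending; ties broken by
#' vocabulary index). If individual dimensions carry meaning, the top
#' entities of a dimension form a clinically coherent group.
#'
#' @param emb An [ehr_embedding()].
#' @param dim Dimension index, `1..c`.
#' @param k Number of entities (default 10, the conventional table depth).
#' @return A data.frame (`rank`, `code`, `category`, `value`).
#' @export
top_entities_in_dimension <- function(emb, dim, k = 10L) {
  W <- emb$W
  if (dim < 1L || dim > ncol(W)) {
    stop("dim must be in 1..", ncol(W), call. = FALSE)
  }
  if (k < 1L || k > nrow(W)) stop("k must be in 1..", nrow(W), call. = FALSE)
  col <- W[, dim]
  ord <- utils::head(order(-col, seq_len(nrow(W))), k)
  data.frame(rank = seq_along(ord), code = emb$vocab$codes[ord],
             category = emb$vocab$categories[ord], value = col[ord])
}

# ---- embedding I/O ---------------------------------------------------------

#' Write / read embeddings in word2vec text format
#'
#' First line `"h c"`, then one line per entity: the code followed by `c`
#' space-separated values (full `%.17g` precision, so a write/read
#' round-trip is lossless). Codes must not contain whitespace. The
#' category map is written alongside with [write_vocabulary()] when a
#' vocabulary path is given.
#'
#' @param emb An [ehr_embedding()].
#' @param path Output path for the vectors.
#' @param vocab_path Optional TSV path for the vocabulary/category map.
#' @return `path` invisibly (write) or an [ehr_embedding()] (read).
#' @export
write_embeddings <- function(emb, path, vocab_path = NULL) {
  W <- emb$W
  codes <- emb$vocab$codes
  if (any(grepl("[[:space:]]", codes))) {
    stop("entity codes must not contain whitespace for word2vec text output",
         call. = FALSE)
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(W), ncol(W)), con)
  for (i in seq_len(nrow(W))) {
    writeLines(paste(codes[[i]],
                     paste(sprintf("%.17g", W[i, ]), collapse = " ")), con)
  }
  if (!is.null(vocab_path)) write_vocabulary(emb$vocab, vocab_path)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path, vocab_path = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[[1L]]), "[[:space:]]+")[[1L]])
  h <- hdr[[1L]]; cc <- hdr[[2L]]
  if (length(lines) < h + 1L) stop("embedding file truncated", call. = FALSE)
  codes <- character(h)
  W <- matrix(0, h, cc)
  for (i in seq_len(h)) {
    parts <- strsplit(trimws(lines[[i + 1L]]), "[[:space:]]+")[[1L]]
    codes[[i]] <- parts[[1L]]
    W[i, ] <- as.numeric(parts[-1L])
  }
  vocab <- if (!is.null(vocab_path)) {
    read_vocabulary(vocab_path)
  } else {
    new_vocabulary(codes, rep("symptom", h), rep(NA_integer_, h))
  }
  if (!identical(vocab$codes, codes)) {
    vocab <- new_vocabulary(codes, vocab$categories[match(codes, vocab$codes)],
                            vocab$counts[match(codes, vocab$codes)])
  }
  ehr_embedding(W, vocab)
}

#' Save / load a trained model checkpoint
#'
#' A single JSON file holding every weight matrix under a named entry plus
#' the training configuration — plain text, portable, and lossless at
#' full double precision.
#'
#' @param model An `ehr2vec_model` from [train_ehr2vec()].
#' @param path Checkpoint path (`.json`).
#' @return `path` invisibly (write) or an `ehr2vec_model` (read).
#' @export
write_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  p <- model$params
  payload <- list(
    config = unclass(model$config),
    vocab = list(codes = model$embedding$vocab$codes,
                 categories = model$embedding$vocab$categories,
                 counts = model$embedding$vocab$counts),
    W = model$embedding$W,
    Wo = p$Wo, W1 = p$W1, W2 = p$W2,
    Wq = p$Wq, Wk = p$Wk, Wv = p$Wv,
    trace = model$trace)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(train_config, x$config[setdiff(names(x$config), NULL)])
  vocab <- new_vocabulary(x$vocab$codes, x$vocab$categories, x$vocab$counts)
  params <- attention_params(dim = cfg$dim, n_heads = cfg$n_heads,
                             ff_dim = cfg$ff_dim, dropout = cfg$dropout,
                             seed = cfg$seed)
  params$Wo <- as.matrix(x$Wo); params$W1 <- as.matrix(x$W1)
  params$W2 <- as.matrix(x$W2)
  to_mats <- function(a) {
    if (is.array(a) && length(dim(a)) == 3L) {
      lapply(seq_len(dim(a)[[1L]]), function(i) a[i, , ])
    } else if (is.list(a)) lapply(a, as.matrix) else list(as.matrix(a))
  }
  params$Wq <- to_mats(x$Wq); params$Wk <- to_mats(x$Wk)
  params$Wv <- to_mats(x$Wv)
  trace <- as.data.frame(x$trace)
  structure(list(embedding = ehr_embedding(as.matrix(x$W), vocab),
                 params = params, trace = trace, config = cfg),
            class = "ehr2vec_model")
}
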