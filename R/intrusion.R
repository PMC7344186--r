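#' Build a 6-entity intrusion instrument from a similarity ranking
#'
#' Takes the five top-ranked neighbors of the query as members and plants
#' one intruder drawn uniformly from the last 50% of the ranking
#' (positions `ceiling(L/2) + 1 .. L`), then shuffles the six for
#' presentation. A judge who can spot the intruder demonstrates that the
#' top neighbors form a coherent group.
#'
#' @param ranking A ranking from [rank_by_similarity()] with at least 10
#'   rows (so the bottom half cannot overlap the top 5).
#' @param seed RNG seed; fixed seed gives an identical instrument.
#' @return An object of class `intrusion_set`: `query`, `members` (5
#'   codes), `intruder`, `presented_order` (6 shuffled codes) and
#'   `truth_index` (position of the intruder in `presented_order`, 1-based).
#' @export
build_intrusion_set <- function(ranking, seed = 1L) {
  L <- nrow(ranking)
  if (L < 10L) stop("ranking must have at least 10 entries", call. = FALSE)
  members <- ranking$code[1:5]
  lo <- ceiling(L / 2) + 1L
  with_seed(seed, {
    intruder <- ranking$code[[sample(seq.int(lo, L), 1L)]]
    presented <- sample(c(members, intruder))
    structure(list(query = attr(ranking, "query") %||% NA_character_,
                   members = members, intruder = intruder,
                   presented_order = presented,
                   truth_index = match(intruder, presented)),
              class = "intrusion_set")
  })
}

#' @export
print.intrusion_set <- function(x, ...) {
  cat("<intrusion_set> query:", x$query, "\n  presented:",
      paste(x$presented_order, collapse = ", "), "\n")
  invisible(x)
}

#' Geometric odd-one-out judge
#'
#' Automates the judging step: picks the presented entity with the largest
#' mean cosine *distance* (1 - cosine) to the other five. Because it uses
#' the same geometry the embedding optimizes, its accuracy measures the
#' internal coherence of the neighborhoods, not clinical validity. Ties
#' resolve to the lowest presented index.
#'
#' @param set An [build_intrusion_set()] instrument.
#' @param emb The embedding the codes live in.
#' @return Chosen presented index (1-based).
#' @export
simulated_expert_choice <- function(set, emb) {
  idx <- vocab_index(emb$vocab, set$presented_order)
  if (anyNA(idx)) {
    stop("unknown code in intrusion set: ",
         set$presented_order[[which(is.na(idx))[[1L]]]], call. = FALSE)
  }
  V <- emb$W[idx, , drop = FALSE]
  norms <- sqrt(rowSums(V * V))
  if (any(norms == 0)) stop("zero-norm vector in intrusion set", call. = FALSE)
  Cs <- tcrossprod(sweep(V, 1L, norms, "/"))
  Cs <- pmin(pmax(Cs, -1), 1)
  mean_dist <- vapply(seq_len(6L), function(i) mean(1 - Cs[i, -i]), numeric(1L))
  which.max(mean_dist)  # first maximum wins: lowest-index tie rule
}

#' Model precision of intrusion choices
#'
#' Fraction of instruments where the chosen presented index equals the
#' planted intruder's index: `MP = (1/S) * sum_s 1(chosen_s == truth_s)`.
#'
#' @param chosen Integer vector of chosen presented indices.
#' @param truth Integer vector of true intruder indices (same length).
#' @return MP in `[0, 1]`.
#' @export
model_precision <- function(chosen, truth) {
  if (length(chosen) != length(truth)) {
    stop("chosen and truth must have equal length", call. = FALSE)
  }
  if (length(chosen) < 1L) stop("need at least one instrument (S >= 1)",
                                call. = FALSE)
  mean(chosen == truth)
}

#' Run the full intrusion protocol against an embedding
#'
#' Builds `n_sets` instruments by cycling over `queries` (full-vocabulary
#' rankings, no category filter), judges each with
#' [simulated_expert_choice()], and scores MP.
#'
#' @param emb An [ehr_embedding()].
#' @param queries Codes to query; defaults to the whole vocabulary.
#' @param n_sets Number of instruments.
#' @param seed Master seed; per-set seeds are derived from it.
#' @return List of class `intrusion_report`: `sets`, `chosen`, `truth`,
#'   `mp`, and a `results` data.frame.
#' @export
run_intrusion_eval <- function(emb, queries = emb$vocab$codes, n_sets = 50L,
                               seed = 1L) {
  if (n_sets < 1L) stop("n_sets must be >= 1", call. = FALSE)
  qs <- rep_len(queries, n_sets)
  set_seeds <- with_seed(seed, sample.int(2^30, n_sets))
  sets <- vector("list", n_sets)
  chosen <- integer(n_sets)
  truth <- integer(n_sets)
  for (k in seq_len(n_sets)) {
    rk <- rank_by_similarity(emb, qs[[k]], top_n = nrow(emb$W) - 1L)
    sets[[k]] <- build_intrusion_set(rk, seed = set_seeds[[k]])
    chosen[[k]] <- simulated_expert_choice(sets[[k]], emb)
    truth[[k]] <- sets[[k]]$truth_index
  }
  structure(list(sets = sets, chosen = chosen, truth = truth,
                 mp = model_precision(chosen, truth),
                 results = data.frame(set_id = seq_len(n_sets), query = qs,
                                      chosen = chosen, truth = truth,
                                      correct = chosen == truth)),
            class = "intrusion_report")
}

#' @export
print.intrusion_report <- function(x, ...) {
  cat("<intrusion_report> S =", length(x$chosen),
      "| MP =", sprintf("%.3f", x$mp), "\n")
  invisible(x)
}

#' Export intrusion instruments for human annotation
#'
#' CSV columns: `set_id`, `query`, `code_1` .. `code_6` in presented order.
#'
#' @param sets List of `intrusion_set` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_intrusion_sets <- function(sets, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    c(set_id = i, query = s$query,
      stats::setNames(s$presented_order, paste0("code_", 1:6)))
  })
  df <- as.data.frame(do.call(rbind, rows))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read human intrusion answers
#'
#' CSV with columns `set_id` and `chosen_index` (presented index, 1-6).
#' Answers are aligned to `sets` by `set_id`.
#'
#' @param path CSV path.
#' @param sets The instruments the answers refer to.
#' @return Integer vector of chosen indices, one per set in `sets` order.
#' @export
read_human_answers <- function(path, sets) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop("answer file is empty (S = 0)", call. = FALSE)
  if (!all(c("set_id", "chosen_index") %in% names(df))) {
    stop("answer file needs columns set_id and chosen_index", call. = FALSE)
  }
  if (any(df$chosen_index < 1L | df$chosen_index > 6L)) {
    stop("chosen_index must be between 1 and 6", call. = FALSE)
  }
  if (any(!df$set_id %in% seq_along(sets))) {
    stop("unknown set_id in answer file: ",
         df$set_id[[which(!df$set_id %in% seq_along(sets))[[1L]]]],
         call. = FALSE)
  }
  pos <- match(seq_along(sets), df$set_id)
  if (anyNA(pos)) stop("answer file is missing set_id ",
                       which(is.na(pos))[[1L]], call. = FALSE)
  as.integer(df$chosen_index[pos])
}
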