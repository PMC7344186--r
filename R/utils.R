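# internal helpers shared across modules

#' Run code with a temporarily fixed RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state on exit, so seeded package functions never
#' perturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Legal entity categories
#'
#' The four category tags a medical entity may carry.
#' @return Character vector of the four category names.
#' @export
entity_categories <- function() {
  c("symptom", "medication", "lab_test", "diagnosis")
}

# numerically stable row-wise softmax of a matrix of scores
row_softmax <- function(S) {
  mx <- apply(S, 1L, max)
  E <- exp(sweep(S, 1L, mx, "-"))
  sweep(E, 1L, rowSums(E), "/")
}

# stable log(sum(exp(x))) for a vector
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
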