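#' @title Visit corpus: data model, readers and preprocessing
#'
#' @description
#' A corpus is a list of patient records. Each record holds an opaque
#' `patient_id` and a list of visits; each visit has a `timestamp` (integer
#' day offset or `"YYYY-MM-DD"` string) and its medical entities. In *raw*
#' form a visit carries parallel character vectors `codes` and `categories`
#' (one of `symptom`, `medication`, `lab_test`, `diagnosis`); after
#' [index_corpus()] the visit instead carries `entities`, an integer vector
#' of vocabulary indices with duplicates removed.
#'
#' @name ehr_corpus
NULL

#' Construct a visit event
#'
#' @param timestamp Integer day offset or `"YYYY-MM-DD"` date string.
#' @param codes Character vector of entity codes.
#' @param categories Character vector of category tags, one per code.
#' @return A list with fields `timestamp`, `codes`, `categories`.
#' @export
visit_event <- function(timestamp, codes, categories) {
  codes <- as.character(codes)
  categories <- as.character(categories)
  if (length(codes) != length(categories)) {
    stop("codes and categories must have equal length", call. = FALSE)
  }
  if (any(!nzchar(codes))) stop("entity codes must be non-empty", call. = FALSE)
  bad <- setdiff(unique(categories), entity_categories())
  if (length(bad) > 0L) {
    stop("unknown category '", bad[[1L]], "' for code '",
         codes[[match(bad[[1L]], categories)]], "'", call. = FALSE)
  }
  list(timestamp = timestamp, codes = codes, categories = categories)
}

#' Construct a patient record
#'
#' @param patient_id Opaque string identifier.
#' @param visits List of visits created by [visit_event()].
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, visits) {
  structure(list(patient_id = as.character(patient_id), visits = visits),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record> ", x$patient_id, ": ", length(x$visits),
      " visit(s)\n", sep = "")
  invisible(x)
}

#' Convert a visit timestamp to a day number
#'
#' Integer (or whole numeric) timestamps are taken as day offsets;
#' `"YYYY-MM-DD"` strings are converted via [as.Date()]. Anything else —
#' including `NULL`, `NA`, or an unparseable string — yields `NA`, which
#' downstream filtering treats as a missing date.
#'
#' @param ts A single timestamp.
#' @return A numeric day value, or `NA` if missing/unparseable.
#' @export
timestamp_to_day <- function(ts) {
  if (is.null(ts) || length(ts) != 1L) return(NA_real_)
  if (is.numeric(ts)) {
    if (is.na(ts)) return(NA_real_)
    return(as.numeric(ts))
  }
  if (is.character(ts)) {
    if (is.na(ts) || !grepl("^\\d{4}-\\d{2}-\\d{2}$", ts)) return(NA_real_)
    d <- suppressWarnings(as.Date(ts, format = "%Y-%m-%d"))
    if (is.na(d)) return(NA_real_)
    return(as.numeric(d))
  }
  NA_real_
}

#' Read a line-delimited JSON visit corpus
#'
#' Each line is one patient:
#' `{"patient_id": str, "visits": [{"timestamp": ..., "entities":
#' [{"code": str, "category": str}]}]}`. Codes are kept as raw strings
#' (no vocabulary mapping, duplicates preserved).
#'
#' @param path Path to a JSONL file.
#' @return A list of `patient_record` objects in file order.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  records <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[[ln]], simplifyVector = FALSE),
      error = function(e) stop("malformed JSON on line ", ln, ": ",
                               conditionMessage(e), call. = FALSE))
    if (is.null(obj$patient_id) || is.null(obj$visits)) {
      stop("malformed record on line ", ln,
           ": needs patient_id and visits", call. = FALSE)
    }
    visits <- lapply(obj$visits, function(v) {
      ts <- v$timestamp
      if (is.numeric(ts) && length(ts) == 1L && !is.na(ts) && ts == round(ts)) {
        ts <- as.integer(ts)
      }
      codes <- vapply(v$entities, function(e) as.character(e$code), character(1L))
      cats <- vapply(v$entities, function(e) as.character(e$category), character(1L))
      visit_event(ts, codes, cats)
    })
    records[[ln]] <- patient_record(obj$patient_id, visits)
  }
  records
}

#' Write a corpus as line-delimited JSON
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, p))` reproduces
#' `x` exactly. Only raw-form (code-carrying) records can be written.
#'
#' @param records List of `patient_record` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(records, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  lines <- vapply(records, function(rec) {
    visits <- lapply(rec$visits, function(v) {
      if (is.null(v$codes)) {
        stop("write_corpus expects raw-form records (codes present)",
             call. = FALSE)
      }
      list(timestamp = jsonlite::unbox(v$timestamp),
           entities = mapply(function(co, ca) {
             list(code = jsonlite::unbox(co), category = jsonlite::unbox(ca))
           }, v$codes, v$categories, SIMPLIFY = FALSE, USE.NAMES = FALSE))
    })
    jsonlite::toJSON(list(patient_id = jsonlite::unbox(rec$patient_id),
                          visits = visits),
                     auto_unbox = FALSE, digits = NA)
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Exclude patients with one visit or a missing first-visit date
#'
#' Drops patients with fewer than 2 visits, and patients whose earliest
#' recorded visit has a missing or unparseable timestamp. Order of the
#' surviving patients is preserved; counts removed per reason are reported
#' via [message()].
#'
#' @param records List of `patient_record` objects.
#' @return The filtered list.
#' @export
filter_patients <- function(records) {
  n_single <- 0L
  n_nodate <- 0L
  keep <- vapply(records, function(rec) {
    if (length(rec$visits) < 2L) {
      n_single <<- n_single + 1L
      return(FALSE)
    }
    days <- vapply(rec$visits, function(v) timestamp_to_day(v$timestamp),
                   numeric(1L))
    first <- if (all(is.na(days))) NA_real_ else days[[which.min(replace(days, is.na(days), Inf))]]
    if (is.na(days[[1L]]) || is.na(first)) {
      n_nodate <<- n_nodate + 1L
      return(FALSE)
    }
    TRUE
  }, logical(1L))
  if (n_single > 0L) message("filter_patients: removed ", n_single,
                             " patient(s) with <2 visits")
  if (n_nodate > 0L) message("filter_patients: removed ", n_nodate,
                             " patient(s) with missing first-visit date")
  records[keep]
}

#' Sort a patient's visits by time
#'
#' Stable ascending sort on the day value of each visit timestamp; visits
#' sharing a day keep their original relative order.
#'
#' @param record A `patient_record`.
#' @return The record with visits time-ordered.
#' @export
sort_visits_temporally <- function(record) {
  days <- vapply(record$visits, function(v) timestamp_to_day(v$timestamp),
                 numeric(1L))
  if (anyNA(days)) {
    stop("patient '", record$patient_id,
         "' has a visit with a missing or unparseable timestamp",
         call. = FALSE)
  }
  record$visits <- record$visits[order(days)]  # order() is a stable sort
  record
}

#' Build an indexed vocabulary from a corpus
#'
#' Counts each code once per visit it appears in (repeat mentions within a
#' visit carry no extra weight), keeps codes with frequency >= `min_count`,
#' and indexes them in order of first appearance. A code tagged with two
#' different categories anywhere in the corpus is an error.
#'
#' @param records List of raw-form `patient_record` objects.
#' @param min_count Minimum corpus frequency to enter the vocabulary.
#' @return An object of class `ehr_vocabulary` with fields `codes`,
#'   `categories`, `counts` (parallel vectors; index = position).
#' @export
build_vocabulary <- function(records, min_count = 1L) {
  counts <- integer(0)
  cats <- character(0)
  for (rec in records) {
    for (v in rec$visits) {
      keep <- !duplicated(v$codes)
      codes <- v$codes[keep]
      vcats <- v$categories[keep]
      pos <- match(codes, names(counts))
      new <- is.na(pos)
      if (any(!new)) {
        p <- pos[!new]
        conflict <- cats[p] != vcats[!new]
        if (any(conflict)) {
          stop("code '", codes[!new][conflict][[1L]],
               "' appears under two categories", call. = FALSE)
        }
        counts[p] <- counts[p] + 1L
      }
      if (any(new)) {
        add <- stats::setNames(rep.int(1L, sum(new)), codes[new])
        counts <- c(counts, add)
        cats <- c(cats, vcats[new])
      }
    }
  }
  keep <- counts >= min_count
  new_vocabulary(codes = names(counts)[keep],
                 categories = unname(cats[keep]),
                 counts = unname(counts[keep]))
}

new_vocabulary <- function(codes, categories, counts) {
  if (anyDuplicated(codes)) stop("vocabulary codes must be unique", call. = FALSE)
  structure(list(codes = as.character(codes),
                 categories = as.character(categories),
                 counts = as.integer(counts)),
            class = "ehr_vocabulary")
}

#' @export
print.ehr_vocabulary <- function(x, ...) {
  cat("<ehr_vocabulary> ", length(x$codes), " entities (",
      paste(sprintf("%s: %d", entity_categories(),
                    vapply(entity_categories(),
                           function(ct) sum(x$categories == ct), integer(1L))),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Look up vocabulary indices for codes
#'
#' @param vocab An `ehr_vocabulary`.
#' @param codes Character vector of codes.
#' @return Integer indices (`NA` for out-of-vocabulary codes).
#' @export
vocab_index <- function(vocab, codes) {
  match(codes, vocab$codes)
}

#' Export / import a vocabulary as TSV
#'
#' Columns: `index`, `code`, `category`, `count`.
#'
#' @param vocab An `ehr_vocabulary`.
#' @param path Output path.
#' @return `path` invisibly (write) or an `ehr_vocabulary` (read).
#' @export
write_vocabulary <- function(vocab, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(index = seq_along(vocab$codes), code = vocab$codes,
                   category = vocab$categories, count = vocab$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character",
                                         "character", "integer"))
  df <- df[order(df$index), , drop = FALSE]
  new_vocabulary(df$code, df$category, df$count)
}

#' Map corpus codes to vocabulary indices
#'
#' Replaces codes by integer indices. Within each visit duplicates are
#' removed (first occurrence kept) and out-of-vocabulary codes dropped;
#' visits left empty are removed, and patients left with fewer than 2
#' visits are removed. Dropped OOV mentions are counted in a [message()].
#'
#' @param records List of raw-form `patient_record` objects.
#' @param vocab An `ehr_vocabulary`.
#' @return List of index-form `patient_record` objects (each visit has an
#'   integer `entities` field instead of `codes`/`categories`).
#' @export
index_corpus <- function(records, vocab) {
  n_oov <- 0L
  out <- lapply(records, function(rec) {
    visits <- lapply(rec$visits, function(v) {
      idx <- vocab_index(vocab, v$codes)
      n_oov <<- n_oov + sum(is.na(idx))
      idx <- idx[!is.na(idx)]
      idx <- idx[!duplicated(idx)]
      if (length(idx) == 0L) return(NULL)
      list(timestamp = v$timestamp, entities = idx)
    })
    visits <- visits[!vapply(visits, is.null, logical(1L))]
    if (length(visits) < 2L) return(NULL)
    patient_record(rec$patient_id, visits)
  })
  if (n_oov > 0L) message("index_corpus: dropped ", n_oov,
                          " out-of-vocabulary entity mention(s)")
  out[!vapply(out, is.null, logical(1L))]
}
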