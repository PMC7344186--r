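#' Configuration for the synthetic EHR generator
#'
#' Defines a corpus of longitudinal patient records with planted
#' comorbidity-topic structure. Each topic owns a small pool of
#' category-typed entities; a patient carries one latent topic at a time
#' and may drift to an *adjacent* topic between visits, mimicking gradual
#' comorbidity progression. A shared background vocabulary injects
#' topic-free noise.
#'
#' Defaults emulate the shape of a real multi-visit cohort: a strong
#' majority of patients with fewer than 10 visits, visit intervals from a
#' few days to several months, and mixed-category visits.
#'
#' @param n_patients Number of patients.
#' @param n_topics Number of comorbidity topics.
#' @param vocab_per_topic Named integer vector: entities per topic per
#'   category. Default 10 entities/topic: 4 symptom, 3 medication,
#'   2 lab_test, 1 diagnosis.
#' @param background_vocab Number of background (topic-free) entities.
#' @param visit_p Geometric parameter for visits per patient: a patient has
#'   `2 + rgeom(visit_p)` visits, truncated at `max_visits`.
#' @param max_visits Truncation for visits per patient.
#' @param entities_per_visit Integer range `c(lo, hi)` sampled uniformly.
#' @param topic_switch_prob Per-visit probability of moving to an adjacent
#'   topic.
#' @param background_noise_prob Per-entity probability of replacement by a
#'   background entity.
#' @param interval_days Integer range of days between consecutive visits.
#' @param seed RNG seed; fixed seed gives a byte-identical corpus.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 500L,
                       n_topics = 5L,
                       vocab_per_topic = c(symptom = 4L, medication = 3L,
                                           lab_test = 2L, diagnosis = 1L),
                       background_vocab = 50L,
                       visit_p = 0.45,
                       max_visits = 30L,
                       entities_per_visit = c(3L, 8L),
                       topic_switch_prob = 0.15,
                       background_noise_prob = 0.2,
                       interval_days = c(3L, 90L),
                       seed = 7L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_topics = as.integer(n_topics),
              vocab_per_topic = vocab_per_topic,
              background_vocab = as.integer(background_vocab),
              visit_p = visit_p, max_visits = as.integer(max_visits),
              entities_per_visit = as.integer(entities_per_visit),
              topic_switch_prob = topic_switch_prob,
              background_noise_prob = background_noise_prob,
              interval_days = as.integer(interval_days),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_patients < 0L) stop("n_patients must be >= 0", call. = FALSE)
  if (cfg$n_topics < 1L) stop("n_topics must be positive", call. = FALSE)
  if (!all(names(cfg$vocab_per_topic) %in% entity_categories()) ||
      length(cfg$vocab_per_topic) == 0L) {
    stop("vocab_per_topic must be named by entity categories", call. = FALSE)
  }
  if (any(cfg$vocab_per_topic < 0L) || sum(cfg$vocab_per_topic) < 1L) {
    stop("vocab_per_topic counts must be non-negative, with at least one entity",
         call. = FALSE)
  }
  if (cfg$background_vocab < 0L) stop("background_vocab must be >= 0", call. = FALSE)
  for (p in c("visit_p", "topic_switch_prob", "background_noise_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0,1]", call. = FALSE)
  }
  if (cfg$visit_p <= 0) stop("visit_p must be > 0", call. = FALSE)
  if (length(cfg$entities_per_visit) != 2L ||
      cfg$entities_per_visit[[1L]] < 1L ||
      diff(cfg$entities_per_visit) < 0L) {
    stop("entities_per_visit must be a positive c(lo, hi) range", call. = FALSE)
  }
  if (length(cfg$interval_days) != 2L || cfg$interval_days[[1L]] < 1L ||
      diff(cfg$interval_days) < 0L) {
    stop("interval_days must be a positive c(lo, hi) range", call. = FALSE)
  }
  if (cfg$max_visits < 2L) stop("max_visits must be >= 2", call. = FALSE)
  invisible(cfg)
}

# deterministic code pools for topics and background
sim_vocab_pools <- function(cfg) {
  topics <- lapply(seq_len(cfg$n_topics), function(tp) {
    codes <- character(0)
    cats <- character(0)
    for (ct in names(cfg$vocab_per_topic)) {
      k <- cfg$vocab_per_topic[[ct]]
      if (k > 0L) {
        codes <- c(codes, sprintf("t%d_%s_%d", tp, ct, seq_len(k)))
        cats <- c(cats, rep.int(ct, k))
      }
    }
    list(codes = codes, categories = cats)
  })
  bg_cats <- rep_len(entity_categories(), cfg$background_vocab)
  bg_codes <- sprintf("bg_%s_%02d", bg_cats, seq_len(cfg$background_vocab))
  list(topics = topics,
       background = list(codes = bg_codes, categories = bg_cats))
}

#' Generate a synthetic visit corpus with planted topics
#'
#' Each patient starts in a uniformly drawn topic; before every subsequent
#' visit the topic moves to an adjacent topic index with probability
#' `topic_switch_prob`. Visit entities are drawn without replacement from
#' the current topic's pool, then each is independently replaced by a
#' uniform background entity with probability `background_noise_prob`.
#' Timestamps are integer day offsets accumulating uniform intervals.
#'
#' @param cfg A [sim_config()].
#' @return A list with `records` (list of raw-form [patient_record()]s) and
#'   `truth` (a `ground_truth` object: named integer vector mapping each
#'   code to its topic id, `NA` for background entities).
#' @export
generate_corpus <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  pools <- sim_vocab_pools(cfg)
  truth <- integer(0)
  for (tp in seq_len(cfg$n_topics)) {
    truth <- c(truth, stats::setNames(rep.int(tp, length(pools$topics[[tp]]$codes)),
                                      pools$topics[[tp]]$codes))
  }
  truth <- c(truth, stats::setNames(rep.int(NA_integer_,
                                            length(pools$background$codes)),
                                    pools$background$codes))
  all_cats <- c(unlist(lapply(pools$topics, `[[`, "categories")),
                pools$background$categories)
  names(all_cats) <- names(truth)

  records <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_patients), function(p) {
      n_visits <- min(2L + stats::rgeom(1L, cfg$visit_p), cfg$max_visits)
      topic <- sample.int(cfg$n_topics, 1L)
      day <- 0L
      visits <- vector("list", n_visits)
      for (vi in seq_len(n_visits)) {
        if (vi > 1L) {
          day <- day + sample(seq.int(cfg$interval_days[[1L]],
                                      cfg$interval_days[[2L]]), 1L)
          if (stats::runif(1L) < cfg$topic_switch_prob && cfg$n_topics > 1L) {
            nbr <- c(topic - 1L, topic + 1L)
            nbr <- nbr[nbr >= 1L & nbr <= cfg$n_topics]
            topic <- if (length(nbr) == 1L) nbr else sample(nbr, 1L)
          }
        }
        pool <- pools$topics[[topic]]
        n_e <- sample(seq.int(cfg$entities_per_visit[[1L]],
                              cfg$entities_per_visit[[2L]]), 1L)
        n_e <- min(n_e, length(pool$codes))
        pick <- sample.int(length(pool$codes), n_e)
        codes <- pool$codes[pick]
        if (cfg$background_vocab > 0L && cfg$background_noise_prob > 0) {
          swap <- stats::runif(n_e) < cfg$background_noise_prob
          if (any(swap)) {
            codes[swap] <- pools$background$codes[
              sample.int(cfg$background_vocab, sum(swap), replace = TRUE)]
          }
        }
        codes <- codes[!duplicated(codes)]
        visits[[vi]] <- visit_event(as.integer(day), codes,
                                    unname(all_cats[codes]))
      }
      patient_record(sprintf("sim_%04d", p), visits)
    })
  })
  structure(list(records = records,
                 truth = structure(truth, class = "ground_truth")),
            class = "sim_corpus")
}

#' Ground-truth topic neighbors of an entity
#'
#' @param code An entity code present in `truth`.
#' @param truth The `ground_truth` mapping from [generate_corpus()].
#' @return Character vector of all *other* codes sharing the code's topic;
#'   empty for background entities.
#' @export
ground_truth_neighbors <- function(code, truth) {
  if (!code %in% names(truth)) stop("unknown code: ", code, call. = FALSE)
  tp <- truth[[code]]
  if (is.na(tp)) return(character(0))
  setdiff(names(truth)[!is.na(truth) & truth == tp], code)
}

#' Write / read the ground-truth topic map as TSV
#'
#' Columns `code`, `topic`; background entities carry topic `NA`.
#'
#' @param truth A `ground_truth` object.
#' @param path File path.
#' @return `path` invisibly (write) or a `ground_truth` (read).
#' @export
write_ground_truth <- function(truth, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(code = names(truth), topic = as.integer(truth))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer"))
  structure(stats::setNames(df$topic, df$code), class = "ground_truth")
}
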