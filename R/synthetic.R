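# Seeded synthetic-corpus generators with planted ground truth.
#
# These emulate the study corpus: short informal English posts
# mentioning the four tracked medication families (misspellings
# included), entity spans planted from gazetteers, latent topic word
# distributions, timestamps across a five-month window, and records
# violating each exclusion rule.  Every generator is a pure function
# of its arguments and seed.

#' Default entity gazetteers
#'
#' Term lists per entity label.  Drug terms embed the four medication
#' keyword families (with misspellings) plus other substances commonly
#' co-mentioned; adverse-event and symptom terms are everyday
#' colloquial effects (drowsiness, fatigue, pain, nausea, headaches,
#' dizziness, ...).  Multi-word terms exercise multi-token spans.
#'
#' @return Named list label -> character vector of terms.
#' @export
default_gazetteers <- function() {
  list(
    DRUG = c(unique(unlist(default_keyword_families(), use.names = FALSE)),
             "tramadol", "oxycodone", "heroin", "cocaine",
             "methamphetamine"),
    ADE = c("drowsiness", "fatigue", "nausea", "headaches", "dizziness",
            "hallucinations", "insomnia", "mood swings", "vomiting",
            "sweating"),
    SYMPTOM = c("anxiety", "panic", "stress", "cravings", "tremors",
                "agitation", "depression"),
    TREATMENT = c("rehab", "detox", "counseling", "group therapy",
                  "nature therapy", "meditation", "yoga"),
    AGE = c("19", "21", "24", "27", "32", "38", "45"),
    GENDER = c("male", "female", "man", "woman")
  )
}

# Tweet-register templates: token skeletons with {LABEL} slots.  The
# filler vocabulary is disjoint from every gazetteer, so corpora stay
# separable when slots go unfilled.
#' @noRd
default_templates <- function() {
  lapply(strsplit(c(
    "took {DRUG} again last night and felt {ADE} for hours",
    "my doctor put me on {DRUG} for the {SYMPTOM} honestly",
    "week two of {TREATMENT} after quitting {DRUG} wish me luck",
    "i am a {AGE} year old {GENDER} dealing with {SYMPTOM} every day",
    "cant sleep because {DRUG} gives me {ADE} and {ADE} all night",
    "anyone tried {TREATMENT} for coming off {DRUG} asking for a friend",
    "been mixing {DRUG} and {DRUG} lately not a good idea at all",
    "the {ADE} from {DRUG} is worse than the {SYMPTOM} ever was"
  ), " "), identity)
}

#' @noRd
default_fillers <- function() {
  c("stuff", "things", "that", "it", "something", "coffee", "tea",
    "water", "nothing", "whatever")
}

#' @noRd
random_timestamps <- function(n, date_range) {
  start <- parse_utc(date_range[1])
  end <- parse_utc(date_range[2])
  as.POSIXct(stats::runif(n, as.numeric(start), as.numeric(end)),
             origin = "1970-01-01", tz = "UTC")
}

#' Generate a corpus with planted entity spans
#'
#' Fills sentence templates with gazetteer terms: each slot becomes an
#' entity (term drawn from the slot label's gazetteer, exact token
#' span recorded) with probability `entity_rate`, otherwise a neutral
#' filler word.  Filler and skeleton vocabulary are disjoint from the
#' gazetteers, so entity terms never occur outside planted spans — a
#' correctly implemented tagger can separate them perfectly.
#'
#' @param n_records Number of posts.
#' @param seed RNG seed; corpora are bit-identical per seed.
#' @param gazetteers Named list label -> terms (all requested labels
#'   non-empty).
#' @param entity_rate Probability a slot is filled from its gazetteer.
#' @param date_range Closed ISO-8601 interval for timestamps; default
#'   the study's five-month window.
#' @return List of class `nmu_synth_corpus` with `corpus`
#'   (`nmu_corpus`), `sequences` (list of `tokens`/`tags`), `gold_ner`
#'   (list of span data frames), and `manifest`.
#' @export
generate_ner_corpus <- function(n_records = 200, seed = 1,
                                gazetteers = default_gazetteers(),
                                entity_rate = 0.7,
                                date_range = c("2021-05-31T00:00:00Z",
                                               "2021-10-31T23:59:59Z")) {
  templates <- default_templates()
  slot_labels <- sub("\\{([A-Z]+)\\}", "\\1",
                     grep("^\\{", unlist(templates), value = TRUE))
  for (lab in unique(slot_labels)) {
    if (is.null(gazetteers[[lab]]) || length(gazetteers[[lab]]) == 0) {
      stop_nmu("empty gazetteer for label ", lab,
               class = "nmutext_config_error")
    }
  }
  fillers <- default_fillers()
  families <- default_keyword_families()
  schema_all <- tag_schema(names(gazetteers))
  with_local_seed(seed, {
    ts <- random_timestamps(n_records, date_range)
    sequences <- vector("list", n_records)
    gold <- vector("list", n_records)
    texts <- character(n_records)
    meds <- character(n_records)
    for (i in seq_len(n_records)) {
      tpl <- templates[[sample(length(templates), 1)]]
      toks <- character(0)
      starts <- integer(0); ends <- integer(0); labs <- character(0)
      for (w in tpl) {
        if (grepl("^\\{", w)) {
          lab <- sub("\\{([A-Z]+)\\}", "\\1", w)
          if (stats::runif(1) < entity_rate) {
            term <- sample(gazetteers[[lab]], 1)
            sub_toks <- strsplit(term, " ")[[1]]
            starts <- c(starts, length(toks))
            ends <- c(ends, length(toks) + length(sub_toks))
            labs <- c(labs, lab)
            toks <- c(toks, sub_toks)
          } else {
            toks <- c(toks, sample(fillers, 1))
          }
        } else {
          toks <- c(toks, w)
        }
      }
      spans <- data.frame(start = starts, end = ends, label = labs,
                          stringsAsFactors = FALSE)
      tags <- chunks_to_iob(spans, length(toks), schema_all)
      sequences[[i]] <- list(tokens = toks, tags = tags)
      gold[[i]] <- spans
      texts[i] <- paste(toks, collapse = " ")
      planted_drugs <- toks[unlist(lapply(which(labs == "DRUG"), function(k) {
        (starts[k] + 1L):ends[k]
      }))]
      fam_hit <- names(families)[vapply(families, function(terms) {
        any(planted_drugs %in% terms)
      }, logical(1))]
      meds[i] <- if (length(fam_hit) > 0) fam_hit[1] else
        sample(names(families), 1)
    }
    corpus <- as_corpus(data.frame(
      tweet_id = sprintf("t%05d", seq_len(n_records)),
      user_id = sprintf("user_%03d", sample(max(20, n_records %/% 10),
                                            n_records, replace = TRUE)),
      created_at = format_utc(ts),
      text = texts, medication = meds,
      is_retweet = FALSE, is_quote = FALSE,
      stringsAsFactors = FALSE
    ))
    structure(
      list(corpus = corpus, sequences = sequences, gold_ner = gold,
           manifest = list(kind = "ner", n_records = n_records, seed = seed,
                           entity_rate = entity_rate,
                           date_range = date_range)),
      class = "nmu_synth_corpus"
    )
  })
}

#' Generate a corpus with planted latent topics
#'
#' Each record draws its topic from the mixing weights, then draws
#' tokens from that topic's vocabulary with probability `1 -
#' noise_rate` (otherwise from the union of all vocabularies).
#' Timestamps are uniform over `date_range`.  With `noise_rate = 0`
#' and pairwise-disjoint vocabularies the corpus is perfectly
#' separable by topic.
#'
#' @param n_records Number of posts.
#' @param seed RNG seed.
#' @param topic_specs List of `list(vocabulary = <character>, weight =
#'   <numeric>)`, at least two entries; weights normalized internally.
#' @param noise_rate Off-topic token probability in [0, 1).
#' @param doc_length Integer range (min, max) of tokens per record.
#' @param date_range Timestamp interval (default five-month window).
#' @return List of class `nmu_synth_corpus` with `corpus`,
#'   `gold_topic` (integer vector, 0-based), and `manifest`.
#' @export
generate_topic_corpus <- function(n_records = 600, seed = 1,
                                  topic_specs = default_topic_specs(),
                                  noise_rate = 0,
                                  doc_length = c(12, 20),
                                  date_range = c("2021-05-31T00:00:00Z",
                                                 "2021-10-31T23:59:59Z")) {
  if (length(topic_specs) < 2) {
    stop_nmu("need at least two topic specs", class = "nmutext_config_error")
  }
  weights <- vapply(topic_specs, function(s) s$weight, numeric(1))
  weights <- weights / sum(weights)
  vocabs <- lapply(topic_specs, `[[`, "vocabulary")
  all_vocab <- unique(unlist(vocabs))
  families <- names(default_keyword_families())
  with_local_seed(seed, {
    ts <- random_timestamps(n_records, date_range)
    topic <- sample(length(topic_specs), n_records, replace = TRUE,
                    prob = weights) - 1L
    texts <- character(n_records)
    for (i in seq_len(n_records)) {
      len <- sample(doc_length[1]:doc_length[2], 1)
      own <- vocabs[[topic[i] + 1L]]
      off <- stats::runif(len) < noise_rate
      toks <- ifelse(off,
                     sample(all_vocab, len, replace = TRUE),
                     sample(own, len, replace = TRUE))
      texts[i] <- paste(toks, collapse = " ")
    }
    corpus <- as_corpus(data.frame(
      tweet_id = sprintf("d%05d", seq_len(n_records)),
      user_id = sprintf("user_%03d", sample(50, n_records, replace = TRUE)),
      created_at = format_utc(ts),
      text = texts,
      medication = sample(families, n_records, replace = TRUE),
      is_retweet = FALSE, is_quote = FALSE,
      stringsAsFactors = FALSE
    ))
    structure(
      list(corpus = corpus, gold_topic = topic,
           manifest = list(kind = "topic", n_records = n_records,
                           seed = seed, noise_rate = noise_rate,
                           weights = weights)),
      class = "nmu_synth_corpus"
    )
  })
}

#' Default disjoint three-topic vocabularies
#'
#' Themes mirroring prominent strands of medication chatter: side
#' effects/withdrawal, prescription and treatment, and study/focus
#' use.  Pairwise disjoint, so zero-noise corpora are fully separable.
#'
#' @return List of topic specs for [generate_topic_corpus()].
#' @export
default_topic_specs <- function() {
  list(
    list(vocabulary = c("withdrawal", "overdose", "tolerance", "dependence",
                        "shaking", "sweats", "relapse", "craving"),
         weight = 1 / 3),
    list(vocabulary = c("prescription", "doctor", "refill", "pharmacy",
                        "dosage", "taper", "clinic", "appointment"),
         weight = 1 / 3),
    list(vocabulary = c("exam", "focus", "studying", "allnighter", "grades",
                        "deadline", "productivity", "cramming"),
         weight = 1 / 3)
  )
}

#' Fixture with one record violating each exclusion rule
#'
#' Emits exactly one record per filtering rule (off-date, non-English,
#' keyword-free, too short, retweet, bot account, non-NMU content)
#' plus one clean record, together with a matching filter
#' configuration whose bot/NMU predicates reject the planted
#' violators.  Applying the filters retains exactly the clean record
#' with one removal attributed to each rule.
#'
#' @param seed RNG seed (affects only user id assignment).
#' @return List of class `nmu_synth_corpus` with `corpus`, `config`
#'   (an `nmu_filter_config`), and `manifest` mapping tweet id to the
#'   violated rule.
#' @export
generate_filter_fixture <- function(seed = 1) {
  rows <- data.frame(
    tweet_id = sprintf("f%03d", 1:8),
    user_id = c("user_001", "user_002", "user_003", "user_004",
                "user_005", "bot_001", "user_007", "user_008"),
    created_at = c("2020-01-15T12:00:00Z", rep("2021-07-15T12:00:00Z", 7)),
    text = c(
      "took xanax again last night could not sleep",      # off-date
      "паника и тревога каждую ночь без сна",  # non-English
      "feeling very tired today honestly no reason why",  # keyword-free
      "need adderall now",                                # too short
      "morphine for the pain again tonight cant cope",    # retweet
      "fentanyl test strips available here every day",    # bot account
      "buy cheap adderall online no prescription needed", # not NMU chatter
      "took xanax again last night and slept twelve hours"# clean
    ),
    medication = c("alprazolam", "alprazolam", "alprazolam", "adderall",
                   "morphine", "fentanyl", "adderall", "alprazolam"),
    is_retweet = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    is_quote = FALSE,
    stringsAsFactors = FALSE
  )
  config <- filter_config(
    bot_predicate = function(row) !startsWith(row$user_id, "bot_"),
    nmu_predicate = function(row) !grepl("buy cheap", row$text, fixed = TRUE)
  )
  manifest <- data.frame(
    tweet_id = rows$tweet_id,
    violates = c("date", "language", "keyword", "length", "retweet_quote",
                 "bot", "nmu", NA),
    stringsAsFactors = FALSE
  )
  structure(
    list(corpus = as_corpus(rows), config = config, manifest = manifest,
         seed = seed),
    class = "nmu_synth_corpus"
  )
}
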