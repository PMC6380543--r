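#' @title Synthetic clinical-note corpus generator
#' @description Generates corpora with the statistical structure the
#'   classification pipeline assumes: ~37% label prevalence, a right-skewed
#'   notes-per-patient distribution (truncated log-normal, mean ~129,
#'   median ~70, range 1-876 at the defaults), note text assembled from
#'   sentence templates carrying lexicon terms at label-conditional rates,
#'   and explicit negation phrases so the extractor's negation logic is
#'   exercised end to end.
#' @name synthetic_data
NULL

#' Generator configuration
#'
#' @param n_patients number of patients (>= 2).
#' @param prevalence probability a patient carries the positive past-year
#'   suicide-attempt label. Default 0.37, the prevalence observed in the
#'   73-patient cohort the generator emulates.
#' @param notes_meanlog,notes_sdlog log-normal parameters of the
#'   notes-per-patient distribution. The defaults (`log(70)`, 1.16) yield
#'   median ~70 and mean ~129 after rounding and truncation to
#'   `[notes_min, notes_max]`.
#' @param notes_min,notes_max hard range for notes per patient (default 1-876).
#' @param lexicon `cui_lexicon` supplying the surface terms notes are built
#'   from; default [build_default_lexicon()].
#' @param signal_cuis data.frame with columns `cui`, `rate_if_positive`,
#'   `rate_if_negative`: per-note mention probability of each signal concept
#'   conditional on the patient label. Defaults: the ten suicidality-cluster
#'   CUIs at 0.30 vs 0.02. These rates are illustrative knobs, not estimates
#'   of any study population.
#' @param noise_cuis data.frame with columns `cui`, `base_rate`: label-free
#'   per-note mention probability for the remaining concepts (default 0.04).
#' @param negation_rate probability a generated mention is rendered inside a
#'   negation phrase ("No ...", "Denies ...", "Without ..."). Default 0.10.
#' @param extra_negated_rate additional per-note probability that a label-0
#'   patient's note documents a signal concept in negated form only
#'   (mirrors "no suicide attempts" documentation). Default 0.08.
#' @param seed integer RNG seed; identical config + seed gives a
#'   byte-identical corpus.
#' @return A `generator_config` list, validated.
#' @export
generator_config <- function(n_patients = 73,
                             prevalence = 0.37,
                             notes_meanlog = log(70),
                             notes_sdlog = 1.16,
                             notes_min = 1,
                             notes_max = 876,
                             lexicon = build_default_lexicon(),
                             signal_cuis = NULL,
                             noise_cuis = NULL,
                             negation_rate = 0.10,
                             extra_negated_rate = 0.08,
                             seed = 1L) {
  if (is.null(signal_cuis)) {
    signal_cuis <- data.frame(cui = default_signal_cuis(),
                              rate_if_positive = 0.30,
                              rate_if_negative = 0.02,
                              stringsAsFactors = FALSE)
  }
  if (is.null(noise_cuis)) {
    others <- setdiff(unique(lexicon$cui), signal_cuis$cui)
    noise_cuis <- data.frame(cui = others, base_rate = 0.04,
                             stringsAsFactors = FALSE)
  }
  cfg <- list(n_patients = as.integer(n_patients), prevalence = prevalence,
              notes_meanlog = notes_meanlog, notes_sdlog = notes_sdlog,
              notes_min = as.integer(notes_min), notes_max = as.integer(notes_max),
              lexicon = lexicon, signal_cuis = signal_cuis,
              noise_cuis = noise_cuis, negation_rate = negation_rate,
              extra_negated_rate = extra_negated_rate, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 2)
  rates <- c(cfg$prevalence, cfg$signal_cuis$rate_if_positive,
             cfg$signal_cuis$rate_if_negative, cfg$noise_cuis$base_rate,
             cfg$negation_rate, cfg$extra_negated_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$notes_min < 1 || cfg$notes_max < cfg$notes_min) {
    stop("notes-per-patient range invalid: [", cfg$notes_min, ", ",
         cfg$notes_max, "]")
  }
  if (cfg$notes_sdlog < 0) stop("notes_sdlog must be >= 0")
  if (cfg$notes_sdlog == 0) {
    fixed <- round(exp(cfg$notes_meanlog))
    if (fixed < cfg$notes_min || fixed > cfg$notes_max) {
      stop("degenerate notes distribution: zero variance with point mass ",
           fixed, " outside [", cfg$notes_min, ", ", cfg$notes_max, "]")
    }
  }
  miss <- setdiff(c(cfg$signal_cuis$cui, cfg$noise_cuis$cui),
                  unique(cfg$lexicon$cui))
  if (length(miss) > 0) {
    stop("configured CUI(s) absent from lexicon: ", paste(miss, collapse = ", "))
  }
  invisible(cfg)
}

# sentence templates; exactly one "%s" concept slot each
AFFIRMED_TEMPLATES <- c(
  "Patient reports %s.",
  "Discussed %s in session.",
  "History of %s documented in chart.",
  "Ongoing %s per collateral report."
)
NEGATED_TEMPLATES <- c(
  "No %s.",
  "Denies %s.",
  "Without %s at this time.",
  "Patient denied %s today.",
  "Negative for %s."
)
LEAD_SENTENCES <- c(
  "Seen today for scheduled visit.",
  "Met with patient for routine review.",
  "Telephone contact with treatment team.",
  "Clinic visit for medication review."
)

#' Generate a synthetic cohort
#'
#' Labels are independent Bernoulli(prevalence); notes per patient come from
#' the truncated log-normal; each note's text is assembled from sentence
#' templates whose concept slots are filled with lexicon surface terms
#' sampled at label-conditional rates; a sampled mention is wrapped in a
#' negation phrase with probability `negation_rate`, and label-0 patients
#' additionally receive negated-only documentation of signal concepts at
#' `extra_negated_rate`.
#'
#' @param config a `generator_config`.
#' @return A validated `note_corpus`. Identical config and seed give an
#'   identical corpus (and identical JSONL bytes via [write_corpus()]).
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  labels <- stats::rbinom(n, 1L, config$prevalence)
  counts <- round(exp(stats::rnorm(n, config$notes_meanlog, config$notes_sdlog)))
  counts <- pmin(pmax(counts, config$notes_min), config$notes_max)

  variants_of <- split(config$lexicon$variant, config$lexicon$cui)
  sig <- config$signal_cuis
  noi <- config$noise_cuis
  cuis <- c(sig$cui, noi$cui)
  n_sig <- nrow(sig)
  n_cui <- length(cuis)

  sexes <- c("male", "female")
  races <- c("white", "black", "hispanic", "asian", "other")
  insurance <- c("public", "private")
  index_date <- as.Date("2016-09-01")

  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    attempt_label = as.integer(labels),
    stringsAsFactors = FALSE
  )
  patients$demographics <- lapply(seq_len(n), function(i) {
    c(age = as.character(sample(12:20, 1)),
      sex = sample(sexes, 1),
      race_ethnicity = sample(races, 1),
      insurance = sample(insurance, 1))
  })

  note_id <- character(sum(counts))
  note_pat <- character(sum(counts))
  note_date <- integer(sum(counts))
  note_text <- character(sum(counts))
  k <- 0L
  for (i in seq_len(n)) {
    m <- counts[i]
    rate <- if (labels[i] == 1L) sig$rate_if_positive else sig$rate_if_negative
    rates <- c(rate, noi$base_rate)
    days <- sort(sample.int(365, m, replace = TRUE), decreasing = TRUE)
    for (j in seq_len(m)) {
      present <- stats::runif(n_cui) < rates
      mention_cui <- cuis[present]
      negated <- stats::runif(length(mention_cui)) < config$negation_rate
      if (labels[i] == 0L && config$extra_negated_rate > 0) {
        extra <- sig$cui[stats::runif(n_sig) < config$extra_negated_rate]
        extra <- setdiff(extra, mention_cui)
        if (length(extra) > 0) {
          mention_cui <- c(mention_cui, extra)
          negated <- c(negated, rep(TRUE, length(extra)))
        }
      }
      sentences <- sample(LEAD_SENTENCES, 1)
      if (length(mention_cui) > 0) {
        terms <- vapply(mention_cui, function(cc) {
          v <- variants_of[[cc]]
          if (length(v) == 1) v else sample(v, 1)
        }, "")
        tpl_a <- sample(AFFIRMED_TEMPLATES, length(mention_cui), replace = TRUE)
        tpl_n <- sample(NEGATED_TEMPLATES, length(mention_cui), replace = TRUE)
        tpl <- ifelse(negated, tpl_n, tpl_a)
        sentences <- c(sentences, sprintf(tpl, terms))
      }
      k <- k + 1L
      note_id[k] <- sprintf("N%07d", k)
      note_pat[k] <- patients$patient_id[i]
      note_date[k] <- as.integer(index_date - days[j])
      note_text[k] <- paste(sentences, collapse = " ")
    }
  }
  notes <- data.frame(note_id = note_id, patient_id = note_pat,
                      timestamp = as.Date(note_date, origin = "1970-01-01"),
                      text = note_text, stringsAsFactors = FALSE)
  note_corpus(patients, notes)
}

#' Summarize a cohort
#'
#' @param corpus a non-empty `note_corpus`.
#' @return List with `n_patients`, `n_notes`, `prevalence`, and
#'   notes-per-patient `mean`, `median`, `min`, `max` (patients with zero
#'   notes count as zero).
#' @export
summarize_cohort <- function(corpus) {
  if (nrow(corpus$patients) == 0) stop("empty corpus")
  counts <- table(factor(corpus$notes$patient_id,
                         levels = corpus$patients$patient_id))
  counts <- as.integer(counts)
  list(
    n_patients = nrow(corpus$patients),
    n_notes = nrow(corpus$notes),
    prevalence = mean(corpus$patients$attempt_label),
    notes_mean = mean(counts),
    notes_median = stats::median(counts),
    notes_min = min(counts),
    notes_max = max(counts)
  )
}
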