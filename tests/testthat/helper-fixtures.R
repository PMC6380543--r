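# small in-code fixtures shared across test files

tiny_lexicon <- function() {
  cui_lexicon(data.frame(
    cui = c("C0038663", "C0038663", "C0038661", "C0030193",
            "C0011111", "C0588008"),
    preferred_term = c("Suicide attempt", "Suicide attempt",
                       "Suicidal ideation", "Pain", "Suicide (bare)",
                       "Severe depression"),
    variant = c("suicide attempt", "suicide attempts", "suicidal thoughts",
                "pain", "suicide", "severe depression"),
    stringsAsFactors = FALSE))
}

tiny_corpus <- function() {
  patients <- data.frame(
    patient_id = c("P1", "P2"),
    attempt_label = c(1L, 0L),
    stringsAsFactors = FALSE)
  notes <- data.frame(
    note_id = c("N1", "N2", "N3"),
    patient_id = c("P1", "P1", "P2"),
    timestamp = as.Date(c("2016-01-02", "2016-03-04", "2016-05-06")),
    text = c("Reports suicide attempt last month.",
             "No suicidal thoughts today.",
             "Complains of pain."),
    stringsAsFactors = FALSE)
  note_corpus(patients, notes)
}

# corpus of n label-only patients (no notes); for split/fold tests
label_corpus <- function(n, n_positive = round(0.37 * n)) {
  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    attempt_label = c(rep(1L, n_positive), rep(0L, n - n_positive)),
    stringsAsFactors = FALSE)
  notes <- data.frame(note_id = character(0), patient_id = character(0),
                      timestamp = as.Date(character(0)), text = character(0),
                      stringsAsFactors = FALSE)
  note_corpus(patients, notes)
}

# a feature matrix built from explicit code sets
fm_from_sets <- function(sets, labels) {
  n_pat <- length(labels)
  patients <- data.frame(patient_id = names(labels),
                         attempt_label = as.integer(labels),
                         stringsAsFactors = FALSE)
  # one note per set; note i belongs to the patient encoded in its name
  note_pat <- sub("\\..*$", "", names(sets))
  notes <- data.frame(note_id = names(sets), patient_id = note_pat,
                      timestamp = as.Date("2016-01-01") + seq_along(sets),
                      text = "", stringsAsFactors = FALSE)
  corpus <- note_corpus(patients, notes)
  names(sets) <- notes$note_id
  list(fm = build_note_matrix(sets, corpus), corpus = corpus)
}

# small reduced lexicon for pipeline-scale tests: the 10 suicidality signal
# concepts plus n_noise other concepts from the default lexicon
pipeline_lexicon <- function(n_noise = 20) {
  lex <- build_default_lexicon()
  sig <- attemptnlp:::default_signal_cuis()
  other <- setdiff(unique(lex$cui), sig)[seq_len(n_noise)]
  cui_lexicon(as.data.frame(lex[lex$cui %in% c(sig, other), ]))
}

# generator config at reduced note volume used for full-pipeline tests
pipeline_config <- function(seed, n_patients = 400, rate_pos = 0.30,
                            rate_neg = 0.02, null_signal = FALSE,
                            lexicon = pipeline_lexicon()) {
  sig <- attemptnlp:::default_signal_cuis()
  noise <- setdiff(unique(lexicon$cui), sig)
  if (null_signal) {
    signal <- data.frame(cui = sig, rate_if_positive = 0.04,
                         rate_if_negative = 0.04, stringsAsFactors = FALSE)
    extra <- 0
  } else {
    signal <- data.frame(cui = sig, rate_if_positive = rate_pos,
                         rate_if_negative = rate_neg, stringsAsFactors = FALSE)
    extra <- 0.08
  }
  generator_config(
    n_patients = n_patients, prevalence = 0.37,
    notes_meanlog = log(8), notes_sdlog = 0.7, notes_min = 1, notes_max = 40,
    lexicon = lexicon,
    signal_cuis = signal,
    noise_cuis = data.frame(cui = noise, base_rate = 0.04,
                            stringsAsFactors = FALSE),
    negation_rate = 0.10, extra_negated_rate = extra, seed = seed)
}

# the eleven holdout operating points of the published per-cutoff holdout
# table (counts: tn, fn, fp, tp), cutoffs 0%..100%
published_holdout_counts <- function() {
  data.frame(
    cutoff = seq(0, 1, by = 0.1),
    tn = c(0, 1, 2, 4, 8, 8, 8, 9, 9, 9, 9),
    fn = c(0, 0, 1, 2, 3, 5, 5, 6, 6, 6, 6),
    fp = c(9, 8, 7, 5, 1, 1, 1, 0, 0, 0, 0),
    tp = c(6, 6, 5, 4, 3, 1, 1, 0, 0, 0, 0))
}

# cross-validation mean sensitivities/specificities of the published
# per-cutoff CV table
published_cv_means <- function() {
  data.frame(
    cutoff = seq(0, 1, by = 0.1),
    mean_sensitivity = c(1.00, 0.87, 0.72, 0.51, 0.42, 0.25, 0, 0, 0, 0, 0),
    mean_specificity = c(0.00, 0.15, 0.26, 0.50, 0.74, 0.88, 0.88, 0.95,
                         0.98, 1.00, 1.00))
}
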