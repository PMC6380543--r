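#' @title Corpus, lexicon, and curated-term I/O
#' @description Readers, writers, and validators for the three inputs every
#'   downstream stage consumes: a JSONL corpus of patients and notes, a TSV
#'   concept lexicon (CUI -> surface-term variants), and a TSV curated
#'   clinical term list (risk / protective categories).
#' @name corpus_io
NULL

CUI_PATTERN <- "^C[0-9]{7}$"

#' Construct a validated note corpus
#'
#' A corpus holds a patient table (one row per patient, with a binary
#' past-year suicide-attempt label) and a note table (one row per clinical
#' note, keyed to a patient). Validation enforces unique identifiers,
#' labels in \{0,1\}, and referential integrity (no orphan notes).
#'
#' @param patients data.frame with columns `patient_id` (character),
#'   `attempt_label` (integer 0/1) and optionally `demographics`
#'   (list-column of named character vectors).
#' @param notes data.frame with columns `note_id`, `patient_id`,
#'   `timestamp` (`Date`), `text` (character; may be empty).
#' @return An object of class `note_corpus`.
#' @export
note_corpus <- function(patients, notes) {
  if (is.null(patients$demographics)) {
    patients$demographics <- replicate(nrow(patients), character(0), simplify = FALSE)
  }
  patients$patient_id <- as.character(patients$patient_id)
  patients$attempt_label <- as.integer(patients$attempt_label)
  notes$note_id <- as.character(notes$note_id)
  notes$patient_id <- as.character(notes$patient_id)
  notes$timestamp <- as.Date(notes$timestamp)
  notes$text <- as.character(notes$text)
  corpus <- structure(list(patients = patients, notes = notes),
                      class = "note_corpus")
  validate_corpus(corpus)
  corpus
}

#' Validate a note corpus
#'
#' @param corpus a `note_corpus`.
#' @return The corpus, invisibly; errors describe the first violation found.
#' @export
validate_corpus <- function(corpus) {
  p <- corpus$patients
  n <- corpus$notes
  dup <- p$patient_id[duplicated(p$patient_id)]
  if (length(dup) > 0) {
    stop("duplicate patient_id: ", paste(unique(dup), collapse = ", "))
  }
  if (length(p$attempt_label) && !all(p$attempt_label %in% c(0L, 1L))) {
    bad <- p$patient_id[!p$attempt_label %in% c(0L, 1L)]
    stop("attempt_label must be 0 or 1; offending patient_id: ",
         paste(bad, collapse = ", "))
  }
  dupn <- n$note_id[duplicated(n$note_id)]
  if (length(dupn) > 0) {
    stop("duplicate note_id: ", paste(unique(dupn), collapse = ", "))
  }
  orphan <- setdiff(n$patient_id, p$patient_id)
  if (length(orphan) > 0) {
    bad <- n$note_id[n$patient_id %in% orphan]
    stop("orphan note(s) referencing unknown patient: note_id ",
         paste(bad, collapse = ", "))
  }
  invisible(corpus)
}

#' @export
print.note_corpus <- function(x, ...) {
  cat(sprintf("<note_corpus> %d patients, %d notes, prevalence %.3f\n",
              nrow(x$patients), nrow(x$notes),
              if (nrow(x$patients)) mean(x$patients$attempt_label) else NA_real_))
  invisible(x)
}

#' Read a corpus from JSONL
#'
#' One JSON record per line with a `"kind"` discriminator:
#' `{"kind":"patient","patient_id",...,"attempt_label",...}` or
#' `{"kind":"note","note_id",...,"patient_id",...,"timestamp",...,"text",...}`.
#'
#' @param path path to a JSONL file.
#' @return A validated `note_corpus`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  pats <- list(); nts <- list()
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) {
                      stop(sprintf("malformed JSON at line %d: %s", i, conditionMessage(e)),
                           call. = FALSE)
                    })
    kind <- rec$kind
    if (is.null(kind)) stop(sprintf("record at line %d lacks \"kind\"", i))
    if (kind == "patient") {
      pats[[length(pats) + 1L]] <- rec
    } else if (kind == "note") {
      nts[[length(nts) + 1L]] <- rec
    } else {
      stop(sprintf("unknown record kind %s at line %d", kind, i))
    }
  }
  patients <- data.frame(
    patient_id = vapply(pats, function(r) as.character(r$patient_id), ""),
    attempt_label = vapply(pats, function(r) as.integer(r$attempt_label), 0L),
    stringsAsFactors = FALSE
  )
  patients$demographics <- lapply(pats, function(r) {
    d <- r$demographics
    if (is.null(d) || length(d) == 0) return(character(0))
    unlist(d)
  })
  notes <- data.frame(
    note_id = vapply(nts, function(r) as.character(r$note_id), ""),
    patient_id = vapply(nts, function(r) as.character(r$patient_id), ""),
    timestamp = as.Date(vapply(nts, function(r) as.character(r$timestamp), "")),
    text = vapply(nts, function(r) as.character(r$text), ""),
    stringsAsFactors = FALSE
  )
  if (length(nts) == 0) {
    notes <- data.frame(note_id = character(0), patient_id = character(0),
                        timestamp = as.Date(character(0)), text = character(0),
                        stringsAsFactors = FALSE)
  }
  if (length(pats) == 0) {
    patients <- data.frame(patient_id = character(0),
                           attempt_label = integer(0), stringsAsFactors = FALSE)
    patients$demographics <- list()
  }
  corpus <- note_corpus(patients, notes)
  message(sprintf("read corpus: %d patients, %d notes",
                  nrow(corpus$patients), nrow(corpus$notes)))
  corpus
}

#' Write a corpus to JSONL
#'
#' Patient records first, then notes, each serialized deterministically so
#' that writing the same corpus twice yields byte-identical files and
#' `read_corpus(write_corpus(c))` round-trips exactly.
#'
#' @param corpus a `note_corpus`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  p <- corpus$patients
  n <- corpus$notes
  plines <- vapply(seq_len(nrow(p)), function(i) {
    rec <- list(kind = "patient", patient_id = p$patient_id[i],
                attempt_label = p$attempt_label[i])
    d <- p$demographics[[i]]
    if (length(d) > 0) rec$demographics <- as.list(d)
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, "")
  nlines <- vapply(seq_len(nrow(n)), function(i) {
    rec <- list(kind = "note", note_id = n$note_id[i],
                patient_id = n$patient_id[i],
                timestamp = format(n$timestamp[i], "%Y-%m-%d"),
                text = n$text[i])
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(c(plines, nlines)), con, useBytes = TRUE)
  invisible(path)
}

#' Construct a concept lexicon
#'
#' A lexicon maps Concept Unique Identifiers (CUIs, pattern `C` + 7 digits)
#' to a preferred term and one or more surface-term variants. Stored as one
#' row per (cui, variant); case is preserved, matching downstream is
#' case-insensitive.
#'
#' @param df data.frame with columns `cui`, `preferred_term`, `variant`.
#' @return An object of class `cui_lexicon`.
#' @export
cui_lexicon <- function(df) {
  df$cui <- as.character(df$cui)
  df$preferred_term <- as.character(df$preferred_term)
  df$variant <- as.character(df$variant)
  bad <- unique(df$cui[!grepl(CUI_PATTERN, df$cui)])
  if (length(bad) > 0) {
    stop("invalid CUI code(s): ", paste(bad, collapse = ", "),
         " (expected \"C\" followed by 7 digits)")
  }
  if (any(!nzchar(df$variant))) stop("empty lexicon variant")
  dup <- duplicated(df[c("cui", "variant")])
  if (any(dup)) {
    warning(sprintf("%d duplicate (cui, variant) row(s) dropped", sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  # a CUI must carry a single preferred term
  pt <- tapply(df$preferred_term, df$cui, function(x) length(unique(x)))
  if (any(pt > 1)) {
    stop("conflicting preferred_term for CUI(s): ",
         paste(names(pt)[pt > 1], collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df[c("cui", "preferred_term", "variant")], class = c("cui_lexicon", "data.frame"))
}

#' Read a lexicon from TSV
#'
#' Expects a header row and columns `cui`, `preferred_term`, `variant`
#' (one variant per row; variants are grouped per CUI).
#'
#' @param path path to a UTF-8 TSV file.
#' @return A `cui_lexicon`.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                          quote = "", comment.char = "")
  need <- c("cui", "preferred_term", "variant")
  if (!all(need %in% names(df))) {
    stop("lexicon TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) {
    return(cui_lexicon(data.frame(cui = character(0), preferred_term = character(0),
                                  variant = character(0), stringsAsFactors = FALSE)))
  }
  cui_lexicon(df)
}

#' Write a lexicon to TSV
#'
#' @param lexicon a `cui_lexicon`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.table(as.data.frame(lexicon), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a curated clinical term list
#'
#' Clinician-assembled surface terms labelled `risk` or `protective`; when
#' resolved against a corpus they are force-included as candidate features.
#'
#' @param df data.frame with columns `term`, `category`.
#' @return An object of class `curated_lexicon`.
#' @export
curated_lexicon <- function(df) {
  df$term <- as.character(df$term)
  df$category <- as.character(df$category)
  if (any(!nzchar(df$term))) stop("empty curated term")
  bad <- unique(df$category[!df$category %in% c("risk", "protective")])
  if (length(bad) > 0) {
    stop("unknown curated category: ", paste(bad, collapse = ", "),
         " (expected \"risk\" or \"protective\")")
  }
  dup <- duplicated(tolower(df$term))
  if (any(dup)) {
    warning(sprintf("%d duplicate curated term(s) dropped", sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df[c("term", "category")], class = c("curated_lexicon", "data.frame"))
}

#' Read a curated term list from TSV
#'
#' @param path path to a UTF-8 TSV with columns `term`, `category`.
#' @return A `curated_lexicon`.
#' @export
read_curated_terms <- function(path) {
  if (!file.exists(path)) stop("curated term file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                          quote = "", comment.char = "")
  need <- c("term", "category")
  if (!all(need %in% names(df))) {
    stop("curated TSV must have columns: ", paste(need, collapse = ", "))
  }
  curated_lexicon(df)
}

#' Write a curated term list to TSV
#'
#' @param curated a `curated_lexicon`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curated_terms <- function(curated, path) {
  utils::write.table(as.data.frame(curated), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The default curated term list shipped with the package
#'
#' 34 risk terms and 30 protective terms. The terms follow the clusters the
#' underlying study reported as most associated with suicide attempt
#' (suicide-related phrases, family relations, psychiatric disorders,
#' psychotropic medications) padded with literature-standard risk and
#' protective factors for adolescent suicidality; the list is fully
#' user-replaceable via `read_curated_terms()`.
#'
#' @return A `curated_lexicon` with 64 terms.
#' @export
default_curated_terms <- function() {
  path <- system.file("extdata", "curated_terms.tsv", package = "attemptnlp",
                      mustWork = TRUE)
  read_curated_terms(path)
}
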