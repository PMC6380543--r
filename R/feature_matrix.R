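#' @title Note-by-concept dummy matrix
#' @description Builds the binary note x feature-code presence matrix,
#'   applies the minimum-distinct-patients column filter, and resolves
#'   curated clinical terms to the feature codes actually observed in a
#'   corpus. Note labels inherit the patient outcome: supervision exists
#'   only at patient level while classification operates at note level.
#' @name feature_matrix
NULL

new_feature_matrix <- function(rows, codes, m) {
  stopifnot(nrow(rows) == nrow(m), length(codes) == ncol(m))
  dimnames(m) <- list(rows$note_id, codes)
  structure(list(rows = rows, codes = codes, m = m), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d notes x %d codes (%d patients, density %.4f)\n",
              nrow(x$rows), length(x$codes),
              length(unique(x$rows$patient_id)),
              if (prod(dim(x$m)) > 0) Matrix::nnzero(x$m) / prod(dim(x$m))
              else NA_real_))
  invisible(x)
}

#' Build the note x feature-code dummy matrix
#'
#' One row per note in `cui_sets`, one column per distinct code observed in
#' any note, in lexicographic code order; cell is 1 iff the code belongs to
#' that note's set. Each row carries the note's patient and the note label
#' inherited from the patient's attempt label.
#'
#' @param cui_sets named list (by note_id) of character vectors of feature
#'   codes, e.g. from [extract_corpus_cuis()].
#' @param corpus the `note_corpus` the notes belong to.
#' @return A `feature_matrix` (sparse binary).
#' @export
build_note_matrix <- function(cui_sets, corpus) {
  note_ids <- names(cui_sets)
  idx <- match(note_ids, corpus$notes$note_id)
  if (anyNA(idx)) {
    stop("unknown note_id: ", paste(note_ids[is.na(idx)], collapse = ", "))
  }
  pat <- corpus$notes$patient_id[idx]
  lab <- corpus$patients$attempt_label[match(pat, corpus$patients$patient_id)]
  rows <- data.frame(note_id = note_ids, patient_id = pat,
                     note_label = as.integer(lab), stringsAsFactors = FALSE)
  codes <- sort(unique(unlist(cui_sets, use.names = FALSE)))
  lens <- lengths(cui_sets)
  if (length(codes) == 0) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                              dims = c(length(note_ids), 0))
    return(new_feature_matrix(rows, character(0), m))
  }
  i <- rep.int(seq_along(cui_sets), lens)
  j <- match(unlist(cui_sets, use.names = FALSE), codes)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(note_ids), length(codes)))
  m <- methods::as(m, "CsparseMatrix")
  m@x[] <- 1
  new_feature_matrix(rows, codes, m)
}

# distinct patients contributing at least one note containing each code
patients_per_code <- function(fm) {
  if (length(fm$codes) == 0) return(stats::setNames(integer(0), character(0)))
  tm <- methods::as(fm$m, "TsparseMatrix")
  counts <- integer(length(fm$codes))
  if (length(tm@i) > 0) {
    pat <- fm$rows$patient_id[tm@i + 1L]
    key <- paste(tm@j, pat, sep = "\r")
    uj <- tm@j[!duplicated(key)] + 1L
    counts <- tabulate(uj, nbins = length(fm$codes))
  }
  stats::setNames(counts, fm$codes)
}

#' Drop codes observed in too few distinct patients
#'
#' Retains exactly the columns whose code appears in at least `min_patients`
#' distinct patients' notes (distinct-patient counting, not note counting);
#' the row set is unchanged. Idempotent, and monotone in `min_patients`.
#'
#' @param fm a `feature_matrix`.
#' @param min_patients minimum distinct patients per code (default 4).
#' @return The filtered `feature_matrix`.
#' @export
filter_min_patients <- function(fm, min_patients = 4L) {
  stopifnot(min_patients >= 1)
  keep <- patients_per_code(fm) >= min_patients
  new_feature_matrix(fm$rows, fm$codes[keep], fm$m[, keep, drop = FALSE])
}

#' Subset a feature matrix to given notes
#'
#' @param fm a `feature_matrix`.
#' @param note_ids notes to keep (order preserved as given).
#' @param drop_empty_cols if `TRUE`, also drop codes absent from every kept
#'   note (used to restrict a fold's training matrix to codes that
#'   originate from its own training notes).
#' @return A `feature_matrix`.
#' @export
subset_notes <- function(fm, note_ids, drop_empty_cols = FALSE) {
  idx <- match(note_ids, fm$rows$note_id)
  if (anyNA(idx)) stop("unknown note_id in subset: ",
                       paste(note_ids[is.na(idx)], collapse = ", "))
  m <- fm$m[idx, , drop = FALSE]
  rows <- fm$rows[idx, , drop = FALSE]
  rownames(rows) <- NULL
  codes <- fm$codes
  if (drop_empty_cols && length(codes) > 0) {
    keep <- Matrix::colSums(m) > 0
    m <- m[, keep, drop = FALSE]
    codes <- codes[keep]
  }
  new_feature_matrix(rows, codes, m)
}

#' Subset a feature matrix to given codes
#'
#' @param fm a `feature_matrix`.
#' @param codes feature codes to keep, in the order given; codes absent
#'   from `fm` are an error.
#' @return A `feature_matrix`.
#' @export
subset_codes <- function(fm, codes) {
  idx <- match(codes, fm$codes)
  if (anyNA(idx)) stop("unknown code in subset: ",
                       paste(codes[is.na(idx)], collapse = ", "))
  new_feature_matrix(fm$rows, codes, fm$m[, idx, drop = FALSE])
}

#' Resolve curated terms to observed feature codes
#'
#' A curated surface term maps to every CUI one of whose lexicon variants
#' contains the term as a contiguous token subsequence (case-insensitive);
#' of those, only CUIs observed in at least one corpus note are kept, in
#' whichever observed form (affirmed and/or `_neg`). Curated terms matching
#' nothing are reported, not errors.
#'
#' @param curated a `curated_lexicon`.
#' @param corpus a `note_corpus`.
#' @param lexicon a `cui_lexicon`.
#' @param cui_sets optional pre-computed [extract_corpus_cuis()] result for
#'   `corpus` (avoids re-extraction).
#' @param options an [extraction_options()].
#' @return List with `codes` (sorted character vector of observed feature
#'   codes), `provenance` (data.frame code, term), and `unmatched`
#'   (character vector of curated terms that resolved to nothing).
#' @export
resolve_curated <- function(curated, corpus, lexicon, cui_sets = NULL,
                            options = extraction_options()) {
  if (is.null(cui_sets)) cui_sets <- extract_corpus_cuis(corpus, lexicon, options)
  observed <- sort(unique(unlist(cui_sets, use.names = FALSE)))
  observed_base <- sub("_neg$", "", observed)
  var_toks <- lapply(lexicon$variant, tokenize_term, options = options)
  codes <- character(0); prov_code <- character(0); prov_term <- character(0)
  unmatched <- character(0)
  for (k in seq_len(nrow(curated))) {
    term <- curated$term[k]
    tt <- tokenize_term(term, options)
    if (length(tt) == 0) { unmatched <- c(unmatched, term); next }
    hit_cui <- character(0)
    for (v in seq_along(var_toks)) {
      vt <- var_toks[[v]]
      if (length(vt) < length(tt)) next
      for (s in seq_len(length(vt) - length(tt) + 1L)) {
        if (all(vt[s:(s + length(tt) - 1L)] == tt)) {
          hit_cui <- c(hit_cui, lexicon$cui[v])
          break
        }
      }
    }
    hit_cui <- unique(hit_cui)
    obs_codes <- observed[observed_base %in% hit_cui]
    if (length(obs_codes) == 0) {
      unmatched <- c(unmatched, term)
    } else {
      codes <- c(codes, obs_codes)
      prov_code <- c(prov_code, obs_codes)
      prov_term <- c(prov_term, rep(term, length(obs_codes)))
    }
  }
  list(codes = sort(unique(codes)),
       provenance = data.frame(code = prov_code, term = prov_term,
                               stringsAsFactors = FALSE),
       unmatched = unmatched)
}

#' Write a feature matrix as MTX plus sidecar TSVs
#'
#' Writes `<stem>.mtx` (MatrixMarket coordinate), `<stem>_rows.tsv`
#' (note_id, patient_id, note_label) and `<stem>_cols.tsv` (code).
#'
#' @param fm a `feature_matrix`.
#' @param stem path stem (no extension).
#' @return `stem`, invisibly.
#' @export
write_feature_matrix <- function(fm, stem) {
  Matrix::writeMM(methods::as(fm$m, "generalMatrix"), paste0(stem, ".mtx"))
  utils::write.table(fm$rows, paste0(stem, "_rows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(data.frame(code = fm$codes), paste0(stem, "_cols.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(stem)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param stem path stem (no extension).
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(stem) {
  m <- Matrix::readMM(paste0(stem, ".mtx"))
  # binary matrices are stored in MatrixMarket "pattern" form; re-coerce to
  # the numeric presence representation used everywhere else
  m <- methods::as(m * 1, "CsparseMatrix")
  rows <- utils::read.delim(paste0(stem, "_rows.tsv"), stringsAsFactors = FALSE,
                            colClasses = c(note_id = "character",
                                           patient_id = "character",
                                           note_label = "integer"))
  cols <- utils::read.delim(paste0(stem, "_cols.tsv"), stringsAsFactors = FALSE)
  new_feature_matrix(rows, as.character(cols$code), m)
}
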