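#' @title Dictionary concept extraction with rule-based negation
#' @description Converts free note text into concept codes: sentence
#'   splitting, token normalization, greedy leftmost-longest dictionary
#'   matching against the lexicon's surface variants, and NegEx-style
#'   negation scoping with a bounded token window. A negated mention of CUI
#'   `X` contributes the feature code `X_neg`; an affirmed mention
#'   contributes `X`. Extraction is pure: same inputs, same outputs.
#'
#'   Full clinical NLP engines add part-of-speech tagging, shallow parsing,
#'   and UMLS named-entity resolution; because the downstream model consumes
#'   only presence/absence of a fixed code set, this module deliberately
#'   uses dictionary matching plus rule negation, which is reproducible and
#'   dependency-free.
#' @name concept_extraction
NULL

#' Extraction options
#'
#' @param negation_window number of tokens preceding a mention within which
#'   a negation trigger negates it (default 6).
#' @param pre_triggers negation trigger phrases scanned before a mention;
#'   multi-word triggers allowed.
#' @param post_triggers trigger phrases scanned after a mention (default
#'   none; the default rule set uses pre-mention triggers only).
#' @param conjunctions tokens that terminate a negation scope when they
#'   intervene between trigger and mention.
#' @param stemming if `TRUE`, apply light suffix stripping (s/es/ed/ing) to
#'   tokens on both sides of the match. Default `FALSE`.
#' @return An `extraction_options` list.
#' @export
extraction_options <- function(negation_window = 6L,
                               pre_triggers = c("no", "not", "denies",
                                                "denied", "without",
                                                "negative for"),
                               post_triggers = character(0),
                               conjunctions = c("but", "however"),
                               stemming = FALSE) {
  structure(list(negation_window = as.integer(negation_window),
                 pre_triggers = pre_triggers,
                 post_triggers = post_triggers,
                 conjunctions = conjunctions,
                 stemming = isTRUE(stemming)),
            class = "extraction_options")
}

# internal tokenizer: maximal [A-Za-z0-9]+ runs, lowercased; 0-based
# half-open offsets; returns plain vectors (no data.frame) for speed
tok_fast <- function(sentence, stemming = FALSE) {
  if (is.na(sentence) || !nzchar(sentence)) {
    return(list(token = character(0), start = integer(0), end = integer(0)))
  }
  m <- gregexpr("[A-Za-z0-9]+", sentence)[[1]]
  if (m[1] == -1) {
    return(list(token = character(0), start = integer(0), end = integer(0)))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tok <- tolower(substring(sentence, starts, starts + lens - 1L))
  if (stemming) tok <- strip_suffix(tok)
  list(token = tok, start = starts - 1L, end = starts + lens - 1L)
}

strip_suffix <- function(tok) {
  out <- sub("(ing|ed|es)$", "", tok)
  out <- ifelse(nchar(out) < 3, tok, out)
  out2 <- sub("s$", "", out)
  ifelse(nchar(out2) < 3, out, out2)
}

#' Split text into sentences
#'
#' Boundaries fall at `.`, `!` or `?` followed by whitespace (or end of
#' text), and at newlines. Offsets are 0-based character positions into the
#' original text; each returned sentence substring maps back exactly.
#'
#' @param text a single string.
#' @return data.frame with columns `text` and `start` (0-based offset);
#'   zero rows for empty input.
#' @export
split_sentences <- function(text) {
  empty <- data.frame(text = character(0), start = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  sp <- sentence_spans(text)
  if (length(sp$start) == 0) return(empty)
  data.frame(text = sp$text, start = sp$start, stringsAsFactors = FALSE)
}

# internal: sentence substrings with 0-based start offsets
sentence_spans <- function(text) {
  m <- gregexpr("[.!?](?=[ \t\r\n]|$)|\n", text, perl = TRUE)[[1]]
  nch <- nchar(text)
  ends <- if (m[1] == -1) integer(0) else as.integer(m)  # 1-based boundary pos
  incl <- if (length(ends)) substring(text, ends, ends) != "\n" else logical(0)
  last <- ends[length(ends)]
  if (length(ends) == 0 || last < nch) {
    ends <- c(ends, nch); incl <- c(incl, TRUE)
  }
  out_text <- character(0); out_start <- integer(0)
  cur <- 1L
  for (q in seq_along(ends)) {
    e <- if (incl[q]) ends[q] else ends[q] - 1L
    chunk <- substr(text, cur, e)
    ws <- regmatches(chunk, regexpr("^[ \t\r\n]*", chunk))
    s <- cur + nchar(ws)
    chunk <- sub("[ \t\r\n]+$", "", substr(text, s, e))
    if (nzchar(chunk)) {
      out_text <- c(out_text, chunk)
      out_start <- c(out_start, s - 1L)
    }
    cur <- ends[q] + 1L
  }
  list(text = out_text, start = out_start)
}

#' Normalize a sentence into matching tokens
#'
#' Tokens are maximal runs of ASCII letters and digits, lowercased for
#' matching; `start`/`end` are 0-based half-open character offsets into the
#' sentence as given.
#'
#' @param sentence a single string.
#' @param options an [extraction_options()] (controls stemming).
#' @return data.frame with columns `token`, `start`, `end`.
#' @export
normalize_tokens <- function(sentence, options = extraction_options()) {
  tk <- tok_fast(sentence, options$stemming)
  data.frame(token = tk$token, start = tk$start, end = tk$end,
             stringsAsFactors = FALSE)
}

tokenize_term <- function(term, options = extraction_options()) {
  tok_fast(term, options$stemming)$token
}

#' Compile a lexicon for matching
#'
#' Pre-tokenizes every variant (and the negation trigger phrases of
#' `options`) and indexes variants by first token so the matcher can look
#' up candidates in constant time per position. Ties at a position (equal
#' token length) break by lexicographic CUI order.
#'
#' @param lexicon a `cui_lexicon`.
#' @param options an [extraction_options()].
#' @return A `compiled_lexicon` (internal structure).
#' @export
compile_lexicon <- function(lexicon, options = extraction_options()) {
  toks <- lapply(lexicon$variant, tokenize_term, options = options)
  keep <- lengths(toks) > 0
  toks <- toks[keep]
  cui <- lexicon$cui[keep]
  nlen <- lengths(toks)
  first <- vapply(toks, `[`, "", 1L)
  ord <- order(first, -nlen, cui)
  entries <- lapply(ord, function(i) list(cui = cui[i], tokens = toks[[i]],
                                          len = nlen[i]))
  by_first <- split(entries, vapply(entries, function(e) e$tokens[1], ""))
  structure(list(by_first = list2env(by_first, parent = emptyenv()),
                 options = options,
                 trig = compile_triggers(options)),
            class = "compiled_lexicon")
}

compile_triggers <- function(options) {
  list(pre = lapply(options$pre_triggers, tokenize_term, options = options),
       post = lapply(options$post_triggers, tokenize_term, options = options),
       conj = options$conjunctions,
       window = options$negation_window)
}

# 1-based inclusive token spans of every occurrence of any trigger phrase
trigger_spans <- function(tok, trig_tokens) {
  n <- length(tok)
  ss <- integer(0); ee <- integer(0)
  for (tt in trig_tokens) {
    L <- length(tt)
    if (L == 0 || L > n) next
    cand <- which(tok == tt[1])
    cand <- cand[cand + L - 1L <= n]
    for (i in cand) {
      if (L == 1L || all(tok[i:(i + L - 1L)] == tt)) {
        ss <- c(ss, i); ee <- c(ee, i + L - 1L)
      }
    }
  }
  list(start = ss, end = ee)
}

# core matcher on a token vector; returns 1-based inclusive token spans
match_fast <- function(tok, by_first) {
  n <- length(tok)
  out_cui <- character(0); out_s <- integer(0); out_e <- integer(0)
  i <- 1L
  while (i <= n) {
    cands <- if (exists(tok[i], envir = by_first, inherits = FALSE)) {
      get(tok[i], envir = by_first)
    } else NULL
    hit <- NULL
    if (!is.null(cands)) {
      for (cand in cands) {             # sorted longest-first, then CUI
        L <- cand$len
        if (i + L - 1L <= n &&
            (L == 1L || all(tok[i:(i + L - 1L)] == cand$tokens))) {
          hit <- cand
          break
        }
      }
    }
    if (!is.null(hit)) {
      out_cui <- c(out_cui, hit$cui)
      out_s <- c(out_s, i)
      out_e <- c(out_e, i + hit$len - 1L)
      i <- i + hit$len
    } else {
      i <- i + 1L
    }
  }
  list(cui = out_cui, tok_start = out_s, tok_end = out_e)
}

# negation flags for mention token spans within one sentence
neg_fast <- function(tok, tok_start, tok_end, trig) {
  nm <- length(tok_start)
  neg <- logical(nm)
  if (nm == 0) return(neg)
  pre <- trigger_spans(tok, trig$pre)
  post <- trigger_spans(tok, trig$post)
  w <- trig$window
  conj <- trig$conj
  for (j in seq_len(nm)) {
    ms <- tok_start[j]; me <- tok_end[j]
    for (q in seq_along(pre$end)) {
      te <- pre$end[q]
      if (te < ms && ms - te <= w) {
        between <- if (te + 1L <= ms - 1L) tok[(te + 1L):(ms - 1L)] else character(0)
        if (!any(between %in% conj)) { neg[j] <- TRUE; break }
      }
    }
    if (!neg[j]) {
      for (q in seq_along(post$start)) {
        ts <- post$start[q]
        if (ts > me && ts - me <= w) {
          between <- if (me + 1L <= ts - 1L) tok[(me + 1L):(ts - 1L)] else character(0)
          if (!any(between %in% conj)) { neg[j] <- TRUE; break }
        }
      }
    }
  }
  neg
}

#' Match lexicon concepts in a token sequence
#'
#' Greedy leftmost-longest non-overlapping matching: scan positions left to
#' right; at each position take the longest variant whose token sequence
#' equals the tokens starting there (ties by CUI order), emit the mention,
#' and resume after it.
#'
#' @param tokens data.frame from [normalize_tokens()].
#' @param lexicon a `cui_lexicon` or `compiled_lexicon`.
#' @param options an [extraction_options()] (ignored when `lexicon` is
#'   already compiled).
#' @return data.frame with columns `cui`, `tok_start`, `tok_end` (1-based
#'   token indices, inclusive), `start`, `end` (0-based half-open character
#'   offsets), `negated` (all `FALSE`).
#' @export
match_concepts <- function(tokens, lexicon, options = extraction_options()) {
  cl <- if (inherits(lexicon, "compiled_lexicon")) lexicon else
    compile_lexicon(lexicon, options)
  mm <- match_fast(tokens$token, cl$by_first)
  data.frame(cui = mm$cui, tok_start = mm$tok_start, tok_end = mm$tok_end,
             start = if (length(mm$tok_start)) tokens$start[mm$tok_start] else integer(0),
             end = if (length(mm$tok_end)) tokens$end[mm$tok_end] else integer(0),
             negated = logical(length(mm$cui)), stringsAsFactors = FALSE)
}

#' Flag negated mentions
#'
#' A mention is negated iff a trigger phrase ends within the
#' `negation_window` tokens preceding it in the same sentence, with no
#' conjunction token between the trigger and the mention. Post-mention
#' triggers, when configured, use the mirrored rule.
#'
#' @param mentions data.frame from [match_concepts()].
#' @param tokens data.frame from [normalize_tokens()] for the same sentence.
#' @param options an [extraction_options()].
#' @return `mentions` with the `negated` column set.
#' @export
detect_negation <- function(mentions, tokens,
                            options = extraction_options()) {
  if (nrow(mentions) == 0) return(mentions)
  trig <- compile_triggers(options)
  mentions$negated <- neg_fast(tokens$token, mentions$tok_start,
                               mentions$tok_end, trig)
  mentions
}

# full per-note scan; returns vectors (cui, start, end, negated) with
# note-level character offsets
scan_note <- function(text, cl) {
  sp <- sentence_spans(text)
  cui <- character(0); cs <- integer(0); ce <- integer(0); neg <- logical(0)
  stem <- cl$options$stemming
  for (i in seq_along(sp$text)) {
    tk <- tok_fast(sp$text[i], stem)
    if (length(tk$token) == 0) next
    mm <- match_fast(tk$token, cl$by_first)
    if (length(mm$cui) == 0) next
    ng <- neg_fast(tk$token, mm$tok_start, mm$tok_end, cl$trig)
    cui <- c(cui, mm$cui)
    cs <- c(cs, tk$start[mm$tok_start] + sp$start[i])
    ce <- c(ce, tk$end[mm$tok_end] + sp$start[i])
    neg <- c(neg, ng)
  }
  list(cui = cui, start = cs, end = ce, negated = neg)
}

#' Extract all concept mentions from a note text
#'
#' Composition over sentences: split, tokenize, match, scope negation.
#' Character offsets are 0-based half-open into the original note text and
#' `matched_text` always equals the spanned substring.
#'
#' @param text note text.
#' @param lexicon a `cui_lexicon` or `compiled_lexicon`.
#' @param options an [extraction_options()].
#' @return data.frame with columns `cui`, `start`, `end`, `matched_text`,
#'   `negated`.
#' @export
extract_mentions <- function(text, lexicon, options = extraction_options()) {
  cl <- if (inherits(lexicon, "compiled_lexicon")) lexicon else
    compile_lexicon(lexicon, options)
  sc <- scan_note(text, cl)
  matched <- if (length(sc$start)) substring(text, sc$start + 1L, sc$end)
             else character(0)
  data.frame(cui = sc$cui, start = sc$start, end = sc$end,
             matched_text = matched,
             negated = sc$negated, stringsAsFactors = FALSE)
}

codes_of <- function(sc) {
  if (length(sc$cui) == 0) return(character(0))
  sort(unique(ifelse(sc$negated, paste0(sc$cui, "_neg"), sc$cui)))
}

#' Extract the feature-code set of one note
#'
#' Set semantics: duplicate mentions collapse; an affirmed mention of CUI
#' `X` contributes code `X`, a negated mention contributes `X_neg`, and the
#' two are distinct features.
#'
#' @param note a list or one-row data.frame with `note_id` and `text`, or a
#'   plain string (then `note_id` is `NA`).
#' @param lexicon a `cui_lexicon` or `compiled_lexicon`.
#' @param options an [extraction_options()].
#' @return List with `note_id` and `codes` (sorted character vector).
#' @export
extract_note_cuis <- function(note, lexicon, options = extraction_options()) {
  if (is.character(note)) note <- list(note_id = NA_character_, text = note)
  cl <- if (inherits(lexicon, "compiled_lexicon")) lexicon else
    compile_lexicon(lexicon, options)
  list(note_id = note$note_id, codes = codes_of(scan_note(note$text, cl)))
}

#' Extract feature codes for every note of a corpus
#'
#' @param corpus a `note_corpus`.
#' @param lexicon a `cui_lexicon`.
#' @param options an [extraction_options()].
#' @return Named list (by `note_id`, in corpus note order) of sorted
#'   character vectors of feature codes.
#' @export
extract_corpus_cuis <- function(corpus, lexicon,
                                options = extraction_options()) {
  cl <- if (inherits(lexicon, "compiled_lexicon")) lexicon else
    compile_lexicon(lexicon, options)
  out <- lapply(corpus$notes$text, function(tx) codes_of(scan_note(tx, cl)))
  names(out) <- corpus$notes$note_id
  out
}
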