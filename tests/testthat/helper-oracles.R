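# independent brute-force oracles; deliberately structured differently from
# the package implementation (no first-token index, no greedy scan state)

# sentence splitter oracle: character-by-character walk with the same rule
# set (terminator . ! ? followed by whitespace/EOS; newline always ends)
oracle_split <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(text = character(0), start = integer(0),
                      stringsAsFactors = FALSE))
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  nch <- length(chars)
  ws <- c(" ", "\t", "\r", "\n")
  ends <- integer(0)
  for (i in seq_len(nch)) {
    if (chars[i] == "\n") ends <- c(ends, i)
    else if (chars[i] %in% c(".", "!", "?") &&
             (i == nch || chars[i + 1] %in% ws)) ends <- c(ends, i)
  }
  if (length(ends) == 0 || ends[length(ends)] < nch) ends <- c(ends, nch)
  res_t <- character(0); res_s <- integer(0)
  cur <- 1L
  for (e in ends) {
    hi <- if (chars[e] == "\n") e - 1L else e
    s <- cur
    while (s <= hi && chars[s] %in% ws) s <- s + 1L
    h <- hi
    while (h >= s && chars[h] %in% ws) h <- h - 1L
    if (h >= s) {
      res_t <- c(res_t, paste(chars[s:h], collapse = ""))
      res_s <- c(res_s, s - 1L)
    }
    cur <- e + 1L
  }
  data.frame(text = res_t, start = res_s, stringsAsFactors = FALSE)
}

oracle_tokens <- function(sentence) {
  m <- gregexpr("[A-Za-z0-9]+", sentence)[[1]]
  if (m[1] == -1) return(character(0))
  tolower(substring(sentence, m, m + attr(m, "match.length") - 1))
}

# enumerate every (variant, position) match, then emulate leftmost-longest
# non-overlapping selection by sorting candidates on (start, -len, cui)
oracle_match <- function(tok, lexicon) {
  cand <- list()
  for (r in seq_len(nrow(lexicon))) {
    vt <- oracle_tokens(lexicon$variant[r])
    L <- length(vt)
    if (L == 0 || L > length(tok)) next
    for (s in seq_len(length(tok) - L + 1)) {
      if (all(tok[s:(s + L - 1)] == vt)) {
        cand[[length(cand) + 1]] <- list(cui = lexicon$cui[r], s = s,
                                         e = s + L - 1, len = L)
      }
    }
  }
  if (length(cand) == 0) {
    return(data.frame(cui = character(0), s = integer(0), e = integer(0)))
  }
  starts <- vapply(cand, `[[`, 0, "s")
  lens <- vapply(cand, `[[`, 0, "len")
  cuis <- vapply(cand, `[[`, "", "cui")
  ord <- order(starts, -lens, cuis)
  sel <- list(); ptr <- 1
  for (i in ord) {
    if (cand[[i]]$s >= ptr) {
      sel[[length(sel) + 1]] <- cand[[i]]
      ptr <- cand[[i]]$e + 1
    }
  }
  data.frame(cui = vapply(sel, `[[`, "", "cui"),
             s = vapply(sel, `[[`, 0, "s"),
             e = vapply(sel, `[[`, 0, "e"), stringsAsFactors = FALSE)
}

ORACLE_TRIGGERS <- list("no", "not", "denies", "denied", "without",
                        c("negative", "for"))
ORACLE_CONJ <- c("but", "however")

# negation oracle: enumerate all trigger occurrences and test the scope
# rule (trigger ends within the 6 tokens before the mention, no
# conjunction strictly between)
oracle_negated <- function(tok, mention_start, window = 6) {
  for (tt in ORACLE_TRIGGERS) {
    L <- length(tt)
    if (L > length(tok)) next
    for (s in seq_len(length(tok) - L + 1)) {
      if (!all(tok[s:(s + L - 1)] == tt)) next
      e <- s + L - 1
      if (e >= mention_start || mention_start - e > window) next
      between <- if (e + 1 <= mention_start - 1)
        tok[(e + 1):(mention_start - 1)] else character(0)
      if (!any(between %in% ORACLE_CONJ)) return(TRUE)
    }
  }
  FALSE
}

# full note-level oracle: sentences -> tokens -> matches -> negation ->
# feature code set
oracle_note_codes <- function(text, lexicon) {
  sents <- oracle_split(text)
  codes <- character(0)
  for (i in seq_len(nrow(sents))) {
    tok <- oracle_tokens(sents$text[i])
    if (length(tok) == 0) next
    mm <- oracle_match(tok, lexicon)
    for (j in seq_len(nrow(mm))) {
      neg <- oracle_negated(tok, mm$s[j])
      codes <- c(codes, if (neg) paste0(mm$cui[j], "_neg") else mm$cui[j])
    }
  }
  sort(unique(codes))
}

# random short clinical-ish notes mixing variant words, triggers,
# conjunctions, and filler
random_note <- function(lexicon, n_sentences = 3) {
  words <- unique(unlist(strsplit(tolower(lexicon$variant), " ")))
  filler <- c("patient", "today", "visit", "reports", "follow", "stable",
              "mild", "chronic")
  trig <- c("no", "not", "denies", "denied", "without", "negative for")
  conj <- c("but", "however")
  pool <- c(words, filler, trig, conj)
  sents <- vapply(seq_len(n_sentences), function(i) {
    k <- sample(2:8, 1)
    paste0(paste(sample(pool, k, replace = TRUE), collapse = " "), ".")
  }, "")
  paste(sents, collapse = " ")
}
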