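test_that("note matrix has one row per note, one column per observed code", {
  sets <- list(P1.a = c("Ca1234567"), P1.b = c("Ca1234567", "Cb1234567"),
               P2.a = character(0))
  # codes here are arbitrary strings; the matrix does not re-validate them
  out <- fm_from_sets(sets, c(P1 = 1L, P2 = 0L))
  fm <- out$fm
  expect_equal(dim(fm$m), c(3L, 2L))
  expect_equal(as.numeric(Matrix::rowSums(fm$m)), c(1, 2, 0))
  expect_equal(fm$codes, c("Ca1234567", "Cb1234567"))
  expect_equal(fm$rows$note_label, c(1L, 1L, 0L))

  # all-empty sets -> zero columns
  out0 <- fm_from_sets(list(P1.a = character(0), P2.a = character(0)),
                       c(P1 = 1L, P2 = 0L))
  expect_equal(ncol(out0$fm$m), 0L)

  # unknown note id errors
  co <- tiny_corpus()
  expect_error(build_note_matrix(list(NX = "C0030193"), co), "unknown note_id")
})

test_that("matrix cells equal set membership on randomized inputs", {
  set.seed(31)
  codes <- sprintf("C%07d", 1:40)
  pats <- sprintf("P%02d", 1:12)
  labels <- stats::setNames(sample(0:1, 12, replace = TRUE), pats)
  sets <- list()
  for (i in 1:60) {
    nm <- paste0(sample(pats, 1), ".", i)
    sets[[nm]] <- sample(codes, sample(0:8, 1))
  }
  out <- fm_from_sets(sets, labels)
  fm <- out$fm
  for (probe in 1:1000) {
    r <- sample(nrow(fm$rows), 1)
    cc <- sample(fm$codes, 1)
    expect_equal(unname(fm$m[r, cc]),
                 as.numeric(cc %in% sets[[fm$rows$note_id[r]]]))
  }
})

test_that("min-patients filter counts distinct patients, not notes", {
  # code A in notes of 4 patients; code B in 3 patients; code C in 10 notes
  # of one patient
  sets <- c(
    stats::setNames(lapply(1:4, function(i) "CA0000001"),
                    paste0("P", 1:4, ".a")),
    stats::setNames(lapply(1:3, function(i) "CB0000001"),
                    paste0("P", 1:3, ".b")),
    stats::setNames(lapply(1:10, function(i) "CC0000001"),
                    paste0("P1.c", 1:10)))
  labels <- stats::setNames(rep(0:1, 2), paste0("P", 1:4))
  out <- fm_from_sets(sets, labels)
  f4 <- filter_min_patients(out$fm, 4)
  expect_equal(f4$codes, "CA0000001")
  expect_equal(nrow(f4$rows), nrow(out$fm$rows))  # rows unchanged
  # min_patients = 1 is the identity on columns
  f1 <- filter_min_patients(out$fm, 1)
  expect_equal(f1$codes, out$fm$codes)
})

test_that("min-patients filter is idempotent, monotone, and matches a brute-force tally", {
  set.seed(17)
  for (rep in 1:10) {
    codes <- sprintf("C%07d", 1:25)
    pats <- sprintf("P%02d", 1:10)
    labels <- stats::setNames(sample(0:1, 10, replace = TRUE), pats)
    sets <- list()
    for (i in 1:50) {
      nm <- paste0(sample(pats, 1), ".", i)
      sets[[nm]] <- sample(codes, sample(0:5, 1))
    }
    out <- fm_from_sets(sets, labels)
    fm <- out$fm
    # brute-force: distinct patients per code
    tally <- vapply(fm$codes, function(cc) {
      length(unique(fm$rows$patient_id[
        vapply(fm$rows$note_id, function(nid) cc %in% sets[[nid]], TRUE)]))
    }, 0L)
    for (mp in c(2, 4)) {
      filt <- filter_min_patients(fm, mp)
      expect_equal(filt$codes, fm$codes[tally >= mp])
      expect_equal(filter_min_patients(filt, mp)$codes, filt$codes)  # idempotent
    }
    expect_true(all(filter_min_patients(fm, 5)$codes %in%
                    filter_min_patients(fm, 3)$codes))  # monotone
  }
})

test_that("matrix construction is order-independent up to row permutation", {
  set.seed(13)
  codes <- sprintf("C%07d", 1:10)
  pats <- c("P1", "P2", "P3")
  labels <- stats::setNames(c(1L, 0L, 1L), pats)
  sets <- list()
  for (i in 1:12) {
    sets[[paste0(sample(pats, 1), ".", i)]] <- sample(codes, sample(0:4, 1))
  }
  out1 <- fm_from_sets(sets, labels)
  perm <- sample(length(sets))
  out2 <- fm_from_sets(sets[perm], labels)
  expect_equal(out1$fm$codes, out2$fm$codes)
  for (nid in out1$fm$rows$note_id) {
    r1 <- which(out1$fm$rows$note_id == nid)
    r2 <- which(out2$fm$rows$note_id == nid)
    expect_equal(as.numeric(out1$fm$m[r1, ]), as.numeric(out2$fm$m[r2, ]))
  }
})

test_that("curated terms resolve to observed codes via variant token subsequence", {
  lex <- build_default_lexicon()
  patients <- data.frame(patient_id = c("P1", "P2"),
                         attempt_label = c(1L, 0L), stringsAsFactors = FALSE)
  notes <- data.frame(
    note_id = c("N1", "N2"), patient_id = c("P1", "P2"),
    timestamp = as.Date("2016-01-01") + 0:1,
    text = c("Reports suicide attempt. Denies bipolar disorder.",
             "Discussed coping skills."), stringsAsFactors = FALSE)
  co <- note_corpus(patients, notes)
  cur <- curated_lexicon(data.frame(
    term = c("suicide attempt", "bipolar", "coping skills", "firearm access"),
    category = c("risk", "risk", "protective", "risk")))
  rc <- resolve_curated(cur, co, lex)
  expect_true("C0038663" %in% rc$codes)                 # affirmed form observed
  expect_true("C0005586_neg" %in% rc$codes)             # only negated observed
  expect_false("C0005586" %in% rc$codes)
  expect_true("C0009244" %in% rc$codes)
  expect_equal(rc$unmatched, "firearm access")
  # provenance maps each code back to its curated term
  expect_equal(rc$provenance$term[rc$provenance$code == "C0038663"],
               "suicide attempt")
})

test_that("a curated term matching several observed concepts includes them all", {
  lex <- cui_lexicon(data.frame(
    cui = c("C0000001", "C0000002"),
    preferred_term = c("Alpha pain", "Beta pain"),
    variant = c("sharp pain", "dull pain"), stringsAsFactors = FALSE))
  patients <- data.frame(patient_id = "P1", attempt_label = 1L)
  notes <- data.frame(note_id = c("N1", "N2"), patient_id = "P1",
                      timestamp = as.Date("2016-01-01") + 0:1,
                      text = c("sharp pain", "dull pain"))
  co <- note_corpus(patients, notes)
  cur <- curated_lexicon(data.frame(term = "pain", category = "risk"))
  rc <- resolve_curated(cur, co, lex)
  expect_equal(rc$codes, c("C0000001", "C0000002"))
})

test_that("feature matrix round-trips through MTX plus sidecar TSVs", {
  sets <- list(P1.a = c("C0000001", "C0000003"), P1.b = "C0000002",
               P2.a = character(0))
  out <- fm_from_sets(sets, c(P1 = 1L, P2 = 0L))
  stem <- file.path(withr::local_tempdir(), "fm")
  write_feature_matrix(out$fm, stem)
  back <- read_feature_matrix(stem)
  expect_equal(back$rows, out$fm$rows)
  expect_equal(back$codes, out$fm$codes)
  expect_equal(as.matrix(back$m), as.matrix(out$fm$m),
               ignore_attr = TRUE)
})
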