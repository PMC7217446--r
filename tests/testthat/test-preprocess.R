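test_that("cleaning replaces floats, large integers and abbreviations", {
  expect_equal(clean_text("Tumor measures 3.5 cm."),
               c("tumor", "measures", "floattoken", "cm", "."))
  expect_equal(clean_text("depth 250 mm"), c("depth", "largeinttoken", "mm"))
  expect_equal(clean_text("exactly 100 units"), c("exactly", "100", "units"))
  expect_equal(clean_text("and 101 units"), c("and", "largeinttoken", "units"))
  expect_equal(clean_text("grade:2"), c("grade", ":", "2"))
  expect_equal(clean_text("seen by Dr. Smith at 9 am."),
               c("seen", "by", "dr", "smith", "at", "9", "am"))
  # integers embedded in alphanumerics are untouched
  expect_equal(clean_text("stage t2n0 and bg1234"),
               c("stage", "t2n0", "and", "bg1234"))
})

test_that("cleaning collapses repeats, pads punctuation and strips markup", {
  expect_equal(clean_text("-----"), "-")
  expect_equal(clean_text("a---b"), c("a", "-", "b"))
  expect_equal(clean_text("<b>Bold</b> text"), c("bold", "text"))
  expect_equal(clean_text("café résumé"),
               clean_text(iconv("café résumé",
                                "UTF-8", "ASCII//TRANSLIT")))
  expect_equal(clean_text("one\ttwo"), c("one", "two"))
})

test_that("cleaning is idempotent on its own output", {
  samples <- c("Tumor measures 3.5 cm. Depth 250 mm!!",
               "Dr. Who saw SPECIMEN <id>77</id>; grade:2---3",
               "multi\nline\n\ntext with 4.25 and 1000 things")
  for (s in samples) {
    once <- clean_text(s)
    twice <- clean_text(paste(once, collapse = " "))
    expect_equal(twice, once)
  }
})

test_that("line segmentation obeys both linebreak character sets", {
  # short line kept whole
  short <- list(rep("tok", 40L))
  seg <- segment_lines(short)
  expect_equal(nrow(seg$lines), 1L)
  expect_equal(seg$lines[1L, ], c(start = 1L, end = 40L))
  # 60-token line with ";" at position 30 -> two ranges split at the ";"
  ln <- rep("tok", 60L); ln[30L] <- ";"
  seg <- segment_lines(list(ln))
  expect_equal(nrow(seg$lines), 2L)
  expect_equal(unname(seg$lines[1L, ]), c(1L, 30L))
  expect_equal(unname(seg$lines[2L, ]), c(31L, 60L))
  # 55-token line, no set-1 characters, comma at 20 -> set-2 split at comma
  ln2 <- rep("tok", 55L); ln2[20L] <- ","
  seg2 <- segment_lines(list(ln2))
  expect_equal(nrow(seg2$lines), 2L)
  expect_equal(unname(seg2$lines[1L, ]), c(1L, 20L))
  # standalone single letters except "a" are set-2 split points
  ln3 <- rep("tok", 55L); ln3[25L] <- "b"
  expect_equal(nrow(segment_lines(list(ln3))$lines), 2L)
  ln4 <- rep("tok", 55L); ln4[25L] <- "a"
  expect_equal(nrow(segment_lines(list(ln4))$lines), 1L)
})

test_that("segmentation ranges are contiguous, cover the tokens, never empty", {
  set.seed(4)
  for (rep_i in 1:20) {
    n_lines <- sample(1:5, 1L)
    lines <- lapply(seq_len(n_lines), function(i) {
      n <- sample(c(3:20, 60:80), 1L)
      toks <- sample(c("tok", "word", ".", ",", "b", "x2"), n, replace = TRUE)
      toks
    })
    seg <- segment_lines(lines)
    expect_equal(length(seg$tokens), sum(lengths(lines)))
    expect_true(all(seg$lines[, "end"] >= seg$lines[, "start"]))
    expect_equal(seg$lines[1L, "start"], c(start = 1L))
    expect_equal(unname(seg$lines[nrow(seg$lines), "end"]), length(seg$tokens))
    if (nrow(seg$lines) > 1L)
      expect_equal(seg$lines[-1L, "start"],
                   seg$lines[-nrow(seg$lines), "end"] + 1L,
                   ignore_attr = TRUE)
  }
})

test_that("vocabulary respects the min-count boundary and is deterministic", {
  docs <- list(rep("common", 10L), rep("edge", 5L), rep("rare", 4L),
               c("common", "edge"))
  v <- build_vocab(docs, min_count = 5L)
  expect_true("common" %in% names(v))
  expect_true("edge" %in% names(v))     # exactly 5 occurrences keeps its id
  expect_false("rare" %in% names(v))    # 4 occurrences maps to unknowntoken
  ids <- encode_tokens(c("common", "rare", "nevermet"), v)
  expect_equal(ids[2L], unname(v[["unknowntoken"]]))
  expect_equal(ids[3L], unname(v[["unknowntoken"]]))
  expect_false(ids[1L] == ids[2L])
  # dense 1-based ids with specials always present
  expect_equal(sort(unname(v)), seq_along(v))
  expect_true(all(c("paddingtoken", "unknowntoken", "floattoken",
                    "largeinttoken", "separatortoken") %in% names(v)))
  # identical counts give identical vocabularies
  v2 <- build_vocab(rev(docs), min_count = 5L)
  expect_identical(unclass(v)[order(names(v))], unclass(v2)[order(names(v2))])
  expect_error(build_vocab(list()), "empty")
})

test_that("vocabulary round-trips through its TSV format", {
  v <- build_vocab(list(rep("alpha", 6L), rep("beta", 7L)), min_count = 5L)
  f <- tempfile(fileext = ".tsv")
  write_vocab(v, f)
  v2 <- read_vocab(f)
  expect_equal(names(v2), names(v))
  expect_equal(as.integer(v2), as.integer(v))
})

test_that("tokenized corpora round-trip through their JSON-Lines layout", {
  docs <- list(rep("alpha", 6L), rep("beta", 7L))
  v <- build_vocab(docs, min_count = 5L)
  td <- list(
    r1 = tokenize_report("alpha beta\nbeta alpha alpha", v),
    r2 = tokenize_report("beta 3.5", v)
  )
  f <- tempfile(fileext = ".jsonl")
  write_tokenized_corpus(td, f)
  back <- read_tokenized_corpus(f)
  expect_equal(names(back), names(td))
  for (rid in names(td)) {
    expect_equal(back[[rid]]$ids, td[[rid]]$ids)
    expect_equal(unname(back[[rid]]$lines), unname(td[[rid]]$lines))
  }
})

test_that("tokenize_report never emits ids outside the vocabulary range", {
  docs <- list(rep("alpha", 6L), rep("beta", 7L), c("alpha", "beta", "gamma"))
  v <- build_vocab(docs, min_count = 5L)
  td <- tokenize_report("Alpha beta GAMMA delta 3.5\nnew line of text", v)
  expect_true(all(td$ids >= 1L & td$ids <= length(v)))
  expect_equal(length(td$ids), length(td$tokens))
})
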