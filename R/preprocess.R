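# Text preprocessing: the report-cleaning procedure, line segmentation for the
# hierarchical encoder, and corpus vocabulary construction.
#
# Cleaning steps, applied in order: remove XML tags; lowercase; tabs to spaces
# (line breaks retained); drop the period in "dr.", "am.", "pm."; replace
# floats with "floattoken"; replace standalone integers greater than 100 with
# "largeinttoken"; transliterate unicode to ASCII (unmappable characters
# dropped); collapse consecutive repeats of the same non-alphanumeric character
# to one; pad every non-alphanumeric character with spaces; whitespace-
# tokenize. Identifier segments are schema-level fields, not text spans, so
# their removal happens at corpus I/O rather than here. Rare-token replacement
# with "unknowntoken" is corpus-wide and lives in encode_tokens()/build_vocab().

PAD_TOKEN <- "paddingtoken"
UNK_TOKEN <- "unknowntoken"
FLOAT_TOKEN <- "floattoken"
LARGEINT_TOKEN <- "largeinttoken"
SEP_TOKEN <- "separatortoken"
SPECIAL_TOKENS <- c(PAD_TOKEN, UNK_TOKEN, FLOAT_TOKEN, LARGEINT_TOKEN, SEP_TOKEN)

# Linebreak character set 1: characters at which over-long lines are split first
LINEBREAK_SET1 <- c(".", ":", ";", "/", "?", "~", "*", "<", "#")
# Set 2: standalone single letters except "a", plus , - _ =
LINEBREAK_SET2_PUNCT <- c(",", "-", "_", "=")

# cleaning applied to one line of text (everything except tokenization)
clean_line_string <- function(x) {
  x <- gsub("<[^>]*>", " ", x)                     # XML tags
  x <- tolower(x)
  x <- gsub("\\b(dr|am|pm)\\.", "\\1", x)          # abbreviation periods
  # floats -> floattoken (standalone digits.digits only; embedded runs like
  # "t2n0" are left alone)
  x <- gsub("(?<![[:alnum:]])[0-9]+\\.[0-9]+(?![[:alnum:]])",
            FLOAT_TOKEN, x, perl = TRUE)
  # standalone integers > 100 -> largeinttoken
  m <- gregexpr("(?<![[:alnum:]])[0-9]+(?![[:alnum:]])", x, perl = TRUE)
  regmatches(x, m) <- lapply(regmatches(x, m), function(v) {
    if (length(v)) ifelse(suppressWarnings(as.numeric(v)) > 100,
                          LARGEINT_TOKEN, v) else v
  })
  # unicode -> ASCII, dropping what cannot be transliterated
  y <- iconv(x, "UTF-8", "ASCII//TRANSLIT", sub = "")
  bad <- is.na(y)
  if (any(bad)) y[bad] <- iconv(x[bad], "UTF-8", "ASCII", sub = "")
  bad <- is.na(y)
  if (any(bad)) y[bad] <- gsub("[^\x01-\x7f]", "", x[bad], useBytes = TRUE)
  x <- y
  # collapse runs of the same non-alphanumeric character
  x <- gsub("([^[:alnum:][:space:]])\\1+", "\\1", x)
  # pad non-alphanumerics with spaces
  x <- gsub("([^[:alnum:][:space:]])", " \\1 ", x)
  x
}

split_natural_lines <- function(raw) {
  raw <- gsub("\r\n?", "\n", raw)
  raw <- gsub("\t", " ", raw)
  strsplit(raw, "\n", fixed = TRUE)[[1L]]
}

#' Clean raw report text into a token sequence
#'
#' Applies the full in-order cleaning procedure (see file header) and
#' whitespace-tokenizes the result. Line structure is not preserved; use
#' [tokenize_report()] when line ranges are needed for hierarchical encoding.
#'
#' @param raw a character scalar of raw report text
#' @return character vector of tokens (possibly empty)
#' @export
clean_text <- function(raw) {
  unlist(clean_text_lines(raw), use.names = FALSE)
}

# cleaned tokens grouped by natural (non-empty) line
clean_text_lines <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  lines <- split_natural_lines(raw)
  if (length(lines) == 0L) return(list())
  cleaned <- clean_line_string(lines)
  toks <- strsplit(trimws(cleaned), "[[:space:]]+")
  toks <- lapply(toks, function(v) v[nzchar(v)])
  toks[lengths(toks) > 0L]
}

is_set2_token <- function(tok) {
  (nchar(tok) == 1L & grepl("^[b-z]$", tok)) | tok %in% LINEBREAK_SET2_PUNCT
}

# cut a token vector after every position where `at` is TRUE
split_after <- function(tokens, at) {
  cut <- which(at)
  cut <- cut[cut < length(tokens)]
  if (length(cut) == 0L) return(list(tokens))
  starts <- c(1L, cut + 1L)
  ends <- c(cut, length(tokens))
  mapply(function(s, e) tokens[s:e], starts, ends, SIMPLIFY = FALSE)
}

#' Segment cleaned lines into bounded-length line ranges
#'
#' Lines longer than `max_tokens` are split at any character of linebreak set 1
#' (`. : ; / ? ~ * < #`); segments still longer than `max_tokens` are re-split
#' at set 2 (standalone single letters except "a", comma, hyphen, underscore,
#' equals). A segment with no split characters is kept whole even if over the
#' limit. The split character ends its segment.
#'
#' @param lines list of token vectors, one per natural line
#' @param max_tokens maximum tokens per line before splitting (default 50)
#' @return list with `tokens` (flattened token vector) and `lines` (integer
#'   matrix with columns `start`, `end`; contiguous, non-overlapping, covering
#'   the whole sequence)
#' @export
segment_lines <- function(lines, max_tokens = 50L) {
  segs <- list()
  for (ln in lines) {
    if (length(ln) <= max_tokens) {
      segs <- c(segs, list(ln))
      next
    }
    s1 <- split_after(ln, ln %in% LINEBREAK_SET1)
    for (seg in s1) {
      if (length(seg) <= max_tokens) {
        segs <- c(segs, list(seg))
      } else {
        segs <- c(segs, split_after(seg, is_set2_token(seg)))
      }
    }
  }
  segs <- segs[lengths(segs) > 0L]
  tokens <- unlist(segs, use.names = FALSE)
  ends <- cumsum(lengths(segs))
  starts <- c(1L, ends[-length(ends)] + 1L)
  list(tokens = tokens,
       lines = cbind(start = as.integer(starts), end = as.integer(ends)))
}

#' Build a corpus vocabulary
#'
#' Tokens occurring fewer than `min_count` times across the entire corpus map
#' to `"unknowntoken"`. Ids are assigned deterministically: special tokens
#' first, then corpus tokens by descending frequency with lexicographic
#' tie-break.
#'
#' @param docs list of token vectors (one per document)
#' @param min_count minimum corpus-wide count for a token to keep its own id
#'   (default 5)
#' @return a `vocab` object: named integer vector mapping token to id (1-based,
#'   dense), with attributes `min_count` and `n_special`
#' @export
build_vocab <- function(docs, min_count = 5L) {
  if (length(docs) == 0L) stop("cannot build a vocabulary from an empty corpus")
  counts <- table(unlist(docs, use.names = FALSE))
  counts <- counts[!(names(counts) %in% SPECIAL_TOKENS)]
  keep <- counts[counts >= min_count]
  ord <- order(-as.integer(keep), names(keep), method = "radix")
  toks <- c(SPECIAL_TOKENS, names(keep)[ord])
  ids <- seq_along(toks)
  names(ids) <- toks
  structure(ids, class = "vocab", min_count = as.integer(min_count),
            n_special = length(SPECIAL_TOKENS))
}

#' @export
print.vocab <- function(x, ...) {
  cat("<vocab> ", length(x), " tokens (", attr(x, "n_special"),
      " special), min_count = ", attr(x, "min_count"), "\n", sep = "")
  invisible(x)
}

#' Map tokens to vocabulary ids
#'
#' Tokens outside the vocabulary receive the id of `"unknowntoken"`.
#'
#' @param tokens character vector of tokens
#' @param vocab a [build_vocab()] object
#' @return integer vector of ids
#' @export
encode_tokens <- function(tokens, vocab) {
  ids <- unname(vocab[tokens])
  ids[is.na(ids)] <- unname(vocab[[UNK_TOKEN]])
  as.integer(ids)
}

#' Tokenize one report for model input
#'
#' Cleans the text, segments lines for hierarchical encoding, and (when a
#' vocabulary is given) maps tokens to ids.
#'
#' @param raw raw report text
#' @param vocab optional [build_vocab()] object
#' @param max_line_tokens maximum tokens per line before splitting
#' @return list with `tokens`, `lines` (range matrix) and, with a vocabulary,
#'   `ids`
#' @export
tokenize_report <- function(raw, vocab = NULL, max_line_tokens = 50L) {
  seg <- segment_lines(clean_text_lines(raw), max_tokens = max_line_tokens)
  if (!is.null(vocab)) seg$ids <- encode_tokens(seg$tokens, vocab)
  seg
}

#' Write / read a vocabulary as a two-column TSV (token, id)
#' @param vocab a `vocab` object
#' @param path file path
#' @export
write_vocab <- function(vocab, path) {
  utils::write.table(
    data.frame(token = names(vocab), id = as.integer(vocab)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write / read a tokenized corpus as JSON Lines
#'
#' One object per document with the report id, its token-id array and the
#' line ranges used by the hierarchical encoder.
#'
#' @param docs named list of tokenized documents ([tokenize_report()] results
#'   with an `ids` field), keyed by report id
#' @param path file path
#' @export
write_tokenized_corpus <- function(docs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rid in names(docs)) {
    d <- docs[[rid]]
    rec <- list(report_id = rid, ids = as.integer(d$ids),
                lines = lapply(seq_len(nrow(d$lines)), function(i)
                  c(d$lines[i, 1L], d$lines[i, 2L])))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_tokenized_corpus
#' @export
read_tokenized_corpus <- function(path) {
  lines <- readLines(path)
  docs <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    rng <- rec$lines                       # simplified to a matrix, or a list
    if (is.list(rng)) rng <- do.call(rbind, rng)
    if (is.null(rng) || length(rng) == 0L) rng <- NULL
    if (!is.null(rng) && is.null(dim(rng))) rng <- matrix(rng, nrow = 1L)
    list(ids = as.integer(rec$ids),
         lines = if (is.null(rng)) NULL else
           cbind(start = as.integer(rng[, 1L]), end = as.integer(rng[, 2L])))
  })
  names(docs) <- vapply(lines, function(l)
    jsonlite::fromJSON(l)$report_id, character(1L))
  docs
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ids <- as.integer(df$id)
  names(ids) <- df$token
  structure(ids, class = "vocab", min_count = NA_integer_,
            n_special = sum(names(ids) %in% SPECIAL_TOKENS))
}
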