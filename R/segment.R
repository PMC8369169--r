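#' Construct a lexicon for maximum-matching segmentation
#'
#' @param words Character vector of words (empty strings dropped,
#'   duplicates removed). An empty lexicon is allowed; segmentation then
#'   yields all singletons.
#' @return Object of class `ner_lexicon` with components `words`, `max_len`
#'   and an internal hash for O(1) membership tests.
#' @export
#' @examples
#' lex <- lexicon(c("ab", "abc"))
#' lex$max_len
lexicon <- function(words = character()) {
  words <- unique(enc2utf8(as.character(words)))
  words <- words[nzchar(words)]
  h <- new.env(hash = TRUE, parent = emptyenv(), size = max(29L, length(words)))
  for (w in words) assign(w, TRUE, envir = h)
  structure(
    list(words = words,
         max_len = if (length(words)) max(nchar(words)) else 0L,
         hash = h),
    class = "ner_lexicon"
  )
}

#' @export
print.ner_lexicon <- function(x, ...) {
  cat("Lexicon:", length(x$words), "words, max length", x$max_len, "\n")
  invisible(x)
}

lexicon_has <- function(lex, word) {
  exists(word, envir = lex$hash, inherits = FALSE)
}

#' Greedy forward maximum-matching segmentation
#'
#' Scans left to right; at each position takes the longest lexicon word
#' starting there, else emits a singleton character-word. Deterministic and
#' total. Segmentation is used only to build word-level representations for
#' the fusion module; tagging always stays character-level.
#'
#' @param chars Character vector of single characters, or a single string.
#' @param lex A [lexicon()] (possibly empty).
#' @return Object of class `ner_segmentation`: a list with `spans` (data
#'   frame of 0-based half-open `start`,`end` columns partitioning the
#'   sentence), `words` (surface strings) and `word_of_char` (1-based span
#'   index per character).
#' @export
#' @examples
#' segment_text("abc", lexicon("ab"))$spans
segment_text <- function(chars, lex = lexicon()) {
  chars <- as_chars(chars)
  n <- length(chars)
  starts <- integer(); ends <- integer()
  i <- 1L
  while (i <= n) {
    len <- 1L
    if (lex$max_len >= 2L) {
      for (l in seq(min(lex$max_len, n - i + 1L), 2L)) {
        if (l < 2L) break
        cand <- paste(chars[i:(i + l - 1L)], collapse = "")
        if (lexicon_has(lex, cand)) { len <- l; break }
      }
    }
    starts <- c(starts, i - 1L)
    ends <- c(ends, i - 1L + len)
    i <- i + len
  }
  spans <- data.frame(start = starts, end = ends)
  words <- vapply(seq_len(nrow(spans)), function(k) {
    paste(chars[(spans$start[k] + 1L):spans$end[k]], collapse = "")
  }, character(1))
  structure(
    list(spans = spans, words = words,
         word_of_char = rep(seq_len(nrow(spans)), spans$end - spans$start)),
    class = "ner_segmentation"
  )
}

#' @export
print.ner_segmentation <- function(x, ...) {
  cat("Segmentation:", nrow(x$spans), "words /", sum(x$spans$end - x$spans$start),
      "characters\n")
  cat(" ", paste(x$words, collapse = " | "), "\n")
  invisible(x)
}

#' Broadcast word indices to character positions
#'
#' @param seg A segmentation from [segment_text()].
#' @return Integer vector, one 1-based word index per character; constant
#'   within each word span and non-decreasing.
#' @export
broadcast_word_ids <- function(seg) {
  stopifnot(inherits(seg, "ner_segmentation"))
  seg$word_of_char
}

#' Read a lexicon file (one word per line, UTF-8)
#'
#' @param path File path.
#' @return A [lexicon()].
#' @export
read_lexicon <- function(path) {
  lexicon(readLines(path, encoding = "UTF-8", warn = FALSE))
}

#' Write a lexicon file (one word per line, UTF-8)
#'
#' @param lex A [lexicon()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lex$words, con, useBytes = TRUE)
  invisible(path)
}
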