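# Readers and writers. CoNLL-style files are two tab-separated columns,
# one character per line, blank line between sentences, UTF-8. At the file
# boundary tag stems print with a space ("B-treatment law"); internal
# identifiers use an underscore.

tag_to_file <- function(tags) gsub("_", " ", tags, fixed = TRUE)
tag_from_file <- function(tags) gsub(" ", "_", tags, fixed = TRUE)

#' Read a CoNLL-style character/tag file
#'
#' @param path File path (UTF-8, `<char>\t<tag>` lines, blank line between
#'   sentences).
#' @return A `ner_corpus` whose samples have `chars`, `tags` and `text`.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sch <- tag_schema()
  samples <- list()
  chars <- character(); tags <- character()
  flush <- function() {
    if (length(chars)) {
      samples[[length(samples) + 1L]] <<- list(
        chars = chars, tags = tags, text = paste(chars, collapse = ""))
    }
    chars <<- character(); tags <<- character()
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "") { flush(); next }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || nchar(parts[1L]) != 1L) {
      stop(sprintf("%s:%d: malformed line (expected `<char>\\t<tag>`)",
                   path, i), call. = FALSE)
    }
    tg <- tag_from_file(parts[2L])
    if (!tg %in% sch$tags) {
      stop(sprintf("%s:%d: unknown tag label: %s", path, i, parts[2L]),
           call. = FALSE)
    }
    chars <- c(chars, parts[1L])
    tags <- c(tags, tg)
  }
  flush()
  structure(list(samples = samples, lexicon = NULL, manifest = NULL,
                 spec = NULL), class = "ner_corpus")
}

#' Write a CoNLL-style character/tag file
#'
#' Inverse of [read_conll()]; round-trips byte-identically for canonical
#' files.
#'
#' @param samples A `ner_corpus` or list of samples with `chars` and `tags`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(samples, path) {
  corp <- as_ner_samples(samples)
  blocks <- vapply(corp, function(s) {
    paste(paste0(s$chars, "\t", tag_to_file(s$tags)), collapse = "\n")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(blocks, collapse = "\n\n"), con, useBytes = TRUE)
  invisible(path)
}

#' Read / write JSONL samples
#'
#' One JSON object per line with fields `text` (string) and `entities`
#' (array of `{cls, start, end}` objects, 0-based half-open spans).
#'
#' @param path File path.
#' @return For `read_jsonl`, a `ner_corpus` with tags derived from the
#'   entity spans via [encode_entities()].
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  samples <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyDataFrame = TRUE),
                    error = function(e) {
                      stop(sprintf("%s:%d: invalid JSON: %s", path, i,
                                   conditionMessage(e)), call. = FALSE)
                    })
    chars <- split_chars(obj$text)
    ents <- obj$entities
    ents <- if (is.null(ents) || length(ents) == 0L) {
      data.frame(class = character(), start = integer(), end = integer())
    } else {
      data.frame(class = ents$cls, start = as.integer(ents$start),
                 end = as.integer(ents$end), stringsAsFactors = FALSE)
    }
    list(text = obj$text, chars = chars,
         tags = encode_entities(chars, ents), entities = ents)
  })
  structure(list(samples = samples, lexicon = NULL, manifest = NULL,
                 spec = NULL), class = "ner_corpus")
}

#' @rdname read_jsonl
#' @param samples A `ner_corpus` or list of samples.
#' @export
write_jsonl <- function(samples, path) {
  corp <- if (inherits(samples, "ner_corpus")) samples$samples else samples
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (s in corp) {
    chars <- if (!is.null(s$chars)) s$chars else split_chars(s$text)
    ents <- if (!is.null(s$entities)) s$entities else decode_tags(s$tags)
    obj <- list(text = paste(chars, collapse = ""),
                entities = lapply(seq_len(nrow(ents)), function(i) {
                  list(cls = ents$class[i], start = ents$start[i],
                       end = ents$end[i])
                }))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' A run configuration bundles paths, model settings (fusion variant,
#' encoder kind, dimensions, head), training settings (epochs, batch size,
#' learning rate, seed) and the evaluation modes to emit. The seed is
#' mandatory; every referenced input path must exist at load time.
#'
#' @param path Configuration file; format chosen by extension.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  seed <- cfg$training$seed %||% cfg$seed
  if (is.null(seed)) stop("configuration must set a seed", call. = FALSE)
  for (key in names(cfg$paths)) {
    p <- cfg$paths[[key]]
    if (key %in% c("corpus", "lexicon", "train", "valid", "test", "input") &&
        !is.null(p) && !file.exists(p)) {
      stop(sprintf("configured input path does not exist: %s = %s", key, p),
           call. = FALSE)
    }
  }
  cfg
}
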