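#' Entity classes of the CSDTH schema
#'
#' The five entity classes used throughout the package: clinical
#' manifestation (symptoms and signs, including tongue and pulse findings),
#' syndrome (the TCM diagnostic pattern), disease, treatment law (the
#' therapeutic principle) and herb. Internal identifiers use underscores.
#'
#' @return Character vector of the five class names.
#' @export
#' @examples
#' entity_classes()
entity_classes <- function() {
  c("clinical_manifestation", "syndrome", "disease", "treatment_law", "herb")
}

# Tag stem per class. Clinical manifestation tags use the "symptom" stem,
# which is the conventional tag name for that class.
.tag_stems <- c(
  clinical_manifestation = "symptom",
  syndrome               = "syndrome",
  disease                = "disease",
  treatment_law          = "treatment_law",
  herb                   = "herb"
)

#' BIO tag schema
#'
#' Builds the 11-tag vocabulary: a B-/I- pair for each of the five entity
#' classes plus the outside tag `O`. Tag strings use underscores internally
#' (`B-treatment_law`); the file format uses a space (`B-treatment law`),
#' see [read_conll()].
#'
#' @return An object of class `tag_schema` with components:
#' \describe{
#'   \item{tags}{ordered character vector of the 11 tags}
#'   \item{index}{named integer vector mapping tag to 1-based index}
#'   \item{class_of}{named character vector mapping tag to entity class
#'     (`NA` for `O`)}
#' }
#' @export
#' @examples
#' sch <- tag_schema()
#' sch$tags
tag_schema <- function() {
  stems <- unname(.tag_stems)
  tags <- c(as.vector(rbind(paste0("B-", stems), paste0("I-", stems))), "O")
  structure(
    list(
      tags = tags,
      index = stats::setNames(seq_along(tags), tags),
      class_of = stats::setNames(c(rep(entity_classes(), each = 2L), NA_character_), tags)
    ),
    class = "tag_schema"
  )
}

#' @export
print.tag_schema <- function(x, ...) {
  cat("BIO tag schema:", length(x$tags), "tags\n")
  cat(" ", paste(x$tags, collapse = ", "), "\n")
  invisible(x)
}

# Split a string into Unicode code points. No normalization is applied.
split_chars <- function(text) {
  if (length(text) != 1L || !is.character(text))
    stop("`text` must be a single character string", call. = FALSE)
  strsplit(enc2utf8(text), "", useBytes = FALSE)[[1L]]
}

# Accept either a single string or an already-split character vector.
as_chars <- function(x) {
  if (length(x) == 1L && nchar(x) != 1L) split_chars(x) else as.character(x)
}

.tag_for_class <- function(cls, prefix) {
  stem <- .tag_stems[cls]
  if (anyNA(stem)) {
    stop("unknown entity class: ", paste(cls[is.na(stem)], collapse = ", "),
         call. = FALSE)
  }
  paste0(prefix, "-", unname(stem))
}

validate_entities <- function(entities, n_chars) {
  if (is.null(entities) || nrow(entities) == 0L) {
    return(data.frame(class = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(c("class", "start", "end") %in% names(entities)))
  ent <- entities[order(entities$start, entities$end), , drop = FALSE]
  bad <- ent$start < 0L | ent$end > n_chars | ent$start >= ent$end
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("entity span [%d,%d) out of bounds for a %d-character sentence",
                 ent$start[i], ent$end[i], n_chars), call. = FALSE)
  }
  if (nrow(ent) > 1L) {
    overlap <- which(ent$start[-1L] < ent$end[-nrow(ent)])
    if (length(overlap)) {
      i <- overlap[1L]
      stop(sprintf("overlapping entity spans [%d,%d) and [%d,%d)",
                   ent$start[i], ent$end[i], ent$start[i + 1L], ent$end[i + 1L]),
           call. = FALSE)
    }
  }
  ent
}

#' Encode entity spans as per-character BIO tags
#'
#' The first character of each entity receives `B-<class tag>`, remaining
#' characters `I-<class tag>`, and all other positions `O`. Spans are 0-based
#' and half-open, so an entity covering the first two characters is
#' `start = 0, end = 2`.
#'
#' @param chars Character vector of single characters, or a single string.
#' @param entities Data frame with columns `class`, `start`, `end`
#'   (0-based half-open spans, non-overlapping).
#' @return Character vector of tags, one per character.
#' @seealso [decode_tags()] for the inverse.
#' @export
#' @examples
#' encode_entities("abc", data.frame(class = "herb", start = 0, end = 2))
encode_entities <- function(chars, entities) {
  chars <- as_chars(chars)
  n <- length(chars)
  ent <- validate_entities(entities, n)
  tags <- rep("O", n)
  for (i in seq_len(nrow(ent))) {
    s <- ent$start[i]; e <- ent$end[i]
    tags[s + 1L] <- .tag_for_class(ent$class[i], "B")
    if (e - s > 1L) tags[(s + 2L):e] <- .tag_for_class(ent$class[i], "I")
  }
  tags
}

#' Decode a BIO tag sequence into entity spans
#'
#' Maximal B-I runs of one class become entities. The decoder is total over
#' arbitrary tag sequences: an `I-` tag that does not continue a run of the
#' same class is repaired to `B-` (begin repair), so raw model output can
#' always be scored without erroring.
#'
#' @param tags Character vector of tags from [tag_schema()].
#' @param chars Optional character vector (or string) used to fill the
#'   `text` column of the result.
#' @return Data frame with columns `class`, `start`, `end` (0-based,
#'   half-open, sorted, non-overlapping) and, when `chars` is given, `text`.
#' @export
#' @examples
#' decode_tags(c("B-herb", "I-herb", "B-herb"))
decode_tags <- function(tags, chars = NULL) {
  sch <- tag_schema()
  unknown <- setdiff(unique(tags), sch$tags)
  if (length(unknown)) {
    stop("unknown tag label: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cls <- unname(sch$class_of[tags])
  prefix <- substr(tags, 1L, 1L)
  n <- length(tags)
  out_class <- character(); out_start <- integer(); out_end <- integer()
  cur_class <- NA_character_; cur_start <- NA_integer_
  close_run <- function(end_pos) {
    if (!is.na(cur_class)) {
      out_class <<- c(out_class, cur_class)
      out_start <<- c(out_start, cur_start)
      out_end <<- c(out_end, end_pos)
    }
  }
  for (i in seq_len(n)) {
    if (tags[i] == "O") {
      close_run(i - 1L)
      cur_class <- NA_character_
    } else if (prefix[i] == "B" || is.na(cur_class) || cls[i] != cur_class) {
      # B- always begins a new entity; orphan I- is repaired to a begin
      close_run(i - 1L)
      cur_class <- cls[i]
      cur_start <- i - 1L
    }
    # else: I- continuing the current run
  }
  close_run(n)
  res <- data.frame(class = out_class, start = out_start, end = out_end,
                    stringsAsFactors = FALSE)
  if (!is.null(chars)) {
    chars <- as_chars(chars)
    res$text <- vapply(seq_len(nrow(res)), function(i) {
      paste(chars[(res$start[i] + 1L):res$end[i]], collapse = "")
    }, character(1))
  }
  res
}
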