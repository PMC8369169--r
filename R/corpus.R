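# Seeded generator of TCM-like labeled corpora. The generator emulates the
# *structure* of a mixed publication / clinical-record NER dataset: five
# entity classes, variable-length entities (clinical manifestations are
# long), entity-sparse "publication" sentences and entity-dense "record"
# sentences -- not any real TCM vocabulary.

.default_length_dists <- function() {
  list(
    clinical_manifestation = list(
      lengths = 2:12,
      prob = c(0.02, 0.04, 0.06, 0.08, 0.10, 0.14, 0.16, 0.15, 0.12, 0.08, 0.05)),
    syndrome      = list(lengths = 3:6, prob = c(0.20, 0.35, 0.30, 0.15)),
    disease       = list(lengths = 2:4, prob = c(0.40, 0.40, 0.20)),
    treatment_law = list(lengths = 3:6, prob = c(0.25, 0.35, 0.25, 0.15)),
    herb          = list(lengths = 2:4, prob = c(0.35, 0.45, 0.20))
  )
}

.default_rates <- function() {
  list(
    publication = c(clinical_manifestation = 0.5, syndrome = 0.2,
                    disease = 0.1, treatment_law = 0.25, herb = 0.25),
    record = c(clinical_manifestation = 2.0, syndrome = 0.8,
               disease = 0.3, treatment_law = 0.8, herb = 2.2)
  )
}

#' Specification of a synthetic labeled corpus
#'
#' Defines the generating distributions: how many samples of each style,
#' per-class expected entity counts per sample (records are entity-dense,
#' publications entity-sparse), per-class entity-length distributions
#' (clinical manifestations run 2-12 characters with most mass above 6),
#' the synthetic character alphabet, and the class-signal knob.
#'
#' Characters are drawn from the CJK ideograph block so the pipeline faces
#' real multi-byte text. Each class owns a small set of marker characters;
#' `marker_noise` is the probability that an entity character is drawn from
#' the shared (class-ambiguous) pool instead of the class's marker set.
#' High noise makes character identity nearly useless for classifying an
#' entity while the word surface remains fully informative -- the regime in
#' which word-level fusion should help most.
#'
#' @param n_publication,n_record Samples per style.
#' @param rates Named list `publication`/`record` of per-class expected
#'   entity counts per sample (Poisson).
#' @param length_dists Per-class entity length distributions
#'   (`list(lengths=, prob=)`).
#' @param alphabet_size Total synthetic characters.
#' @param marker_noise Probability in \[0,1\] of drawing an entity character
#'   from the shared pool (see above).
#' @param words_per_class Entity vocabulary size per class.
#' @param n_distractors Filler-alphabet distractor words added to the
#'   lexicon.
#' @param filler_mean Named vector, mean filler-segment length per style.
#' @param max_len Maximum sample length in characters.
#' @param seed Seed for the vocabulary (alphabet, entity surfaces, lexicon).
#' @param sample_seed Seed for sample drawing; defaults to `seed + 1`. Two
#'   specs sharing `seed` but differing in `sample_seed` share their
#'   vocabulary and lexicon, giving disjoint train/test corpora over one
#'   entity inventory.
#' @return Object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_publication = 300L, n_record = 100L,
                        rates = .default_rates(),
                        length_dists = .default_length_dists(),
                        alphabet_size = 420L,
                        marker_noise = 0.5,
                        words_per_class = 80L,
                        n_distractors = 60L,
                        filler_mean = c(publication = 8, record = 2.5),
                        max_len = 160L,
                        seed = 1L, sample_seed = NULL) {
  stopifnot(marker_noise >= 0, marker_noise <= 1,
            all(unlist(rates) >= 0), alphabet_size >= 200L)
  for (cl in entity_classes()) {
    d <- length_dists[[cl]]
    stopifnot(length(d$lengths) == length(d$prob),
              abs(sum(d$prob) - 1) < 1e-8)
  }
  mean_len <- vapply(entity_classes(), function(cl) {
    sum(length_dists[[cl]]$lengths * length_dists[[cl]]$prob)
  }, numeric(1))
  for (style in c("publication", "record")) {
    contrib <- rates[[style]][entity_classes()] * mean_len
    k <- sum(rates[[style]])
    expected <- sum(contrib) + (k + 1) * filler_mean[[style]]
    if (expected > max_len) {
      stop(sprintf(
        "entity rates imply an expected %s sentence of %.0f characters (> max_len %d); largest contributor: %s",
        style, expected, max_len, names(which.max(contrib))), call. = FALSE)
    }
  }
  structure(
    list(n_publication = as.integer(n_publication),
         n_record = as.integer(n_record),
         rates = rates, length_dists = length_dists,
         alphabet_size = as.integer(alphabet_size),
         marker_noise = marker_noise,
         words_per_class = as.integer(words_per_class),
         n_distractors = as.integer(n_distractors),
         filler_mean = filler_mean, max_len = as.integer(max_len),
         seed = as.integer(seed),
         sample_seed = as.integer(if (is.null(sample_seed)) seed + 1L
                                  else sample_seed)),
    class = "corpus_spec"
  )
}

#' High-signal spec for controlled fusion experiments
#'
#' A [corpus_spec()] preset in which entity characters are almost entirely
#' drawn from the shared pool (`marker_noise = 0.95`) over a larger entity
#' vocabulary, so entity class is essentially a property of the word, not
#' of its characters.
#'
#' @param n_publication,n_record,seed,sample_seed,marker_noise,words_per_class
#'   As in [corpus_spec()], with high-signal defaults.
#' @param ... Further overrides passed to [corpus_spec()].
#' @return A `corpus_spec`.
#' @export
high_signal_spec <- function(n_publication = 1500L, n_record = 500L,
                             seed = 1L, sample_seed = NULL,
                             marker_noise = 0.95, words_per_class = 250L,
                             ...) {
  corpus_spec(n_publication = n_publication, n_record = n_record,
              marker_noise = marker_noise, words_per_class = words_per_class,
              seed = seed, sample_seed = sample_seed, ...)
}

# Character pools: one marker set per class, a shared entity pool, and a
# disjoint filler pool, all sampled from the CJK ideograph block.
build_alphabet <- function(spec) {
  n <- spec$alphabet_size
  cps <- 0x4E00L + seq_len(n) - 1L
  chars <- intToUtf8(cps, multiple = TRUE)
  n_marker <- 12L
  marker <- list()
  at <- 1L
  for (cl in entity_classes()) {
    marker[[cl]] <- chars[at:(at + n_marker - 1L)]
    at <- at + n_marker
  }
  n_filler <- 60L
  shared <- chars[at:(n - n_filler)]
  filler <- chars[(n - n_filler + 1L):n]
  list(marker = marker, shared = shared, filler = filler)
}

rand_word <- function(len, marker_chars, shared_chars, noise) {
  from_shared <- stats::runif(len) < noise
  ch <- character(len)
  if (any(from_shared))
    ch[from_shared] <- sample(shared_chars, sum(from_shared), replace = TRUE)
  if (any(!from_shared))
    ch[!from_shared] <- sample(marker_chars, sum(!from_shared), replace = TRUE)
  paste(ch, collapse = "")
}

# Entity vocabularies, stratified by length so that drawing a length from
# the spec distribution and then a uniform word of that length reproduces
# the spec's length distribution exactly.
build_vocab <- function(spec, alpha) {
  vocab <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (cl in entity_classes()) {
    d <- spec$length_dists[[cl]]
    by_len <- list()
    for (k in seq_along(d$lengths)) {
      n_w <- max(1L, round(spec$words_per_class * d$prob[k]))
      words <- character(0)
      guard <- 0L
      while (length(words) < n_w && guard < 1000L) {
        w <- rand_word(d$lengths[k], alpha$marker[[cl]], alpha$shared,
                       spec$marker_noise)
        if (!exists(w, envir = seen, inherits = FALSE)) {
          assign(w, TRUE, envir = seen)
          words <- c(words, w)
        }
        guard <- guard + 1L
      }
      by_len[[as.character(d$lengths[k])]] <- words
    }
    vocab[[cl]] <- by_len
  }
  vocab
}

draw_entity_surface <- function(vocab_cl, d) {
  len <- sample(d$lengths, 1L, prob = d$prob)
  ws <- vocab_cl[[as.character(len)]]
  ws[sample.int(length(ws), 1L)]
}

draw_filler <- function(mean_len, pool, min_len = 0L) {
  len <- max(min_len, stats::rpois(1L, mean_len))
  if (len == 0L) return("")
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic labeled corpus
#'
#' Draws entity vocabularies and the lexicon under `spec$seed`, then
#' samples sentences under `spec$sample_seed`: per sentence and class, a
#' Poisson number of entities, laid out in random order with filler
#' segments between them (at least one filler character separates
#' consecutive entities). Gold tags come from [encode_entities()]. Every
#' generated entity surface is in the emitted lexicon, and no entity
#' crosses a sample boundary. Deterministic given the spec.
#'
#' @param spec A [corpus_spec()].
#' @return Object of class `ner_corpus`: list with `samples` (each with
#'   `text`, `chars`, `tags`, `entities`, `style`), `lexicon`, `manifest`
#'   (per style x class entity counts) and `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  alpha <- NULL; vocab <- NULL; lex_words <- NULL
  with_seed(spec$seed, {
    alpha <- build_alphabet(spec)
    vocab <- build_vocab(spec, alpha)
    distractors <- unique(vapply(seq_len(spec$n_distractors), function(i) {
      paste(sample(alpha$filler, sample(2:3, 1L), replace = TRUE),
            collapse = "")
    }, character(1)))
    lex_words <- c(unlist(vocab, use.names = FALSE), distractors)
  })
  classes <- entity_classes()
  samples <- list()
  counts <- matrix(0L, 2L, length(classes),
                   dimnames = list(c("publication", "record"), classes))
  with_seed(spec$sample_seed, {
    styles <- c(rep("publication", spec$n_publication),
                rep("record", spec$n_record))
    for (si in seq_along(styles)) {
      style <- styles[si]
      rates <- spec$rates[[style]]
      k_cls <- stats::rpois(length(classes), rates[classes])
      ents <- character(0); ent_cls <- character(0)
      for (ci in seq_along(classes)) {
        if (k_cls[ci] > 0L) {
          for (j in seq_len(k_cls[ci])) {
            ents <- c(ents, draw_entity_surface(vocab[[classes[ci]]],
                                                spec$length_dists[[classes[ci]]]))
            ent_cls <- c(ent_cls, classes[ci])
          }
        }
      }
      if (length(ents)) {
        ord <- sample.int(length(ents))
        ents <- ents[ord]; ent_cls <- ent_cls[ord]
      }
      # draw filler segments, dropping entities (rare) until the sentence
      # fits max_len exactly as laid out
      fm <- spec$filler_mean[[style]]
      repeat {
        k <- length(ents)
        fillers <- character(k + 1L)
        fillers[1L] <- draw_filler(fm, alpha$filler,
                                   min_len = if (k == 0L) 1L else 0L)
        if (k > 1L) {
          for (j in 2:k) fillers[j] <- draw_filler(fm, alpha$filler,
                                                   min_len = 1L)
        }
        if (k > 0L) fillers[k + 1L] <- draw_filler(fm, alpha$filler)
        total <- sum(nchar(ents)) + sum(nchar(fillers))
        if (total <= spec$max_len || k == 0L) break
        ents <- ents[-k]; ent_cls <- ent_cls[-k]
      }
      if (length(ents) == 0L && total > spec$max_len) {
        fillers <- substr(paste(fillers, collapse = ""), 1L, spec$max_len)
      }
      starts <- integer(0); ends <- integer(0)
      pieces <- fillers[1L]
      pos <- nchar(fillers[1L])
      for (j in seq_along(ents)) {
        starts <- c(starts, pos)
        pos <- pos + nchar(ents[j])
        ends <- c(ends, pos)
        pieces <- c(pieces, ents[j], fillers[j + 1L])
        pos <- pos + nchar(fillers[j + 1L])
      }
      text <- paste(pieces, collapse = "")
      entities <- data.frame(class = ent_cls, start = starts, end = ends,
                             stringsAsFactors = FALSE)
      chars <- split_chars(text)
      tags <- encode_entities(chars, entities)
      for (cl in unique(ent_cls)) {
        counts[style, cl] <- counts[style, cl] + sum(ent_cls == cl)
      }
      samples[[si]] <- list(text = text, chars = chars, tags = tags,
                            entities = entities, style = style)
    }
  })
  manifest <- as.data.frame(as.table(counts), stringsAsFactors = FALSE)
  names(manifest) <- c("style", "class", "n_entities")
  structure(list(samples = samples, lexicon = lexicon(lex_words),
                 manifest = manifest, spec = spec),
            class = "ner_corpus")
}

#' @export
print.ner_corpus <- function(x, ...) {
  n <- length(x$samples)
  cat("Synthetic NER corpus:", n, "samples\n")
  if (!is.null(x$manifest)) {
    tot <- stats::aggregate(n_entities ~ class, x$manifest, sum)
    cat("  entities:", paste(sprintf("%s=%d", tot$class, tot$n_entities),
                             collapse = ", "), "\n")
  }
  if (!is.null(x$lexicon)) cat("  lexicon:", length(x$lexicon$words), "words\n")
  invisible(x)
}

#' Train/validation/test sizes under floor-with-remainder-to-train
#'
#' Sizes are `floor(p_i * n)` for validation and test with the remainder
#' assigned to the training split.
#'
#' @param n Total number of samples.
#' @param proportions Positive length-3 vector (train, valid, test),
#'   normalised to sum to 1.
#' @return Named integer vector `c(train, valid, test)` summing to `n`.
#' @export
#' @examples
#' split_sizes(94380, c(6, 2, 2))
split_sizes <- function(n, proportions = c(6, 2, 2)) {
  stopifnot(length(proportions) == 3L, all(proportions > 0), n >= 1)
  p <- proportions / sum(proportions)
  valid <- floor(p[2L] * n)
  test <- floor(p[3L] * n)
  train <- n - valid - test
  c(train = as.integer(train), valid = as.integer(valid),
    test = as.integer(test))
}

#' Split a corpus into train/validation/test sets
#'
#' Samples are shuffled under `seed` and partitioned into disjoint sets
#' sized by [split_sizes()].
#'
#' @param corpus A `ner_corpus` or list of samples.
#' @param proportions Positive length-3 vector, normalised to sum to 1.
#' @param seed Shuffle seed.
#' @return List of three `ner_corpus` objects named `train`, `valid`,
#'   `test`, sharing the parent's lexicon.
#' @export
split_corpus <- function(corpus, proportions = c(6, 2, 2), seed = 1L) {
  samples <- if (inherits(corpus, "ner_corpus")) corpus$samples else corpus
  lex <- if (inherits(corpus, "ner_corpus")) corpus$lexicon else NULL
  n <- length(samples)
  if (n == 0L) stop("cannot split an empty corpus", call. = FALSE)
  sizes <- split_sizes(n, proportions)
  ord <- with_seed(seed, sample.int(n))
  idx <- list(train = ord[seq_len(sizes[["train"]])],
              valid = ord[sizes[["train"]] + seq_len(sizes[["valid"]])],
              test = ord[sizes[["train"]] + sizes[["valid"]] +
                           seq_len(sizes[["test"]])])
  lapply(idx, function(ii) {
    structure(list(samples = samples[ii], lexicon = lex, manifest = NULL,
                   spec = NULL), class = "ner_corpus")
  })
}
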