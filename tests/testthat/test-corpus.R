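test_that("zero entity rates give an all-O corpus", {
  zero <- list(publication = stats::setNames(rep(0, 5), entity_classes()),
               record = stats::setNames(rep(0, 5), entity_classes()))
  corp <- generate_corpus(corpus_spec(n_publication = 15, n_record = 5,
                                      rates = zero, seed = 2))
  expect_length(corp$samples, 20L)
  expect_true(all(unlist(lapply(corp$samples, `[[`, "tags")) == "O"))
  expect_true(all(corp$manifest$n_entities == 0L))
})

test_that("generation is byte-identical under the same seed", {
  spec <- corpus_spec(n_publication = 30, n_record = 10, seed = 17)
  a <- generate_corpus(spec)
  b <- generate_corpus(spec)
  expect_identical(lapply(a$samples, `[[`, "text"),
                   lapply(b$samples, `[[`, "text"))
  expect_identical(lapply(a$samples, `[[`, "tags"),
                   lapply(b$samples, `[[`, "tags"))
  expect_identical(a$lexicon$words, b$lexicon$words)
})

test_that("specs sharing a vocabulary seed share their lexicon but not samples", {
  a <- generate_corpus(corpus_spec(n_publication = 10, n_record = 0,
                                   seed = 5, sample_seed = 100))
  b <- generate_corpus(corpus_spec(n_publication = 10, n_record = 0,
                                   seed = 5, sample_seed = 200))
  expect_identical(a$lexicon$words, b$lexicon$words)
  expect_false(identical(lapply(a$samples, `[[`, "text"),
                         lapply(b$samples, `[[`, "text")))
})

test_that("samples validate against the schema and the manifest recounts", {
  corp <- generate_corpus(corpus_spec(n_publication = 40, n_record = 20,
                                      seed = 3))
  sch <- tag_schema()
  for (s in corp$samples) {
    expect_length(s$tags, length(s$chars))
    expect_true(all(s$tags %in% sch$tags))
    expect_identical(s$tags, encode_entities(s$chars, s$entities))
    expect_lte(length(s$chars), corp$spec$max_len)
  }
  recount <- table(factor(unlist(lapply(corp$samples, function(s) s$entities$class)),
                          levels = entity_classes()))
  tot <- stats::aggregate(n_entities ~ class, corp$manifest, sum)
  expect_equal(as.integer(recount[tot$class]), tot$n_entities)
})

test_that("every generated entity surface is in the lexicon and segmentation recovers gold word spans", {
  corp <- generate_corpus(corpus_spec(n_publication = 30, n_record = 15,
                                      seed = 23))
  for (s in corp$samples) {
    if (!nrow(s$entities)) next
    surfaces <- decode_tags(s$tags, s$chars)$text
    expect_true(all(surfaces %in% corp$lexicon$words))
    seg <- segment_text(s$chars, corp$lexicon)
    key <- paste(seg$spans$start, seg$spans$end)
    expect_true(all(paste(s$entities$start, s$entities$end) %in% key))
  }
})

test_that("records are entity-denser than publications", {
  corp <- generate_corpus(corpus_spec(n_publication = 200, n_record = 200,
                                      seed = 29))
  dens <- vapply(c("publication", "record"), function(st) {
    ss <- Filter(function(s) s$style == st, corp$samples)
    mean(vapply(ss, function(s) nrow(s$entities), numeric(1)))
  }, numeric(1))
  expect_gt(dens[["record"]], dens[["publication"]])
})

test_that("large-sample entity counts and lengths match the generating distributions", {
  spec <- corpus_spec(n_publication = 7500, n_record = 2500, seed = 1000)
  corp <- generate_corpus(spec)
  cls <- unlist(lapply(corp$samples, function(s) s$entities$class))
  lens <- unlist(lapply(corp$samples, function(s) s$entities$end - s$entities$start))
  # per-class counts within 3 sigma of the Poisson totals implied by the rates
  for (cl in entity_classes()) {
    lambda <- spec$n_publication * spec$rates$publication[[cl]] +
      spec$n_record * spec$rates$record[[cl]]
    expect_lt(abs(sum(cls == cl) - lambda), 3 * sqrt(lambda) + 1)
  }
  # most of the clinical-manifestation mass sits above 6 characters
  expect_gt(mean(lens[cls == "clinical_manifestation"] > 6), 0.5)
  # length histogram: chi-squared GOF at alpha = 0.01. A correct generator
  # still fails a single 1%-level test 1% of the time, so the decision rule
  # is replication-based: reject only if at least 2 of 3 independent
  # corpora reject (false-alarm ~3e-4 under the generating distribution).
  d <- spec$length_dists$clinical_manifestation
  pvals <- vapply(c(1000, 2000, 3000), function(sd) {
    cc <- if (sd == 1000) corp else
      generate_corpus(corpus_spec(n_publication = 7500, n_record = 2500,
                                  seed = sd))
    cl2 <- unlist(lapply(cc$samples, function(s) s$entities$class))
    ln2 <- unlist(lapply(cc$samples, function(s) s$entities$end - s$entities$start))
    obs <- table(factor(ln2[cl2 == "clinical_manifestation"],
                        levels = d$lengths))
    stats::chisq.test(as.integer(obs), p = d$prob)$p.value
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 2L)
})

test_that("a spec whose rates overflow the maximum length is rejected", {
  heavy <- list(
    publication = stats::setNames(c(30, 0, 0, 0, 0), entity_classes()),
    record = stats::setNames(rep(0.1, 5), entity_classes()))
  err <- expect_error(corpus_spec(rates = heavy, max_len = 100),
                      "expected publication sentence")
  expect_match(conditionMessage(err), "clinical_manifestation")
})

test_that("split sizes use floor with the remainder going to train", {
  expect_equal(split_sizes(94380, c(6, 2, 2)),
               c(train = 56628L, valid = 18876L, test = 18876L))
  expect_equal(split_sizes(10, c(6, 2, 2)),
               c(train = 6L, valid = 2L, test = 2L))
  for (n in 1:100) {
    p <- stats::runif(3, 0.05, 1)
    sz <- split_sizes(n, p)
    expect_equal(sum(sz), n)
    expect_true(all(sz >= 0))
    pn <- p / sum(p)
    expect_equal(sz[["valid"]], floor(pn[2] * n))
    expect_equal(sz[["test"]], floor(pn[3] * n))
  }
})

test_that("split_corpus partitions the corpus into disjoint seeded sets", {
  corp <- generate_corpus(corpus_spec(n_publication = 40, n_record = 10,
                                      seed = 4))
  sp <- split_corpus(corp, c(6, 2, 2), seed = 9)
  texts <- lapply(sp, function(cc) vapply(cc$samples, `[[`, character(1), "text"))
  expect_length(unlist(texts), 50L)
  expect_equal(length(sp$train$samples), 30L)
  expect_equal(length(sp$valid$samples), 10L)
  # same seed, same split
  sp2 <- split_corpus(corp, c(6, 2, 2), seed = 9)
  expect_identical(texts$train, vapply(sp2$train$samples, `[[`, character(1), "text"))
  expect_error(split_corpus(list(), c(6, 2, 2)), "empty")
})
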