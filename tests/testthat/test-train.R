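# Training behaviour at miniature scale: memorization, determinism,
# prediction contracts. Dimensions are kept tiny so each block runs in
# seconds.

tiny_corpus <- function(n_pub = 8, n_rec = 4, seed = 51) {
  generate_corpus(corpus_spec(n_publication = n_pub, n_record = n_rec,
                              seed = seed))
}

test_that("a single repeated sample is memorised", {
  corp <- tiny_corpus(3, 1)
  one <- corp$samples[2]
  reps <- rep(one, 8)
  m <- ner_train(reps, lexicon = corp$lexicon, fusion = "bilinear",
                 encoder = "bilstm", head = "crf", d_char = 12, d_word = 12,
                 hidden = 12, epochs = 30, lr = 0.01, seed = 1)
  expect_lt(utils::tail(m$history$loss, 1), 0.01 * m$history$loss[1])
  pred <- predict(m, one)
  expect_identical(pred[[1]], one[[1]]$tags)
})

test_that("training is deterministic under a fixed seed", {
  corp <- tiny_corpus()
  fit <- function() ner_train(corp, fusion = "bilinear", encoder = "lstm",
                              d_char = 8, d_word = 8, hidden = 8, epochs = 2,
                              seed = 99)
  m1 <- fit(); m2 <- fit()
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$params$W_emit, m2$params$W_emit)
  m3 <- ner_train(corp, fusion = "bilinear", encoder = "lstm", d_char = 8,
                  d_word = 8, hidden = 8, epochs = 2, seed = 100)
  expect_false(identical(m1$history$loss, m3$history$loss))
})

test_that("invalid corpora are rejected before training", {
  expect_error(ner_train(list()), "empty")
  bad <- list(list(chars = c("a", "b"), tags = c("O", "B-banana")))
  expect_error(ner_train(bad), "B-banana")
  short <- list(list(chars = c("a", "b"), tags = "O"))
  expect_error(ner_train(short), "2 characters")
})

test_that("prediction is batch-invariant and handles empty input", {
  corp <- tiny_corpus()
  m <- ner_train(corp, fusion = "bilinear", encoder = "bilstm", d_char = 8,
                 d_word = 8, hidden = 8, epochs = 1, seed = 7)
  texts <- vapply(corp$samples[1:5], `[[`, character(1), "text")
  batch <- predict(m, texts)
  onebyone <- lapply(texts, function(t) predict(m, t)[[1]])
  expect_identical(batch, onebyone)
  expect_identical(predict(m, character()), list())
  expect_identical(predict(m, "")[[1]], character())
  # entity output decodes the tags
  ents <- predict(m, texts[1], type = "entities")[[1]]
  expect_identical(ents, decode_tags(batch[[1]], split_chars(texts[1])))
})

test_that("softmax head and identity encoder also train and predict", {
  corp <- tiny_corpus(6, 2, seed = 53)
  m <- ner_train(corp, fusion = "none", encoder = "identity", head = "softmax",
                 d_char = 10, epochs = 8, lr = 0.05, seed = 2)
  expect_true(all(is.finite(m$history$loss)))
  expect_lt(utils::tail(m$history$loss, 1), m$history$loss[1])
  pred <- predict(m, corp)
  expect_identical(lengths(pred),
                   lengths(lapply(corp$samples, `[[`, "tags")))
})

test_that("the multihead variant trains end to end", {
  corp <- tiny_corpus(6, 2, seed = 54)
  m <- ner_train(corp, fusion = "multihead", encoder = "lstm", d_char = 8,
                 d_word = 8, d_model = 8, n_heads = 2, hidden = 8,
                 epochs = 3, seed = 3)
  expect_lt(utils::tail(m$history$loss, 1), m$history$loss[1])
})

test_that("checkpoints round-trip with a JSON sidecar", {
  corp <- tiny_corpus(4, 2, seed = 55)
  m <- ner_train(corp, fusion = "bilinear", encoder = "identity", d_char = 6,
                 d_word = 6, epochs = 1, seed = 4)
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  save_model(m, path)
  m2 <- load_model(path)
  texts <- vapply(corp$samples[1:3], `[[`, character(1), "text")
  expect_identical(predict(m, texts), predict(m2, texts))
  sidecar <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(sidecar$format, "charner_checkpoint")
  expect_equal(sidecar$fusion, "bilinear")
  expect_equal(sidecar$seed, 4L)
  # a foreign RDS is rejected
  saveRDS(list(1), path)
  expect_error(load_model(path), "not a charner model")
})

test_that("model methods print, summarise, plot and expose coefficients", {
  corp <- tiny_corpus(4, 2, seed = 56)
  m <- ner_train(corp, fusion = "none", encoder = "identity", d_char = 6,
                 epochs = 2, seed = 5, track_accuracy = TRUE)
  expect_output(print(m), "fusion: none")
  expect_output(print(summary(m)), "trainable parameters")
  expect_true(is.matrix(coef(m)$W_emit))
  pdf(NULL)
  on.exit(dev.off(), add = TRUE)
  expect_silent(plot(m))
  expect_false(anyNA(m$history$token_accuracy))
})

test_that("per-epoch training logs are valid line-delimited JSON", {
  corp <- tiny_corpus(4, 2, seed = 57)
  log <- tempfile(fileext = ".ndjson")
  on.exit(unlink(log), add = TRUE)
  m <- ner_train(corp, fusion = "none", encoder = "identity", d_char = 6,
                 epochs = 3, seed = 6, log_file = log)
  lines <- readLines(log)
  expect_length(lines, 3L)
  rec <- jsonlite::fromJSON(lines[2])
  expect_equal(rec$epoch, 2L)
  expect_equal(rec$split, "train")
  expect_equal(rec$loss, m$history$loss[2])
})

test_that("mini-batching changes the optimisation path but stays deterministic", {
  corp <- tiny_corpus(6, 2, seed = 58)
  m4a <- ner_train(corp, fusion = "none", encoder = "identity", d_char = 6,
                   epochs = 2, batch_size = 4, seed = 8)
  m4b <- ner_train(corp, fusion = "none", encoder = "identity", d_char = 6,
                   epochs = 2, batch_size = 4, seed = 8)
  expect_identical(m4a$params$W_emit, m4b$params$W_emit)
  expect_true(all(is.finite(m4a$history$loss)))
})

test_that("analytic end-to-end gradients match finite differences", {
  ns <- asNamespace("charner")
  corp <- tiny_corpus(3, 1, seed = 59)
  for (fus in c("bilinear", "multihead")) {
    m <- ner_train(corp, fusion = fus, encoder = "bilstm", head = "crf",
                   d_char = 5, d_word = 4, d_model = 4, n_heads = 2,
                   hidden = 4, epochs = 1, lr = 0, seed = 3)
    net <- ns$model_as_net(m)
    s <- corp$samples[[4]]
    prep <- ns$prep_sample(list(chars = s$chars, tags = s$tags), m$config,
                           m$vocab$chars, m$vocab$words, m$lexicon,
                           tag_schema())
    loss_fn <- function(P) {
      net2 <- net; net2$P <- P
      fwd <- ns$net_forward(net2, prep)
      ns$head_loss(net2, fwd$emissions, prep$tags_idx)$loss
    }
    fwd <- ns$net_forward(net, prep)
    hl <- ns$head_loss(net, fwd$emissions, prep$tags_idx)
    acc <- ns$zero_like(net$P)
    acc$trans <- acc$trans + hl$d_trans
    acc <- ns$net_backward(net, prep, fwd, hl$d_emissions, acc)
    eps <- 1e-5
    set.seed(17)
    for (nm in names(net$P)) {
      p <- net$P[[nm]]
      finite <- which(is.finite(p))
      for (ii in sample(finite, min(4, length(finite)))) {
        P2 <- net$P; P2[[nm]][ii] <- P2[[nm]][ii] + eps; up <- loss_fn(P2)
        P2[[nm]][ii] <- P2[[nm]][ii] - 2 * eps; dn <- loss_fn(P2)
        expect_equal(acc[[nm]][ii], (up - dn) / (2 * eps), tolerance = 1e-4)
      }
    }
  }
})
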