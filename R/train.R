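# Model fitting: embeddings -> optional word-character fusion -> encoder
# (identity / LSTM / BiLSTM) -> emission projection -> CRF or per-position
# softmax head. All gradients are analytic; the LSTM cell and the CRF
# forward-backward live in src/.

as_ner_samples <- function(x) {
  if (inherits(x, "ner_corpus")) x <- x$samples
  if (!is.list(x)) stop("`samples` must be a list of labeled samples", call. = FALSE)
  lapply(x, function(s) {
    chars <- if (!is.null(s$chars)) as.character(s$chars) else split_chars(s$text)
    tags <- as.character(s$tags)
    if (length(tags) != length(chars)) {
      stop("sample has ", length(chars), " characters but ", length(tags),
           " tags", call. = FALSE)
    }
    list(chars = chars, tags = tags,
         text = if (!is.null(s$text)) s$text else paste(chars, collapse = ""))
  })
}

# Minimal fusion-parameter view over the flat trained parameter list.
net_fusion_view <- function(net) {
  c(net$P, net$dims)
}

net_encode <- function(net, X) {
  kind <- net$config$encoder
  if (kind == "identity") return(list(H = X))
  f <- cpp_lstm_forward(X, net$P$W_lf, net$P$U_lf, net$P$b_lf)
  if (kind == "lstm") return(list(H = f$H, f = f))
  L <- nrow(X)
  Xr <- X[L:1L, , drop = FALSE]
  b <- cpp_lstm_forward(Xr, net$P$W_lb, net$P$U_lb, net$P$b_lb)
  list(H = cbind(f$H, b$H[L:1L, , drop = FALSE]), f = f, b = b, Xr = Xr)
}

net_forward <- function(net, prep, train = FALSE) {
  cfg <- net$config
  fus <- NULL
  if (cfg$fusion == "none") {
    X <- net$P$E_char[prep$char_ids, , drop = FALSE]
  } else if (cfg$fusion == "bilinear") {
    Ec <- net$P$E_char[prep$char_ids, , drop = FALSE]
    Ew <- net$P$E_word[prep$word_ids, , drop = FALSE]
    fus <- cpp_bilinear_forward(Ec, Ew, net$P$W_char, net$P$W_word,
                                net$P$W_attn, net$P$b_attn,
                                prep$seg$spans$start, prep$seg$spans$end,
                                cfg$collapse_words)
    fus$Ec <- Ec; fus$Ew <- Ew
    X <- fus$X
  } else {
    fp <- net_fusion_view(net)
    fus <- fuse_multihead_forward(prep$char_ids, prep$word_ids, prep$seg, fp)
    X <- fus$X
  }
  enc <- net_encode(net, X)
  H <- enc$H
  drop_mask <- NULL
  if (train && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    drop_mask <- matrix(stats::rbinom(length(H), 1L, keep) / keep,
                        nrow(H), ncol(H))
    H <- H * drop_mask
  }
  Em <- H %*% net$P$W_emit +
    matrix(net$P$b_emit, nrow(H), length(net$P$b_emit), byrow = TRUE)
  list(X = X, fus = fus, enc = enc, H = H, drop_mask = drop_mask,
       emissions = Em)
}

# Loss and emission gradient for one sentence under the configured head.
head_loss <- function(net, emissions, tags_idx) {
  if (net$config$head == "crf") {
    res <- crf_nll(emissions, tags_idx, net$crf_meta(net$P$trans))
    list(loss = res$nll, d_emissions = res$d_emissions,
         d_trans = res$d_transitions)
  } else {
    L <- nrow(emissions)
    m <- apply(emissions, 1L, max)
    Z <- exp(emissions - m)
    probs <- Z / rowSums(Z)
    gold <- cbind(seq_len(L), tags_idx)
    loss <- -sum(log(pmax(probs[gold], 1e-300)))
    dEm <- probs
    dEm[gold] <- dEm[gold] - 1
    list(loss = loss, d_emissions = dEm, d_trans = NULL)
  }
}

net_backward <- function(net, prep, fwd, dEm, acc) {
  cfg <- net$config
  acc$W_emit <- acc$W_emit + crossprod(fwd$H, dEm)
  acc$b_emit <- acc$b_emit + colSums(dEm)
  dH <- dEm %*% t(net$P$W_emit)
  if (!is.null(fwd$drop_mask)) dH <- dH * fwd$drop_mask
  kind <- cfg$encoder
  if (kind == "identity") {
    dX <- dH
  } else if (kind == "lstm") {
    g <- cpp_lstm_backward(fwd$X, net$P$W_lf, net$P$U_lf, net$P$b_lf,
                           fwd$enc$f$H, fwd$enc$f$C, fwd$enc$f$G, dH)
    acc$W_lf <- acc$W_lf + g$dW; acc$U_lf <- acc$U_lf + g$dU
    acc$b_lf <- acc$b_lf + as.vector(g$db)
    dX <- g$dX
  } else {
    L <- nrow(fwd$X); Hh <- ncol(fwd$enc$f$H)
    gf <- cpp_lstm_backward(fwd$X, net$P$W_lf, net$P$U_lf, net$P$b_lf,
                            fwd$enc$f$H, fwd$enc$f$C, fwd$enc$f$G,
                            dH[, seq_len(Hh), drop = FALSE])
    dHb <- dH[, Hh + seq_len(Hh), drop = FALSE][L:1L, , drop = FALSE]
    gb <- cpp_lstm_backward(fwd$enc$Xr, net$P$W_lb, net$P$U_lb, net$P$b_lb,
                            fwd$enc$b$H, fwd$enc$b$C, fwd$enc$b$G, dHb)
    acc$W_lf <- acc$W_lf + gf$dW; acc$U_lf <- acc$U_lf + gf$dU
    acc$b_lf <- acc$b_lf + as.vector(gf$db)
    acc$W_lb <- acc$W_lb + gb$dW; acc$U_lb <- acc$U_lb + gb$dU
    acc$b_lb <- acc$b_lb + as.vector(gb$db)
    dX <- gf$dX + gb$dX[L:1L, , drop = FALSE]
  }
  if (cfg$fusion == "none") {
    for (i in seq_along(prep$char_ids)) {
      r <- prep$char_ids[i]
      acc$E_char[r, ] <- acc$E_char[r, ] + dX[i, ]
    }
  } else if (cfg$fusion == "bilinear") {
    fb <- cpp_bilinear_backward(dX, fwd$fus$Ec, fwd$fus$Ew, fwd$fus$Rc,
                                fwd$fus$Rw, net$P$W_char, net$P$W_word,
                                net$P$W_attn, net$P$b_attn,
                                prep$seg$spans$start, prep$seg$spans$end)
    for (i in seq_along(prep$char_ids)) {
      r <- prep$char_ids[i]
      acc$E_char[r, ] <- acc$E_char[r, ] + fb$dEc_rows[i, ]
    }
    for (k in seq_along(prep$word_ids)) {
      r <- prep$word_ids[k]
      acc$E_word[r, ] <- acc$E_word[r, ] + fb$dEw_rows[k, ]
    }
    acc$W_char <- acc$W_char + fb$dW_char
    acc$W_word <- acc$W_word + fb$dW_word
    acc$W_attn <- acc$W_attn + fb$dW_attn
    acc$b_attn <- acc$b_attn + fb$db_attn
  } else {
    fp <- net_fusion_view(net)
    fb <- fuse_multihead_backward(dX, fwd$fus, prep$char_ids, prep$word_ids,
                                  prep$seg, fp)
    for (i in seq_along(prep$char_ids)) {
      r <- prep$char_ids[i]
      acc$E_char[r, ] <- acc$E_char[r, ] + fb$dEc_rows[i, ]
    }
    for (key in names(fb$dE_word)) {
      r <- as.integer(key)
      acc$E_word[r, ] <- acc$E_word[r, ] + fb$dE_word[[key]]
    }
    acc$P_char <- acc$P_char + fb$dP_char
    acc$P_word <- acc$P_word + fb$dP_word
  }
  acc
}

zero_like <- function(P) lapply(P, function(p) p * 0)

adam_step <- function(P, g, st, lr, scale = 1) {
  st$t <- st$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(g)) {
    gr <- g[[nm]] * scale
    if (nm == "trans") gr[!is.finite(P$trans)] <- 0
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * gr
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * gr * gr
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    P[[nm]] <- P[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(P = P, st = st)
}

prep_sample <- function(sample, cfg, char_vocab, word_vocab, lex, schema) {
  out <- list(char_ids = vocab_ids(char_vocab, sample$chars),
              L = length(sample$chars))
  if (cfg$fusion != "none") {
    seg <- segment_text(sample$chars, lex)
    out$seg <- seg
    out$word_ids <- vocab_ids(word_vocab, seg$words)
  }
  if (!is.null(sample$tags)) {
    out$tags_idx <- unname(schema$index[sample$tags])
  }
  out
}

#' Train a character-level NER tagger
#'
#' Fits the full tagging pipeline on labeled character sequences: character
#' (and, with fusion enabled, word) embeddings, the word-character
#' integrated attention module, an encoder, an emission projection and a
#' linear-chain CRF (or per-position softmax) head. Training minimises the
#' exact CRF negative log-likelihood (or cross-entropy) with Adam; all
#' gradients are analytic.
#'
#' One master `seed` drives parameter initialisation, epoch shuffling and
#' dropout, so identical inputs and seed give bit-identical models.
#' Mini-batches are realised as gradient accumulation over the shuffled
#' sentence stream; sentences keep their natural length throughout, so no
#' padding enters the likelihood or decoding.
#'
#' @param samples A corpus: a `ner_corpus` (from [generate_corpus()] or
#'   [read_conll()]) or a list of samples, each a list with `chars` (or
#'   `text`) and `tags`.
#' @param lexicon Optional [lexicon()] used to segment sentences for the
#'   fusion module. Defaults to the corpus lexicon when `samples` carries
#'   one, else an empty lexicon (all singleton words).
#' @param fusion `"none"` (raw character embeddings), `"bilinear"` or
#'   `"multihead"`; see [fuse_sequence()].
#' @param encoder `"bilstm"`, `"lstm"` or `"identity"`.
#' @param head `"crf"` (exact likelihood, Viterbi decoding) or
#'   `"softmax"` (independent per-position tagger).
#' @param d_char,d_word,d_model,n_heads Fusion dimensions, see
#'   [fusion_params()].
#' @param hidden LSTM hidden size per direction.
#' @param epochs,lr,batch_size,dropout Optimisation settings.
#' @param collapse_words Must be `FALSE`: the literal summed bilinear form
#'   is available through [fuse_sequence()] for representation analysis but
#'   is not a trainable configuration, since collapsing a word to one
#'   vector discards the per-character resolution the tagger needs.
#' @param seed Master seed (mandatory for reproducibility).
#' @param track_accuracy Record training-set token accuracy each epoch
#'   (costs one decoding pass per epoch).
#' @param log_file Optional path; one JSON line per epoch with loss and
#'   accuracy is appended.
#' @param verbose Print per-epoch progress.
#' @return Object of class `charner_model` with components `params`,
#'   `config`, `vocab`, `schema`, `lexicon` and `history` (data frame of
#'   per-epoch loss). Use [predict.charner_model()] to tag new text.
#' @seealso [evaluate_tags()], [run_ablation()], [save_model()]
#' @export
ner_train <- function(samples, lexicon = NULL,
                      fusion = c("none", "bilinear", "multihead"),
                      encoder = c("bilstm", "lstm", "identity"),
                      head = c("crf", "softmax"),
                      d_char = 24L, d_word = 24L, d_model = 24L, n_heads = 2L,
                      hidden = 24L, epochs = 5L, lr = 1e-3, batch_size = 1L,
                      dropout = 0, collapse_words = FALSE, seed = 1L,
                      track_accuracy = FALSE, log_file = NULL,
                      verbose = FALSE) {
  fusion <- match.arg(fusion)
  encoder <- match.arg(encoder)
  head <- match.arg(head)
  stopifnot(dropout >= 0, dropout < 1, hidden > 0, epochs >= 1)
  if (isTRUE(collapse_words)) {
    stop("collapse_words applies to fuse_sequence() only; ",
         "training requires the per-character fused form", call. = FALSE)
  }
  if (inherits(samples, "ner_corpus") && is.null(lexicon)) {
    lexicon <- samples$lexicon
  }
  if (is.null(lexicon)) lexicon <- lexicon()
  corp <- as_ner_samples(samples)
  if (length(corp) == 0L) stop("training corpus is empty", call. = FALSE)
  schema <- tag_schema()
  all_tags <- unique(unlist(lapply(corp, `[[`, "tags")))
  bad <- setdiff(all_tags, schema$tags)
  if (length(bad)) {
    stop("tag outside the schema: ", paste(bad, collapse = ", "), call. = FALSE)
  }

  cfg <- list(fusion = fusion, encoder = encoder, head = head,
              d_char = as.integer(d_char), d_word = as.integer(d_word),
              d_model = as.integer(d_model), n_heads = as.integer(n_heads),
              hidden = as.integer(hidden), epochs = as.integer(epochs),
              lr = lr, batch_size = as.integer(batch_size), dropout = dropout,
              collapse_words = collapse_words, seed = as.integer(seed),
              n_tags = length(schema$tags))

  char_vocab <- make_vocab(unique(unlist(lapply(corp, `[[`, "chars"))))
  preps <- vector("list", length(corp))
  word_vocab <- stats::setNames(integer(), character())
  if (fusion != "none") {
    segs <- lapply(corp, function(s) segment_text(s$chars, lexicon))
    word_vocab <- make_vocab(unique(unlist(lapply(segs, `[[`, "words"))))
  }
  for (i in seq_along(corp)) {
    preps[[i]] <- prep_sample(corp[[i]], cfg, char_vocab, word_vocab, lexicon,
                              schema)
  }

  d_in <- switch(fusion, none = cfg$d_char,
                 bilinear = cfg$d_char + cfg$d_word,
                 multihead = cfg$d_char + cfg$d_model)
  enc_dim <- switch(encoder, identity = d_in, lstm = cfg$hidden,
                    bilstm = 2L * cfg$hidden)

  crf_template <- crf_params(cfg$n_tags, init_scale = 0)
  crf_meta <- function(trans) {
    crf_template$transitions <- trans
    crf_template
  }

  history <- data.frame(epoch = integer(), loss = numeric(),
                        token_accuracy = numeric())

  net <- with_seed(seed, {
    if (cfg$d_model %% cfg$n_heads != 0L) {
      stop(sprintf("model dimension %d is not divisible by n_heads = %d",
                   cfg$d_model, cfg$n_heads), call. = FALSE)
    }
    P <- list(E_char = runif_mat(length(char_vocab) + 2L, cfg$d_char))
    if (fusion == "bilinear") {
      P$E_word <- runif_mat(length(word_vocab) + 2L, cfg$d_word)
      P$W_char <- runif_mat(cfg$d_char, cfg$d_char)
      P$W_word <- runif_mat(cfg$d_word, cfg$d_word)
      P$W_attn <- runif_mat(cfg$d_word, cfg$d_char)
      P$b_attn <- 0
    } else if (fusion == "multihead") {
      P$E_word <- runif_mat(length(word_vocab) + 2L, cfg$d_word)
      P$P_char <- runif_mat(cfg$d_char, cfg$d_model)
      P$P_word <- runif_mat(cfg$d_word, cfg$d_model)
    }
    if (encoder %in% c("lstm", "bilstm")) {
      P$W_lf <- runif_mat(d_in, 4L * cfg$hidden)
      P$U_lf <- runif_mat(cfg$hidden, 4L * cfg$hidden)
      P$b_lf <- numeric(4L * cfg$hidden)
    }
    if (encoder == "bilstm") {
      P$W_lb <- runif_mat(d_in, 4L * cfg$hidden)
      P$U_lb <- runif_mat(cfg$hidden, 4L * cfg$hidden)
      P$b_lb <- numeric(4L * cfg$hidden)
    }
    P$W_emit <- runif_mat(enc_dim, cfg$n_tags)
    P$b_emit <- numeric(cfg$n_tags)
    if (head == "crf") {
      P$trans <- crf_params(cfg$n_tags, init_scale = 0.1,
                            seed = seed)$transitions
    }

    net <- list(P = P, config = cfg,
                dims = list(d_char = cfg$d_char, d_word = cfg$d_word,
                            d_model = cfg$d_model, n_heads = cfg$n_heads),
                crf_meta = crf_meta)
    st <- list(t = 0L, m = zero_like(P), v = zero_like(P))
    n_tokens_total <- sum(vapply(preps, `[[`, integer(1), "L"))

    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(length(corp))
      total_loss <- 0
      i <- 1L
      while (i <= length(ord)) {
        batch <- ord[i:min(i + cfg$batch_size - 1L, length(ord))]
        acc <- zero_like(P)
        for (s in batch) {
          prep <- preps[[s]]
          fwd <- net_forward(net, prep, train = TRUE)
          hl <- head_loss(net, fwd$emissions, prep$tags_idx)
          total_loss <- total_loss + hl$loss
          if (!is.null(hl$d_trans)) acc$trans <- acc$trans + hl$d_trans
          acc <- net_backward(net, prep, fwd, hl$d_emissions, acc)
        }
        upd <- adam_step(net$P, acc, st, cfg$lr, scale = 1 / length(batch))
        net$P <- upd$P; st <- upd$st
        if (head == "crf") {
          net$P$trans[, crf_template$start] <- -Inf
          net$P$trans[crf_template$stop, ] <- -Inf
        }
        i <- i + cfg$batch_size
      }
      mean_loss <- total_loss / n_tokens_total
      tok_acc <- NA_real_
      if (track_accuracy) {
        correct <- 0L
        for (s in seq_along(corp)) {
          pred <- decode_net(net, preps[[s]])
          correct <- correct + sum(pred == preps[[s]]$tags_idx)
        }
        tok_acc <- correct / n_tokens_total
      }
      history[nrow(history) + 1L, ] <- list(epoch, mean_loss, tok_acc)
      if (!is.null(log_file)) {
        line <- jsonlite::toJSON(list(epoch = epoch, split = "train",
                                      loss = mean_loss,
                                      token_accuracy = tok_acc),
                                 auto_unbox = TRUE, na = "null", digits = NA)
        cat(line, "\n", sep = "", file = log_file, append = TRUE)
      }
      if (verbose) {
        message(sprintf("epoch %d/%d  loss %.5f%s", epoch, cfg$epochs,
                        mean_loss,
                        if (is.na(tok_acc)) "" else
                          sprintf("  acc %.4f", tok_acc)))
      }
    }
    net
  })

  structure(
    list(params = net$P, config = cfg, dims = net$dims,
         vocab = list(chars = char_vocab, words = word_vocab),
         schema = schema, lexicon = lexicon, history = history,
         call = match.call()),
    class = "charner_model"
  )
}

# Decode one prepared sentence to 1-based tag indices.
decode_net <- function(net, prep) {
  fwd <- net_forward(net, prep, train = FALSE)
  if (net$config$head == "crf") {
    crf_viterbi(fwd$emissions, net$crf_meta(net$P$trans))$tags
  } else {
    apply(fwd$emissions, 1L, which.max)
  }
}

model_as_net <- function(object) {
  crf_template <- crf_params(object$config$n_tags, init_scale = 0)
  list(P = object$params, config = object$config, dims = object$dims,
       crf_meta = function(trans) {
         crf_template$transitions <- trans
         crf_template
       })
}

#' Tag new text with a trained model
#'
#' @param object A `charner_model` from [ner_train()].
#' @param newdata Character vector of sentences, a list of character
#'   vectors, or a `ner_corpus`. Unseen characters/words map to UNK.
#' @param type `"tags"` for per-character tag labels, `"entities"` for
#'   decoded entity spans (via [decode_tags()], with begin repair).
#' @param ... Unused.
#' @return A list, one element per sentence: a character vector of tags, or
#'   a data frame of entities.
#' @export
predict.charner_model <- function(object, newdata, type = c("tags", "entities"),
                                  ...) {
  type <- match.arg(type)
  if (inherits(newdata, "ner_corpus")) newdata <- newdata$samples
  if (is.character(newdata)) newdata <- lapply(newdata, function(t) list(text = t))
  net <- model_as_net(object)
  out <- vector("list", length(newdata))
  for (i in seq_along(newdata)) {
    s <- newdata[[i]]
    if (is.character(s) && is.null(names(s))) s <- list(chars = s)
    chars <- if (!is.null(s$chars)) as.character(s$chars) else split_chars(s$text)
    if (length(chars) == 0L) {
      out[[i]] <- if (type == "tags") character() else
        decode_tags(character())
      next
    }
    prep <- prep_sample(list(chars = chars), object$config,
                        object$vocab$chars, object$vocab$words,
                        object$lexicon, object$schema)
    idx <- decode_net(net, prep)
    tags <- object$schema$tags[idx]
    out[[i]] <- if (type == "tags") tags else decode_tags(tags, chars)
  }
  out
}

#' @export
print.charner_model <- function(x, ...) {
  cfg <- x$config
  cat("Character-level NER model\n")
  cat(sprintf("  fusion: %s | encoder: %s | head: %s\n",
              cfg$fusion, cfg$encoder, cfg$head))
  cat(sprintf("  vocab: %d characters, %d words | %d tags\n",
              length(x$vocab$chars), length(x$vocab$words), cfg$n_tags))
  cat(sprintf("  trained %d epochs, final loss %.5f (per token)\n",
              nrow(x$history), utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' @export
summary.charner_model <- function(object, ...) {
  n_par <- sum(vapply(object$params, length, integer(1)))
  structure(list(config = object$config, n_parameters = n_par,
                 history = object$history,
                 vocab_sizes = vapply(object$vocab, length, integer(1))),
            class = "summary.charner_model")
}

#' @export
print.summary.charner_model <- function(x, ...) {
  cat("Model configuration:\n")
  cfg <- x$config
  cat(sprintf("  fusion=%s encoder=%s head=%s d_char=%d hidden=%d seed=%d\n",
              cfg$fusion, cfg$encoder, cfg$head, cfg$d_char, cfg$hidden,
              cfg$seed))
  cat(sprintf("  %d trainable parameters\n", x$n_parameters))
  cat("Training history (last rows):\n")
  print(utils::tail(x$history, 5L), row.names = FALSE)
  invisible(x)
}

#' @export
coef.charner_model <- function(object, ...) {
  object$params
}

#' @export
plot.charner_model <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$loss, type = "b",
                 xlab = "epoch", ylab = "mean per-token loss",
                 main = "Training loss", ...)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a binary RDS file; a JSON sidecar (`<path>.json`)
#' records the dimensions, vocabulary sizes, seed and variant so runs can
#' be audited without loading the binary.
#'
#' @param model A `charner_model`.
#' @param path Checkpoint path (e.g. `model.rds`).
#' @return `path` invisibly for `save_model`; the model for `load_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "charner_model"))
  saveRDS(model, path)
  sidecar <- list(
    format = "charner_checkpoint", version = 1L,
    fusion = model$config$fusion, encoder = model$config$encoder,
    head = model$config$head, seed = model$config$seed,
    dims = model$dims,
    n_chars = length(model$vocab$chars), n_words = length(model$vocab$words),
    n_tags = model$config$n_tags
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "charner_model")) {
    stop("not a charner model checkpoint: ", path, call. = FALSE)
  }
  model
}
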