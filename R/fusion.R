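#' @useDynLib charner, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Numerically stable softmax over a vector.
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

runif_mat <- function(nr, nc, scale = 0.1) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

# Reserved embedding-table rows. Unseen characters/words map to UNK rather
# than erroring; PAD exists for interface completeness.
UNK_ID <- 1L
PAD_ID <- 2L

# Build an id map (named integer vector) over a vocabulary with UNK/PAD
# reserved at indices 1 and 2.
make_vocab <- function(items) {
  items <- setdiff(unique(items), c("<unk>", "<pad>"))
  stats::setNames(seq_along(items) + 2L, items)
}

vocab_ids <- function(vocab, keys) {
  ids <- unname(vocab[keys])
  ids[is.na(ids)] <- UNK_ID
  ids
}

#' Initialise word-character fusion parameters
#'
#' Embedding tables and attention parameters for the word-character
#' integrated attention module. All weights are drawn uniform(-0.1, 0.1)
#' under `seed`; rows 1 and 2 of each embedding table are reserved for the
#' UNK and PAD ids.
#'
#' Two variants share these parameters. The bilinear variant transforms
#' embeddings with square matrices `W_char` (`d_char` x `d_char`) and
#' `W_word` (`d_word` x `d_word`) and scores each character of a word with
#' the bilinear form `word %*% W_attn %*% char + b_attn`. The multi-head
#' variant projects characters and words to a shared model dimension
#' (`P_char`, `P_word`) and applies scaled dot-product attention with the
#' word representation as query and the word's characters as keys/values.
#'
#' @param char_vocab Character vector of known characters.
#' @param word_vocab Character vector of known words.
#' @param d_char,d_word Embedding dimensions.
#' @param d_model Shared model dimension for the multi-head variant; must be
#'   divisible by `n_heads`.
#' @param n_heads Number of attention heads (multi-head variant).
#' @param seed Integer seed for initialisation.
#' @return Object of class `fusion_params`.
#' @export
fusion_params <- function(char_vocab, word_vocab = character(),
                          d_char = 24L, d_word = 24L,
                          d_model = 24L, n_heads = 2L, seed = 1L) {
  if (d_model %% n_heads != 0L) {
    stop(sprintf("model dimension %d is not divisible by n_heads = %d",
                 d_model, n_heads), call. = FALSE)
  }
  cv <- make_vocab(char_vocab)
  wv <- make_vocab(word_vocab)
  with_seed(seed, {
    p <- list(
      E_char = runif_mat(length(cv) + 2L, d_char),
      E_word = runif_mat(length(wv) + 2L, d_word),
      W_char = runif_mat(d_char, d_char),
      W_word = runif_mat(d_word, d_word),
      W_attn = runif_mat(d_word, d_char),
      b_attn = 0,
      P_char = runif_mat(d_char, d_model),
      P_word = runif_mat(d_word, d_model)
    )
    structure(
      c(p, list(char_vocab = cv, word_vocab = wv,
                d_char = as.integer(d_char), d_word = as.integer(d_word),
                d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                seed = as.integer(seed))),
      class = "fusion_params"
    )
  })
}

#' Bilinear attention weights over a word's characters
#'
#' Scores each character `i` of a word as
#' `s_i = word_vec %*% W_attn %*% char_vecs[i, ] + b_attn`
#' and returns `softmax(s)`: positive weights summing to 1, each weight the
#' importance of the i-th character within the word/phrase. Scores are used
#' unscaled.
#'
#' @param word_vec Numeric vector of length `d_word`.
#' @param char_vecs Numeric matrix, one row per character, `d_char` columns.
#' @param W_attn `d_word` x `d_char` matrix.
#' @param b_attn Scalar bias.
#' @return Numeric vector of length `nrow(char_vecs)` summing to 1.
#' @export
attention_weights <- function(word_vec, char_vecs, W_attn, b_attn = 0) {
  char_vecs <- rbind(char_vecs)
  if (length(word_vec) != nrow(W_attn) || ncol(char_vecs) != ncol(W_attn)) {
    stop(sprintf(
      "dimension mismatch: word_vec length %d, char_vecs %dx%d, W_attn %dx%d",
      length(word_vec), nrow(char_vecs), ncol(char_vecs),
      nrow(W_attn), ncol(W_attn)), call. = FALSE)
  }
  scores <- as.vector(char_vecs %*% crossprod(W_attn, word_vec)) + b_attn
  softmax(scores)
}

# Forward pass of the bilinear fusion for one sentence, keeping the
# intermediates needed by the backward pass.
fuse_bilinear_forward <- function(char_ids, word_ids_per_span, seg, params,
                                  collapse_words = FALSE) {
  Ec <- params$E_char[char_ids, , drop = FALSE]
  Rc <- Ec %*% params$W_char                       # L x d_char
  spans <- seg$spans
  L <- length(char_ids)
  d_out <- params$d_char + params$d_word
  X <- matrix(0, L, d_out)
  attn <- numeric(L)
  Rw <- matrix(0, nrow(spans), params$d_word)
  weights <- vector("list", nrow(spans))
  for (k in seq_len(nrow(spans))) {
    idx <- (spans$start[k] + 1L):spans$end[k]
    rw <- as.vector(params$E_word[word_ids_per_span[k], ] %*% params$W_word)
    Rw[k, ] <- rw
    e <- attention_weights(rw, Rc[idx, , drop = FALSE],
                           params$W_attn, params$b_attn)
    weights[[k]] <- e
    attn[idx] <- e
    fused <- cbind(Rc[idx, , drop = FALSE],
                   matrix(rw, length(idx), params$d_word, byrow = TRUE)) * e
    if (collapse_words) {
      # literal summed form: every character of the word carries the
      # word-level weighted sum
      X[idx, ] <- matrix(colSums(rbind(fused)), length(idx), d_out, byrow = TRUE)
    } else {
      X[idx, ] <- fused
    }
  }
  list(X = X, attention = attn, Ec = Ec, Rc = Rc, Rw = Rw, weights = weights)
}

# Backward pass matching fuse_bilinear_forward (collapse_words = FALSE).
# Returns gradients for the embedding rows used and the fusion matrices.
fuse_bilinear_backward <- function(dX, fwd, char_ids, word_ids_per_span, seg,
                                   params) {
  dc <- params$d_char; dw <- params$d_word
  dRc <- matrix(0, nrow(fwd$Rc), dc)
  dW_attn <- matrix(0, dw, dc)
  db_attn <- 0
  dW_word <- matrix(0, dw, dw)
  dE_word <- list()
  spans <- seg$spans
  for (k in seq_len(nrow(spans))) {
    idx <- (spans$start[k] + 1L):spans$end[k]
    e <- fwd$weights[[k]]
    rw <- fwd$Rw[k, ]
    Rck <- fwd$Rc[idx, , drop = FALSE]
    dXc <- dX[idx, seq_len(dc), drop = FALSE]
    dXw <- dX[idx, dc + seq_len(dw), drop = FALSE]
    # X_i = e_i * [Rc_i, rw]
    de <- rowSums(dXc * Rck) + as.vector(dXw %*% rw)
    dRc[idx, ] <- dRc[idx, ] + dXc * e
    drw <- colSums(dXw * e)
    # softmax backward
    ds <- e * (de - sum(e * de))
    # s_i = rw' W_attn Rc_i + b
    dRc[idx, ] <- dRc[idx, ] + outer(ds, as.vector(crossprod(params$W_attn, rw)))
    drw <- drw + as.vector(params$W_attn %*% crossprod(Rck, ds))
    dW_attn <- dW_attn + outer(rw, as.vector(crossprod(Rck, ds)))
    db_attn <- db_attn + sum(ds)
    # rw = E_word[w] %*% W_word
    ew <- params$E_word[word_ids_per_span[k], ]
    dW_word <- dW_word + outer(ew, drw)
    dew <- as.vector(params$W_word %*% drw)
    key <- as.character(word_ids_per_span[k])
    dE_word[[key]] <- (dE_word[[key]] %||% 0) + dew
  }
  # Rc = E_char %*% W_char
  dW_char <- crossprod(fwd$Ec, dRc)
  dEc_rows <- dRc %*% t(params$W_char)
  list(dEc_rows = dEc_rows, dW_char = dW_char, dW_word = dW_word,
       dW_attn = dW_attn, db_attn = db_attn, dE_word = dE_word)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Multi-head fusion forward for one sentence. Attention is masked to each
# word's span: per word, query = projected word embedding, keys/values =
# projected character embeddings of that word. Output per character is
# [raw char embedding, word-context vector].
fuse_multihead_forward <- function(char_ids, word_ids_per_span, seg, params) {
  Ec <- params$E_char[char_ids, , drop = FALSE]
  K <- Ec %*% params$P_char                        # L x d_model
  nh <- params$n_heads
  dk <- params$d_model / nh
  spans <- seg$spans
  L <- length(char_ids)
  X <- matrix(0, L, params$d_char + params$d_model)
  X[, seq_len(params$d_char)] <- Ec
  attn <- numeric(L)
  cache <- vector("list", nrow(spans))
  for (k in seq_len(nrow(spans))) {
    idx <- (spans$start[k] + 1L):spans$end[k]
    ew <- params$E_word[word_ids_per_span[k], ]
    q <- as.vector(ew %*% params$P_word)           # d_model
    Kk <- K[idx, , drop = FALSE]
    ctx <- numeric(params$d_model)
    a_heads <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- (h - 1L) * dk + seq_len(dk)
      s <- as.vector(Kk[, cols, drop = FALSE] %*% q[cols]) / sqrt(dk)
      a <- softmax(s)
      a_heads[[h]] <- a
      ctx[cols] <- as.vector(crossprod(Kk[, cols, drop = FALSE], a))
    }
    X[idx, params$d_char + seq_len(params$d_model)] <-
      matrix(ctx, length(idx), params$d_model, byrow = TRUE)
    attn[idx] <- Reduce(`+`, a_heads) / nh
    cache[[k]] <- list(q = q, a = a_heads, ew = ew)
  }
  list(X = X, attention = attn, Ec = Ec, K = K, cache = cache)
}

fuse_multihead_backward <- function(dX, fwd, char_ids, word_ids_per_span, seg,
                                    params) {
  dc <- params$d_char; dm <- params$d_model
  nh <- params$n_heads; dk <- dm / nh
  dEc_rows <- dX[, seq_len(dc), drop = FALSE]
  dK <- matrix(0, nrow(fwd$K), dm)
  dP_word <- matrix(0, dw <- params$d_word, dm)
  dE_word <- list()
  spans <- seg$spans
  for (k in seq_len(nrow(spans))) {
    idx <- (spans$start[k] + 1L):spans$end[k]
    cch <- fwd$cache[[k]]
    Kk <- fwd$K[idx, , drop = FALSE]
    dctx <- colSums(dX[idx, dc + seq_len(dm), drop = FALSE])
    dq <- numeric(dm)
    for (h in seq_len(nh)) {
      cols <- (h - 1L) * dk + seq_len(dk)
      a <- cch$a[[h]]
      Kh <- Kk[, cols, drop = FALSE]
      # ctx_h = t(Kh) %*% a
      da <- as.vector(Kh %*% dctx[cols])
      dK[idx, cols] <- dK[idx, cols] + outer(a, dctx[cols])
      ds <- a * (da - sum(a * da))
      dK[idx, cols] <- dK[idx, cols] + outer(ds, cch$q[cols]) / sqrt(dk)
      dq[cols] <- dq[cols] + as.vector(crossprod(Kh, ds)) / sqrt(dk)
    }
    dP_word <- dP_word + outer(cch$ew, dq)
    dew <- as.vector(params$P_word %*% dq)
    key <- as.character(word_ids_per_span[k])
    dE_word[[key]] <- (dE_word[[key]] %||% 0) + dew
  }
  dP_char <- crossprod(fwd$Ec, dK)
  dEc_rows <- dEc_rows + dK %*% t(params$P_char)
  list(dEc_rows = dEc_rows, dP_char = dP_char, dP_word = dP_word,
       dE_word = dE_word)
}

#' Fuse word semantics into a character-level representation
#'
#' Produces one vector per character. Both variants share this signature so
#' any downstream labeler can consume either (plug-and-play), or raw
#' character embeddings when no fusion is wanted.
#'
#' * `"bilinear"`: each character vector is gated by its attention weight
#'   within its word and concatenated with the word vector:
#'   `fused_i = e_i * c(R_char_i, R_word)`. With `collapse_words = TRUE`
#'   the weighted vectors are instead summed over the word span and the sum
#'   broadcast to every character of the word.
#' * `"multihead"`: scaled dot-product multi-head attention restricted to
#'   each word's span, word representation as query, that word's character
#'   representations as keys and values; the per-word context vector is
#'   concatenated with each raw character embedding.
#'
#' Unseen characters or words map to the reserved UNK embedding.
#'
#' @param chars Character vector or single string.
#' @param seg Segmentation from [segment_text()] covering `chars`.
#' @param params [fusion_params()].
#' @param variant `"bilinear"` or `"multihead"`.
#' @param collapse_words Bilinear variant only: emit the literal summed
#'   word vector at every character of the word.
#' @return List with `vectors` (L x d matrix) and `attention` (length-L
#'   weights; within each word span they are positive and sum to 1; for the
#'   multi-head variant, averaged over heads).
#' @export
fuse_sequence <- function(chars, seg, params,
                          variant = c("bilinear", "multihead"),
                          collapse_words = FALSE) {
  variant <- match.arg(variant)
  chars <- as_chars(chars)
  stopifnot(inherits(seg, "ner_segmentation"),
            inherits(params, "fusion_params"))
  if (sum(seg$spans$end - seg$spans$start) != length(chars)) {
    stop("segmentation does not cover the character sequence", call. = FALSE)
  }
  char_ids <- vocab_ids(params$char_vocab, chars)
  word_ids <- vocab_ids(params$word_vocab, seg$words)
  fwd <- if (variant == "bilinear") {
    fuse_bilinear_forward(char_ids, word_ids, seg, params, collapse_words)
  } else {
    fuse_multihead_forward(char_ids, word_ids, seg, params)
  }
  list(vectors = fwd$X, attention = fwd$attention)
}
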