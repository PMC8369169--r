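make_params <- function(seed = 3, d_char = 4, d_word = 4, d_model = 4,
                        n_heads = 2) {
  fusion_params(letters[1:6], c("ab", "cde", "fa"), d_char = d_char,
                d_word = d_word, d_model = d_model, n_heads = n_heads,
                seed = seed)
}

test_that("attention weights: singleton, constant-score and oracle cases", {
  expect_equal(attention_weights(c(1, 2), rbind(c(3, 4)), matrix(0, 2, 2), 5),
               1.0)
  # zero bilinear map -> constant scores -> uniform
  expect_equal(
    attention_weights(c(1, -1, 2), matrix(rnorm(12), 4, 3), matrix(0, 3, 3), 0.7),
    rep(0.25, 4))
  set.seed(21)
  for (rep in 1:20) {
    dw <- sample(2:5, 1); dc <- sample(2:5, 1); l <- sample(1:6, 1)
    wv <- rnorm(dw); cm <- matrix(rnorm(l * dc), l, dc)
    W <- matrix(rnorm(dw * dc), dw, dc); b <- rnorm(1)
    expect_equal(attention_weights(wv, cm, W, b), oracle_attention(wv, cm, W, b),
                 tolerance = 1e-9)
  }
})

test_that("attention weights reject mismatched shapes with the shapes named", {
  expect_error(attention_weights(c(1, 2, 3), rbind(c(1, 2)), matrix(0, 2, 2)),
               "dimension mismatch")
})

test_that("attention weights are a distribution within every word span", {
  set.seed(22)
  params <- make_params()
  for (rep in 1:1000) {
    l <- sample(1:8, 1)
    wv <- rnorm(4); cm <- matrix(rnorm(l * 4), l, 4)
    e <- attention_weights(wv, cm, params$W_attn, params$b_attn)
    expect_true(all(e > 0))
    expect_equal(sum(e), 1, tolerance = 1e-12)
  }
})

test_that("bilinear fusion matches a step-by-step scalar recomputation", {
  params <- make_params()
  text <- "abcde"
  seg <- segment_text(text, lexicon(c("ab", "cde")))
  out <- fuse_sequence(text, seg, params, "bilinear")
  expect_equal(dim(out$vectors), c(5L, 8L))
  # independent recomputation from the embedding tables
  cid <- unname(params$char_vocab[strsplit(text, "")[[1]]])
  wid <- unname(params$word_vocab[c("ab", "cde")])
  Rc <- params$E_char[cid, ] %*% params$W_char
  for (k in 1:2) {
    idx <- if (k == 1) 1:2 else 3:5
    rw <- as.vector(params$E_word[wid[k], ] %*% params$W_word)
    e <- oracle_attention(rw, Rc[idx, , drop = FALSE], params$W_attn,
                          params$b_attn)
    for (ii in seq_along(idx)) {
      expected <- e[ii] * c(Rc[idx[ii], ], rw)
      expect_equal(out$vectors[idx[ii], ], expected, tolerance = 1e-9)
      expect_equal(out$attention[idx[ii]], e[ii], tolerance = 1e-9)
    }
  }
})

test_that("single-character words get weight 1 and the plain concatenation", {
  params <- make_params()
  seg <- segment_text("b", lexicon())
  out <- fuse_sequence("b", seg, params, "bilinear")
  expect_equal(out$attention, 1.0)
  cid <- unname(params$char_vocab["b"])
  rc <- as.vector(params$E_char[cid, ] %*% params$W_char)
  # single-char word "b" is not in the word vocab -> UNK word embedding
  rw <- as.vector(params$E_word[1L, ] %*% params$W_word)
  expect_equal(as.vector(out$vectors), c(rc, rw), tolerance = 1e-12)
})

test_that("collapse_words sums the weighted vectors over the span", {
  params <- make_params()
  seg <- segment_text("ab", lexicon("ab"))
  per_char <- fuse_sequence("ab", seg, params, "bilinear")
  summed <- fuse_sequence("ab", seg, params, "bilinear", collapse_words = TRUE)
  expect_equal(summed$vectors[1, ], colSums(per_char$vectors))
  expect_equal(summed$vectors[1, ], summed$vectors[2, ])
})

test_that("multihead fusion matches the dense head-by-head oracle", {
  params <- make_params(n_heads = 2)
  text <- "cdeab"
  seg <- segment_text(text, lexicon(c("cde", "ab")))
  out <- fuse_sequence(text, seg, params, "multihead")
  cid <- unname(params$char_vocab[strsplit(text, "")[[1]]])
  wid <- unname(params$word_vocab[c("cde", "ab")])
  K <- params$E_char[cid, ] %*% params$P_char
  for (k in 1:2) {
    idx <- if (k == 1) 1:3 else 4:5
    q <- as.vector(params$E_word[wid[k], ] %*% params$P_word)
    ctx <- oracle_multihead(q, K[idx, , drop = FALSE], 2)
    for (ii in idx) {
      expect_equal(out$vectors[ii, ], c(params$E_char[cid[ii], ], ctx),
                   tolerance = 1e-6)
    }
  }
})

test_that("multihead degenerate cases: singleton word and equal keys", {
  params <- make_params(n_heads = 1)
  seg1 <- segment_text("a", lexicon())
  out1 <- fuse_sequence("a", seg1, params, "multihead")
  cid <- unname(params$char_vocab["a"])
  expect_equal(out1$vectors[1, 5:8],
               as.vector(params$E_char[cid, ] %*% params$P_char))
  # all-equal keys -> uniform attention -> mean of values
  seg2 <- segment_text("aaa", lexicon("aaa"))
  out2 <- fuse_sequence("aaa", seg2, params, "multihead")
  expect_equal(out2$attention, rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("fusion rejects a model dimension not divisible by n_heads", {
  expect_error(make_params(d_model = 5, n_heads = 2), "divisible")
})

test_that("bilinear fusion is local to each word and deterministic", {
  params <- make_params()
  lex <- lexicon(c("ab", "cde"))
  a <- fuse_sequence("abcde", segment_text("abcde", lex), params, "bilinear")
  # change a character outside the first word
  b <- fuse_sequence("abcdf", segment_text("abcdf", lex), params, "bilinear")
  expect_equal(a$vectors[1:2, ], b$vectors[1:2, ])
  # bit-identical re-run
  a2 <- fuse_sequence("abcde", segment_text("abcde", lex), params, "bilinear")
  expect_identical(a$vectors, a2$vectors)
  # same-seed params are bit-identical too
  expect_identical(make_params(seed = 3)$E_char, params$E_char)
})

test_that("unseen characters and words map to the UNK embedding", {
  params <- make_params()
  seg <- segment_text("zz", lexicon("zz"))
  out <- fuse_sequence("zz", seg, params, "bilinear")
  Rc_unk <- as.vector(params$E_char[1L, ] %*% params$W_char)
  rw_unk <- as.vector(params$E_word[1L, ] %*% params$W_word)
  e <- attention_weights(rw_unk, rbind(Rc_unk, Rc_unk), params$W_attn,
                         params$b_attn)
  expect_equal(out$vectors[1, ], e[1] * c(Rc_unk, rw_unk), tolerance = 1e-12)
})
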