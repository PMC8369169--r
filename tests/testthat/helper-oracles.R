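# Independent brute-force oracles. These re-derive expected values by
# enumeration or direct arithmetic and deliberately share no code with the
# implementation they check.

# Run-finding BIO decoder: walk the tags, treating any entity tag that does
# not continue a same-class run as the start of a new entity.
oracle_decode <- function(tags) {
  cls_of <- function(tg) {
    map <- c(symptom = "clinical_manifestation", syndrome = "syndrome",
             disease = "disease", treatment_law = "treatment_law",
             herb = "herb")
    unname(map[sub("^[BI]-", "", tg)])
  }
  cls <- character(); st <- integer(); en <- integer()
  i <- 1L
  n <- length(tags)
  while (i <= n) {
    if (tags[i] == "O") { i <- i + 1L; next }
    cl <- cls_of(tags[i])
    j <- i + 1L
    while (j <= n && startsWith(tags[j], "I-") && identical(cls_of(tags[j]), cl)) {
      j <- j + 1L
    }
    cls <- c(cls, cl); st <- c(st, i - 1L); en <- c(en, j - 1L)
    i <- j
  }
  data.frame(class = cls, start = st, end = en, stringsAsFactors = FALSE)
}

# Longest-match-at-each-position segmentation oracle (substring scan, no
# hash table).
oracle_segment <- function(text, words) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  starts <- integer(); ends <- integer()
  i <- 1L
  while (i <= n) {
    best <- 1L
    for (w in words) {
      l <- nchar(w)
      if (l >= 2 && l > best && i + l - 1L <= n &&
          paste(chars[i:(i + l - 1L)], collapse = "") == w) {
        best <- l
      }
    }
    # among equal-length lexicon matches the surface string is unique, so
    # the longest match is well defined
    starts <- c(starts, i - 1L); ends <- c(ends, i - 1L + best)
    i <- i + best
  }
  data.frame(start = starts, end = ends)
}

# Scalar-arithmetic bilinear attention oracle.
oracle_attention <- function(word_vec, char_mat, W, b) {
  scores <- numeric(nrow(char_mat))
  for (i in seq_len(nrow(char_mat))) {
    s <- 0
    for (a in seq_along(word_vec)) for (cc in seq_len(ncol(char_mat))) {
      s <- s + word_vec[a] * W[a, cc] * char_mat[i, cc]
    }
    scores[i] <- s + b
  }
  e <- exp(scores - max(scores))
  e / sum(e)
}

# Dense head-by-head multi-head attention oracle for one word span.
oracle_multihead <- function(q, K, n_heads) {
  dm <- length(q)
  dk <- dm / n_heads
  ctx <- numeric(dm)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1) * dk + seq_len(dk)
    s <- as.vector(K[, cols, drop = FALSE] %*% q[cols]) / sqrt(dk)
    a <- exp(s - max(s)); a <- a / sum(a)
    ctx[cols] <- colSums(K[, cols, drop = FALSE] * a)
  }
  ctx
}

# Enumerate all T^L paths of a linear-chain CRF.
oracle_all_path_scores <- function(em, trans, start, stop_) {
  L <- nrow(em); T_ <- ncol(em)
  paths <- as.matrix(expand.grid(rep(list(seq_len(T_)), L)))
  apply(paths, 1L, function(tg) {
    s <- trans[start, tg[1]] + trans[tg[L], stop_] + sum(em[cbind(1:L, tg)])
    if (L > 1) s <- s + sum(trans[cbind(tg[-L], tg[-1])])
    s
  })
}

oracle_logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

# Position-filtering identification oracle: keep gold-entity positions,
# tally exact agreements and non-O predictions.
oracle_identification <- function(gold, pred) {
  g <- unlist(gold); p <- unlist(pred)
  keep <- g != "O"
  g <- g[keep]; p <- p[keep]
  tp <- sum(g == p)
  npred <- sum(p != "O")
  prec <- if (npred) tp / npred else 0
  rec <- if (length(g)) tp / length(g) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1, tp = tp,
       predicted = npred, gold = length(g))
}

# Random tag sequence over the full schema.
rand_tags <- function(n, schema = tag_schema()) {
  sample(schema$tags, n, replace = TRUE)
}

# Random non-overlapping entity spans on a sentence of length n.
rand_entities <- function(n, max_ents = 3L) {
  pick <- function(v) v[sample.int(length(v), 1L)]
  classes <- entity_classes()
  out <- data.frame(class = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  used_end <- 0L
  for (k in seq_len(max_ents)) {
    if (used_end >= n) break
    s <- pick(used_end:(n - 1L))
    e <- pick((s + 1L):n)
    if (stats::runif(1) < 0.7) {
      out <- rbind(out, data.frame(class = sample(classes, 1L), start = s,
                                   end = e, stringsAsFactors = FALSE))
      used_end <- e
    } else {
      used_end <- s
    }
  }
  out
}
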