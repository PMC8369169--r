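#' Paired-seed ablation of the word-character fusion module
#'
#' For each seed, generates a high-signal synthetic train/test pair (shared
#' entity vocabulary, disjoint samples), trains two models that differ only
#' in the fusion module (`fusion` vs `"none"`) from identical
#' initialisation seeds, and compares their O-filtered identification F1 on
#' the held-out set. The quantity of interest is the per-seed delta
#' `F1(fused) - F1(baseline)` and its mean.
#'
#' @param seeds Integer vector of paired seeds.
#' @param n_train,n_test Samples per split (publication:record mixed 3:1).
#' @param fusion Fusion variant to ablate against the character-only
#'   baseline.
#' @param spec_args Overrides passed to [high_signal_spec()].
#' @param epochs,hidden,d_char,d_word,lr,batch_size Training settings
#'   shared by both arms.
#' @param verbose Print progress.
#' @return Object of class `ner_ablation`: a data frame with one row per
#'   seed (identification F1 of both arms, delta) and attribute
#'   `mean_delta`.
#' @export
run_ablation <- function(seeds = 1:3, n_train = 2000L, n_test = 500L,
                         fusion = "bilinear", spec_args = list(),
                         epochs = 3L, hidden = 24L, d_char = 24L,
                         d_word = 24L, lr = 3e-3, batch_size = 4L,
                         verbose = FALSE) {
  rows <- lapply(seeds, function(s) {
    base <- as.integer(s) * 10000L
    spec_train <- do.call(high_signal_spec, c(list(
      n_publication = as.integer(round(n_train * 0.75)),
      n_record = n_train - as.integer(round(n_train * 0.75)),
      seed = base + 1L, sample_seed = base + 2L), spec_args))
    spec_test <- do.call(high_signal_spec, c(list(
      n_publication = as.integer(round(n_test * 0.75)),
      n_record = n_test - as.integer(round(n_test * 0.75)),
      seed = base + 1L, sample_seed = base + 3L), spec_args))
    train <- generate_corpus(spec_train)
    test <- generate_corpus(spec_test)
    gold <- lapply(test$samples, `[[`, "tags")
    f1_of <- function(variant) {
      m <- ner_train(train, fusion = variant, encoder = "bilstm",
                     head = "crf", d_char = d_char, d_word = d_word,
                     hidden = hidden, epochs = epochs, lr = lr,
                     batch_size = batch_size, seed = base + 7L,
                     verbose = verbose)
      pred <- predict(m, test)
      identification_metrics(gold, pred)$f1
    }
    if (verbose) message("seed ", s, ": training fused model")
    f_fused <- f1_of(fusion)
    if (verbose) message("seed ", s, ": training baseline model")
    f_base <- f1_of("none")
    data.frame(seed = s, f1_fused = f_fused, f1_baseline = f_base,
               delta = f_fused - f_base)
  })
  out <- do.call(rbind, rows)
  structure(out, mean_delta = mean(out$delta),
            class = c("ner_ablation", "data.frame"))
}

#' @export
print.ner_ablation <- function(x, ...) {
  cat("Paired-seed fusion ablation (identification F1, held-out)\n")
  df <- as.data.frame(x)
  df$f1_fused <- round_half_away(100 * df$f1_fused)
  df$f1_baseline <- round_half_away(100 * df$f1_baseline)
  df$delta <- round_half_away(100 * df$delta)
  print(df, row.names = FALSE)
  cat(sprintf("mean delta: %+.1f F1 points\n",
              round_half_away(100 * attr(x, "mean_delta"))))
  invisible(x)
}
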