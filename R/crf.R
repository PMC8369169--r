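#' Linear-chain CRF parameters
#'
#' A transition matrix over `n_tags` real tags plus virtual START and STOP
#' states at indices `n_tags + 1` and `n_tags + 2`. Transitions into START
#' and out of STOP are masked to `-Inf` and never updated.
#'
#' @param n_tags Number of real tags.
#' @param init_scale Transitions are initialised uniform(-init_scale,
#'   init_scale); 0 gives an all-zero (uniform) chain.
#' @param seed Seed for the initialisation draw.
#' @return Object of class `crf_params` with components `transitions`
#'   (`(n_tags+2) x (n_tags+2)` matrix), `n_tags`, `start`, `stop`.
#' @export
crf_params <- function(n_tags, init_scale = 0.1, seed = 1L) {
  K <- n_tags + 2L
  trans <- if (init_scale > 0) {
    with_seed(seed, runif_mat(K, K, init_scale))
  } else {
    matrix(0, K, K)
  }
  start <- n_tags + 1L
  stop_ <- n_tags + 2L
  trans[, start] <- -Inf
  trans[stop_, ] <- -Inf
  structure(list(transitions = trans, n_tags = as.integer(n_tags),
                 start = start, stop = stop_),
            class = "crf_params")
}

check_emissions <- function(emissions, crf) {
  emissions <- rbind(emissions)
  if (ncol(emissions) != crf$n_tags) {
    stop(sprintf("emissions have %d columns but the CRF has %d tags",
                 ncol(emissions), crf$n_tags), call. = FALSE)
  }
  emissions
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Score of one tag path under a linear-chain CRF
#'
#' `score = sum_t emission[t, tag_t] + transition(START -> tag_1) +
#' sum_t transition(tag_t -> tag_{t+1}) + transition(tag_L -> STOP)`.
#'
#' @param emissions `L x n_tags` matrix of per-position tag scores.
#' @param tags Integer vector of 1-based tag indices, length `L`.
#' @param crf [crf_params()].
#' @return Scalar path score.
#' @export
crf_path_score <- function(emissions, tags, crf) {
  emissions <- check_emissions(emissions, crf)
  L <- nrow(emissions)
  tags <- as.integer(tags)
  if (length(tags) != L || any(tags < 1L | tags > crf$n_tags)) {
    stop("tag indices must be in 1..n_tags and match the emission length",
         call. = FALSE)
  }
  tr <- crf$transitions
  s <- sum(emissions[cbind(seq_len(L), tags)]) +
    tr[crf$start, tags[1L]] + tr[tags[L], crf$stop]
  if (L > 1L) s <- s + sum(tr[cbind(tags[-L], tags[-1L])])
  s
}

#' Log-partition function of a linear-chain CRF
#'
#' The log of the sum over all `n_tags^L` tag paths of `exp(path score)`,
#' computed by the forward recursion in log space.
#'
#' @inheritParams crf_path_score
#' @return Scalar `log Z`.
#' @export
crf_log_partition <- function(emissions, crf) {
  emissions <- check_emissions(emissions, crf)
  L <- nrow(emissions); T_ <- crf$n_tags
  tr <- crf$transitions
  alpha <- tr[crf$start, seq_len(T_)] + emissions[1L, ]
  if (L > 1L) {
    for (t in 2:L) {
      alpha <- vapply(seq_len(T_), function(j) {
        logsumexp(alpha + tr[seq_len(T_), j])
      }, numeric(1)) + emissions[t, ]
    }
  }
  logsumexp(alpha + tr[seq_len(T_), crf$stop])
}

#' Viterbi decoding of a linear-chain CRF
#'
#' Returns the highest-scoring tag path and its score. Ties are broken by
#' the lowest tag index at each backtracking step.
#'
#' @inheritParams crf_path_score
#' @return List with `tags` (1-based indices) and `score`, satisfying
#'   `score == crf_path_score(emissions, tags, crf)`.
#' @export
crf_viterbi <- function(emissions, crf) {
  emissions <- check_emissions(emissions, crf)
  L <- nrow(emissions); T_ <- crf$n_tags
  tr <- crf$transitions
  delta <- tr[crf$start, seq_len(T_)] + emissions[1L, ]
  back <- matrix(0L, L, T_)
  if (L > 1L) {
    for (t in 2:L) {
      new_delta <- numeric(T_)
      for (j in seq_len(T_)) {
        v <- delta + tr[seq_len(T_), j]
        b <- which.max(v)            # first max = lowest index
        back[t, j] <- b
        new_delta[j] <- v[b] + emissions[t, j]
      }
      delta <- new_delta
    }
  }
  final <- delta + tr[seq_len(T_), crf$stop]
  tags <- integer(L)
  tags[L] <- which.max(final)
  if (L > 1L) {
    for (t in L:2) tags[t - 1L] <- back[t, tags[t]]
  }
  list(tags = tags, score = crf_path_score(emissions, tags, crf))
}

#' CRF negative log-likelihood and analytic gradients
#'
#' `nll = log Z - path score(tags)`, with gradients with respect to the
#' emissions and the transition matrix obtained from the forward-backward
#' marginals. Used as the training objective of the CRF head; exposed so
#' the gradients can be verified against finite differences.
#'
#' @inheritParams crf_path_score
#' @return List with `nll`, `d_emissions` (`L x n_tags`) and
#'   `d_transitions` (same shape as `crf$transitions`; zero at masked
#'   entries).
#' @export
crf_nll <- function(emissions, tags, crf) {
  emissions <- check_emissions(emissions, crf)
  res <- cpp_crf_nll(emissions, crf$transitions, as.integer(tags) - 1L)
  res$d_transitions[!is.finite(crf$transitions)] <- 0
  res
}
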